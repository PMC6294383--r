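#' Probability of co-occurrence at exactly j sites
#'
#' Probabilistic model of pairwise co-occurrence: given `n_sites` equally
#' likely sites, a species observed at `n_a` of them and another at `n_b`,
#' the number of shared sites under random, independent placement follows the
#' hypergeometric law
#' \deqn{P(j) = \binom{n_a}{j}\binom{N - n_a}{n_b - j} / \binom{N}{n_b}.}
#' Probabilities are evaluated with log-gamma arithmetic ([stats::dhyper()])
#' so they stay finite for site counts in the thousands.
#'
#' @param n_sites Total number of sites, N.
#' @param n_a,n_b Occurrence counts of the two species.
#' @param j Number of shared sites; may be a vector. Must lie in
#'   `0..min(n_a, n_b)`; values below the feasible lower bound
#'   `max(0, n_a + n_b - N)` return probability 0.
#'
#' @return Numeric vector of probabilities; for fixed N, n_a, n_b they sum to
#'   1 over the feasible range of `j`.
#' @export
#'
#' @examples
#' cooccurrence_probability(3, 1, 1, 1)   # 1/3
#' sum(cooccurrence_probability(10, 5, 5, 0:5))  # 1
cooccurrence_probability <- function(n_sites, n_a, n_b, j) {
  n_sites <- check_count(n_sites, "n_sites")
  n_a <- check_count(n_a, "n_a")
  n_b <- check_count(n_b, "n_b")
  if (n_a > n_sites || n_b > n_sites) {
    stop_domain("occurrence counts cannot exceed the number of sites")
  }
  if (length(j) < 1L || !is.numeric(j) || anyNA(j) || any(j != floor(j))) {
    stop_domain("`j` must be integer-valued")
  }
  if (any(j < 0L) || any(j > min(n_a, n_b))) {
    stop_domain("`j` must lie in 0..min(n_a, n_b)")
  }
  dhyper(j, m = n_a, n = n_sites - n_a, k = n_b)
}

#' Observed vs expected co-occurrence for one species pair
#'
#' Compares the observed shared-site count of two species with its
#' expectation `n_a * n_b / N` under the probabilistic model, and reports
#' exact lower/upper tail probabilities and a standardized effect size
#' `(observed - expected) / N`. The raw difference `observed - expected` is
#' also reported (`effect_raw`); the standardized form is the default
#' summary because it is bounded in `[-1, 1]` and comparable across basins
#' with different site counts.
#'
#' @param occ A validated `poolnet_occurrence`.
#' @param a,b Species ids present in `occ`.
#' @return A one-row tibble: `species_a`, `species_b`, `n_sites`, `n_a`,
#'   `n_b`, `observed`, `expected`, `effect`, `effect_raw`, `p_le`, `p_ge`.
#' @export
#'
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("A", "B")))
#' pair_stats(occurrence_matrix(m), "A", "B")
pair_stats <- function(occ, a, b) {
  occ <- occurrence_matrix(occ)
  for (sp in c(a, b)) {
    if (!sp %in% colnames(occ)) stop_domain(sprintf("unknown species id '%s'", sp))
  }
  n <- nrow(occ)
  n_a <- sum(occ[, a])
  n_b <- sum(occ[, b])
  obs <- sum(occ[, a] * occ[, b])
  expected <- n_a * n_b / n
  tibble::tibble(
    species_a = a, species_b = b,
    n_sites = n, n_a = n_a, n_b = n_b,
    observed = obs, expected = expected,
    effect = (obs - expected) / n,
    effect_raw = obs - expected,
    p_le = phyper(obs, m = n_a, n = n - n_a, k = n_b),
    p_ge = phyper(obs - 1L, m = n_a, n = n - n_a, k = n_b, lower.tail = FALSE)
  )
}

#' Pairwise effect-size table for all species pairs
#'
#' One row per unordered species pair, including pairs that never co-occur
#' (`observed = 0`), so that within- vs among-group effect summaries cover
#' the complete pair set. Tail probabilities are reported, not used to drop
#' pairs: the networks in this package are built from raw co-occurrence, and
#' significance thresholding of edges is deliberately left out.
#'
#' @param occ A validated `poolnet_occurrence`.
#' @return A tibble with `choose(n_species, 2)` rows, columns as in
#'   [pair_stats()] (pairs ordered by column position).
#' @export
effect_size_table <- function(occ) {
  occ <- occurrence_matrix(occ)
  if (ncol(occ) < 2L) stop_degenerate("need at least 2 species for an effect-size table")
  sp <- colnames(occ)
  n <- nrow(occ)
  counts <- unname(colSums(occ))
  co <- crossprod(occ)
  idx <- which(upper.tri(co), arr.ind = TRUE)
  n_a <- counts[idx[, 1L]]
  n_b <- counts[idx[, 2L]]
  obs <- as.integer(co[idx])
  expected <- n_a * n_b / n
  tibble::tibble(
    species_a = sp[idx[, 1L]],
    species_b = sp[idx[, 2L]],
    n_sites = n,
    n_a = as.integer(n_a), n_b = as.integer(n_b),
    observed = obs, expected = expected,
    effect = (obs - expected) / n,
    effect_raw = obs - expected,
    p_le = phyper(obs, m = n_a, n = n - n_a, k = n_b),
    p_ge = phyper(obs - 1L, m = n_a, n = n - n_a, k = n_b, lower.tail = FALSE)
  )
}
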