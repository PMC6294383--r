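#' Congruence between two partitions of the same species
#'
#' Congruence `C` is the maximum proportion of species assigned to the same
#' group by two partitions, taken over all one-to-one matchings of the
#' group labels of `b` onto those of `a` (labels are arbitrary, so a direct
#' label-by-label comparison would understate agreement). With `k` groups on
#' both sides this amounts to examining the `k!` label "rotations"; the
#' exhaustive search is used when the smaller label set has at most
#' `exhaustive_max` groups and records how many matchings it examined.
#' For larger label sets the identical optimum is found as a maximum-weight
#' bipartite assignment on the group-by-group contingency table
#' ([clue::solve_LSAP()]).
#'
#' When the two partitions have different numbers of groups the matching is
#' injective from the smaller label set into the larger, unmatched groups
#' contribute nothing, and the result is flagged as an `extension` (in that
#' situation perfect congruence is impossible by construction). Species
#' present in only one partition are excluded before comparison and listed
#' in the result.
#'
#' @param a,b Partitions (see [as_partition()]); `a` is the reference (e.g.
#'   network modules), `b` the partition whose labels are matched onto it
#'   (e.g. PAM clusters).
#' @param exhaustive_max Largest smaller-side group count for which the
#'   exhaustive search is used.
#' @return A `poolnet_congruence` object: list with `c` (`= n_matched /
#'   n_total`), `n_matched`, `n_total`, `matching` (tibble `label_a`,
#'   `label_b`), `n_matchings_examined` (`NA` for the assignment path),
#'   `extension`, `excluded`.
#' @export
#'
#' @examples
#' a <- c(A = 1, B = 1, C = 2, D = 2)
#' b <- c(A = 9, B = 9, C = 9, D = 5)
#' congruence(a, b)$c  # 0.75
congruence <- function(a, b, exhaustive_max = 6L) {
  al <- align_partitions(a, b)
  pa <- unclass(al$a)
  pb <- unclass(al$b)
  n <- length(pa)
  tab <- table(pa, pb)
  ka <- nrow(tab)
  kb <- ncol(tab)

  res <- congruence_matching(unclass(tab), exhaustive_max = exhaustive_max)
  matching <- tibble::tibble(
    label_a = as.integer(rownames(tab)[res$rows]),
    label_b = as.integer(colnames(tab)[res$cols])
  )
  structure(list(
    c = res$n_matched / n,
    n_matched = as.integer(res$n_matched),
    n_total = n,
    k_a = ka, k_b = kb,
    matching = matching,
    n_matchings_examined = res$n_examined,
    extension = ka != kb,
    excluded = al$excluded,
    p_raw = NA_real_, p = NA_real_, n_perm = NA_integer_
  ), class = "poolnet_congruence")
}

# Maximum-agreement matching on a contingency table. Returns matched row and
# column indices, the matched species count, and (for the exhaustive path)
# the number of matchings examined.
congruence_matching <- function(tab, exhaustive_max = 6L) {
  ka <- nrow(tab)
  kb <- ncol(tab)
  transposed <- ka > kb
  if (transposed) tab <- t(tab)  # rows = smaller label set
  ks <- nrow(tab)
  kl <- ncol(tab)
  if (ks <= exhaustive_max) {
    perms <- injections(kl, ks)
    scores <- vapply(perms, function(idx) {
      sum(tab[cbind(seq_len(ks), idx)])
    }, numeric(1))
    best <- perms[[which.max(scores)]]
    out <- list(rows = seq_len(ks), cols = best,
                n_matched = max(scores), n_examined = length(perms))
  } else {
    sol <- clue::solve_LSAP(tab, maximum = TRUE)
    out <- list(rows = seq_len(ks), cols = as.integer(sol),
                n_matched = sum(tab[cbind(seq_len(ks), as.integer(sol))]),
                n_examined = NA_integer_)
  }
  if (transposed) out[c("rows", "cols")] <- out[c("cols", "rows")]
  out
}

# All injective maps of 1..k_small into 1..k_large (k_large!/(k_large-k_small)!
# of them; k! label rotations in the square case).
injections <- function(k_large, k_small) {
  stopifnot(k_small <= k_large)
  grow <- function(prefix) {
    if (length(prefix) == k_small) return(list(prefix))
    remaining <- setdiff(seq_len(k_large), prefix)
    unlist(lapply(remaining, function(r) grow(c(prefix, r))), recursive = FALSE)
  }
  grow(integer(0))
}

#' Permutation test for congruence
#'
#' Tests whether the observed congruence exceeds what random assignment of
#' species to groups of the same sizes would produce. Each permutation
#' shuffles species across the groups of `b`, holding group sizes fixed, and
#' `C` is recomputed. The add-one p-value `(count + 1) / (n_perm + 1)` is
#' reported alongside the raw proportion `count / n_perm` (the raw form can
#' be 0, conventionally reported as `p < 1/n_perm`).
#'
#' @inheritParams congruence
#' @param n_perm Number of permutations (>= 1; 999 is the conventional
#'   default).
#' @param seed Integer seed.
#' @return A `poolnet_congruence` object with `p` (add-one), `p_raw` and
#'   `n_perm` filled in.
#' @export
congruence_test <- function(a, b, n_perm = 999L, seed = NULL, exhaustive_max = 6L) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  obs <- congruence(a, b, exhaustive_max = exhaustive_max)
  al <- align_partitions(a, b)
  pa <- unclass(al$a)
  pb <- unclass(al$b)
  n <- length(pa)
  ka <- max(pa)
  kb <- max(pb)
  small_first <- ka <= kb
  perms <- if (min(ka, kb) <= exhaustive_max) injections(max(ka, kb), min(ka, kb))
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pbp <- pb[sample.int(n)]
      tab <- matrix(tabulate((pa - 1L) * kb + pbp, ka * kb), nrow = ka, byrow = TRUE)
      if (!small_first) tab <- t(tab)
      c_perm <- if (!is.null(perms)) {
        ks <- nrow(tab)
        max(vapply(perms, function(idx) sum(tab[cbind(seq_len(ks), idx)]), numeric(1)))
      } else {
        sol <- clue::solve_LSAP(tab, maximum = TRUE)
        sum(tab[cbind(seq_len(nrow(tab)), as.integer(sol))])
      }
      if (c_perm >= obs$n_matched) hits <- hits + 1L
    }
    hits
  })
  obs$p_raw <- count / n_perm
  obs$p <- (count + 1L) / (n_perm + 1L)
  obs$n_perm <- n_perm
  obs
}

#' @export
print.poolnet_congruence <- function(x, ...) {
  cat(sprintf(
    "<poolnet_congruence: C = %.3f (%d/%d species)%s%s>\n",
    x$c, x$n_matched, x$n_total,
    if (!is.na(x$p)) sprintf(", p = %.4g (%d perms)", x$p, x$n_perm) else "",
    if (x$extension) " [unequal group counts: injective extension]" else ""
  ))
  invisible(x)
}

#' @describeIn congruence Label matching as a tibble.
#' @param x A `poolnet_congruence` object.
#' @param ... Unused.
#' @export
tidy.poolnet_congruence <- function(x, ...) x$matching

#' @describeIn congruence One-row summary (C, counts, p-values).
#' @export
glance.poolnet_congruence <- function(x, ...) {
  tibble::tibble(
    c = x$c, n_matched = x$n_matched, n_total = x$n_total,
    k_a = x$k_a, k_b = x$k_b,
    p = x$p, p_raw = x$p_raw, n_perm = x$n_perm,
    extension = x$extension, n_excluded = length(x$excluded),
    matching = paste(sprintf("%d>%d", x$matching$label_a, x$matching$label_b),
                     collapse = ";")
  )
}
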