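#' Partition species around medoids (PAM)
#'
#' k-medoid clustering of the species-by-species Jaccard dissimilarity
#' matrix: the greedy BUILD phase seeds `k` medoids, then the SWAP phase
#' exchanges medoids with non-medoids until no single swap lowers the total
#' cost (the sum of each species' dissimilarity to its medoid). Because SWAP
#' only guarantees a local optimum, the search is additionally restarted
#' from `nstart - 1` random medoid sets and the lowest-cost local optimum is
#' returned; each returned solution still satisfies the swap-local-optimality
#' contract. Assignment ties (equal dissimilarity to two medoids) are broken
#' toward the medoid with the lower species index, for determinism.
#'
#' @param d Square symmetric dissimilarity matrix with species dimnames (or
#'   a [stats::dist]).
#' @param k Number of clusters, `1 <= k <= n_species`.
#' @param seed Integer seed for the random restarts.
#' @param nstart Total number of PAM runs (1 deterministic BUILD start plus
#'   `nstart - 1` random starts).
#' @return A `poolnet_pam` object: list with `partition` (source
#'   `"cluster"`), `medoids`, `total_cost`, `k`.
#' @export
#'
#' @examples
#' m <- matrix(c(1,1,0,0, 1,0,0,0, 0,0,1,1), nrow = 4,
#'             dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
#' d <- jaccard_dissimilarity(occurrence_matrix(m))
#' pam_cluster(d, k = 2, seed = 1)
pam_cluster <- function(d, k, seed = NULL, nstart = 5L) {
  d <- as_dissimilarity(d)
  n <- nrow(d)
  k <- check_count(k, "k", min = 1L)
  nstart <- check_count(nstart, "nstart", min = 1L)
  if (k > n) stop_domain(sprintf("k = %d exceeds the number of species (%d)", k, n))
  dd <- stats::as.dist(d)

  cost_of <- function(medoid_idx) {
    sum(apply(d[, medoid_idx, drop = FALSE], 1L, min))
  }
  if (k == n) {
    # trivial solution: every species is its own medoid
    return(structure(list(
      partition = as_partition(stats::setNames(seq_len(n), rownames(d)),
                               source = "cluster"),
      medoids = rownames(d), total_cost = 0, k = k
    ), class = "poolnet_pam"))
  }
  with_seed(seed, {
    fit <- cluster::pam(dd, k = k, diss = TRUE)
    best_idx <- match(fit$medoids, rownames(d))
    best_cost <- cost_of(best_idx)
    if (nstart > 1L && k < n) {
      for (r in seq_len(nstart - 1L)) {
        start <- sample.int(n, k)
        fit_r <- cluster::pam(dd, k = k, diss = TRUE, medoids = start)
        idx_r <- match(fit_r$medoids, rownames(d))
        cost_r <- cost_of(idx_r)
        if (cost_r < best_cost - 1e-12) {
          best_idx <- idx_r
          best_cost <- cost_r
        }
      }
    }
    best_idx <- sort(best_idx)
    # deterministic assignment: nearest medoid, ties to the lower species index
    assign_idx <- apply(d[, best_idx, drop = FALSE], 1L, which.min)
    labels <- stats::setNames(as.integer(assign_idx), rownames(d))
    labels[best_idx] <- seq_along(best_idx)  # each medoid anchors its own group
    structure(list(
      partition = as_partition(labels, source = "cluster"),
      medoids = rownames(d)[best_idx],
      total_cost = cost_of(best_idx),
      k = k
    ), class = "poolnet_pam")
  })
}

#' @export
print.poolnet_pam <- function(x, ...) {
  cat(sprintf(
    "<poolnet_pam: k = %d, total cost = %.4f, medoids: %s>\n",
    x$k, x$total_cost, paste(x$medoids, collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn pam_cluster Per-species cluster membership as a tibble.
#' @param x A `poolnet_pam` object.
#' @param ... Unused.
#' @export
tidy.poolnet_pam <- function(x, ...) {
  dplyr::mutate(tidy(x$partition), medoid = x$medoids[.data$group])
}

#' @describeIn pam_cluster One-row summary.
#' @export
glance.poolnet_pam <- function(x, ...) {
  tibble::tibble(k = x$k, total_cost = x$total_cost, n_species = length(x$partition))
}

as_dissimilarity <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_domain("`d` must be a square matrix or dist")
  if (is.null(rownames(d))) stop_domain("`d` needs species ids as dimnames")
  if (max(abs(d - t(d))) > 1e-8) stop_domain("`d` must be symmetric")
  if (any(d < -1e-12)) stop_domain("dissimilarities must be non-negative")
  d
}

#' Gap statistic for the number of PAM clusters
#'
#' Chooses the number of clusters by comparing the observed within-cluster
#' dispersion with that of reference data free of cluster structure. Because
#' the input is a dissimilarity matrix rather than a feature matrix, the
#' reference distribution is built by classical multidimensional scaling:
#' species are embedded in the components carrying at least 95% of the
#' positive eigenvalue mass, reference points are drawn uniformly within the
#' embedding's bounding box, and Euclidean dissimilarities are recomputed.
#' Dispersion `W_k` is PAM's own objective (summed dissimilarity of species
#' to their medoids), so the quantity being compared is the one being
#' optimised.
#'
#' `gap(k) = mean_b log W*_kb - log W_k`; the default selection is the 1-SE
#' rule: the smallest `k` with `gap(k) >= gap(k+1) - se(k+1)`. `k_opt = 1`
#' is a legal outcome (no multi-cluster structure).
#'
#' @inheritParams pam_cluster
#' @param k_max Largest number of clusters evaluated.
#' @param b_refs Number of reference data sets.
#' @param seed Integer seed (reference sampling and PAM restarts).
#' @param rule `"firstSEmax"` (1-SE rule, default) or `"globalmax"`.
#' @return A `poolnet_gap` object: list with `profile` (tibble `k`, `gap`,
#'   `se`, `log_w`), `k_opt`, `b_refs`, `seed`, `rule`.
#' @export
gap_statistic <- function(d, k_max, b_refs = 50L, seed = NULL,
                          rule = c("firstSEmax", "globalmax"), nstart = 5L) {
  rule <- match.arg(rule)
  d <- as_dissimilarity(d)
  n <- nrow(d)
  k_max <- check_count(k_max, "k_max", min = 1L)
  b_refs <- check_count(b_refs, "b_refs", min = 1L)
  if (k_max >= n) stop_domain("k_max must be smaller than the number of species")

  seeds <- derive_seeds(seed, 2L + b_refs)
  ks <- seq_len(k_max)
  log_w <- vapply(ks, function(k) {
    log(max(pam_cluster(d, k, seed = seeds[[1L]], nstart = nstart)$total_cost,
            .Machine$double.eps))
  }, numeric(1))

  # MDS embedding retaining >= 95% of positive eigenvalue mass
  # non-Euclidean input (e.g. Jaccard) yields some negative eigenvalues;
  # only the positive part carries the embedding
  mds <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  pos <- mds$eig > 1e-12
  if (!any(pos)) stop_degenerate("dissimilarity matrix has no positive MDS eigenvalues")
  eig <- mds$eig[pos]
  m_dim <- which(cumsum(eig) / sum(eig) >= 0.95)[1L]
  pts <- mds$points[, seq_len(m_dim), drop = FALSE]
  lo <- apply(pts, 2L, min)
  hi <- apply(pts, 2L, max)

  log_w_ref <- matrix(NA_real_, nrow = b_refs, ncol = k_max)
  for (b in seq_len(b_refs)) {
    ref <- with_seed(seeds[[2L + b]], {
      matrix(runif(n * m_dim, min = rep(lo, each = n), max = rep(hi, each = n)),
             nrow = n, ncol = m_dim)
    })
    rownames(ref) <- rownames(d)
    d_ref <- as.matrix(dist(ref))
    for (k in ks) {
      log_w_ref[b, k] <- log(max(
        pam_cluster(d_ref, k, seed = seeds[[2L]], nstart = nstart)$total_cost,
        .Machine$double.eps
      ))
    }
  }
  gap <- colMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 2L, sd) * sqrt(1 + 1 / b_refs)

  k_opt <- if (rule == "globalmax") {
    ks[which.max(gap)]
  } else {
    hit <- which(gap[-k_max] >= gap[-1L] - se[-1L])
    if (k_max == 1L || length(hit) == 0L) k_max else ks[hit[1L]]
  }
  structure(list(
    profile = tibble::tibble(k = ks, gap = gap, se = se, log_w = log_w),
    k_opt = k_opt, b_refs = b_refs, seed = seed, rule = rule
  ), class = "poolnet_gap")
}

#' @export
print.poolnet_gap <- function(x, ...) {
  cat(sprintf(
    "<poolnet_gap: k_opt = %d (%s rule, %d reference sets)>\n",
    x$k_opt, x$rule, x$b_refs
  ))
  print(x$profile)
  invisible(x)
}

#' @describeIn gap_statistic Gap profile as a tibble.
#' @param x A `poolnet_gap` object.
#' @param ... Unused.
#' @export
tidy.poolnet_gap <- function(x, ...) x$profile

#' @describeIn gap_statistic One-row summary.
#' @export
glance.poolnet_gap <- function(x, ...) {
  tibble::tibble(k_opt = x$k_opt, b_refs = x$b_refs, rule = x$rule,
                 seed = x$seed %||% NA_integer_)
}
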