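# Independent oracles and fixture builders shared across the suite. All are
# deliberately naive (double loops, exhaustive enumeration) so they stay
# independent of the implementation paths they check.

rand_occ <- function(n_sites, n_species, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * n_species, 1L, p), nrow = n_sites,
              dimnames = list(sprintf("s%03d", seq_len(n_sites)),
                              sprintf("sp%02d", seq_len(n_species))))
  m
}

# valid random occurrence matrix: no empty species or sites
rand_occ_valid <- function(n_sites, n_species, p = 0.4, seed = 1) {
  m <- rand_occ(n_sites, n_species, p, seed)
  i <- seed
  while (any(colSums(m) == 0) || any(rowSums(m) == 0)) {
    i <- i + 1000
    m <- rand_occ(n_sites, n_species, p, i)
  }
  m
}

# brute-force pairwise co-occurrence counts (double loop over column pairs)
brute_edge_list <- function(m) {
  sp <- colnames(m)
  out <- list()
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      shared <- sum(m[, i] == 1 & m[, j] == 1)
      if (shared >= 1) {
        out[[length(out) + 1]] <- data.frame(
          species_a = sp[i], species_b = sp[j], n_shared_sites = shared
        )
      }
    }
  }
  do.call(rbind, out)
}

# per-pair Jaccard via explicit set arithmetic
brute_jaccard <- function(m) {
  sp <- colnames(m)
  d <- matrix(0, ncol(m), ncol(m), dimnames = list(sp, sp))
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      A <- which(m[, i] == 1)
      B <- which(m[, j] == 1)
      d[i, j] <- 1 - length(intersect(A, B)) / length(union(A, B))
    }
  }
  d
}

# all permutations of 1..n (recursive, independent of any package code)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# brute-force congruence: max co-assignment count over all injective label
# matchings of the smaller label set into the larger (k! enumeration)
brute_congruence <- function(a, b) {
  shared <- intersect(names(a), names(b))
  pa <- as.integer(factor(a[shared]))
  pb <- as.integer(factor(b[shared]))
  ka <- max(pa); kb <- max(pb)
  if (ka > kb) { tmp <- pa; pa <- pb; pb <- tmp; tmp <- ka; ka <- kb; kb <- tmp }
  tab <- matrix(0L, ka, kb)
  for (i in seq_along(pa)) tab[pa[i], pb[i]] <- tab[pa[i], pb[i]] + 1L
  best <- 0L
  for (perm in all_perms(kb)) {
    idx <- perm[seq_len(ka)]
    best <- max(best, sum(tab[cbind(seq_len(ka), idx)]))
  }
  list(n_matched = best, c = best / length(shared))
}

# enumerate all set partitions of n elements as restricted growth strings
set_partitions <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) grow(c(labels, lab), max(k, lab))
  }
  grow(integer(0), 0L)
  out
}

# exhaustive maximum modularity over all partitions (igraph::modularity as
# the independent scoring routine)
brute_max_q <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  for (labels in set_partitions(n)) {
    q <- igraph::modularity(g, labels)
    if (q > best) best <- q
  }
  best
}

# Fig-2-style worked example: 12 species, 3 modules (5/3/4) vs 3 clusters
# (4/4/4) whose best matching co-assigns exactly 8 species
fig2_partitions <- function() {
  modules <- c(A = 1, B = 1, C = 1, D = 1, E = 1,
               F = 2, G = 2, H = 2,
               I = 3, J = 3, K = 3, L = 3)
  clusters <- c(A = 1, B = 1, C = 1, J = 1,
                F = 2, G = 2, D = 2, E = 2,
                I = 3, K = 3, L = 3, H = 3)
  list(modules = modules, clusters = clusters)
}

# exact spatial-clustering p-value by enumerating every assignment of
# species to two groups of three (choose(6, 3) = 20 splits)
exact_spatial_p <- function(coords) {
  stopifnot(nrow(coords) == 6)
  dmat <- as.matrix(dist(coords))
  ratio_of <- function(g1) {
    labels <- ifelse(seq_len(6) %in% g1, 1L, 2L)
    same <- outer(labels, labels, "==")
    ut <- upper.tri(dmat)
    mean(dmat[ut & same]) / mean(dmat[ut & !same])
  }
  splits <- combn(6, 3)
  ratios <- apply(splits, 2, ratio_of)
  obs <- ratio_of(1:3)
  list(obs = obs, p_exact = mean(ratios <= obs + 1e-12))
}

rigid_motion <- function(coords, angle, dx, dy) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(as.matrix(coords) %*% R, 2, c(-dx, -dy))
}
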