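#' Interpolate a species range centroid from occupied units
#'
#' A species' range centroid is the unweighted arithmetic mean of the
#' (planar, equal-area projected) centroids of all occupancy units in its
#' range, in km. No geodesic computation is performed: coordinates are
#' assumed already projected.
#'
#' @param units A data frame with columns `unit_id`, `x_km`, `y_km` (one row
#'   per occupancy unit).
#' @param occupied Character vector of occupied unit ids.
#' @return A one-row tibble with `x_km`, `y_km`.
#' @export
#'
#' @examples
#' units <- tibble::tibble(unit_id = c("u1", "u2", "u3"),
#'                         x_km = c(0, 2, 1), y_km = c(0, 0, 3))
#' interpolate_centroid(units, c("u1", "u2", "u3"))  # (1, 1)
interpolate_centroid <- function(units, occupied) {
  units <- validate_units(units)
  if (length(occupied) == 0L) stop_domain("empty occupancy: no units to average")
  missing <- setdiff(occupied, units$unit_id)
  if (length(missing) > 0L) {
    stop_domain(sprintf("unknown unit id(s): %s", paste(head(missing, 5L), collapse = ", ")))
  }
  sel <- units[match(occupied, units$unit_id), ]
  tibble::tibble(x_km = mean(sel$x_km), y_km = mean(sel$y_km))
}

validate_units <- function(units) {
  if (!is.data.frame(units) || !all(c("unit_id", "x_km", "y_km") %in% names(units))) {
    stop_domain("`units` needs columns unit_id, x_km, y_km")
  }
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) stop_domain("duplicate unit ids")
  if (!all(is.finite(units$x_km)) || !all(is.finite(units$y_km))) {
    stop_domain("unit coordinates must be finite")
  }
  tibble::as_tibble(units)
}

#' Range centroids for every species
#'
#' Applies [interpolate_centroid()] to each species of a species-by-unit
#' occupancy table. Species occupying no unit are excluded from the result
#' and listed in the `missing_centroid` attribute (they cannot take part in
#' spatial tests).
#'
#' @inheritParams interpolate_centroid
#' @param occupancy A 0/1 matrix with species row names and unit column
#'   names, or a data frame whose first column holds species ids.
#' @return A tibble with columns `species`, `x_km`, `y_km` and attribute
#'   `missing_centroid`.
#' @export
species_centroids <- function(units, occupancy) {
  units <- validate_units(units)
  if (is.data.frame(occupancy)) {
    sp <- as.character(occupancy[[1L]])
    occupancy <- as.matrix(occupancy[, -1L, drop = FALSE])
    rownames(occupancy) <- sp
  }
  if (is.null(rownames(occupancy)) || is.null(colnames(occupancy))) {
    stop_domain("`occupancy` needs species row names and unit column names")
  }
  res <- purrr::map_dfr(rownames(occupancy), function(sp) {
    occ_units <- colnames(occupancy)[occupancy[sp, ] == 1]
    if (length(occ_units) == 0L) return(NULL)
    dplyr::bind_cols(tibble::tibble(species = sp),
                     interpolate_centroid(units, occ_units))
  })
  missing <- setdiff(rownames(occupancy), res$species)
  if (length(missing) > 0L) {
    rlang::warn(sprintf("%d species without occupied units have no centroid: %s",
                        length(missing), paste(head(missing, 5L), collapse = ", ")))
  }
  attr(res, "missing_centroid") <- missing
  res
}

#' Within- vs among-group mean centroid distances
#'
#' The spatial-clustering statistic: `md_within` is the mean Euclidean
#' distance (km) over all same-group species pairs, pooled across groups
#' (unweighted by group size); `md_among` the mean over all different-group
#' pairs; their ratio is below 1 when groups are spatially clustered.
#' Singleton groups contribute no within pairs but do contribute among
#' pairs. A size-weighted MRPP delta (`sum_g n_g/N * mean within-group
#' distance`) is also reported for comparability with standard MRPP
#' routines.
#'
#' @param centroids Tibble from [species_centroids()] (`species`, `x_km`,
#'   `y_km`).
#' @param partition Partition of (a subset of) the centroid species; every
#'   partitioned species must have a centroid.
#' @return A `poolnet_spatial` object: list with `md_within`, `md_among`,
#'   `ratio`, `delta`, `n_within_pairs`, `n_among_pairs`, `k`, `n_species`
#'   (p-value fields `NA` until [spatial_test()]).
#' @export
#'
#' @examples
#' cen <- tibble::tibble(species = c("a", "b", "c", "d"),
#'                       x_km = c(0, 0, 10, 10), y_km = c(0, 1, 0, 1))
#' mean_distance_ratio(cen, c(a = 1, b = 1, c = 2, d = 2))
mean_distance_ratio <- function(centroids, partition) {
  prep <- prep_spatial(centroids, partition)
  res <- spatial_stats(prep$dmat, prep$labels)
  structure(c(res, list(
    k = max(prep$labels), n_species = length(prep$labels),
    p = NA_real_, p_raw = NA_real_, n_perm = NA_integer_,
    statistic = NA_character_, direction = NA_character_
  )), class = "poolnet_spatial")
}

prep_spatial <- function(centroids, partition) {
  p <- as_partition(partition)
  if (!all(c("species", "x_km", "y_km") %in% names(centroids))) {
    stop_domain("`centroids` needs columns species, x_km, y_km")
  }
  missing <- setdiff(names(p), centroids$species)
  if (length(missing) > 0L) {
    stop_domain(sprintf("no centroid for partitioned species: %s",
                        paste(head(missing, 5L), collapse = ", ")))
  }
  if (n_groups(p) < 2L) {
    stop_single_group("among-group comparison impossible: partition has a single group")
  }
  sel <- centroids[match(names(p), centroids$species), ]
  dmat <- as.matrix(dist(cbind(sel$x_km, sel$y_km)))
  labels <- as.integer(p)
  if (all(tabulate(labels) <= 1L)) stop_degenerate("no within-group pairs: all groups are singletons")
  list(dmat = dmat, labels = labels)
}

# Pooled within/among mean distances plus size-weighted MRPP delta, from a
# precomputed distance matrix and integer labels.
spatial_stats <- function(dmat, labels) {
  same <- outer(labels, labels, "==")
  ut <- upper.tri(dmat)
  w <- dmat[ut & same]
  a <- dmat[ut & !same]
  k <- max(labels)
  sizes <- tabulate(labels, k)
  d_g <- vapply(seq_len(k), function(g) {
    if (sizes[g] < 2L) return(0)
    sub <- dmat[labels == g, labels == g]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  list(
    md_within = mean(w),
    md_among = mean(a),
    ratio = mean(w) / mean(a),
    delta = sum(sizes / sum(sizes) * d_g),
    n_within_pairs = length(w),
    n_among_pairs = length(a)
  )
}

#' Permutation test of spatial clustering (MRPP-style)
#'
#' Tests whether species in the same group have closer range centroids than
#' expected if species were shuffled among groups at random (group sizes
#' held fixed). The test statistic is by default the within:among mean
#' distance ratio; `statistic = "delta"` uses the size-weighted MRPP delta
#' instead. Following the multi-response permutation procedure, the p-value
#' is the (add-one) proportion of permutations whose statistic is as small
#' as or smaller than the observed one — i.e. spatial clustering at least
#' as strong as observed. `direction = "literal"` instead reports the
#' proportion of permutations in which `md_within >= md_among`, a
#' descriptive quantity (approximately 0.5 under any null) retained for
#' audit only.
#'
#' @inheritParams mean_distance_ratio
#' @param n_perm Number of permutations (999 conventional).
#' @param seed Integer seed.
#' @param statistic `"ratio"` (default) or `"delta"`.
#' @param direction `"mrpp"` (default) or `"literal"`.
#' @return A `poolnet_spatial` object with `p`, `p_raw`, `n_perm`,
#'   `statistic`, `direction` filled in.
#' @export
spatial_test <- function(centroids, partition, n_perm = 999L, seed = NULL,
                         statistic = c("ratio", "delta"),
                         direction = c("mrpp", "literal")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  prep <- prep_spatial(centroids, partition)
  res <- spatial_stats(prep$dmat, prep$labels)
  obs <- res[[if (statistic == "ratio") "ratio" else "delta"]]
  n <- length(prep$labels)
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      perm <- spatial_stats(prep$dmat, prep$labels[sample.int(n)])
      hit <- if (direction == "literal") {
        perm$md_within >= perm$md_among
      } else {
        perm[[if (statistic == "ratio") "ratio" else "delta"]] <= obs + 1e-12
      }
      if (hit) hits <- hits + 1L
    }
    hits
  })
  structure(c(res, list(
    k = max(prep$labels), n_species = n,
    p = (count + 1L) / (n_perm + 1L), p_raw = count / n_perm, n_perm = n_perm,
    statistic = statistic, direction = direction
  )), class = "poolnet_spatial")
}

#' @export
print.poolnet_spatial <- function(x, ...) {
  cat(sprintf(
    "<poolnet_spatial: MD_within = %.2f km, MD_among = %.2f km, ratio = %.3f%s>\n",
    x$md_within, x$md_among, x$ratio,
    if (!is.na(x$p)) sprintf(", p = %.4g (%d perms, %s/%s)",
                             x$p, x$n_perm, x$statistic, x$direction) else ""
  ))
  invisible(x)
}

#' @describeIn spatial_test One-row summary of the spatial-clustering test.
#' @param x A `poolnet_spatial` object.
#' @param ... Unused.
#' @export
glance.poolnet_spatial <- function(x, ...) {
  tibble::tibble(
    md_within = x$md_within, md_among = x$md_among, ratio = x$ratio,
    delta = x$delta, k = x$k, n_species = x$n_species,
    n_within_pairs = x$n_within_pairs, n_among_pairs = x$n_among_pairs,
    p = x$p, p_raw = x$p_raw, n_perm = x$n_perm
  )
}

#' @describeIn spatial_test `tidy()` is an alias of `glance()` for this
#'   one-row result.
#' @export
tidy.poolnet_spatial <- function(x, ...) glance(x)
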