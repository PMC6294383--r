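#' Build a validated site-by-species occurrence matrix
#'
#' The occurrence matrix is the raw input of every analysis in the package:
#' a binary incidence of species (columns) at sampled sites (rows).
#' Validation enforces the two invariants every downstream stage relies on:
#' species observed at no site are dropped (they cannot join any edge,
#' cluster or centroid), and sites with no species are dropped (they carry no
#' co-occurrence information). Both drops are reported with a warning and
#' recorded on the returned object.
#'
#' @param x A 0/1 matrix with site row names and species column names, or a
#'   data frame whose first column holds site ids and remaining columns hold
#'   0/1 species incidences.
#' @param min_sites Minimum number of retained sites for the data set to be
#'   analysable (e.g. 70 for medium-scale basins, 35 for small-scale basins).
#'   Falling short signals an `poolnet_insufficient_samples` condition,
#'   distinguishable from parse errors.
#'
#' @return A `poolnet_occurrence` object: the validated incidence matrix plus
#'   attributes `dropped_species` and `dropped_sites`.
#' @export
#'
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("A", "B")))
#' occ <- occurrence_matrix(m)
#' site_count(occ)
occurrence_matrix <- function(x, min_sites = 1L) {
  min_sites <- check_count(min_sites, "min_sites", min = 1L)
  if (is.data.frame(x)) {
    sites <- as.character(x[[1L]])
    inc <- as.matrix(x[, -1L, drop = FALSE])
    rownames(inc) <- sites
  } else if (is.matrix(x)) {
    inc <- x
  } else {
    stop_parse("`x` must be a matrix or data frame")
  }
  if (is.null(rownames(inc)) || is.null(colnames(inc))) {
    stop_parse("occurrence matrix needs site row names and species column names")
  }
  if (anyDuplicated(rownames(inc))) stop_parse("duplicate site ids")
  if (anyDuplicated(colnames(inc))) stop_parse("duplicate species ids")

  bad <- which(!(inc %in% c(0, 1)) | is.na(inc))
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(inc)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(inc)) + 1L
    stop_parse(sprintf(
      "cell (%s, %s) is not 0/1: %s",
      rownames(inc)[i], colnames(inc)[j], as.character(inc[i, j])
    ))
  }
  storage.mode(inc) <- "integer"

  dropped_species <- colnames(inc)[colSums(inc) == 0L]
  if (length(dropped_species) > 0L) {
    inc <- inc[, colSums(inc) > 0L, drop = FALSE]
    rlang::warn(sprintf(
      "dropped %d species with zero occurrences: %s",
      length(dropped_species), paste(dropped_species, collapse = ", ")
    ))
  }
  dropped_sites <- rownames(inc)[rowSums(inc) == 0L]
  if (length(dropped_sites) > 0L) {
    inc <- inc[rowSums(inc) > 0L, , drop = FALSE]
    rlang::warn(sprintf("dropped %d sites with no species", length(dropped_sites)))
  }
  if (nrow(inc) < min_sites) {
    stop_insufficient(sprintf(
      "insufficient samples: %d sites retained, %d required", nrow(inc), min_sites
    ))
  }
  structure(inc,
    dropped_species = dropped_species, dropped_sites = dropped_sites,
    class = c("poolnet_occurrence", "matrix", "array")
  )
}

#' Read an occurrence matrix from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row of species ids and
#' a first column of site ids; every remaining cell must be `0` or `1`.
#'
#' @param path Path to the CSV file.
#' @inheritParams occurrence_matrix
#' @return A validated `poolnet_occurrence` (see [occurrence_matrix()]).
#' @export
read_occurrence_matrix <- function(path, min_sites = 1L) {
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop_parse(sprintf("cannot read '%s': %s", path, conditionMessage(e)))
  )
  if (ncol(df) < 2L) stop_parse("occurrence CSV needs a site id column plus species columns")
  sites <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  ok <- cells %in% c("0", "1")
  if (any(!ok)) {
    bad <- which(!ok)[1L]
    i <- ((bad - 1L) %% nrow(cells)) + 1L
    j <- ((bad - 1L) %/% nrow(cells)) + 1L
    stop_parse(sprintf(
      "cell (row %s, column %s) is not 0/1: '%s'", sites[i], colnames(cells)[j], cells[i, j]
    ))
  }
  inc <- matrix(as.integer(cells), nrow = nrow(cells),
                dimnames = list(sites, colnames(cells)))
  occurrence_matrix(inc, min_sites = min_sites)
}

#' @export
print.poolnet_occurrence <- function(x, ...) {
  cat(sprintf(
    "<poolnet_occurrence: %d sites x %d species (%d species, %d sites dropped)>\n",
    nrow(x), ncol(x), length(attr(x, "dropped_species")), length(attr(x, "dropped_sites"))
  ))
  invisible(x)
}

#' @rdname occurrence_matrix
#' @param occ A `poolnet_occurrence`.
#' @export
site_count <- function(occ) nrow(occ)

#' @rdname occurrence_matrix
#' @export
species_ids <- function(occ) colnames(occ)

#' Co-occurrence edge list
#'
#' Converts an occurrence matrix into the two-column list of species pairs
#' sharing at least one site, the raw material of the unweighted network.
#' Shared-site counts are retained so the probabilistic effect-size model can
#' reuse them without recomputation (the network itself ignores them).
#'
#' @param occ A validated `poolnet_occurrence`.
#' @return A tibble with columns `species_a`, `species_b`, `n_shared_sites`,
#'   one row per unordered pair with `n_shared_sites >= 1` (pairs ordered by
#'   column position, `species_a` before `species_b`).
#' @export
#'
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0, 1, 0, 0), nrow = 4,
#'             dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
#' build_edge_list(occurrence_matrix(m))
build_edge_list <- function(occ) {
  occ <- occurrence_matrix(occ)
  if (ncol(occ) < 2L) stop_degenerate("need at least 2 species to build an edge list")
  co <- crossprod(occ)
  idx <- which(upper.tri(co) & co >= 1L, arr.ind = TRUE)
  tibble::tibble(
    species_a = colnames(occ)[idx[, 1L]],
    species_b = colnames(occ)[idx[, 2L]],
    n_shared_sites = as.integer(co[idx])
  )
}

#' Species-by-species Jaccard dissimilarity
#'
#' Jaccard dissimilarity between the site sets of every species pair:
#' `1 - |A intersect B| / |A union B|`. Computed between species across sites
#' (the occurrence matrix is transposed before the distance call) because the
#' clustering stage partitions species, not sites.
#'
#' @param occ A validated `poolnet_occurrence`.
#' @return A square symmetric numeric matrix with zero diagonal and species
#'   ids as dimnames; all entries in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(occ) {
  occ <- occurrence_matrix(occ)
  if (ncol(occ) < 2L) stop_degenerate("need at least 2 species for a dissimilarity matrix")
  d <- as.matrix(vegan::vegdist(t(unclass(occ)), method = "jaccard", binary = TRUE))
  diag(d) <- 0
  d
}

#' Write a co-occurrence edge list to CSV
#'
#' @param edges Tibble from [build_edge_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_csv(edges, path)
  invisible(path)
}
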