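#' Pipeline configuration
#'
#' Collects the tunable parameters of a basin run in one place: the
#' annealing schedule, permutation counts, gap-statistic settings and the
#' minimum site count for a basin to be analysable. Defaults are the
#' conventional ones used throughout the package (999 permutations, 100
#' spins, start temperature 1, stop temperature 0.01, cooling 0.99).
#'
#' @param min_sites Minimum retained sites for the basin.
#' @param n_perm Permutations for the congruence and spatial tests.
#' @param spins,start_temp,stop_temp,cooling,restarts Annealing settings
#'   (see [detect_modules()]).
#' @param k_max Largest k evaluated by the gap statistic (capped at
#'   `n_species - 1`).
#' @param b_refs Reference data sets for the gap statistic.
#' @param gap_rule Gap selection rule (see [gap_statistic()]).
#' @param nstart PAM restarts (see [pam_cluster()]).
#' @param seed Master seed; fans out to per-stage seeds via a fixed
#'   derivation so stages can be re-run in isolation.
#' @return A `poolnet_pipeline_config` list.
#' @export
pipeline_config <- function(min_sites = 1L, n_perm = 999L, spins = 100L,
                            start_temp = 1, stop_temp = 0.01, cooling = 0.99,
                            restarts = 1L, k_max = 10L, b_refs = 50L,
                            gap_rule = "firstSEmax", nstart = 5L, seed = NULL) {
  structure(list(
    min_sites = check_count(min_sites, "min_sites", min = 1L),
    n_perm = check_count(n_perm, "n_perm", min = 1L),
    spins = check_count(spins, "spins", min = 2L),
    start_temp = start_temp, stop_temp = stop_temp, cooling = cooling,
    restarts = check_count(restarts, "restarts", min = 1L),
    k_max = check_count(k_max, "k_max", min = 1L),
    b_refs = check_count(b_refs, "b_refs", min = 1L),
    gap_rule = gap_rule,
    nstart = check_count(nstart, "nstart", min = 1L),
    seed = seed
  ), class = "poolnet_pipeline_config")
}

#' Run the full analysis for one basin
#'
#' Executes the complete workflow on one basin's data: validate the
#' occurrence matrix, build the edge list and Jaccard dissimilarities,
#' detect network modules by simulated annealing, cluster species by PAM at
#' `k = n_modules` and at the gap-statistic optimum, compare modules and
#' clusters by congruence (with permutation test), run spatial-clustering
#' tests on species range centroids for every grouping, and evaluate a
#' declared nest-associate complex if one is supplied.
#'
#' Analyses the data cannot support are skipped with an explicit reason
#' rather than omitted: congruence vs the optimal-k clustering is skipped
#' when `k_opt != n_modules` (perfect congruence would be impossible by
#' construction), and spatial among-group statistics are skipped when a
#' grouping has a single group.
#'
#' @param occurrence Occurrence input: a path to a CSV, a matrix/data frame,
#'   or a ready `poolnet_occurrence`.
#' @param units Optional unit-centroid table (`unit_id`, `x_km`, `y_km`) for
#'   spatial tests.
#' @param occupancy Optional species-by-unit occupancy table (matrix or data
#'   frame with a species id first column).
#' @param complex Optional [nest_complex()].
#' @param config A [pipeline_config()].
#' @param basin Basin identifier carried into the report.
#' @param scale Scale label carried into the report.
#' @return A `poolnet_basin_report` list; `tidy()` renders it as a one-row
#'   report table.
#' @export
run_basin_analysis <- function(occurrence, units = NULL, occupancy = NULL,
                               complex = NULL, config = pipeline_config(),
                               basin = "basin", scale = NA_character_) {
  stopifnot(inherits(config, "poolnet_pipeline_config"))
  seeds <- derive_seeds(config$seed, 6L)
  occ <- if (inherits(occurrence, "poolnet_occurrence")) {
    if (site_count(occurrence) < config$min_sites) {
      stop_insufficient(sprintf("basin %s: %d sites < min_sites = %d",
                                basin, site_count(occurrence), config$min_sites))
    }
    occurrence
  } else if (is.character(occurrence) && length(occurrence) == 1L) {
    read_occurrence_matrix(occurrence, min_sites = config$min_sites)
  } else {
    occurrence_matrix(occurrence, min_sites = config$min_sites)
  }

  edges <- build_edge_list(occ)
  d <- jaccard_dissimilarity(occ)
  net <- build_network(edges, species = species_ids(occ))

  modules <- detect_modules(
    net, spins = config$spins, start_temp = config$start_temp,
    stop_temp = config$stop_temp, cooling = config$cooling,
    restarts = config$restarts, seed = seeds[[1L]]
  )
  pam_k <- pam_cluster(d, k = modules$k, seed = seeds[[2L]], nstart = config$nstart)
  cong <- congruence_test(modules$partition, pam_k$partition,
                          n_perm = config$n_perm, seed = seeds[[3L]])
  gap <- gap_statistic(d, k_max = min(config$k_max, ncol(occ) - 1L),
                       b_refs = config$b_refs, seed = seeds[[4L]],
                       rule = config$gap_rule, nstart = config$nstart)
  pam_opt <- if (gap$k_opt == modules$k) pam_k else {
    pam_cluster(d, k = gap$k_opt, seed = seeds[[2L]], nstart = config$nstart)
  }
  cong_opt_skip <- if (gap$k_opt != modules$k) {
    sprintf("congruence not computed: k_opt (%d) != n_modules (%d)", gap$k_opt, modules$k)
  }

  spatial <- list(modules = NULL, clusters_k_modules = NULL, clusters_k_opt = NULL)
  skips <- list()
  centroids <- NULL
  if (!is.null(units) && !is.null(occupancy)) {
    centroids <- species_centroids(units, occupancy)
    run_spatial <- function(partition, label) {
      tryCatch(
        spatial_test(centroids, partition, n_perm = config$n_perm, seed = seeds[[5L]]),
        poolnet_single_group = function(e) {
          skips[[label]] <<- "among-group comparison impossible: single group"
          NULL
        }
      )
    }
    spatial$modules <- run_spatial(modules$partition, "spatial_modules")
    spatial$clusters_k_modules <- run_spatial(pam_k$partition, "spatial_clusters_k_modules")
    spatial$clusters_k_opt <- run_spatial(pam_opt$partition, "spatial_clusters_k_opt")
  } else {
    skips$spatial <- "no unit centroids / occupancy supplied"
  }

  nest <- NULL
  if (!is.null(complex)) {
    pool <- species_ids(occ)
    if (!complex$host %in% pool) {
      skips$nest <- sprintf("host '%s' absent from the basin", complex$host)
    } else {
      effects <- effect_size_table(occ)
      comp <- function(p) tryCatch(completeness(p, complex, pool = pool),
                                   poolnet_error = function(e) NA_real_)
      nest <- list(
        completeness_modules = comp(modules$partition),
        completeness_clusters_k_modules = comp(pam_k$partition),
        completeness_clusters_k_opt = comp(pam_opt$partition),
        contrast = effect_contrast(effects, net, modules$partition, complex)
      )
    }
  }

  structure(list(
    basin = basin, scale = scale,
    n_sites = site_count(occ), n_species = ncol(occ),
    dropped_species = attr(occ, "dropped_species"),
    isolated = net$isolated,
    modules = modules, pam_k = pam_k, gap = gap, pam_opt = pam_opt,
    congruence = cong, congruence_opt_skip = cong_opt_skip,
    spatial = spatial, nest = nest, skips = skips,
    centroids = centroids, seed = config$seed
  ), class = "poolnet_basin_report")
}

#' @export
print.poolnet_basin_report <- function(x, ...) {
  cat(sprintf("<poolnet_basin_report: %s (%s)>\n", x$basin,
              ifelse(is.na(x$scale), "unscaled", x$scale)))
  cat(sprintf("  %d sites, %d species (%d isolated), %d modules (Q = %.3f), k_opt = %d\n",
              x$n_sites, x$n_species, length(x$isolated), x$modules$k, x$modules$q,
              x$gap$k_opt))
  cat(sprintf("  C = %.3f (p = %.4g)\n", x$congruence$c, x$congruence$p))
  for (nm in names(x$skips)) cat(sprintf("  [skipped] %s: %s\n", nm, x$skips[[nm]]))
  invisible(x)
}

#' @describeIn run_basin_analysis One-row report table (basin, module count,
#'   congruence, spatial ratios and p-values, gap k, nest completeness).
#' @param x A `poolnet_basin_report`.
#' @param ... Unused.
#' @export
tidy.poolnet_basin_report <- function(x, ...) {
  sp_cols <- function(s, prefix) {
    if (is.null(s)) {
      tibble::tibble("{prefix}_ratio" := NA_real_, "{prefix}_p" := NA_real_)
    } else {
      tibble::tibble("{prefix}_ratio" := s$ratio, "{prefix}_p" := s$p)
    }
  }
  dplyr::bind_cols(
    tibble::tibble(
      scale = x$scale, basin = x$basin,
      n_sites = x$n_sites, n_species = x$n_species,
      n_modules = x$modules$k, q = x$modules$q,
      c = x$congruence$c, c_p = x$congruence$p,
      gs_k = x$gap$k_opt
    ),
    sp_cols(x$spatial$modules, "md_modules"),
    sp_cols(x$spatial$clusters_k_modules, "md_clusters"),
    sp_cols(x$spatial$clusters_k_opt, "md_clusters_opt"),
    tibble::tibble(
      nest_modules = if (is.null(x$nest)) NA_real_ else as.numeric(x$nest$completeness_modules),
      nest_clusters = if (is.null(x$nest)) NA_real_ else as.numeric(x$nest$completeness_clusters_k_modules),
      nest_clusters_opt = if (is.null(x$nest)) NA_real_ else as.numeric(x$nest$completeness_clusters_k_opt),
      n_perm = x$congruence$n_perm,
      n_isolated = length(x$isolated),
      n_dropped_species = length(x$dropped_species)
    )
  )
}

#' Run several (nested) basins sharing a species namespace
#'
#' Each basin is analysed independently with its scale's `min_sites`
#' threshold; basins falling short are reported as skipped with the reason
#' rather than dropped silently. A species sampled in several basins
#' legitimately appears once per basin report.
#'
#' @param basins A list of basin inputs; each element is a list with fields
#'   `basin`, `scale`, `occurrence` and optionally `units`, `occupancy`,
#'   `complex`.
#' @param config A [pipeline_config()]; `min_sites_by_scale` overrides
#'   `config$min_sites` per scale label.
#' @param min_sites_by_scale Named integer vector, e.g.
#'   `c("HU-2" = 70, "HU-4" = 35)`.
#' @return A list with `reports` (list of `poolnet_basin_report`), `skipped`
#'   (tibble of basin/reason), and `summary` (tidy rows of all reports).
#' @export
run_nested_scales <- function(basins, config = pipeline_config(),
                              min_sites_by_scale = NULL) {
  ids <- vapply(basins, function(b) b$basin, character(1))
  if (anyDuplicated(ids)) stop_domain("overlapping basin ids in `basins`")
  reports <- list()
  skipped <- tibble::tibble(basin = character(0), reason = character(0))
  for (b in basins) {
    cfg <- config
    if (!is.null(min_sites_by_scale) && !is.null(b$scale) &&
        b$scale %in% names(min_sites_by_scale)) {
      cfg$min_sites <- as.integer(min_sites_by_scale[[b$scale]])
    }
    rep_b <- tryCatch(
      run_basin_analysis(b$occurrence, units = b$units, occupancy = b$occupancy,
                         complex = b$complex, config = cfg,
                         basin = b$basin, scale = b$scale %||% NA_character_),
      poolnet_insufficient_samples = function(e) conditionMessage(e)
    )
    if (is.character(rep_b)) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(basin = b$basin, reason = rep_b))
    } else {
      reports[[b$basin]] <- rep_b
    }
  }
  list(
    reports = reports,
    skipped = skipped,
    summary = purrr::map_dfr(reports, tidy)
  )
}
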