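#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the whole pipeline
#' assumes, with known ground truth: binary occurrences with group-structured
#' probabilities (each species occurs with probability `p_in` at sites of its
#' own habitat group and `p_out` elsewhere), group-specific planar range
#' centroids (either clustered around separated group means or drawn from one
#' common distribution), and an optional host-conditional nest-associate
#' complex (each associate occurs with probability `p_assoc_given_host` at
#' sites where the host is present and `p_assoc_no_host` elsewhere,
#' conditioning only on the host, not on the other associates).
#'
#' @param n_sites Number of sampling sites.
#' @param n_groups Number of habitat groups `g`.
#' @param species_per_group Species per group (the host, if any, is one
#'   extra species added to `host_group`).
#' @param p_in,p_out Occurrence probabilities at own-group / other sites.
#' @param site_group_mix Proportions of sites per habitat group (defaults to
#'   equal shares).
#' @param spatial_mode `"clustered"` (group means separated by
#'   `group_sep_km`) or `"common"` (all ranges from one distribution).
#' @param group_sep_km Distance in km between neighbouring group centroid
#'   means (groups are placed on a circle with chord `group_sep_km`).
#' @param sigma_km Isotropic s.d. of unit centroids around their group mean.
#' @param n_units_per_species Occupancy units defining each species' range.
#' @param host_group Group receiving a planted complex, or `NA` for none.
#' @param n_associates Number of associate species.
#' @param p_assoc_given_host,p_assoc_no_host Associate occurrence
#'   probabilities conditional on host presence at the site.
#' @param seed Integer master seed.
#' @return A validated `poolnet_config` list.
#' @export
synthetic_config <- function(n_sites = 100L, n_groups = 3L, species_per_group = 20L,
                             p_in = 0.9, p_out = 0.05, site_group_mix = NULL,
                             spatial_mode = c("clustered", "common"),
                             group_sep_km = 100, sigma_km = 20,
                             n_units_per_species = 30L,
                             host_group = NA, n_associates = 6L,
                             p_assoc_given_host = 0.8, p_assoc_no_host = 0.05,
                             seed = NULL) {
  spatial_mode <- match.arg(spatial_mode)
  cfg <- list(
    n_sites = check_count(n_sites, "n_sites", min = 1L),
    n_groups = check_count(n_groups, "n_groups", min = 1L),
    species_per_group = check_count(species_per_group, "species_per_group", min = 1L),
    p_in = check_prob(p_in, "p_in"),
    p_out = check_prob(p_out, "p_out"),
    site_group_mix = site_group_mix,
    spatial_mode = spatial_mode,
    group_sep_km = group_sep_km,
    sigma_km = sigma_km,
    n_units_per_species = check_count(n_units_per_species, "n_units_per_species", min = 1L),
    host_group = host_group,
    n_associates = check_count(n_associates, "n_associates", min = 1L),
    p_assoc_given_host = check_prob(p_assoc_given_host, "p_assoc_given_host"),
    p_assoc_no_host = check_prob(p_assoc_no_host, "p_assoc_no_host"),
    seed = seed
  )
  if (is.null(cfg$site_group_mix)) {
    cfg$site_group_mix <- rep(1 / cfg$n_groups, cfg$n_groups)
  }
  if (length(cfg$site_group_mix) != cfg$n_groups || any(cfg$site_group_mix < 0) ||
      abs(sum(cfg$site_group_mix) - 1) > 1e-8) {
    stop_domain("`site_group_mix` must be n_groups non-negative proportions summing to 1")
  }
  if (cfg$p_in < cfg$p_out) {
    stop_domain("planted structure requires p_in >= p_out")
  }
  if (!is.na(cfg$host_group)) {
    cfg$host_group <- check_count(cfg$host_group, "host_group", min = 1L)
    if (cfg$host_group > cfg$n_groups) stop_domain("host_group exceeds n_groups")
  }
  if (!is.na(group_sep_km) && group_sep_km < 0) stop_domain("group_sep_km must be >= 0")
  if (sigma_km <= 0) stop_domain("sigma_km must be > 0")
  structure(cfg, class = "poolnet_config")
}

#' Generate a synthetic occurrence matrix with planted group structure
#'
#' Sites are assigned to habitat groups according to `site_group_mix`
#' (deterministic rounded shares). Every species occurs at each site
#' independently with probability `p_in` when the site's habitat matches the
#' species' group and `p_out` otherwise. When a complex is planted, the host
#' is generated first (as an ordinary member of its group) and each
#' associate then occurs with probability `p_assoc_given_host` at sites
#' where the host is present, `p_assoc_no_host` elsewhere. Output is
#' bit-identical given the same seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `occurrence` (validated `poolnet_occurrence`; species that
#'   drew zero occurrences are dropped by validation as usual) and `truth`
#'   (planted partition with source `"planted"`, the site habitat
#'   assignment, and the planted `complex` or `NULL`).
#' @export
#'
#' @examples
#' sim <- generate_occurrences(synthetic_config(n_sites = 30, seed = 1))
#' sim$occurrence
generate_occurrences <- function(cfg) {
  stopifnot(inherits(cfg, "poolnet_config"))
  with_seed(cfg$seed, {
    counts <- diff(round(cumsum(c(0, cfg$site_group_mix)) * cfg$n_sites))
    site_groups <- rep.int(seq_len(cfg$n_groups), counts)
    sites <- sprintf("site%03d", seq_len(cfg$n_sites))

    species <- character(0)
    group_of <- integer(0)
    for (g in seq_len(cfg$n_groups)) {
      ids <- sprintf("g%d_s%02d", g, seq_len(cfg$species_per_group))
      species <- c(species, ids)
      group_of <- c(group_of, rep.int(g, length(ids)))
    }
    complex <- NULL
    if (!is.na(cfg$host_group)) {
      species <- c(species, "host", sprintf("assoc%d", seq_len(cfg$n_associates)))
      group_of <- c(group_of, cfg$host_group, rep.int(cfg$host_group, cfg$n_associates))
      complex <- nest_complex("host", sprintf("assoc%d", seq_len(cfg$n_associates)))
    }

    inc <- matrix(0L, nrow = cfg$n_sites, ncol = length(species),
                  dimnames = list(sites, species))
    habitat_sp <- species[!species %in% c("host", if (!is.null(complex)) complex$associates)]
    for (sp in habitat_sp) {
      g <- group_of[match(sp, species)]
      pr <- ifelse(site_groups == g, cfg$p_in, cfg$p_out)
      inc[, sp] <- stats::rbinom(cfg$n_sites, 1L, pr)
    }
    if (!is.null(complex)) {
      pr_host <- ifelse(site_groups == cfg$host_group, cfg$p_in, cfg$p_out)
      inc[, "host"] <- stats::rbinom(cfg$n_sites, 1L, pr_host)
      pr_assoc <- ifelse(inc[, "host"] == 1L, cfg$p_assoc_given_host, cfg$p_assoc_no_host)
      for (a in complex$associates) {
        inc[, a] <- stats::rbinom(cfg$n_sites, 1L, pr_assoc)
      }
    }
    occurrence <- suppressWarnings(occurrence_matrix(inc))
    truth <- list(
      partition = as_partition(stats::setNames(group_of, species), source = "planted"),
      site_groups = stats::setNames(site_groups, sites),
      complex = complex
    )
    list(occurrence = occurrence, truth = truth)
  })
}

#' Generate unit centroids and species occupancy with planted spatial
#' structure
#'
#' In `"clustered"` mode the group centroid means are placed on a circle so
#' that neighbouring means are `group_sep_km` apart, and each species' range
#' units are drawn as isotropic bivariate normal points (s.d. `sigma_km`)
#' around its group mean; `"common"` mode (or `group_sep_km = 0`) draws all
#' species from one distribution at the origin. Units are per-species (no
#' shared occupancy grid); the centroid interpolation is agnostic to
#' sharing.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Truth list from [generate_occurrences()] (supplies the
#'   planted partition).
#' @return A list: `units` (tibble `unit_id`, `x_km`, `y_km`), `occupancy`
#'   (species-by-unit 0/1 matrix), `group_means` (tibble `group`, `x_km`,
#'   `y_km`).
#' @export
generate_centroid_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "poolnet_config"))
  p <- truth$partition
  seeds <- derive_seeds(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, 1L)
  with_seed(seeds[[1L]], {
    g <- cfg$n_groups
    sep <- if (cfg$spatial_mode == "common") 0 else cfg$group_sep_km
    if (g == 1L || sep == 0) {
      means <- matrix(0, nrow = g, ncol = 2L)
    } else {
      r <- sep / (2 * sin(pi / g))
      theta <- 2 * pi * (seq_len(g) - 1L) / g
      means <- cbind(r * cos(theta), r * sin(theta))
    }
    species <- names(p)
    nu <- cfg$n_units_per_species
    unit_ids <- as.vector(vapply(species, function(sp) sprintf("%s_u%03d", sp, seq_len(nu)),
                                 character(nu)))
    xy <- do.call(rbind, lapply(species, function(sp) {
      mu <- means[unclass(p)[[sp]], ]
      cbind(stats::rnorm(nu, mu[1L], cfg$sigma_km), stats::rnorm(nu, mu[2L], cfg$sigma_km))
    }))
    units <- tibble::tibble(unit_id = unit_ids, x_km = xy[, 1L], y_km = xy[, 2L])
    occupancy <- matrix(0L, nrow = length(species), ncol = length(unit_ids),
                        dimnames = list(species, unit_ids))
    for (i in seq_along(species)) {
      occupancy[i, ((i - 1L) * nu + 1L):(i * nu)] <- 1L
    }
    list(
      units = units, occupancy = occupancy,
      group_means = tibble::tibble(group = seq_len(g),
                                   x_km = means[, 1L], y_km = means[, 2L])
    )
  })
}

#' Sample a planted-partition ("stochastic block") network
#'
#' Draws a simple undirected graph in which species of the same planted
#' group are linked with probability `p_in` and species of different groups
#' with probability `p_out` — the network-level analogue of the occurrence
#' generator, useful for exercising module detection directly at a chosen
#' edge density.
#'
#' @param n_species Number of nodes.
#' @param n_groups Number of planted groups (balanced).
#' @param p_in,p_out Within/between-group edge probabilities.
#' @param seed Integer seed.
#' @return A list: `network` (`poolnet_network`) and `truth` (planted
#'   partition).
#' @export
sample_planted_network <- function(n_species = 60L, n_groups = 3L,
                                   p_in = 0.9, p_out = 0.05, seed = NULL) {
  n_species <- check_count(n_species, "n_species", min = 2L)
  n_groups <- check_count(n_groups, "n_groups", min = 1L)
  p_in <- check_prob(p_in, "p_in")
  p_out <- check_prob(p_out, "p_out")
  if (n_species %% n_groups != 0L) stop_domain("n_species must be a multiple of n_groups")
  sizes <- rep(n_species %/% n_groups, n_groups)
  with_seed(seed, {
    pref <- matrix(p_out, n_groups, n_groups)
    diag(pref) <- p_in
    g <- igraph::sample_sbm(n_species, pref.matrix = pref, block.sizes = sizes)
    igraph::V(g)$name <- sprintf("sp%02d", seq_len(n_species))
    truth <- as_partition(
      stats::setNames(rep(seq_len(n_groups), sizes), igraph::V(g)$name),
      source = "planted"
    )
    list(network = structure(list(graph = g, isolated = character(0)),
                             class = "poolnet_network"),
         truth = truth)
  })
}

#' Write a synthetic data set to the CSV formats the pipeline reads
#'
#' Emits `occurrence.csv` (site-by-species 0/1), `units.csv`,
#' `occupancy.csv`, and `truth.json` (planted partition, complex, group
#' means) into `dir`.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_synthetic_data <- function(cfg, dir) {
  sim <- generate_occurrences(cfg)
  cen <- generate_centroid_tables(cfg, sim$truth)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    occurrence = file.path(dir, "occurrence.csv"),
    units = file.path(dir, "units.csv"),
    occupancy = file.path(dir, "occupancy.csv"),
    truth = file.path(dir, "truth.json")
  )
  occ_df <- tibble::as_tibble(as.data.frame(unclass(sim$occurrence)), rownames = "site_id")
  readr::write_csv(occ_df, paths$occurrence)
  readr::write_csv(cen$units, paths$units)
  occ_units <- tibble::as_tibble(as.data.frame(cen$occupancy), rownames = "species")
  readr::write_csv(occ_units, paths$occupancy)
  truth <- list(
    partition = as.list(stats::setNames(as.integer(sim$truth$partition),
                                        names(sim$truth$partition))),
    complex = if (!is.null(sim$truth$complex)) {
      list(host = sim$truth$complex$host, associates = sim$truth$complex$associates)
    },
    group_means = as.data.frame(cen$group_means)
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA), paths$truth)
  invisible(paths)
}
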