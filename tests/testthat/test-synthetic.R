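test_that("the generator is bit-identical given the same seed", {
  cfg <- synthetic_config(n_sites = 40, species_per_group = 5,
                          host_group = 1, seed = 77)
  a <- generate_occurrences(cfg)
  b <- generate_occurrences(cfg)
  expect_identical(unclass(a$occurrence), unclass(b$occurrence))
  expect_identical(unclass(a$truth$partition), unclass(b$truth$partition))
  ta <- generate_centroid_tables(cfg, a$truth)
  tb <- generate_centroid_tables(cfg, b$truth)
  expect_identical(ta$units, tb$units)
  expect_identical(ta$occupancy, tb$occupancy)
})

test_that("the noise-free limit is block-diagonal and trivially recoverable", {
  cfg <- synthetic_config(n_sites = 30, n_groups = 3, species_per_group = 4,
                          p_in = 1, p_out = 0, seed = 5)
  sim <- generate_occurrences(cfg)
  occ <- unclass(sim$occurrence)
  truth <- sim$truth
  for (sp in colnames(occ)) {
    g <- unclass(truth$partition)[[sp]]
    expect_true(all(occ[truth$site_groups == g, sp] == 1L))
    expect_true(all(occ[truth$site_groups != g, sp] == 0L))
  }
  net <- build_network(build_edge_list(sim$occurrence),
                       species = species_ids(sim$occurrence))
  mod <- detect_modules(net, seed = 1)
  expect_equal(congruence(truth$partition, mod$partition)$c, 1)
  fit <- pam_cluster(jaccard_dissimilarity(sim$occurrence), 3, seed = 1)
  expect_equal(congruence(truth$partition, fit$partition)$c, 1)
})

test_that("occurrence counts match their binomial expectation", {
  cfg <- synthetic_config(n_sites = 300, n_groups = 3, species_per_group = 5,
                          p_in = 0.6, p_out = 0.1, seed = 31)
  sim <- generate_occurrences(cfg)
  truth <- sim$truth
  n_own <- table(truth$site_groups)
  for (sp in species_ids(sim$occurrence)) {
    g <- unclass(truth$partition)[[sp]]
    own <- n_own[[g]]
    other <- 300 - own
    mu <- own * 0.6 + other * 0.1
    sd3 <- 3 * sqrt(own * 0.6 * 0.4 + other * 0.1 * 0.9)
    expect_lt(abs(sum(unclass(sim$occurrence)[, sp]) - mu), sd3)
  }
})

test_that("extreme p_out can empty a species and validation drops it gracefully", {
  cfg <- synthetic_config(n_sites = 4, n_groups = 2, species_per_group = 2,
                          p_in = 0.2, p_out = 0, seed = 2)
  sim <- generate_occurrences(cfg)
  occ <- sim$occurrence
  expect_true(all(colSums(unclass(occ)) >= 1))
  expect_true(all(rowSums(unclass(occ)) >= 1))
  expect_true(length(attr(occ, "dropped_species")) > 0)
})

test_that("zero group separation collapses to the common spatial mode", {
  cfg0 <- synthetic_config(n_sites = 20, species_per_group = 3,
                           group_sep_km = 0, seed = 9)
  sim <- generate_occurrences(cfg0)
  t0 <- generate_centroid_tables(cfg0, sim$truth)
  expect_true(all(t0$group_means$x_km == 0) && all(t0$group_means$y_km == 0))
  cfg_common <- synthetic_config(n_sites = 20, species_per_group = 3,
                                 spatial_mode = "common", group_sep_km = 150,
                                 seed = 9)
  tc <- generate_centroid_tables(cfg_common, sim$truth)
  expect_identical(t0$units, tc$units)
})

test_that("a single unit per species pins the centroid to that unit", {
  cfg <- synthetic_config(n_sites = 20, species_per_group = 2,
                          n_units_per_species = 1, seed = 4)
  sim <- generate_occurrences(cfg)
  tabs <- generate_centroid_tables(cfg, sim$truth)
  cen <- species_centroids(tabs$units, tabs$occupancy)
  for (i in seq_len(nrow(cen))) {
    u <- tabs$units[tabs$occupancy[cen$species[i], ] == 1L, ]
    expect_equal(cen$x_km[i], u$x_km)
    expect_equal(cen$y_km[i], u$y_km)
  }
})

test_that("planted-network sampling respects its block structure and seed", {
  pl1 <- sample_planted_network(n_species = 30, n_groups = 3,
                                p_in = 1, p_out = 0, seed = 11)
  comps <- igraph::components(pl1$network$graph)
  expect_equal(comps$no, 3)
  pl2 <- sample_planted_network(n_species = 30, n_groups = 3,
                                p_in = 1, p_out = 0, seed = 11)
  expect_identical(igraph::as_edgelist(pl1$network$graph),
                   igraph::as_edgelist(pl2$network$graph))
  expect_error(sample_planted_network(n_species = 10, n_groups = 3),
               class = "poolnet_domain_error")
})

test_that("emitted CSV files round-trip through the pipeline's readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_sites = 25, species_per_group = 4,
                          host_group = 2, n_associates = 2, seed = 42)
  paths <- write_synthetic_data(cfg, dir)
  occ <- read_occurrence_matrix(paths$occurrence)
  sim <- generate_occurrences(cfg)
  expect_identical(unclass(occ), unclass(sim$occurrence))
  units <- readr::read_csv(paths$units, show_col_types = FALSE)
  expect_named(units, c("unit_id", "x_km", "y_km"))
  truth <- jsonlite::fromJSON(paths$truth)
  expect_identical(truth$complex$host, "host")
  expect_identical(sort(names(truth$partition)),
                   sort(names(sim$truth$partition)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.5), class = "poolnet_domain_error")
  expect_error(synthetic_config(site_group_mix = c(0.5, 0.5)), class = "poolnet_domain_error")
  expect_error(synthetic_config(host_group = 7), class = "poolnet_domain_error")
  expect_error(synthetic_config(sigma_km = 0), class = "poolnet_domain_error")
})
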