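test_that("centroid interpolation is the arithmetic mean of occupied units", {
  units <- tibble::tibble(unit_id = c("u1", "u2", "u3"),
                          x_km = c(0, 2, 1), y_km = c(0, 0, 3))
  cen <- interpolate_centroid(units, c("u1", "u2", "u3"))
  expect_equal(unlist(cen), c(x_km = 1, y_km = 1))
  expect_equal(interpolate_centroid(units, "u2")$x_km, 2)

  set.seed(81)
  big <- tibble::tibble(unit_id = sprintf("u%02d", 1:50),
                        x_km = runif(50, 0, 100), y_km = runif(50, 0, 100))
  occ <- sample(big$unit_id, 20)
  got <- interpolate_centroid(big, occ)
  sel <- big[big$unit_id %in% occ, ]
  expect_equal(got$x_km, sum(sel$x_km) / 20)
  expect_equal(got$y_km, sum(sel$y_km) / 20)

  expect_error(interpolate_centroid(units, "nope"), class = "poolnet_domain_error")
  expect_error(interpolate_centroid(units, character(0)), class = "poolnet_domain_error")
})

test_that("species centroids come from each species' own units", {
  units <- tibble::tibble(unit_id = c("u1", "u2"), x_km = c(0, 10), y_km = c(5, -5))
  occ <- matrix(c(1L, 0L, 0L, 1L), nrow = 2,
                dimnames = list(c("A", "B"), c("u1", "u2")))
  cen <- species_centroids(units, occ)
  expect_equal(cen$x_km, c(0, 10))
  expect_equal(cen$y_km, c(5, -5))

  all_units <- matrix(1L, 1, 2, dimnames = list("C", c("u1", "u2")))
  cen2 <- species_centroids(units, all_units)
  expect_equal(cen2$x_km, 5)
  expect_equal(cen2$y_km, 0)

  none <- matrix(c(1L, 0L, 1L, 0L), nrow = 2,
                 dimnames = list(c("A", "empty"), c("u1", "u2")))
  expect_warning(cen3 <- species_centroids(units, none), "no centroid")
  expect_identical(attr(cen3, "missing_centroid"), "empty")
})

test_that("generator centroids converge to the planted group means", {
  cfg <- synthetic_config(n_sites = 30, n_groups = 3, species_per_group = 4,
                          group_sep_km = 200, sigma_km = 25,
                          n_units_per_species = 200, seed = 19)
  sim <- generate_occurrences(cfg)
  tabs <- generate_centroid_tables(cfg, sim$truth)
  cen <- species_centroids(tabs$units, tabs$occupancy)
  truth <- sim$truth$partition
  for (i in seq_len(nrow(cen))) {
    g <- unclass(truth)[[cen$species[i]]]
    mu <- tabs$group_means[tabs$group_means$group == g, ]
    tol <- 3 * 25 / sqrt(200)
    expect_lt(abs(cen$x_km[i] - mu$x_km), tol)
    expect_lt(abs(cen$y_km[i] - mu$y_km), tol)
  }
})

test_that("mean distance ratio matches hand computation and degenerate limits", {
  cen <- tibble::tibble(species = c("a", "b", "c", "d"),
                        x_km = c(0, 0, 10, 10), y_km = c(0, 1, 0, 1))
  p <- c(a = 1, b = 1, c = 2, d = 2)
  res <- mean_distance_ratio(cen, p)
  expect_equal(res$md_within, 1)
  expect_equal(res$md_among, (10 + sqrt(101) + sqrt(101) + 10) / 4)
  expect_equal(res$ratio, 1 / ((10 + sqrt(101) + sqrt(101) + 10) / 4))
  expect_identical(res$n_within_pairs + res$n_among_pairs, as.integer(choose(4, 2)))

  stacked <- tibble::tibble(species = c("a", "b", "c", "d"),
                            x_km = c(0, 0, 7, 7), y_km = c(2, 2, 5, 5))
  res2 <- mean_distance_ratio(stacked, p)
  expect_equal(res2$md_within, 0)
  expect_equal(res2$ratio, 0)

  expect_error(mean_distance_ratio(cen, c(a = 1, b = 1, c = 1, d = 1)),
               class = "poolnet_single_group")
  expect_error(mean_distance_ratio(cen[1:2, ], c(a = 1, b = 2)),
               class = "poolnet_degenerate_error")
})

test_that("pair accounting and rigid-motion invariance hold on random inputs", {
  set.seed(83)
  n <- 17
  cen <- tibble::tibble(species = sprintf("sp%02d", 1:n),
                        x_km = runif(n, 0, 500), y_km = runif(n, 0, 500))
  p <- setNames(sample(1:3, n, replace = TRUE), cen$species)
  p[1:3] <- 1:3
  res <- mean_distance_ratio(cen, p)
  expect_identical(res$n_within_pairs + res$n_among_pairs, as.integer(choose(n, 2)))

  moved <- rigid_motion(cbind(cen$x_km, cen$y_km), angle = 0.7, dx = 120, dy = -40)
  cen2 <- tibble::tibble(species = cen$species, x_km = moved[, 1], y_km = moved[, 2])
  res2 <- mean_distance_ratio(cen2, p)
  expect_equal(res$md_within, res2$md_within, tolerance = 1e-9)
  expect_equal(res$md_among, res2$md_among, tolerance = 1e-9)
  st1 <- spatial_test(cen, p, n_perm = 99, seed = 11)
  st2 <- spatial_test(cen2, p, n_perm = 99, seed = 11)
  expect_identical(st1$p, st2$p)
})

test_that("the size-weighted delta matches vegan's MRPP statistic", {
  set.seed(84)
  n <- 15
  cen <- tibble::tibble(species = sprintf("sp%02d", 1:n),
                        x_km = runif(n, 0, 100), y_km = runif(n, 0, 100))
  p <- setNames(sample(1:3, n, replace = TRUE), cen$species)
  p[1:3] <- 1:3
  res <- mean_distance_ratio(cen, p)
  veg <- vegan::mrpp(cbind(cen$x_km, cen$y_km), grouping = as.integer(p),
                     permutations = 2, weight.type = 1)
  expect_equal(res$delta, veg$delta, tolerance = 1e-10)
})

test_that("planted spatial clustering is detected, common-mode is not biased", {
  cfg <- synthetic_config(n_sites = 30, n_groups = 3, species_per_group = 8,
                          group_sep_km = 150, sigma_km = 30,
                          n_units_per_species = 20, seed = 29)
  sim <- generate_occurrences(cfg)
  tabs <- generate_centroid_tables(cfg, sim$truth)
  cen <- species_centroids(tabs$units, tabs$occupancy)
  st <- spatial_test(cen, sim$truth$partition, n_perm = 999, seed = 30)
  expect_lt(st$ratio, 1)
  expect_lte(st$p, 0.005)

  # average ratio over random relabellings of exchangeable centroids ~ 1
  set.seed(85)
  n <- 18
  cen0 <- tibble::tibble(species = sprintf("sp%02d", 1:n),
                         x_km = rnorm(n, 0, 50), y_km = rnorm(n, 0, 50))
  ratios <- replicate(300, {
    p <- setNames(sample(rep(1:3, each = 6)), cen0$species)
    mean_distance_ratio(cen0, p)$ratio
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("the literal direction reports the within >= among proportion", {
  set.seed(86)
  n <- 12
  cen <- tibble::tibble(species = sprintf("sp%02d", 1:n),
                        x_km = rnorm(n), y_km = rnorm(n))
  p <- setNames(rep(1:2, each = 6), cen$species)
  lit <- spatial_test(cen, p, n_perm = 499, seed = 3, direction = "literal")
  # under exchangeable centroids within >= among in roughly half the perms
  expect_gt(lit$p_raw, 0.2)
  expect_lt(lit$p_raw, 0.8)
})
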