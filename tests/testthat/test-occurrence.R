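test_that("CSV round trip preserves a fully occupied matrix", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,A,B", "s1,1,1", "s2,1,1", "s3,1,1"), path)
  occ <- read_occurrence_matrix(path, min_sites = 1)
  expect_identical(dim(occ), c(3L, 2L))
  expect_identical(species_ids(occ), c("A", "B"))
  expect_true(all(unclass(occ) == 1L))
})

test_that("all-zero species are dropped with a warning; empty sites follow", {
  m <- rand_occ(6, 4, p = 0.6, seed = 2)
  m[, 3] <- 0L
  expect_warning(occ <- occurrence_matrix(m), "zero occurrences")
  expect_false(colnames(m)[3] %in% species_ids(occ))
  expect_identical(attr(occ, "dropped_species"), colnames(m)[3])

  m2 <- rand_occ_valid(5, 4, p = 0.7, seed = 3)
  m2 <- rbind(m2, empty = rep(0L, 4))
  expect_warning(occ2 <- occurrence_matrix(m2), "no species")
  expect_identical(site_count(occ2), 5L)
})

test_that("under-sampled basins signal insufficient samples, distinct from parse errors", {
  m <- rand_occ_valid(34, 5, p = 0.6, seed = 4)
  expect_error(occurrence_matrix(m, min_sites = 35),
               class = "poolnet_insufficient_samples")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,A,B", "s1,1,x", "s2,1,1"), path)
  err <- expect_error(read_occurrence_matrix(path), class = "poolnet_parse_error")
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "B")
  expect_false(inherits(err, "poolnet_insufficient_samples"))
})

test_that("edge list matches the brute-force double loop and drops lonely species", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  m[c(1, 2), "A"] <- 1L
  m[c(2, 3), "B"] <- 1L
  m[4, "C"] <- 1L
  e <- build_edge_list(occurrence_matrix(m))
  expect_identical(nrow(e), 1L)
  expect_identical(e$species_a, "A")
  expect_identical(e$species_b, "B")
  expect_identical(e$n_shared_sites, 1L)

  full <- matrix(1L, 5, 4, dimnames = list(paste0("s", 1:5), LETTERS[1:4]))
  ef <- build_edge_list(occurrence_matrix(full))
  expect_identical(nrow(ef), as.integer(choose(4, 2)))
  expect_true(all(ef$n_shared_sites == 5L))

  r <- rand_occ_valid(20, 10, p = 0.3, seed = 11)
  got <- as.data.frame(build_edge_list(occurrence_matrix(r)))
  want <- brute_edge_list(r)
  got <- got[order(got$species_a, got$species_b), ]
  want <- want[order(want$species_a, want$species_b), ]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("edge lists are invariant to species column order", {
  r <- rand_occ_valid(15, 8, p = 0.4, seed = 7)
  e1 <- build_edge_list(occurrence_matrix(r))
  perm <- sample(ncol(r))
  e2 <- build_edge_list(occurrence_matrix(r[, perm]))
  canon <- function(e) {
    key <- paste(pmin(e$species_a, e$species_b), pmax(e$species_a, e$species_b))
    e$n_shared_sites[order(key)]
  }
  expect_identical(canon(e1), canon(e2))
})

test_that("Jaccard dissimilarity matches set arithmetic and its boundary cases", {
  m <- matrix(0L, 3, 2, dimnames = list(paste0("s", 1:3), c("A", "B")))
  m[c(1, 2), "A"] <- 1L
  m[c(2, 3), "B"] <- 1L
  d <- jaccard_dissimilarity(occurrence_matrix(m))
  expect_equal(d["A", "B"], 1 - 1 / 3)

  r <- rand_occ_valid(30, 12, p = 0.35, seed = 13)
  d2 <- jaccard_dissimilarity(occurrence_matrix(r))
  expect_equal(d2, brute_jaccard(r), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d2, t(d2))
  expect_true(all(diag(d2) == 0))
  expect_true(all(d2 >= 0 & d2 <= 1))

  # d = 0 iff identical profiles; d = 1 iff the pair is absent from the edges
  e <- build_edge_list(occurrence_matrix(r))
  key <- paste(e$species_a, e$species_b)
  for (i in 1:(ncol(r) - 1)) {
    for (j in (i + 1):ncol(r)) {
      pair <- paste(colnames(r)[i], colnames(r)[j])
      expect_identical(d2[i, j] == 1, !pair %in% key)
      expect_identical(d2[i, j] == 0, all(r[, i] == r[, j]))
    }
  }
})

test_that("sites without species do not affect downstream results", {
  r <- rand_occ_valid(12, 6, p = 0.5, seed = 5)
  r2 <- rbind(r, blank = rep(0L, 6))
  occ1 <- occurrence_matrix(r)
  occ2 <- suppressWarnings(occurrence_matrix(r2))
  expect_equal(build_edge_list(occ1), build_edge_list(occ2))
  expect_equal(jaccard_dissimilarity(occ1), jaccard_dissimilarity(occ2))
})

test_that("degenerate and malformed inputs are rejected", {
  one <- matrix(1L, 3, 1, dimnames = list(paste0("s", 1:3), "A"))
  expect_error(build_edge_list(occurrence_matrix(one)), class = "poolnet_degenerate_error")
  expect_error(jaccard_dissimilarity(occurrence_matrix(one)), class = "poolnet_degenerate_error")
  dup <- matrix(1L, 2, 2, dimnames = list(c("s1", "s1"), c("A", "B")))
  expect_error(occurrence_matrix(dup), class = "poolnet_parse_error")
  bad <- matrix(c(1, 2, 0, 1), 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_error(occurrence_matrix(bad), class = "poolnet_parse_error")
})
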