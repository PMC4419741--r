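test_that("simulation is deterministic given the seed and cells are substreamed", {
  cfg <- twin_sim_config(50, ace_paths(), seed = 42)
  expect_identical(simulate_twins(cfg), simulate_twins(cfg))
  # a different seed changes the draws
  cfg2 <- twin_sim_config(50, ace_paths(), seed = 43)
  expect_false(identical(simulate_twins(cfg), simulate_twins(cfg2)))
})

test_that("cross-twin correlations match the generating variance components", {
  # E-only: co-twins are independent
  e_only <- paths_from_components(a2 = 0, e2 = 1)
  d <- simulate_twins(twin_sim_config(c(MZM = 50000, DZM = 1, MZF = 1, DZF = 1),
                                      e_only, seed = 9))
  mz <- d[d$zygosity == "MZ" & d$sex == "M", ]
  expect_lt(abs(cor(mz$ph1_t1, mz$ph1_t2)), 0.03)

  # a2 = 0.6, c2 = 0.2: MZ ICC -> 0.8, DZ ICC -> 0.5
  d <- sim_ace(n = 50000, a2 = 0.6, c2 = 0.2, seed = 10)
  expect_equal(cross_twin_icc(d, "MZM", "ph1")$r, 0.8, tolerance = 0.02)
  expect_equal(cross_twin_icc(d, "DZM", "ph1")$r, 0.5, tolerance = 0.03)
})

test_that("DZ cross-twin covariance reflects A/2 + D/4 under an ADE model", {
  p <- paths_from_components(a2 = 0.4, d2 = 0.4, e2 = 0.2)
  d <- simulate_twins(twin_sim_config(40000, p, seed = 11))
  # expectation: MZ 0.8, DZ 0.5*0.4 + 0.25*0.4 = 0.3
  expect_equal(cross_twin_icc(d, "MZF", "ph1")$r, 0.8, tolerance = 0.02)
  expect_equal(cross_twin_icc(d, "DZF", "ph1")$r, 0.3, tolerance = 0.03)
})

test_that("skew transforms are monotone: Spearman cross-twin correlation invariant", {
  base <- twin_sim_config(4000, ace_paths(), seed = 12)
  skewed <- twin_sim_config(4000, ace_paths(), seed = 12,
                            skew = list(ph1 = list(type = "exp", scale = 0.8)))
  d0 <- simulate_twins(base)
  d1 <- simulate_twins(skewed)
  mz0 <- d0[d0$zygosity == "MZ", ]; mz1 <- d1[d1$zygosity == "MZ", ]
  expect_equal(cor(mz0$ph1_t1, mz0$ph1_t2, method = "spearman"),
               cor(mz1$ph1_t1, mz1$ph1_t2, method = "spearman"),
               tolerance = 1e-12)
  expect_gt(sample_skew <- mean((mz1$ph1_t1 - mean(mz1$ph1_t1))^3) /
              sd(mz1$ph1_t1)^3, 1)
  # binning is monotone too and yields integer codes
  binned <- twin_sim_config(500, ace_paths(), seed = 12,
                            skew = list(ph1 = list(type = "bin",
                                                   cuts = c(-1, 0, 1, 2))))
  db <- simulate_twins(binned)
  expect_true(all(db$ph1_t1 %in% 0:4))
})

test_that("missingness is MCAR at the configured rate", {
  cfg <- twin_sim_config(20000, ace_paths(), missing_rate = c(ph1 = 0.3),
                         seed = 13)
  d <- simulate_twins(cfg)
  expect_equal(mean(is.na(d$ph1_t1)), 0.3, tolerance = 0.02)
  # co-twin scores where twin1 is missing look like those where observed
  m1 <- is.na(d$ph1_t1) & !is.na(d$ph1_t2)
  o1 <- !is.na(d$ph1_t1) & !is.na(d$ph1_t2)
  expect_lt(abs(mean(d$ph1_t2[m1]) - mean(d$ph1_t2[o1])), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(twin_sim_config(0, ace_paths()), "n_pairs")
  expect_error(twin_sim_config(10, ace_paths(), missing_rate = c(ph1 = 1)),
               "missing_rate")
  badR <- matrix(c(1, 2, 2, 1), 2)  # not PSD as a correlation matrix
  expect_error(paths_from_components(a2 = c(0.5, 0.5), e2 = c(0.5, 0.5),
                                     rA = badR), "PSD")
  expect_error(path_matrices(X = matrix(c(0, 0, 1, 0), 2), Z = diag(2)),
               "lower-triangular")
  expect_error(path_matrices(Y = diag(2), W = diag(2), Z = diag(2)),
               "C and D")
})

test_that("CSV round-trip is lossless and validated", {
  d <- simulate_twins(twin_sim_config(30, ace_paths(),
                                      missing_rate = c(ph1 = 0.2), seed = 3))
  f <- tempfile(fileext = ".csv")
  write_twin_data(d, f)
  d2 <- read_twin_data(f)
  expect_equal(d2$ph1_t1, d$ph1_t1)
  expect_equal(d2$ph1_t2, d$ph1_t2)
  expect_identical(attr(d2, "phenotypes"), "ph1")

  bad <- d; bad$zygosity[7] <- "XZ"
  write_twin_data(bad, f)
  expect_error(read_twin_data(f), "row 7")

  writeLines(character(), f)
  expect_warning(out <- read_twin_data(f), "empty")
  expect_equal(nrow(out), 0)
})
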