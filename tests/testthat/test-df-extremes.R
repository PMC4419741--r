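# z-score a pair table's phenotypes in place (individual-level pooled)
z_records <- function(d, phenos = twin_phenotypes(d)) {
  for (ph in phenos) {
    v <- c(d[[paste0(ph, "_t1")]], d[[paste0(ph, "_t2")]])
    z <- zscore(v)
    n <- nrow(d)
    d[[paste0(ph, "_t1")]] <- z[seq_len(n)]
    d[[paste0(ph, "_t2")]] <- z[n + seq_len(n)]
  }
  d
}

test_that("proband selection takes the declared tail with inclusive ties", {
  d <- sim_ace(n = 5, seed = 40)   # 20 pairs -> 40 individuals
  d <- z_records(d)
  expect_warning(ps <- select_probands(d, "ph1", proportion = 0.05,
                                       tail = "high"), "fewer than 10")
  long <- twinpath:::stack_twins(d)
  top2 <- sort(long$ph1, decreasing = TRUE)[1:2]
  key <- paste(ps$family_id, ps$twin)
  sel_vals <- long$ph1[paste(long$family_id, long$twin) %in% key]
  expect_equal(sort(sel_vals, decreasing = TRUE), top2)

  # low tail on negated scores selects the same individuals
  dn <- d
  dn$ph1_t1 <- -dn$ph1_t1; dn$ph1_t2 <- -dn$ph1_t2
  expect_warning(pslow <- select_probands(dn, "ph1", 0.05, tail = "low"),
                 "fewer than 10")
  expect_setequal(paste(pslow$family_id, pslow$twin), key)
  expect_error(select_probands(d, "ph1", 0.7), "proportion")
})

test_that("top-5% proband mean matches the truncated-normal oracle", {
  d <- z_records(sim_ace(n = 25000, seed = 41))
  ps <- select_probands(d, "ph1", 0.05, "high")
  # E[Z | Z > z_0.95] = phi(z_0.95) / 0.05
  oracle <- dnorm(qnorm(0.95)) / 0.05
  expect_equal(attr(ps, "proband_mean"), oracle, tolerance = 0.02)
  expect_equal(attr(ps, "population_mean"), 0, tolerance = 0.02)
})

test_that("the DF transformation maps population to 0 and probands to 1", {
  expect_equal(df_transform(0.3, 2, 0.3), 0)
  expect_equal(df_transform(2, 2, 0.3), 1)
  x <- rnorm(50, 2, 0.5)
  tr <- df_transform(x, mean(x), 0)
  expect_equal(mean(tr), 1, tolerance = 1e-12)
  expect_error(df_transform(1, 1, 1), "coincide")
})

test_that("transformed co-twin means order MZ > DZ > 0 under genetic influence", {
  d <- z_records(sim_ace(n = 25000, a2 = 0.6, c2 = 0.2, seed = 42))
  ps <- select_probands(d, "ph1", 0.05, "high")
  mu <- transformed_cotwin_means(ps, d)
  expect_gt(mu[["mu_MZ"]], mu[["mu_DZ"]])
  expect_gt(mu[["mu_DZ"]], 0)
  # co-twins identical to probands: transformed MZ co-twin mean is 1
  dd <- d; dd$ph1_t2 <- dd$ph1_t1
  attr(dd, "phenotypes") <- "ph1"
  ps2 <- select_probands(dd, "ph1", 0.05, "high")
  mu2 <- transformed_cotwin_means(ps2, dd)
  expect_equal(mu2[["mu_MZ"]], 1, tolerance = 1e-2)
})

test_that("univariate DF regression obeys its closed-form identities", {
  # balanced toy data: identical proband score distributions in MZ and DZ
  # (so proband scores are orthogonal to zygosity), plus filler families
  # anchoring the population mean; probands are exactly the twin-1s of the
  # first 2n families
  mk_toy <- function(mu_mz, mu_dz) {
    n <- 40
    p_scores <- rep(c(1.9, 2.1), n / 2)
    filler <- rep(c(-0.2, 0.2), 320 / 2)
    d <- data.frame(
      family_id = seq_len(2 * n + 320),
      zygosity = rep(c("MZ", "DZ", "MZ", "DZ"), c(n, n, 160, 160)),
      sex = "M", age = 12,
      ph1_t1 = c(p_scores, p_scores, filler),
      ph1_t2 = c(rep(mu_mz, n) + rep(c(-0.1, 0.1), n / 2),
                 rep(mu_dz, n) + rep(c(-0.1, 0.1), n / 2),
                 filler))
    attr(d, "phenotypes") <- "ph1"
    d
  }
  d <- mk_toy(0.6, 0.45)
  # the 80 proband twin-1s are the top 10% of 800 individuals
  ps <- select_probands(d, "ph1", 0.1, "high")
  res <- univariate_df(ps, d, covariates = FALSE, double_entry = FALSE)
  mu <- res$cotwin_means
  expect_equal(res$zygosity_coef, 2 * (mu[["mu_MZ"]] - mu[["mu_DZ"]]),
               tolerance = 1e-10)
  expect_false(res$cap_applied)
  expect_equal(res$capped_estimate, res$zygosity_coef, tolerance = 1e-12)

  # equal co-twin means in MZ and DZ: zero group heritability
  deq <- mk_toy(0.5, 0.5)
  pseq <- select_probands(deq, "ph1", 0.1, "high")
  req <- univariate_df(pseq, deq, covariates = FALSE, double_entry = FALSE)
  expect_equal(req$zygosity_coef, 0, tolerance = 1e-10)

  # a large MZ-DZ gap trips the cap at the MZ co-twin mean
  dcap <- mk_toy(0.4, 0.1)
  pscap <- select_probands(dcap, "ph1", 0.1, "high")
  rcap <- univariate_df(pscap, dcap, covariates = FALSE, double_entry = FALSE)
  expect_true(rcap$cap_applied)
  expect_gt(rcap$zygosity_coef, rcap$cotwin_means[["mu_MZ"]])
  expect_equal(rcap$capped_estimate, rcap$cotwin_means[["mu_MZ"]],
               tolerance = 1e-12)
})

test_that("DF outputs are invariant to twin order and x/y swap", {
  d <- z_records(sim_biv(n = 4000, rg = 0.6, seed = 43))
  sw <- d
  flip <- seq(1, nrow(d), by = 3)
  for (ph in c("ph1", "ph2")) {
    a <- paste0(ph, "_t1"); b <- paste0(ph, "_t2")
    tmp <- sw[[a]][flip]; sw[[a]][flip] <- sw[[b]][flip]; sw[[b]][flip] <- tmp
  }
  attr(sw, "phenotypes") <- c("ph1", "ph2")
  sx <- phenotype_spec("ph1", extreme_tail = "high")
  sy <- phenotype_spec("ph2", extreme_tail = "high")
  r1 <- df_extremes(d, sx, sy, proportion = 0.1)
  r2 <- df_extremes(sw, sx, sy, proportion = 0.1)
  expect_equal(r1$uni_x$capped_estimate, r2$uni_x$capped_estimate,
               tolerance = 1e-10)
  expect_equal(r1$r_g$r_g, r2$r_g$r_g, tolerance = 1e-10)
  # swapping the roles of x and y leaves the extremes genetic correlation
  r3 <- df_extremes(d, sy, sx, proportion = 0.1)
  expect_equal(r1$r_g$r_g, r3$r_g$r_g, tolerance = 1e-10)
})

test_that("group phenotypic correlation matches the truncated bivariate-normal oracle", {
  # E[Y | X > t] / E[X | X > t] = rho for standard bivariate normal
  d <- z_records(sim_biv(n = 30000, rg = 0.5, rc = 0.5, re = 0.5, seed = 44))
  # all component correlations 0.5 -> phenotypic correlation 0.5
  ps <- select_probands(d, "ph1", 0.05, "high")
  expect_equal(group_phenotypic_correlation(ps, d, "ph2"), 0.5,
               tolerance = 0.04)
  expect_equal(group_phenotypic_correlation(ps, d, "ph1"), 1, tolerance = 1e-12)
  d0 <- z_records(sim_biv(n = 20000, rg = 0, rc = 0, re = 0, seed = 45))
  ps0 <- select_probands(d0, "ph1", 0.05, "high")
  expect_lt(abs(group_phenotypic_correlation(ps0, d0, "ph2")), 0.06)
})

test_that("bivariate DF reduces to univariate and tracks genetic overlap", {
  d <- z_records(sim_biv(n = 20000, rg = 1, rc = 0, re = 0, seed = 46))
  sx <- phenotype_spec("ph1", extreme_tail = "high")
  sy <- phenotype_spec("ph2", extreme_tail = "high")
  ps <- select_probands(d, sx, 0.05)
  uni <- univariate_df(ps, d)
  biv_same <- bivariate_df(ps, d, "ph1")
  expect_equal(uni$zygosity_coef, biv_same$zygosity_coef, tolerance = 1e-12)

  # full A overlap: h2.xy explains ~ the whole group correlation
  res <- df_extremes(d, sx, sy, proportion = 0.05)
  ratio <- res$biv_xy$capped_estimate / res$group_cor_xy
  expect_equal(ratio, 1, tolerance = 0.25)
  expect_gt(res$r_g$r_g, 0.75)

  # no shared etiology: h2.xy near zero
  d0 <- z_records(sim_biv(n = 20000, rg = 0, rc = 0, re = 0, seed = 47))
  ps0 <- select_probands(d0, sx, 0.05)
  py0 <- select_probands(d0, sy, 0.05)
  b0 <- bivariate_df(ps0, d0, "ph2", outcome_probands = py0)
  expect_lt(abs(b0$zygosity_coef), 0.1)
})

test_that("extremes genetic correlation arithmetic and degenerate cases", {
  expect_equal(extremes_genetic_correlation(0.5, 0.5, 0.5, 0.5)$r_g, 1)
  expect_equal(extremes_genetic_correlation(0, 0.3, 0.6, 0.5)$r_g, 0)
  expect_equal(extremes_genetic_correlation(0.2, 0.3, 0.6, 0.5)$r_g,
               sqrt(0.06 / 0.30), tolerance = 1e-12)
  # negative product: negative correlation of matching magnitude
  expect_equal(extremes_genetic_correlation(-0.2, 0.3, 0.6, 0.5)$r_g,
               -sqrt(0.06 / 0.30), tolerance = 1e-12)
  # magnitude above 1 is clipped and flagged
  big <- extremes_genetic_correlation(0.9, 0.9, 0.3, 0.3)
  expect_equal(big$r_g, 1)
  expect_true(big$clipped)
  bad <- extremes_genetic_correlation(0.2, 0.2, -0.1, 0.5)
  expect_false(bad$valid)
  expect_true(is.na(bad$r_g))
})

test_that("capped group heritability tracks the generating a2", {
  d <- z_records(sim_ace(n = 25000, a2 = 0.6, c2 = 0.2, seed = 48))
  ps <- select_probands(d, "ph1", 0.05, "high")
  res <- univariate_df(ps, d)
  expect_equal(res$capped_estimate, 0.6, tolerance = 0.07)
})
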