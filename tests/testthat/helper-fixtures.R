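# small generating models reused across tests

ace_paths <- function(a2 = 0.6, c2 = 0.2, e2 = 1 - a2 - c2, ...) {
  paths_from_components(a2 = a2, c2 = c2, e2 = e2, ...)
}

# univariate ACE cohort with equal-sized cells, no transforms or missingness
sim_ace <- function(n = 1000, a2 = 0.6, c2 = 0.2, seed = 1) {
  simulate_twins(twin_sim_config(n, ace_paths(a2, c2), seed = seed))
}

# z-scored records ready for model fitting / DF analysis
prep_ace <- function(n = 1000, a2 = 0.6, c2 = 0.2, seed = 1) {
  preprocess_twins(sim_ace(n, a2, c2, seed), list(phenotype_spec("ph1")))
}

# bivariate generator with controllable component correlations
sim_biv <- function(n, a2 = c(0.6, 0.5), c2 = c(0.2, 0.2), rg = 0.5,
                    rc = 0.3, re = 0, seed = 1, missing_rate = NULL) {
  R <- function(r) matrix(c(1, r, r, 1), 2)
  p <- paths_from_components(a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
                             rA = R(rg), rC = R(rc), rE = R(re))
  simulate_twins(twin_sim_config(n, p, missing_rate = missing_rate,
                                 seed = seed))
}

prep_biv <- function(...) {
  preprocess_twins(sim_biv(...),
                   list(phenotype_spec("ph1"), phenotype_spec("ph2")))
}

# brute-force -2LL oracle: per-pair multivariate normal density evaluated
# row by row, independent of the pattern-grouped implementation
brute_force_m2ll <- function(records, phenotypes, paths_by_sex) {
  if (inherits(paths_by_sex, "path_matrices"))
    paths_by_sex <- list(male = paths_by_sex, female = paths_by_sex)
  total <- 0
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    y <- c(unlist(row[paste0(phenotypes, "_t1")]),
           unlist(row[paste0(phenotypes, "_t2")]))
    o <- which(!is.na(y))
    if (!length(o)) next
    paths <- paths_by_sex[[if (row$sex == "M") "male" else "female"]]
    mom <- implied_moments(paths, row$zygosity)
    mu <- mom$mean[o]
    sig <- mom$sigma[o, o, drop = FALSE]
    d <- y[o] - mu
    ld <- determinant(sig, logarithm = TRUE)$modulus
    total <- total - 2 * (-0.5 * (length(o) * log(2 * pi) + ld +
                                  drop(t(d) %*% solve(sig) %*% d)))
  }
  as.numeric(total)
}
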