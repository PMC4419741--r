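# ---- DeFries-Fulker extremes analysis -------------------------------------

#' Select extreme-scoring probands
#'
#' Individuals scoring beyond the empirical quantile of a z-transformed
#' scale: the highest `proportion` for high-tail (trait) scales, the lowest
#' for low-tail (ability) scales. Either twin of a pair may qualify; ties at
#' the threshold are included. Records the proband and population means on
#' the z scale, which define the DF transformation.
#'
#' @param records twin-pair data frame with z-transformed phenotypes
#' @param phenotype the selection phenotype
#' @param proportion tail proportion in (0, 0.5]
#' @param tail `"high"` or `"low"`; a [phenotype_spec()] may be supplied
#'   instead of the phenotype name to carry its `extreme_tail`
#' @return an object of class `proband_set`: data frame of proband
#'   individuals (`family_id`, `twin`) plus means and per-zygosity counts in
#'   attributes
#' @export
select_probands <- function(records, phenotype, proportion = 0.05,
                            tail = c("high", "low")) {
  if (inherits(phenotype, "phenotype_spec")) {
    tail <- phenotype$extreme_tail
    phenotype <- phenotype$name
  } else tail <- match.arg(tail)
  if (proportion <= 0 || proportion > 0.5)
    stop("proportion must lie in (0, 0.5]")
  long <- stack_twins(records)
  z <- long[[phenotype]]
  ok <- !is.na(z)
  if (tail == "high") {
    thr <- stats::quantile(z[ok], 1 - proportion, names = FALSE)
    sel <- ok & z >= thr
  } else {
    thr <- stats::quantile(z[ok], proportion, names = FALSE)
    sel <- ok & z <= thr
  }
  if (!any(sel)) stop("no probands selected")
  if (sum(sel) < 10)
    warning("fewer than 10 probands selected (", sum(sel), ")")
  pro <- long[sel, c("family_id", "twin", "zygosity", "sex")]
  proband_mean <- mean(z[sel])
  population_mean <- mean(z[ok])
  if (abs(proband_mean - population_mean) < 1e-12)
    stop("proband mean equals population mean; selection is degenerate")
  structure(pro,
            phenotype = phenotype, tail = tail, proportion = proportion,
            threshold = thr, proband_mean = proband_mean,
            population_mean = population_mean,
            n_by_zygosity = table(pro$zygosity),
            class = c("proband_set", "data.frame"))
}

#' DF transformation of scores
#'
#' Linear rescaling so the proband mean maps to 1 and the population mean to
#' 0: `(x - population_mean) / (proband_mean - population_mean)`. On this
#' scale the transformed co-twin mean reads as a twin group correlation.
#'
#' @param scores numeric vector
#' @param proband_mean,population_mean means on the input (z) scale
#' @return transformed scores
#' @export
df_transform <- function(scores, proband_mean, population_mean) {
  den <- proband_mean - population_mean
  if (abs(den) < 1e-12) stop("proband and population means coincide")
  if (abs(den) < 0.1)
    warning("proband mean is very close to the population mean; ",
            "transformed scores are poorly scaled")
  (scores - population_mean) / den
}

# proband/co-twin rows for a DF regression: one row per proband (double
# entry, so concordant pairs contribute once per ordering); outcome is the
# co-twin's transformed score, predictor the proband's transformed score on
# the selection variable
df_design <- function(probands, records, outcome_phenotype,
                      double_entry = TRUE) {
  sel_ph <- attr(probands, "phenotype")
  idx <- match(probands$family_id, records$family_id)
  pt <- probands$twin
  sel_self <- records[[paste0(sel_ph, "_t1")]][idx]
  sel_self2 <- records[[paste0(sel_ph, "_t2")]][idx]
  P_raw <- ifelse(pt == 1L, sel_self, sel_self2)
  C_raw <- ifelse(pt == 1L,
                  records[[paste0(outcome_phenotype, "_t2")]][idx],
                  records[[paste0(outcome_phenotype, "_t1")]][idx])
  d <- data.frame(family_id = probands$family_id, twin = pt,
                  zygosity = probands$zygosity,
                  sex = records$sex[idx], age = records$age[idx],
                  P_raw = P_raw, C_raw = C_raw)
  if (!double_entry) d <- d[!duplicated(d$family_id), , drop = FALSE]
  d[!is.na(d$C_raw) & !is.na(d$P_raw), , drop = FALSE]
}

#' Transformed co-twin means by zygosity
#'
#' Means of the DF-transformed co-twin scores on an outcome phenotype, by
#' proband zygosity. Greater regression of the DZ mean toward the population
#' mean (0) than the MZ mean indicates genetic influence on extreme scores.
#' Concordant pairs are double-entered. The outcome is transformed by its
#' own proband/population means, supplied through `outcome_probands` when
#' the outcome differs from the selection variable.
#'
#' @param probands a [select_probands()] object (selection variable)
#' @param records twin-pair data frame with z-transformed phenotypes
#' @param outcome_phenotype outcome phenotype name (default: the selection
#'   variable)
#' @param outcome_probands optional `proband_set` on the outcome phenotype
#'   supplying its transformation means
#' @return named vector `c(mu_MZ =, mu_DZ =)`
#' @export
transformed_cotwin_means <- function(probands, records,
                                     outcome_phenotype = attr(probands, "phenotype"),
                                     outcome_probands = NULL) {
  tr <- outcome_transform(probands, records, outcome_phenotype, outcome_probands)
  d <- df_design(probands, records, outcome_phenotype)
  if (!all(c("MZ", "DZ") %in% d$zygosity))
    stop("a zygosity cell has no proband/co-twin data")
  Ct <- df_transform(d$C_raw, tr["proband"], tr["population"])
  c(mu_MZ = mean(Ct[d$zygosity == "MZ"]), mu_DZ = mean(Ct[d$zygosity == "DZ"]))
}

# transformation means for the outcome variable: its own selection if it
# differs from the selection variable
outcome_transform <- function(probands, records, outcome_phenotype,
                              outcome_probands = NULL) {
  if (identical(outcome_phenotype, attr(probands, "phenotype"))) {
    c(proband = attr(probands, "proband_mean"),
      population = attr(probands, "population_mean"))
  } else {
    if (is.null(outcome_probands))
      stop("supply outcome_probands: the outcome variable is transformed by ",
           "its own proband/population means")
    c(proband = attr(outcome_probands, "proband_mean"),
      population = attr(outcome_probands, "population_mean"))
  }
}

df_regression <- function(d, Pt, Ct, covariates) {
  # zygosity coded as the coefficient of relatedness R (MZ = 1, DZ = 0.5) so
  # that beta2 equals twice the MZ-DZ difference in transformed co-twin means
  R <- ifelse(d$zygosity == "MZ", 1, 0.5)
  dat <- data.frame(C = Ct, P = Pt, R = R)
  form <- C ~ P + R
  if (covariates) {
    dat$sex <- as.numeric(d$sex == "M")
    dat$age <- d$age
    use <- c(stats::var(dat$sex) > 0, stats::var(dat$age) > 0)
    if (any(use))
      form <- stats::reformulate(c("P", "R", c("sex", "age")[use]),
                                 response = "C")
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) stop("collinear DF design matrix")
  fit
}

#' Univariate DeFries-Fulker extremes regression
#'
#' Regresses DF-transformed co-twin scores on proband scores and the
#' coefficient of relatedness (`R` = 1 for MZ, 0.5 for DZ pairs), with sex
#' and age covariates. The zygosity coefficient `beta2` equals twice the
#' difference between the transformed MZ and DZ co-twin means and estimates
#' group heritability `h2g` - the genetic contribution to extreme scores. It
#' is capped at the transformed MZ co-twin mean; an uncapped excess can
#' indicate non-additive genetic influence.
#'
#' @param probands a [select_probands()] object
#' @param records twin-pair data frame with z-transformed phenotypes
#' @param covariates include sex and age in the regression (default TRUE)
#' @param double_entry double-enter concordant pairs (default TRUE)
#' @return an object of class `df_fit`: coefficients, transformed co-twin
#'   means, raw and capped `h2g`, cap flag, per-zygosity proband counts
#' @export
univariate_df <- function(probands, records, covariates = TRUE,
                          double_entry = TRUE) {
  bivariate_df(probands, records,
               outcome_phenotype = attr(probands, "phenotype"),
               covariates = covariates, double_entry = double_entry)
}

#' Bivariate DeFries-Fulker regression
#'
#' As [univariate_df()], but the outcome is the co-twin's DF-transformed
#' score on a second phenotype (transformed by that phenotype's own
#' proband/population means). The zygosity coefficient estimates `h2.xy`,
#' the genetic influence on the selection variable that also influences the
#' outcome at the extreme, capped at the transformed MZ co-twin mean on the
#' outcome. The ratio of `h2.xy` to the phenotypic group correlation gives
#' the proportion of that correlation explained by additive genetic factors;
#' a ratio above 1 is flagged as possible non-additivity.
#'
#' @inheritParams univariate_df
#' @param outcome_phenotype outcome phenotype name
#' @param outcome_probands `proband_set` on the outcome phenotype (required
#'   when the outcome differs from the selection variable)
#' @return an object of class `df_fit`
#' @export
bivariate_df <- function(probands, records, outcome_phenotype,
                         outcome_probands = NULL, covariates = TRUE,
                         double_entry = TRUE) {
  tr <- outcome_transform(probands, records, outcome_phenotype, outcome_probands)
  d <- df_design(probands, records, outcome_phenotype, double_entry)
  if (!all(c("MZ", "DZ") %in% d$zygosity))
    stop("a zygosity cell has no proband/co-twin data")
  sel_tr <- c(attr(probands, "proband_mean"), attr(probands, "population_mean"))
  Pt <- df_transform(d$P_raw, sel_tr[1], sel_tr[2])
  Ct <- df_transform(d$C_raw, tr["proband"], tr["population"])
  fit <- df_regression(d, Pt, Ct, covariates)
  cf <- stats::coef(fit)
  mu <- c(mu_MZ = mean(Ct[d$zygosity == "MZ"]),
          mu_DZ = mean(Ct[d$zygosity == "DZ"]))
  beta2 <- unname(cf["R"])
  cap_applied <- beta2 > mu[["mu_MZ"]]
  univariate <- identical(outcome_phenotype, attr(probands, "phenotype"))
  res <- list(
    selection = attr(probands, "phenotype"),
    outcome = outcome_phenotype,
    proportion = attr(probands, "proportion"),
    univariate = univariate,
    proband_coef = unname(cf["P"]),
    zygosity_coef = beta2,
    intercept = unname(cf["(Intercept)"]),
    covariate_coefs = cf[setdiff(names(cf), c("(Intercept)", "P", "R"))],
    cotwin_means = mu,
    capped_estimate = min(beta2, mu[["mu_MZ"]]),
    cap_applied = cap_applied,
    n_probands = table(d$zygosity),
    lm_fit = fit
  )
  class(res) <- "df_fit"
  res
}

#' @export
print.df_fit <- function(x, digits = 3, ...) {
  lab <- if (x$univariate) "h2g (group heritability)" else "h2.xy"
  cat(sprintf("DeFries-Fulker %s regression: %s selects, outcome %s (top/bottom %g%%)\n",
              if (x$univariate) "univariate" else "bivariate",
              x$selection, x$outcome, 100 * x$proportion))
  cat(sprintf("transformed co-twin means: MZ %.3f, DZ %.3f\n",
              x$cotwin_means[["mu_MZ"]], x$cotwin_means[["mu_DZ"]]))
  cat(sprintf("%s = %.3f (raw %.3f%s)\n", lab, x$capped_estimate,
              x$zygosity_coef,
              if (x$cap_applied) ", capped at MZ co-twin mean" else ""))
  invisible(x)
}

#' @export
coef.df_fit <- function(object, ...) stats::coef(object$lm_fit)

#' @export
summary.df_fit <- function(object, ...) summary(object$lm_fit, ...)

#' Phenotypic group correlation
#'
#' Association between the selection variable and another measure within the
#' extreme-scoring group: the mean proband z-score on the outcome measure
#' divided by the mean proband z-score on the selection measure.
#'
#' @param probands a [select_probands()] object
#' @param records twin-pair data frame with z-transformed phenotypes
#' @param outcome_phenotype outcome phenotype name
#' @return the group correlation (scalar)
#' @export
group_phenotypic_correlation <- function(probands, records, outcome_phenotype) {
  long <- stack_twins(records)
  key <- paste(long$family_id, long$twin)
  pkey <- paste(probands$family_id, probands$twin)
  rows <- long[key %in% pkey, , drop = FALSE]
  zx <- rows[[attr(probands, "phenotype")]]
  zy <- rows[[outcome_phenotype]]
  ok <- !is.na(zx) & !is.na(zy)
  mx <- mean(zx[ok])
  if (abs(mx) < 1e-12) stop("mean proband z on the selection variable is zero")
  mean(zy[ok]) / mx
}

#' Genetic correlation between extreme-scoring groups
#'
#' Combines the two directed bivariate DF estimates with the univariate
#' group heritabilities:
#' `r_g = sign(bxy * byx) * sqrt(|bxy * byx| / (bx * by))`,
#' clipped to [-1, 1] (with a flag when the unclipped magnitude exceeds 1).
#' Both univariate estimates must be positive for the ratio to be defined.
#'
#' @param beta_xy bivariate estimate `h2.xy` with x selecting
#' @param beta_yx the reverse direction
#' @param beta_x,beta_y univariate `h2g` for each phenotype
#' @return list with `r_g`, `valid`, `clipped` and the inputs
#' @export
#' @examples
#' extremes_genetic_correlation(0.2, 0.3, 0.6, 0.5)$r_g  # ~0.447
extremes_genetic_correlation <- function(beta_xy, beta_yx, beta_x, beta_y) {
  if (!is.finite(beta_x * beta_y) || beta_x * beta_y <= 0)
    return(list(r_g = NA_real_, valid = FALSE, clipped = FALSE,
                beta_xy = beta_xy, beta_yx = beta_yx,
                beta_x = beta_x, beta_y = beta_y))
  prod_xy <- beta_xy * beta_yx
  r <- sign(prod_xy) * sqrt(abs(prod_xy) / (beta_x * beta_y))
  clipped <- abs(r) > 1
  list(r_g = max(-1, min(1, r)), valid = TRUE, clipped = clipped,
       beta_xy = beta_xy, beta_yx = beta_yx, beta_x = beta_x, beta_y = beta_y)
}

#' Full DF extremes analysis for a phenotype pair
#'
#' Convenience wrapper running proband selection on both phenotypes, the two
#' univariate and two directed bivariate DF regressions, the phenotypic
#' group correlations, and the extremes genetic correlation.
#'
#' @param records twin-pair data frame with z-transformed phenotypes
#' @param spec_x,spec_y [phenotype_spec()] objects (their `extreme_tail`
#'   decides the selected tail)
#' @param proportion tail proportion
#' @param covariates include sex and age covariates
#' @return an object of class `df_pair`: the four `df_fit`s, group
#'   correlations in both directions, and the extremes `r_g`
#' @export
df_extremes <- function(records, spec_x, spec_y, proportion = 0.05,
                        covariates = TRUE) {
  px <- select_probands(records, spec_x, proportion)
  py <- select_probands(records, spec_y, proportion)
  uni_x <- univariate_df(px, records, covariates)
  uni_y <- univariate_df(py, records, covariates)
  biv_xy <- bivariate_df(px, records, spec_y$name, outcome_probands = py,
                         covariates = covariates)
  biv_yx <- bivariate_df(py, records, spec_x$name, outcome_probands = px,
                         covariates = covariates)
  rg <- extremes_genetic_correlation(
    biv_xy$capped_estimate, biv_yx$capped_estimate,
    uni_x$capped_estimate, uni_y$capped_estimate)
  structure(list(
    x = spec_x$name, y = spec_y$name, proportion = proportion,
    uni_x = uni_x, uni_y = uni_y, biv_xy = biv_xy, biv_yx = biv_yx,
    group_cor_xy = group_phenotypic_correlation(px, records, spec_y$name),
    group_cor_yx = group_phenotypic_correlation(py, records, spec_x$name),
    r_g = rg
  ), class = "df_pair")
}

#' @export
print.df_pair <- function(x, ...) {
  cat(sprintf("DF extremes analysis: %s vs %s at %g%%\n", x$x, x$y,
              100 * x$proportion))
  cat(sprintf("h2g(%s) = %.3f, h2g(%s) = %.3f\n", x$x,
              x$uni_x$capped_estimate, x$y, x$uni_y$capped_estimate))
  cat(sprintf("h2.xy = %.3f (group r %.3f), h2.yx = %.3f (group r %.3f)\n",
              x$biv_xy$capped_estimate, x$group_cor_xy,
              x$biv_yx$capped_estimate, x$group_cor_yx))
  cat(sprintf("extremes r_g = %.3f%s\n", x$r_g$r_g,
              if (isTRUE(x$r_g$clipped)) " (clipped)" else ""))
  invisible(x)
}
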