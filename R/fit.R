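# ---- method-of-moments starting values ------------------------------------

# double-entry within/cross covariance matrices for one zygosity, restricted
# to the given sexes, complete pairs only
de_moments <- function(records, phenotypes, zyg, sexes) {
  k <- length(phenotypes)
  sel <- records[records$zygosity == zyg & records$sex %in% sexes, , drop = FALSE]
  Y1 <- pheno_matrix(sel, phenotypes, 1)
  Y2 <- pheno_matrix(sel, phenotypes, 2)
  cc <- stats::complete.cases(cbind(Y1, Y2))
  if (sum(cc) < k + 2) return(NULL)
  Yd <- rbind(cbind(Y1[cc, , drop = FALSE], Y2[cc, , drop = FALSE]),
              cbind(Y2[cc, , drop = FALSE], Y1[cc, , drop = FALSE]))
  Cv <- stats::cov(Yd)
  list(V = Cv[seq_len(k), seq_len(k), drop = FALSE],
       cross = Cv[seq_len(k), k + seq_len(k), drop = FALSE],
       mean = colMeans(Yd)[seq_len(k)])
}

mom_start_paths <- function(records, phenotypes, spec, sexes) {
  k <- length(phenotypes)
  mz <- de_moments(records, phenotypes, "MZ", sexes)
  dz <- de_moments(records, phenotypes, "DZ", sexes)
  if (is.null(mz) || is.null(dz)) {
    eye <- diag(k) * 0.5
    mats <- list(A = eye, C = eye, D = eye, E = diag(k) * 0.7)
    mu <- rep(0, k)
  } else {
    V <- (mz$V + dz$V) / 2
    cmz <- mz$cross; cdz <- dz$cross
    comps <- spec$components
    A <- C <- D <- matrix(0, k, k)
    if (setequal(comps, c("A", "C", "E"))) {
      A <- 2 * (cmz - cdz); C <- 2 * cdz - cmz
    } else if (setequal(comps, c("A", "D", "E"))) {
      A <- 4 * cdz - cmz; D <- 2 * cmz - 4 * cdz
    } else if (setequal(comps, c("A", "E"))) {
      A <- (cmz + 2 * cdz) / 2
    } else if (setequal(comps, c("C", "E"))) {
      C <- (cmz + cdz) / 2
    }
    E <- V - A - C - D
    mats <- list(A = A, C = C, D = D, E = E)
    mu <- (mz$mean + dz$mean) / 2
  }
  path_matrices(
    X = if ("A" %in% spec$components) lower_chol(mats$A, 1e-3) else NULL,
    Y = if ("C" %in% spec$components) lower_chol(mats$C, 1e-3) else NULL,
    W = if ("D" %in% spec$components) lower_chol(mats$D, 1e-3) else NULL,
    Z = lower_chol(mats$E, 0.02),
    mean = mu
  )
}

run_nlminb <- function(start, obj, gr = NULL, iter.max = 3000) {
  stats::nlminb(start, obj, gradient = gr,
                control = list(iter.max = iter.max, eval.max = 4 * iter.max,
                               rel.tol = 1e-12))
}

# ---- Cholesky model fitting -----------------------------------------------

#' Fit a Cholesky twin model by full-information maximum likelihood
#'
#' Estimates a multivariate ACE / ADE / AE / CE / E model across the four
#' zygosity-sex groups of same-sex twin pairs. Variance components are
#' parameterized through lower-triangular path matrices (guaranteeing
#' positive semi-definite component covariances); means are equated across
#' twins and zygosity, and across sexes unless `sex_limitation =
#' "quantitative"`. The -2 log-likelihood is minimized numerically with
#' method-of-moments starting values plus random restarts; partially missing
#' phenotypes are handled by the full-information likelihood.
#'
#' @param records preprocessed twin-pair data frame (see
#'   [preprocess_twins()])
#' @param phenotypes phenotype names to model (default: all)
#' @param components variance components, e.g. `c("A", "C", "E")`
#' @param sex_limitation `"equated"` or `"quantitative"`
#' @param n_restarts number of optimizer starts (first from method-of-moments
#'   values, the rest jittered)
#' @param seed seed for the restart jitter (does not touch the caller's RNG)
#' @return an object of class `twinfit` with components `paths`
#'   (`list(male =, female =)` of [path_matrices()]), `minus2LL`,
#'   `n_parameters`, `df` (observed data points minus parameters),
#'   `converged`, and `n_restarts_used`
#' @seealso [fit_saturated()], [correlated_factors()],
#'   [likelihood_ratio_test()], [confint.twinfit()]
#' @export
twin_cholesky <- function(records, phenotypes = twin_phenotypes(records),
                          components = c("A", "C", "E"),
                          sex_limitation = c("equated", "quantitative"),
                          n_restarts = 5, seed = 1L) {
  sex_limitation <- match.arg(sex_limitation)
  spec <- biometric_spec(components, length(phenotypes), sex_limitation)
  pd <- build_pattern_data(records, phenotypes)
  if (length(pd) < 2) stop("need data in at least 2 zygosity-sex groups")
  ofns <- make_objective(spec, pd)
  start_paths <- if (n_sex_sets(spec) == 2L) {
    list(male = mom_start_paths(records, phenotypes, spec, "M"),
         female = mom_start_paths(records, phenotypes, spec, "F"))
  } else {
    p <- mom_start_paths(records, phenotypes, spec, c("M", "F"))
    list(male = p, female = p)
  }
  start0 <- pack_paths(start_paths, spec)
  starts <- with_local_seed(substream_seed(seed, "restarts"), {
    lapply(seq_len(max(1, n_restarts)), function(i) {
      if (i == 1) start0
      else start0 + stats::rnorm(length(start0), 0, 0.05 * (abs(start0) + 0.1))
    })
  })
  best <- NULL
  for (s in starts) {
    res <- run_nlminb(s, ofns$fn, ofns$gr)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  paths <- unpack_theta(best$par, spec)
  paths$male <- canonicalize_paths(paths$male)
  paths$female <- canonicalize_paths(paths$female)
  n_par <- count_parameters(spec)
  n_points <- attr(pd, "n_points")
  structure(list(
    spec = spec, paths = paths, minus2LL = best$objective,
    n_parameters = n_par, n_obs_points = n_points, df = n_points - n_par,
    converged = is.finite(best$objective) && best$objective < 1e10,
    n_restarts_used = length(starts), phenotypes = phenotypes,
    records = records, model = model_name(spec), call = match.call()
  ), class = "twinfit")
}

#' Fit the saturated twin model
#'
#' Unstructured means and covariances per group, fitted by full-information
#' maximum likelihood (closed-form sample moments when a group's data are
#' complete). Under `sex_limitation = "quantitative"` moments are free in
#' each of the four zygosity-sex groups; under `"equated"` they are shared
#' across sexes within zygosity.
#'
#' @inheritParams twin_cholesky
#' @return a `twinfit` object with `model = "saturated"`
#' @export
fit_saturated <- function(records, phenotypes = twin_phenotypes(records),
                          sex_limitation = c("quantitative", "equated")) {
  sex_limitation <- match.arg(sex_limitation)
  k <- length(phenotypes); p <- 2 * k
  by <- if (sex_limitation == "quantitative") TWIN_GROUPS else c("MZ", "DZ")
  pd <- build_pattern_data(records, phenotypes, by = by)
  total <- 0
  moments <- list()
  conv <- TRUE
  for (g in names(pd)) {
    pats <- pd[[g]]
    complete <- length(pats) == 1L && length(pats[[1]]$obs) == p
    if (complete) {
      mu <- pats[[1]]$mean
      sig <- pats[[1]]$S
      v <- pattern_m2ll(pats[[1]], mu, sig)
    } else {
      # optimize mean + covariance Cholesky factor for this group alone
      start_sig <- diag(p)
      start_mu <- rep(0, p)
      cp <- pats[[which.max(vapply(pats, function(q) length(q$obs) * q$n, 0))]]
      start_mu[cp$obs] <- cp$mean
      if (length(cp$obs) == p) start_sig <- psd_clip(cp$S, 0.05)
      theta0 <- c(start_mu, lower_to_vec(lower_chol(start_sig, 0.05)))
      geval <- function(th) {
        mu <- th[seq_len(p)]
        L <- vec_to_lower(th[p + seq_len(tri_n(p))], p)
        gg <- group_moment_grad(pats, mu, tcrossprod(L))
        if (is.null(gg)) return(NULL)
        list(val = gg$val,
             grad = c(gg$g, lower_to_vec((gg$G + t(gg$G)) %*% L)))
      }
      gobj <- function(th) {
        gg <- geval(th)
        if (is.null(gg)) 1e10 else gg$val
      }
      ggr <- function(th) {
        gg <- geval(th)
        if (is.null(gg)) rep(0, length(th)) else gg$grad
      }
      res <- run_nlminb(theta0, gobj, ggr)
      conv <- conv && res$objective < 1e10
      mu <- res$par[seq_len(p)]
      sig <- tcrossprod(vec_to_lower(res$par[p + seq_len(tri_n(p))], p))
      v <- res$objective
    }
    moments[[g]] <- list(mean = mu, sigma = sig)
    total <- total + v
  }
  n_par <- count_parameters_saturated(k, length(moments))
  n_points <- attr(pd, "n_points")
  structure(list(
    spec = list(sex_limitation = sex_limitation, k = k), moments = moments,
    minus2LL = total, n_parameters = n_par, n_obs_points = n_points,
    df = n_points - n_par, converged = conv, n_restarts_used = 1L,
    phenotypes = phenotypes, records = records, model = "saturated",
    call = match.call()
  ), class = "twinfit")
}

# ---- model comparison -----------------------------------------------------

#' AIC of a likelihood-ratio comparison
#'
#' Akaike's Information Criterion of a model relative to its comparison
#' model, computed as `delta_chi2 - 2 * delta_df`. Lower (preferably
#' negative) values indicate better fit.
#'
#' @param delta_chi2 change in -2 log-likelihood
#' @param delta_df change in number of parameters
#' @return numeric AIC
#' @export
#' @examples
#' lrt_aic(126.37, 80)   # -33.63
lrt_aic <- function(delta_chi2, delta_df) {
  if (any(delta_df <= 0)) stop("delta_df must be positive")
  delta_chi2 - 2 * delta_df
}

#' Likelihood-ratio test between nested twin models
#'
#' The difference in -2 log-likelihood between a restricted model and the
#' fuller model it is nested in is chi-square distributed with degrees of
#' freedom equal to the difference in parameter counts; a significant result
#' means the restricted model fits worse. Also reports the comparison AIC.
#'
#' @param sub the restricted (nested) `twinfit`
#' @param full the fuller `twinfit` (more parameters, lower -2LL)
#' @return a one-row data frame of class `twin_lrt`: model, comparison,
#'   `minus2LL`, `delta_chi2`, `delta_df`, `p_value`, `AIC`
#' @export
likelihood_ratio_test <- function(sub, full) {
  stopifnot(inherits(sub, "twinfit"), inherits(full, "twinfit"))
  if (!sub$converged || !full$converged)
    stop("both fits must have converged")
  if (sub$n_parameters >= full$n_parameters)
    stop("'sub' must have fewer parameters than 'full'")
  d_chi2 <- sub$minus2LL - full$minus2LL
  tol <- 1e-6 * max(1, abs(full$minus2LL))
  if (d_chi2 < -tol)
    stop("nested model has lower -2LL than the fuller model; refit with ",
         "more restarts")
  d_chi2 <- max(d_chi2, 0)
  d_df <- full$n_parameters - sub$n_parameters
  out <- data.frame(
    model = sub$model, comparison = full$model,
    minus2LL = sub$minus2LL, delta_chi2 = d_chi2, delta_df = d_df,
    p_value = stats::pchisq(d_chi2, d_df, lower.tail = FALSE),
    AIC = lrt_aic(d_chi2, d_df), stringsAsFactors = FALSE
  )
  class(out) <- c("twin_lrt", "data.frame")
  out
}

#' @export
anova.twinfit <- function(object, ...) {
  others <- list(...)
  if (!length(others)) stop("supply a second twinfit to compare against")
  full <- others[[1]]
  if (object$n_parameters < full$n_parameters)
    likelihood_ratio_test(object, full)
  else likelihood_ratio_test(full, object)
}

# ---- standard methods -----------------------------------------------------

#' @export
print.twinfit <- function(x, ...) {
  cat("Twin model:", x$model,
      if (!is.null(x$spec$sex_limitation)) paste0("(", x$spec$sex_limitation, " sexes)"),
      "\n")
  cat("Phenotypes:", paste(x$phenotypes, collapse = ", "), "\n")
  cat(sprintf("-2LL = %.2f on %d observed data points (%d parameters, df = %d)\n",
              x$minus2LL, x$n_obs_points, x$n_parameters, x$df))
  if (!x$converged) cat("WARNING: optimization did not converge\n")
  invisible(x)
}

#' @export
logLik.twinfit <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$n_parameters,
            nobs = object$n_obs_points, class = "logLik")
}

#' @export
coef.twinfit <- function(object, ...) {
  if (object$model == "saturated")
    return(unlist(lapply(object$moments, function(m) c(m$mean, lower_to_vec(lower_chol(m$sigma, 0))))))
  pack_paths(object$paths, object$spec)
}

#' @export
summary.twinfit <- function(object, ...) {
  out <- list(fit = object,
              solution = if (object$model != "saturated")
                correlated_factors(object) else NULL)
  class(out) <- "summary.twinfit"
  out
}

#' @export
print.summary.twinfit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$solution)) print(x$solution)
  invisible(x)
}

#' Simulate from a fitted twin model
#'
#' Draws new twin-pair datasets from the fitted path matrices via
#' [simulate_twins()], preserving the per-group sample sizes of the data the
#' model was fitted to.
#'
#' @param object a converged `twinfit` (Cholesky models only)
#' @param nsim number of datasets
#' @param seed integer seed
#' @param ... unused
#' @return a list of `nsim` twin-pair data frames (a single data frame if
#'   `nsim = 1`)
#' @export
simulate.twinfit <- function(object, nsim = 1, seed = 1L, ...) {
  if (object$model == "saturated")
    stop("simulate() is only available for Cholesky fits")
  counts <- table(factor(paste0(object$records$zygosity, object$records$sex),
                         levels = TWIN_GROUPS))
  n_pairs <- stats::setNames(pmax(as.integer(counts), 1L), TWIN_GROUPS)
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- twin_sim_config(n_pairs, paths = object$paths,
                           phenotypes = object$phenotypes,
                           seed = substream_seed(seed, paste0("sim", i)))
    simulate_twins(cfg)
  })
  if (nsim == 1) out[[1]] else out
}

#' Plot standardized variance components
#'
#' Stacked barplot of the standardized A / C (or D) / E proportions per
#' phenotype and sex from the correlated-factors solution.
#'
#' @param x a converged Cholesky `twinfit`
#' @param ... passed to [graphics::barplot()]
#' @export
plot.twinfit <- function(x, ...) {
  if (x$model == "saturated") stop("no variance components in a saturated fit")
  sol <- correlated_factors(x)
  sexes <- if (x$spec$sex_limitation == "quantitative") c("male", "female") else "male"
  old <- graphics::par(mfrow = c(1, length(sexes)))
  on.exit(graphics::par(old))
  for (s in sexes) {
    pr <- t(sol[[s]]$proportions)
    graphics::barplot(pr, legend.text = rownames(pr),
                      main = paste("Standardized components,", s),
                      ylab = "proportion of variance", las = 2, ...)
  }
  invisible(x)
}
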