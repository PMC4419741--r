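# ---- profile-likelihood confidence intervals ------------------------------

# scalar target functions on the packed parameter vector
target_fun <- function(fit, parm) {
  spec <- fit$spec
  parts <- strsplit(parm, ".", fixed = TRUE)[[1]]
  kind <- parts[1]
  sex <- parts[2]
  comps <- spec$components
  if (kind %in% c("a2", "c2", "d2", "e2")) {
    comp <- toupper(substr(kind, 1, 1))
    ph <- match(parts[3], fit$phenotypes)
    if (is.na(ph)) stop("unknown phenotype in parm: ", parm)
    function(theta) {
      p <- unpack_theta(theta, spec)[[sex]]
      cc <- component_cov(p)
      tot <- cc$A + cc$C + cc$D + cc$E
      cc[[comp]][ph, ph] / tot[ph, ph]
    }
  } else if (kind %in% c("rg", "rc", "rd", "re")) {
    comp <- switch(kind, rg = "A", rc = "C", rd = "D", re = "E")
    i <- match(parts[3], fit$phenotypes)
    j <- match(parts[4], fit$phenotypes)
    if (anyNA(c(i, j))) stop("unknown phenotype in parm: ", parm)
    function(theta) {
      p <- unpack_theta(theta, spec)[[sex]]
      m <- component_cov(p)[[comp]]
      m[i, j] / sqrt(m[i, i] * m[j, j])
    }
  } else stop("unknown parm: ", parm,
              " (use e.g. 'a2.male.ph', 'rg.male.ph1.ph2')")
}

parm_space <- function(parm) {
  if (substr(parm, 2, 2) == "2") c(0, 1) else c(-1, 1)
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# minimize -2LL subject to g(theta) = t by an augmented-Lagrangian scheme
# (moderate quadratic weight plus a multiplier update keeps the subproblems
# well-conditioned); returns the profile -2LL. The likelihood gradient is
# analytic; the cheap algebraic target is differentiated numerically.
profile_point <- function(ofns, gfun, t, start) {
  par <- start
  lam <- 0
  w <- 3e4
  for (outer in 1:2) {
    res <- stats::nlminb(
      par,
      function(th) {
        h <- gfun(th) - t
        ofns$fn(th) + lam * h + w * h^2
      },
      gradient = function(th) {
        h <- gfun(th) - t
        ofns$gr(th) + (lam + 2 * w * h) * num_grad(gfun, th)
      },
      control = list(iter.max = 200, eval.max = 800, rel.tol = 1e-9))
    par <- res$par
    h <- gfun(par) - t
    if (abs(h) < 3e-4) break
    lam <- lam + 2 * w * h
  }
  list(val = ofns$fn(par), par = par, g = gfun(par))
}

# walk outward from the estimate until the profile -2LL crosses the
# chi-square threshold (warm-starting each solve from the previous one),
# then refine the crossing by secant/bisection
profile_bound <- function(ofns, gfun, ghat, theta_hat, m2ll_hat, crit, side,
                          space, tol = 1e-3) {
  thresh <- m2ll_hat + crit
  bnd <- if (side > 0) space[2] else space[1]
  width <- abs(bnd - ghat)
  if (width < 1e-8) return(list(bound = bnd, boundary = TRUE))
  par <- theta_hat
  t_in <- ghat; f_in <- m2ll_hat
  step <- 0.15 * width
  repeat {
    t_try <- t_in + side * step
    hit_edge <- (side > 0 && t_try >= bnd - 1e-6) ||
                (side < 0 && t_try <= bnd + 1e-6)
    if (hit_edge) t_try <- bnd - side * 1e-6
    pp <- profile_point(ofns, gfun, t_try, par)
    if (pp$val <= thresh) {
      t_in <- t_try; f_in <- pp$val; par <- pp$par
      if (hit_edge) return(list(bound = bnd, boundary = TRUE))
      step <- step * 1.7
    } else { t_out <- t_try; f_out <- pp$val; break }
  }
  for (it in 1:30) {
    if (abs(t_out - t_in) < tol) break
    rng <- abs(t_out - t_in)
    t_mid <- t_in + (thresh - f_in) / (f_out - f_in) * (t_out - t_in)
    lo_lim <- min(t_in, t_out); hi_lim <- max(t_in, t_out)
    if (!is.finite(t_mid) || t_mid <= lo_lim + 0.1 * rng ||
        t_mid >= hi_lim - 0.1 * rng)
      t_mid <- (t_in + t_out) / 2
    pp <- profile_point(ofns, gfun, t_mid, par)
    if (pp$val <= thresh) { t_in <- t_mid; f_in <- pp$val; par <- pp$par }
    else { t_out <- t_mid; f_out <- pp$val }
  }
  list(bound = (t_in + t_out) / 2, boundary = FALSE)
}

#' Profile-likelihood confidence intervals for standardized quantities
#'
#' Intervals on standardized variance proportions and etiologic
#' correlations of a Cholesky fit, obtained by profiling the -2
#' log-likelihood: the bound is where the profile rises by the chi-square(1)
#' quantile above the minimum, searched within the parameter space ([0, 1]
#' for proportions, [-1, 1] for correlations). Bounds stuck at the edge of
#' the space (common for shared-environment proportions near 0) are flagged
#' in the `"boundary"` attribute.
#'
#' @param object a converged Cholesky `twinfit`
#' @param parm character vector of target names:
#'   `"a2.<sex>.<phenotype>"` (likewise `c2`, `d2`, `e2`) for standardized
#'   proportions, `"rg.<sex>.<ph1>.<ph2>"` (likewise `rc`, `rd`, `re`) for
#'   etiologic correlations; `<sex>` is `"male"` or `"female"`. Defaults to
#'   all standardized proportions.
#' @param level confidence level
#' @param ... unused
#' @return matrix with columns `estimate`, `lower`, `upper`;
#'   attribute `"boundary"` marks bounds that hit the parameter-space edge
#' @export
confint.twinfit <- function(object, parm = NULL, level = 0.95, ...) {
  if (object$model == "saturated")
    stop("profile intervals are defined for Cholesky fits")
  if (!object$converged) stop("fit did not converge")
  spec <- object$spec
  if (is.null(parm)) {
    sexes <- if (spec$sex_limitation == "quantitative") c("male", "female") else "male"
    kinds <- paste0(tolower(spec$components), "2")
    parm <- as.vector(outer(kinds, sexes, function(kd, s)
      sapply(object$phenotypes, function(ph) paste(kd, s, ph, sep = "."))))
  }
  pd <- build_pattern_data(object$records, object$phenotypes)
  ofns <- make_objective(spec, pd)
  theta_hat <- pack_paths(object$paths, spec)
  crit <- stats::qchisq(level, 1)
  out <- matrix(NA_real_, length(parm), 3,
                dimnames = list(parm, c("estimate", "lower", "upper")))
  boundary <- matrix(FALSE, length(parm), 2,
                     dimnames = list(parm, c("lower", "upper")))
  for (i in seq_along(parm)) {
    gfun <- target_fun(object, parm[i])
    space <- parm_space(parm[i])
    ghat <- gfun(theta_hat)
    lo <- profile_bound(ofns, gfun, ghat, theta_hat, object$minus2LL, crit,
                        side = -1, space = space)
    hi <- profile_bound(ofns, gfun, ghat, theta_hat, object$minus2LL, crit,
                        side = +1, space = space)
    out[i, ] <- c(ghat, lo$bound, hi$bound)
    boundary[i, ] <- c(lo$boundary, hi$boundary)
  }
  attr(out, "boundary") <- boundary
  attr(out, "level") <- level
  out
}
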