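# standardized solution for one sex's path matrices
standardize_paths <- function(paths, components) {
  cc <- component_cov(paths)
  P <- cc$A + cc$C + cc$D + cc$E
  k <- nrow(P)
  sdP <- sqrt(diag(P))
  props <- sapply(components, function(comp) diag(cc[[comp]]) / diag(P))
  props <- matrix(props, nrow = k,
                  dimnames = list(rownames(P), components))
  corr <- list()
  for (comp in components) {
    m <- cc[[comp]]
    v <- diag(m)
    r <- matrix(NA_real_, k, k)
    pos <- v > 1e-10
    if (any(pos)) {
      s <- sqrt(v[pos])
      r[pos, pos] <- m[pos, pos, drop = FALSE] / tcrossprod(s)
    }
    diag(r)[pos] <- 1
    corr[[comp]] <- r
  }
  rph <- P / tcrossprod(sdP)
  # contribution of each component to each phenotypic correlation
  shares <- lapply(components, function(comp) cc[[comp]] / tcrossprod(sdP))
  names(shares) <- components
  list(proportions = props, correlations = corr, rph = rph,
       shares = shares, component_cov = cc, phenotypic_cov = P)
}

#' Correlated-factors standardization of a Cholesky fit
#'
#' Re-expresses the fitted path matrices as the mathematically equivalent
#' correlated-factors solution: per sex and phenotype the standardized
#' proportions of variance due to A, C (or D) and E (summing to 1), and per
#' phenotype pair the etiologic correlations (genetic correlation `r_g`,
#' shared-environmental `r_c` or dominance `r_d`, nonshared `r_e`) plus the
#' decomposition of each model-implied phenotypic correlation into component
#' contributions. A correlation whose component variance is zero for either
#' phenotype is reported as `NA` (undefined), not 0.
#'
#' @param fit a converged Cholesky `twinfit`
#' @return an object of class `twin_cf`: per sex, `proportions` (k x
#'   components), `correlations` (list of k x k matrices), `rph`
#'   (model-implied phenotypic correlations) and `shares` (per-component
#'   contributions to `rph`, summing to `rph`)
#' @export
correlated_factors <- function(fit) {
  stopifnot(inherits(fit, "twinfit"))
  if (fit$model == "saturated") stop("saturated fits have no factor solution")
  if (!fit$converged) stop("fit did not converge")
  comps <- fit$spec$components
  out <- list(male = standardize_paths(fit$paths$male, comps),
              female = standardize_paths(fit$paths$female, comps))
  for (s in c("male", "female")) {
    dimnames(out[[s]]$proportions) <- list(fit$phenotypes, comps)
    for (comp in comps)
      dimnames(out[[s]]$correlations[[comp]]) <-
        list(fit$phenotypes, fit$phenotypes)
    dimnames(out[[s]]$rph) <- list(fit$phenotypes, fit$phenotypes)
  }
  out$components <- comps
  out$phenotypes <- fit$phenotypes
  out$sex_limitation <- fit$spec$sex_limitation
  class(out) <- "twin_cf"
  out
}

#' @export
print.twin_cf <- function(x, digits = 3, ...) {
  sexes <- if (x$sex_limitation == "quantitative") c("male", "female") else "male"
  for (s in sexes) {
    cat(if (x$sex_limitation == "quantitative") paste0("-- ", s, " --\n")
        else "-- both sexes --\n")
    cat("Standardized variance components:\n")
    print(round(x[[s]]$proportions, digits))
    if (length(x$phenotypes) > 1) {
      for (comp in x$components) {
        cat("r_", tolower(comp), ":\n", sep = "")
        print(round(x[[s]]$correlations[[comp]], digits))
      }
    }
  }
  invisible(x)
}

#' Decompose a phenotypic correlation into etiologic shares
#'
#' Bivariate heritability and its environmental analogues: the proportion of
#' the model-implied phenotypic correlation between two phenotypes explained
#' by each component, computed as `sqrt(A1) * r_g * sqrt(A2) / r_ph` for the
#' additive genetic share (with `A1`, `A2` the standardized proportions) and
#' analogously for C, D and E. The shares sum to 1.
#'
#' @param solution a [correlated_factors()] object
#' @param pheno_pair character vector of two phenotype names
#' @param sex `"male"` or `"female"` (ignored for equated-sex fits)
#' @return named numeric vector of shares, one per component, with the
#'   model-implied `r_ph` as attribute `"rph"`
#' @export
#' @examples
#' # A1 = 0.64, A2 = 0.25, r_g = 0.5, r_ph = 0.4 -> A share 0.5
bivariate_heritability <- function(solution, pheno_pair, sex = "male") {
  stopifnot(inherits(solution, "twin_cf"), length(pheno_pair) == 2)
  i <- match(pheno_pair[1], solution$phenotypes)
  j <- match(pheno_pair[2], solution$phenotypes)
  if (anyNA(c(i, j))) stop("unknown phenotype in pheno_pair")
  sol <- solution[[sex]]
  rph <- sol$rph[i, j]
  if (abs(rph) < 1e-8)
    stop("model-implied phenotypic correlation is (numerically) zero; ",
         "shares are undefined")
  shares <- vapply(solution$components,
                   function(comp) sol$shares[[comp]][i, j] / rph, 0)
  attr(shares, "rph") <- rph
  shares
}
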