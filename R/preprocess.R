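#' Phenotype preparation specification
#'
#' Declares how a phenotype is prepared for analysis and which tail of its
#' distribution counts as "extreme": trait scales select their high tail,
#' ability scales their low tail.
#'
#' @param name phenotype name
#' @param log_transform log-transform the scale before analysis (for
#'   positively skewed count-like scales)
#' @param log_offset offset added before taking logs; must be positive when
#'   zeros can occur
#' @param extreme_tail `"high"` or `"low"`
#' @param max_score optional maximum possible score (documentation only)
#' @return an object of class `phenotype_spec`
#' @export
phenotype_spec <- function(name, log_transform = FALSE, log_offset = 1,
                           extreme_tail = c("high", "low"), max_score = NULL) {
  extreme_tail <- match.arg(extreme_tail)
  if (log_transform && log_offset <= 0)
    stop("log_offset must be positive when log transforming")
  structure(list(name = name, log_transform = log_transform,
                 log_offset = log_offset, extreme_tail = extreme_tail,
                 max_score = max_score),
            class = "phenotype_spec")
}

#' Drop excluded twin pairs
#'
#' Removes pairs flagged for exclusion (e.g. severe genetic conditions) and
#' reports how many were dropped.
#'
#' @param records twin-pair data frame
#' @param flags logical vector, `TRUE` = exclude; one entry per pair
#' @return the filtered records
#' @export
apply_exclusions <- function(records, flags) {
  if (length(flags) != nrow(records))
    stop("flags length (", length(flags), ") does not match records (",
         nrow(records), ")")
  flags <- as.logical(flags)
  n_drop <- sum(flags, na.rm = TRUE)
  out <- records[!flags %in% TRUE, , drop = FALSE]
  if (nrow(out) == 0L) warning("all pairs excluded")
  message("apply_exclusions: removed ", n_drop, " of ", nrow(records), " pairs")
  attr(out, "phenotypes") <- attr(records, "phenotypes")
  out
}

#' Log-transform a positively skewed scale
#'
#' Natural log of `value + offset`. Missing values propagate.
#'
#' @param values numeric vector
#' @param offset non-negative offset (default 1, suitable for count scales
#'   that include zero)
#' @return transformed vector
#' @export
log_transform <- function(values, offset = 1) {
  bad <- which(!is.na(values) & values + offset <= 0)
  if (length(bad))
    stop("non-positive argument to log at index ", bad[1],
         " (value ", values[bad[1]], ", offset ", offset, ")")
  log(values + offset)
}

#' Regress sex and age out of a scale
#'
#' Ordinary least-squares residuals of score on a sex indicator and age,
#' fitted on all individuals pooled. Residuals are uncorrelated with both
#' covariates by construction. If a covariate is constant the fit falls back
#' to mean-centering with a warning.
#'
#' @param values numeric scores (missing allowed)
#' @param sex factor or character (`"M"`/`"F"`) or 0/1 numeric
#' @param age numeric ages
#' @return residuals, same length as `values`, missing where `values` is
#' @export
residualize <- function(values, sex, age) {
  sexi <- if (is.numeric(sex)) sex else as.numeric(sex == "M")
  ok <- !is.na(values) & !is.na(sexi) & !is.na(age)
  if (sum(ok) < 3) stop("need at least 3 complete (value, sex, age) triples")
  const_sex <- stats::var(sexi[ok]) == 0
  const_age <- stats::var(age[ok]) == 0
  if (const_sex && const_age) {
    warning("constant covariates; falling back to mean-centering")
    return(values - mean(values[ok]))
  }
  form <- if (const_sex) values ~ age else if (const_age) values ~ sexi
          else values ~ sexi + age
  if (const_sex || const_age)
    warning("constant covariate dropped from residualization")
  fit <- stats::lm(form, data = data.frame(values, sexi, age),
                   na.action = stats::na.exclude)
  as.numeric(stats::residuals(fit))
}

#' Standardize a scale to mean 0, SD 1
#'
#' @param values numeric vector; mean and SD are computed on non-missing
#'   entries
#' @return z-scores
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-transform")
  (values - mean(values[ok])) / s
}

#' Randomly select one twin per pair
#'
#' Breaks the non-independence of twin data for phenotypic correlations by
#' keeping a single randomly chosen twin per family. Reproducible from the
#' seed.
#'
#' @param records twin-pair data frame
#' @param seed integer seed
#' @return an individual-level data frame, one row per family, with
#'   unsuffixed phenotype columns and a `twin` column recording the choice
#' @export
select_one_per_pair <- function(records, seed = 1L) {
  phenos <- twin_phenotypes(records)
  pick <- with_local_seed(seed, sample(c(1L, 2L), nrow(records), replace = TRUE))
  y1 <- pheno_matrix(records, phenos, 1)
  y2 <- pheno_matrix(records, phenos, 2)
  y <- y1
  y[pick == 2L, ] <- y2[pick == 2L, ]
  out <- cbind(records[, c("family_id", "zygosity", "sex", "age")],
               twin = pick, as.data.frame(y))
  rownames(out) <- NULL
  out
}

#' Run the standard preparation chain on a twin-pair table
#'
#' Applies, in fixed order: optional exclusions, log transformation of the
#' scales declared skewed, residualization of sex and age effects (fitted on
#' individuals pooled over twins and zygosity groups) and z-transformation.
#' Every step and parameter is appended to a transforms log carried in the
#' `"transform_log"` attribute of the result.
#'
#' @param records twin-pair data frame
#' @param specs list of [phenotype_spec()] objects (one per phenotype to
#'   prepare; phenotypes without a spec are passed through untouched)
#' @param exclusion_flags optional logical vector for [apply_exclusions()]
#' @return records with prepared phenotype columns and a transform log
#' @export
preprocess_twins <- function(records, specs, exclusion_flags = NULL) {
  logtxt <- character()
  if (!is.null(exclusion_flags)) {
    n0 <- nrow(records)
    records <- apply_exclusions(records, exclusion_flags)
    logtxt <- c(logtxt, sprintf("exclusions: removed %d of %d pairs",
                                n0 - nrow(records), n0))
  }
  phenos <- twin_phenotypes(records)
  specs <- stats::setNames(specs, vapply(specs, `[[`, "", "name"))
  for (ph in phenos) {
    sp <- specs[[ph]]
    if (is.null(sp)) next
    cols <- paste0(ph, c("_t1", "_t2"))
    if (sp$log_transform) {
      for (cl in cols) records[[cl]] <- log_transform(records[[cl]], sp$log_offset)
      logtxt <- c(logtxt, sprintf("%s: log(x + %g)", ph, sp$log_offset))
    }
    # residualize pooled over both twins, then split back
    vals <- c(records[[cols[1]]], records[[cols[2]]])
    sexv <- rep(records$sex, 2)
    agev <- rep(records$age, 2)
    res <- residualize(vals, sexv, agev)
    n <- nrow(records)
    z <- zscore(res)
    records[[cols[1]]] <- z[seq_len(n)]
    records[[cols[2]]] <- z[n + seq_len(n)]
    logtxt <- c(logtxt, sprintf("%s: residualized on sex + age (pooled twins), z-scored", ph))
  }
  attr(records, "phenotypes") <- phenos
  attr(records, "transform_log") <- logtxt
  records
}
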