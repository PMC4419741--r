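#' Configuration for a simulated twin cohort
#'
#' Describes the generating model for a synthetic twin-pair dataset: how many
#' same-sex pairs per zygosity-sex cell, the per-sex path matrices of the
#' biometric model, optional monotone skew transforms, missing-data rates and
#' linear age/sex effects. The generator draws multivariate normal latent
#' liabilities (the exact generative dual of the linear-Gaussian twin model)
#' and applies transforms and missingness afterwards.
#'
#' @param n_pairs named integer vector of pair counts per cell
#'   (`MZM`, `DZM`, `MZF`, `DZF`); a single number recycles to all four cells
#' @param paths either a single [path_matrices()] object (both sexes share the
#'   generating model) or `list(male = , female = )`
#' @param phenotypes character names of the phenotypes (defaults to `ph1..phk`)
#' @param skew optional per-phenotype transform: a named list with entries
#'   `list(type = "exp", scale = )` (exponential of the Gaussian liability,
#'   count-like positive skew) or `list(type = "bin", cuts = )` (ordinal
#'   binning at the given cut points); phenotypes not listed are untouched.
#'   Both transforms are monotone, so rank-based statistics are invariant.
#' @param missing_rate named per-phenotype probability of a score being
#'   missing (missing completely at random, independently per twin); must be
#'   below 1
#' @param age_range min/max age in years; co-twins share their age
#' @param age_effects,sex_effects named per-phenotype linear coefficients; the
#'   sex effect is added for male pairs (female = reference)
#' @param seed integer master seed; each zygosity-sex cell draws from its own
#'   deterministic substream so cells are independently reproducible
#' @return an object of class `twin_sim_config`
#' @export
twin_sim_config <- function(n_pairs, paths, phenotypes = NULL, skew = NULL,
                            missing_rate = NULL, age_range = c(11.5, 12.5),
                            age_effects = NULL, sex_effects = NULL, seed = 1L) {
  if (length(n_pairs) == 1L) n_pairs <- stats::setNames(rep(n_pairs, 4), TWIN_GROUPS)
  if (!all(TWIN_GROUPS %in% names(n_pairs)))
    stop("n_pairs must be named with ", paste(TWIN_GROUPS, collapse = ", "))
  n_pairs <- n_pairs[TWIN_GROUPS]
  if (any(n_pairs < 1)) stop("n_pairs must be >= 1 in every cell")
  if (inherits(paths, "path_matrices")) paths <- list(male = paths, female = paths)
  stopifnot(inherits(paths$male, "path_matrices"),
            inherits(paths$female, "path_matrices"))
  k <- nrow(paths$male$Z)
  if (is.null(phenotypes)) phenotypes <- paste0("ph", seq_len(k))
  if (length(phenotypes) != k) stop("phenotypes must have length ", k)
  for (s in c("male", "female")) {
    sig <- Reduce(`+`, component_cov(paths[[s]]))
    if (!is_psd(sig))
      stop("implied phenotypic covariance for ", s, " sex is not PSD")
  }
  mr <- stats::setNames(rep(0, k), phenotypes)
  if (!is.null(missing_rate)) mr[names(missing_rate)] <- missing_rate
  if (any(mr >= 1) || any(mr < 0)) stop("missing_rate must lie in [0, 1)")
  ae <- stats::setNames(rep(0, k), phenotypes)
  if (!is.null(age_effects)) ae[names(age_effects)] <- age_effects
  se <- stats::setNames(rep(0, k), phenotypes)
  if (!is.null(sex_effects)) se[names(sex_effects)] <- sex_effects
  structure(list(n_pairs = n_pairs, paths = paths, phenotypes = phenotypes,
                 skew = skew, missing_rate = mr, age_range = age_range,
                 age_effects = ae, sex_effects = se, seed = as.integer(seed)),
            class = "twin_sim_config")
}

# correlated standard-normal factor scores for a cell: each of the k factors
# has cross-twin correlation rho, factors independent of each other
draw_factors <- function(n, k, rho) {
  g <- matrix(stats::rnorm(n * k), n, k)
  u1 <- matrix(stats::rnorm(n * k), n, k)
  u2 <- matrix(stats::rnorm(n * k), n, k)
  list(t1 = sqrt(rho) * g + sqrt(1 - rho) * u1,
       t2 = sqrt(rho) * g + sqrt(1 - rho) * u2)
}

apply_skew <- function(x, tr) {
  if (is.null(tr) || identical(tr$type, "none")) return(x)
  switch(tr$type,
    exp = exp(x * (if (is.null(tr$scale)) 1 else tr$scale)),
    bin = {
      cuts <- sort(tr$cuts)
      findInterval(x, cuts)
    },
    stop("unknown skew transform type: ", tr$type)
  )
}

#' Simulate a twin-pair dataset
#'
#' Draws per-twin latent A, C, D and E factor scores with the cross-twin
#' correlations of the classical twin design (A: 1 in MZ, 0.5 in DZ pairs;
#' C: 1 in both; D: 1 in MZ, 0.25 in DZ; E: 0), forms phenotypes as
#' path-weighted factor sums plus linear age and sex effects, then applies
#' any skew transform and missing-completely-at-random masking. The run is
#' fully reproducible from the config seed.
#'
#' @param config a [twin_sim_config()] object
#' @return a data frame with columns `family_id`, `zygosity`, `sex`, `age`
#'   and `<phenotype>_t1` / `<phenotype>_t2` per phenotype, carrying the
#'   phenotype names in the `"phenotypes"` attribute
#' @export
#' @examples
#' cfg <- twin_sim_config(200, paths_from_components(a2 = 0.6, c2 = 0.2, e2 = 0.2))
#' head(simulate_twins(cfg))
simulate_twins <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  k <- length(config$phenotypes)
  out <- vector("list", length(TWIN_GROUPS))
  fam0 <- 0L
  for (gi in seq_along(TWIN_GROUPS)) {
    grp <- TWIN_GROUPS[gi]
    n <- config$n_pairs[[grp]]
    zyg <- group_zygosity(grp)
    sx <- group_sex(grp)
    sh <- share_coef(zyg)
    paths <- config$paths[[if (sx == "M") "male" else "female"]]
    cell <- with_local_seed(substream_seed(config$seed, grp), {
      age <- stats::runif(n, config$age_range[1], config$age_range[2])
      fa <- draw_factors(n, k, sh[["A"]])
      fc <- draw_factors(n, k, sh[["C"]])
      fd <- draw_factors(n, k, sh[["D"]])
      fe <- draw_factors(n, k, sh[["E"]])
      score <- function(f) {
        y <- matrix(rep(paths$mean, each = n), n, k)
        if (!is.null(paths$X)) y <- y + f$a %*% t(paths$X)
        if (!is.null(paths$Y)) y <- y + f$c %*% t(paths$Y)
        if (!is.null(paths$W)) y <- y + f$d %*% t(paths$W)
        y <- y + f$e %*% t(paths$Z)
        y <- y + outer(age, config$age_effects)
        if (sx == "M") y <- y + matrix(rep(config$sex_effects, each = n), n, k)
        y
      }
      y1 <- score(list(a = fa$t1, c = fc$t1, d = fd$t1, e = fe$t1))
      y2 <- score(list(a = fa$t2, c = fc$t2, d = fd$t2, e = fe$t2))
      for (j in seq_len(k)) {
        tr <- config$skew[[config$phenotypes[j]]]
        y1[, j] <- apply_skew(y1[, j], tr)
        y2[, j] <- apply_skew(y2[, j], tr)
        mr <- config$missing_rate[[j]]
        if (mr > 0) {
          y1[stats::runif(n) < mr, j] <- NA
          y2[stats::runif(n) < mr, j] <- NA
        }
      }
      list(age = age, y1 = y1, y2 = y2)
    })
    df <- data.frame(family_id = fam0 + seq_len(n), zygosity = zyg, sex = sx,
                     age = cell$age)
    colnames(cell$y1) <- paste0(config$phenotypes, "_t1")
    colnames(cell$y2) <- paste0(config$phenotypes, "_t2")
    out[[gi]] <- cbind(df, cell$y1, cell$y2)
    fam0 <- fam0 + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "phenotypes") <- config$phenotypes
  res
}

#' Read and write twin-pair tables
#'
#' CSV round-trip for the pair-wise twin schema (`family_id`, `zygosity`,
#' `sex`, `age`, `<phenotype>_t1`, `<phenotype>_t2`). Missing scores are
#' encoded as empty fields. `read_twin_data()` validates zygosity and sex
#' codes and reports the offending row on failure; an empty file yields an
#' empty table with a warning.
#'
#' @param records twin-pair data frame
#' @param path file path
#' @return `read_twin_data()` returns the records data frame with the
#'   `"phenotypes"` attribute set
#' @export
write_twin_data <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_twin_data
#' @export
read_twin_data <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty twin data file: ", path)
    empty <- data.frame(family_id = integer(), zygosity = character(),
                        sex = character(), age = numeric())
    attr(empty, "phenotypes") <- character()
    return(empty)
  }
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  req <- c("family_id", "zygosity", "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  bad <- which(!df$zygosity %in% c("MZ", "DZ"))
  if (length(bad))
    stop("invalid zygosity code '", df$zygosity[bad[1]], "' in row ", bad[1])
  bad <- which(!df$sex %in% c("M", "F"))
  if (length(bad))
    stop("invalid sex code '", df$sex[bad[1]], "' in row ", bad[1])
  attr(df, "phenotypes") <- twin_phenotypes(df)
  df
}
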