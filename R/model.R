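#' Biometric model specification
#'
#' Declares which variance components a Cholesky twin model estimates and
#' whether parameters are equated across the sexes. E (nonshared
#' environment, absorbing measurement error) is always present; C (shared
#' environment) and D (dominance) cannot be estimated together because the
#' same-sex twin design does not identify both.
#'
#' @param components subset of `c("A", "C", "D", "E")`
#' @param k number of phenotypes
#' @param sex_limitation `"equated"` (one parameter set for both sexes) or
#'   `"quantitative"` (same structure, magnitudes free per sex)
#' @return an object of class `biometric_spec`
#' @export
biometric_spec <- function(components = c("A", "C", "E"), k,
                           sex_limitation = c("equated", "quantitative")) {
  sex_limitation <- match.arg(sex_limitation)
  components <- unique(toupper(components))
  if (!all(components %in% c("A", "C", "D", "E")))
    stop("components must be a subset of A, C, D, E")
  if (!"E" %in% components) stop("E must always be estimated")
  if (all(c("C", "D") %in% components))
    stop("C and D cannot be estimated simultaneously")
  if (k < 1) stop("k must be >= 1")
  components <- intersect(c("A", "C", "D", "E"), components)  # canonical order
  structure(list(components = components, k = as.integer(k),
                 sex_limitation = sex_limitation),
            class = "biometric_spec")
}

model_name <- function(spec) paste(spec$components, collapse = "")

n_sex_sets <- function(spec) if (spec$sex_limitation == "quantitative") 2L else 1L

#' Free-parameter counts
#'
#' `count_parameters()` gives the number of free parameters of a Cholesky
#' model: per sex parameter set, one lower-triangular k x k matrix (k(k+1)/2
#' entries) per estimated component plus k phenotype means (means are
#' equated across twins and zygosity, and across sexes unless the model uses
#' quantitative sex limitation). `count_parameters_saturated()` counts the
#' saturated model: per group, 2k free means plus the free 2k x 2k
#' covariance.
#'
#' @param spec a [biometric_spec()]
#' @return integer parameter count
#' @export
#' @examples
#' count_parameters(biometric_spec(c("A", "C", "E"), k = 5))            # 50
#' count_parameters(biometric_spec(c("A", "C", "E"), 5, "quantitative")) # 100
#' count_parameters_saturated(5, 4)                                      # 260
count_parameters <- function(spec) {
  tri <- spec$k * (spec$k + 1) / 2
  per_set <- length(spec$components) * tri + spec$k
  as.integer(per_set * n_sex_sets(spec))
}

#' @rdname count_parameters
#' @param k number of phenotypes
#' @param n_groups number of groups with free moments (4 zygosity-sex groups
#'   under sex limitation, 2 zygosity groups with sexes equated)
#' @export
count_parameters_saturated <- function(k, n_groups = 4) {
  p <- 2 * k
  as.integer(n_groups * (p + p * (p + 1) / 2))
}

#' Model-implied twin-pair moments
#'
#' Assembles the mean vector and 2k x 2k covariance matrix the biometric
#' model implies for a twin pair in a given group. The within-twin block is
#' `A + C + D + E`; the cross-twin block is `alpha * A + C + delta * D` with
#' `alpha` = 1 (MZ) or 0.5 (DZ) and `delta` = 1 (MZ) or 0.25 (DZ).
#'
#' @param paths a [path_matrices()] object
#' @param group group code (`"MZM"` etc.) or bare zygosity (`"MZ"`/`"DZ"`)
#' @return list with `mean` (length 2k) and `sigma` (2k x 2k)
#' @export
#' @examples
#' p <- path_matrices(X = matrix(1), Y = matrix(1), Z = matrix(1))
#' implied_moments(p, "MZ")$sigma  # within 3, cross 2
implied_moments <- function(paths, group) {
  zyg <- if (group %in% c("MZ", "DZ")) group else group_zygosity(group)
  sh <- share_coef(zyg)
  cc <- component_cov(paths)
  within <- cc$A + cc$C + cc$D + cc$E
  cross <- sh[["A"]] * cc$A + cc$C + sh[["D"]] * cc$D
  sigma <- rbind(cbind(within, cross), cbind(t(cross), within))
  list(mean = rep(paths$mean, 2), sigma = sigma, group = group)
}

# ---- FIML machinery -------------------------------------------------------

# Summarize a group's pair-wise data by missingness pattern. Each pattern
# stores the observed column indices, count, mean and MLE scatter of the
# observed sub-vectors, so the likelihood is evaluated from sufficient
# statistics rather than row by row.
build_pattern_data <- function(records, phenotypes, by = TWIN_GROUPS) {
  k <- length(phenotypes)
  out <- list()
  n_points <- 0L
  for (g in by) {
    rows <- if (g %in% c("MZ", "DZ")) records$zygosity == g
            else group_rows(records, g)
    sel <- records[rows, , drop = FALSE]
    if (!nrow(sel)) next
    Y <- cbind(pheno_matrix(sel, phenotypes, 1), pheno_matrix(sel, phenotypes, 2))
    obs <- !is.na(Y)
    keep <- rowSums(obs) > 0   # pairs with no observed score contribute nothing
    Y <- Y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
    if (!nrow(Y)) next
    n_points <- n_points + sum(obs)
    key <- apply(obs, 1, paste, collapse = "")
    pats <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
      o <- which(obs[idx[1], ])
      Ys <- Y[idx, o, drop = FALSE]
      m <- colMeans(Ys)
      S <- crossprod(sweep(Ys, 2, m)) / length(idx)
      list(obs = o, n = length(idx), mean = m, S = S)
    })
    out[[g]] <- pats
  }
  structure(out, n_points = n_points, k = k, phenotypes = phenotypes)
}

# -2 log likelihood of one pattern under group moments; NA if the observed
# sub-matrix is not positive definite
pattern_m2ll <- function(pat, mu, sigma) {
  o <- pat$obs
  R <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  Q <- chol2inv(R)
  d <- pat$mean - mu[o]
  pat$n * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) +
           sum(Q * pat$S) + drop(crossprod(d, Q %*% d)))
}

m2ll_from_patterns <- function(patterns, moments_for_group) {
  tot <- 0
  for (g in names(patterns)) {
    mom <- moments_for_group(g)
    for (pat in patterns[[g]]) {
      v <- pattern_m2ll(pat, mom$mean, mom$sigma)
      if (is.na(v)) return(NA_real_)
      tot <- tot + v
    }
  }
  tot
}

#' Full-information -2 log-likelihood of a Cholesky model
#'
#' Gaussian full-information maximum-likelihood objective: every twin pair
#' contributes the log-density of its observed sub-vector under the implied
#' moments of its zygosity-sex group (rows/columns of missing scores are
#' dropped, so partially observed pairs are retained). Pairs with no
#' observed score contribute nothing.
#'
#' @param paths a [path_matrices()] object, or `list(male =, female =)` of
#'   them when parameters differ by sex
#' @param records preprocessed twin-pair data frame
#' @param phenotypes phenotype names (default: all)
#' @return the total -2 log-likelihood
#' @export
neg2_log_likelihood <- function(paths, records,
                                phenotypes = twin_phenotypes(records)) {
  if (inherits(paths, "path_matrices")) paths <- list(male = paths, female = paths)
  pd <- build_pattern_data(records, phenotypes)
  val <- m2ll_from_patterns(pd, function(g) {
    implied_moments(paths[[if (group_sex(g) == "M") "male" else "female"]], g)
  })
  if (is.na(val))
    stop("implied covariance has a non-positive-definite observed sub-matrix")
  val
}

# ---- parameter packing ----------------------------------------------------

tri_n <- function(k) k * (k + 1) / 2

vec_to_lower <- function(v, k) {
  m <- matrix(0, k, k)
  m[lower.tri(m, diag = TRUE)] <- v
  m
}

lower_to_vec <- function(m) m[lower.tri(m, diag = TRUE)]

# theta layout: for each sex set, one tri-block per component (canonical
# order), then k means
unpack_theta <- function(theta, spec) {
  k <- spec$k; tn <- tri_n(k)
  per_set <- length(spec$components) * tn + k
  sets <- n_sex_sets(spec)
  out <- vector("list", sets)
  for (s in seq_len(sets)) {
    off <- (s - 1) * per_set
    mats <- list(X = NULL, Y = NULL, W = NULL, Z = NULL)
    slot <- c(A = "X", C = "Y", D = "W", E = "Z")
    for (comp in spec$components) {
      mats[[slot[[comp]]]] <- vec_to_lower(theta[off + seq_len(tn)], k)
      off <- off + tn
    }
    mu <- theta[off + seq_len(k)]
    # fast path: inputs are lower-triangular by construction, skip validation
    out[[s]] <- structure(list(X = mats$X, Y = mats$Y, W = mats$W, Z = mats$Z,
                               mean = mu), class = "path_matrices")
  }
  if (sets == 1L) list(male = out[[1]], female = out[[1]])
  else list(male = out[[1]], female = out[[2]])
}

pack_paths <- function(paths_list, spec) {
  slot <- c(A = "X", C = "Y", D = "W", E = "Z")
  sets <- if (n_sex_sets(spec) == 2L) c("male", "female") else "male"
  unlist(lapply(sets, function(s) {
    p <- paths_list[[s]]
    c(unlist(lapply(spec$components, function(comp) lower_to_vec(p[[slot[[comp]]]]))),
      p$mean)
  }), use.names = FALSE)
}

# flip path-matrix column signs so diagonals are non-negative (X S) (X S)' =
# X X', removing the reflection indeterminacy of the Cholesky factors
canonicalize_paths <- function(paths) {
  for (nm in c("X", "Y", "W", "Z")) {
    m <- paths[[nm]]
    if (is.null(m)) next
    s <- ifelse(diag(m) < 0, -1, 1)
    paths[[nm]] <- m %*% diag(s, nrow(m))
  }
  paths
}
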