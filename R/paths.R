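#' Lower-triangular path matrices for a biometric Cholesky model
#'
#' Bundles the per-sex path matrices that parameterize the additive genetic
#' (A), shared environmental (C), dominance (D) and nonshared environmental
#' (E) covariance components as products of lower-triangular factors
#' (`A = X X'`, `C = Y Y'`, `D = W W'`, `E = Z Z'`), plus the phenotype mean
#' vector. The product parameterization keeps every component matrix
#' positive semi-definite by construction.
#'
#' @param X,Y,W,Z lower-triangular k x k path matrices for A, C, D and E;
#'   `Y` and `W` may be `NULL` when the component is absent. `Z` is required.
#' @param mean numeric phenotype mean vector of length k
#' @return an object of class `path_matrices`
#' @export
path_matrices <- function(X = NULL, Y = NULL, W = NULL, Z, mean = NULL) {
  k <- nrow(Z)
  if (is.null(mean)) mean <- rep(0, k)
  for (nm in c("X", "Y", "W", "Z")) {
    m <- get(nm)
    if (is.null(m)) next
    if (!is.matrix(m) || nrow(m) != k || ncol(m) != k)
      stop(nm, " must be a ", k, "x", k, " matrix")
    if (any(abs(m[upper.tri(m)]) > 1e-12))
      stop(nm, " must be lower-triangular")
  }
  if (!is.null(Y) && !is.null(W))
    stop("C and D cannot be parameterized simultaneously")
  if (length(mean) != k) stop("mean must have length ", k)
  structure(list(X = X, Y = Y, W = W, Z = Z, mean = as.numeric(mean)),
            class = "path_matrices")
}

#' Build path matrices from standardized variance components
#'
#' Convenience constructor that turns standardized variance proportions and
#' component correlation matrices into Cholesky path matrices with unit
#' phenotypic variance. For phenotype i the proportions `a2[i]`, `c2[i]`
#' (or `d2[i]`) and `e2[i]` must sum to 1; component covariance matrices are
#' assembled as `diag(sqrt(v)) R diag(sqrt(v))` and factorized.
#'
#' @param a2,c2,d2,e2 standardized variance proportions per phenotype
#'   (vectors of equal length; `c2` and `d2` are mutually exclusive)
#' @param rA,rC,rD,rE component correlation matrices (default identity)
#' @param mean phenotype means (default 0)
#' @return a [path_matrices()] object
#' @export
#' @examples
#' p <- paths_from_components(a2 = 0.6, c2 = 0.2, e2 = 0.2)
#' tcrossprod(p$X)  # A = 0.6
paths_from_components <- function(a2, c2 = NULL, d2 = NULL, e2,
                                  rA = NULL, rC = NULL, rD = NULL, rE = NULL,
                                  mean = NULL) {
  k <- length(a2)
  if (!is.null(c2) && !is.null(d2))
    stop("C and D cannot be parameterized simultaneously")
  tot <- a2 + (if (is.null(c2)) 0 else c2) + (if (is.null(d2)) 0 else d2) + e2
  if (any(abs(tot - 1) > 1e-8))
    stop("standardized components must sum to 1 per phenotype")
  comp_cov <- function(v, R) {
    if (is.null(R)) R <- diag(k)
    if (!is_psd(R)) stop("component correlation matrix is not PSD")
    s <- diag(sqrt(v), k)
    s %*% R %*% s
  }
  fac <- function(v, R) {
    if (all(v < 1e-12)) return(matrix(0, k, k))
    # tiny floor keeps the factorization defined for singular component
    # covariances (e.g. a component correlation of exactly +/-1)
    lower_chol(comp_cov(v, R), floor = 1e-9)
  }
  path_matrices(
    X = fac(a2, rA),
    Y = if (is.null(c2)) NULL else fac(c2, rC),
    W = if (is.null(d2)) NULL else fac(d2, rD),
    Z = fac(e2, rE),
    mean = if (is.null(mean)) rep(0, k) else mean
  )
}

# component covariance matrices implied by path matrices
component_cov <- function(paths) {
  k <- nrow(paths$Z)
  zero <- matrix(0, k, k)
  list(
    A = if (is.null(paths$X)) zero else tcrossprod(paths$X),
    C = if (is.null(paths$Y)) zero else tcrossprod(paths$Y),
    D = if (is.null(paths$W)) zero else tcrossprod(paths$W),
    E = tcrossprod(paths$Z)
  )
}
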