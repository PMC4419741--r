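#' @keywords internal
"_PACKAGE"

# Zygosity-sex cells used throughout: monozygotic / dizygotic males and females.
TWIN_GROUPS <- c("MZM", "DZM", "MZF", "DZF")

# Cross-twin sharing coefficients for the additive (A) and dominance (D)
# factors. MZ pairs share all segregating variants, DZ pairs half of them on
# average; the dominance sharing coefficient for DZ pairs is 1/4.
share_coef <- function(zygosity) {
  switch(zygosity,
    MZ = c(A = 1, C = 1, D = 1, E = 0),
    DZ = c(A = 0.5, C = 1, D = 0.25, E = 0),
    stop("unknown zygosity: ", zygosity)
  )
}

group_zygosity <- function(group) substr(group, 1, 2)
group_sex <- function(group) ifelse(substr(group, 3, 3) == "M", "M", "F")

#' Phenotype columns of a twin-pair table
#'
#' Phenotype scores are stored pair-wise as `<name>_t1` / `<name>_t2`.
#' @param records twin-pair data frame
#' @return character vector of phenotype names
#' @export
twin_phenotypes <- function(records) {
  ph <- attr(records, "phenotypes")
  if (!is.null(ph)) return(ph)
  cols <- names(records)
  t1 <- sub("_t1$", "", grep("_t1$", cols, value = TRUE))
  t2 <- sub("_t2$", "", grep("_t2$", cols, value = TRUE))
  intersect(t1, t2)
}

pheno_matrix <- function(records, phenotypes, twin) {
  cols <- paste0(phenotypes, "_t", twin)
  m <- as.matrix(records[, cols, drop = FALSE])
  colnames(m) <- phenotypes
  m
}

# stacked individual-level view: one row per twin
stack_twins <- function(records, phenotypes = twin_phenotypes(records)) {
  base <- records[, c("family_id", "zygosity", "sex", "age")]
  long <- rbind(
    cbind(base, twin = 1L, pheno_matrix(records, phenotypes, 1)),
    cbind(base, twin = 2L, pheno_matrix(records, phenotypes, 2))
  )
  rownames(long) <- NULL
  long
}

# run an expression with a local RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed per named stream, kept inside 32-bit integer range
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483587) + 1L
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

# nearest PSD clip used for method-of-moments starting values
psd_clip <- function(m, floor = 1e-4) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% diag(v, nrow = length(v)) %*% t(e$vectors)
}

lower_chol <- function(m, floor = 1e-4) {
  t(chol(psd_clip(m, floor)))
}

fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) return(c(NA_real_, NA_real_))
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

sample_skew <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^3) / s^3
}
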