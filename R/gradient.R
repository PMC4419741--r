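# ---- analytic gradients of the FIML objective -----------------------------
#
# For one missingness pattern with count n, observed mean m, MLE scatter S
# and observed index set o, the contribution to -2LL is
#   F = n [ p log 2pi + log|So| + tr(So^-1 S) + d' So^-1 d ],  d = m - mu_o,
# whose derivatives are
#   dF/dSigma_o = n [ So^-1 - So^-1 (S + d d') So^-1 ]
#   dF/dmu_o    = -2 n So^-1 d.
# These are accumulated into a full 2k x 2k matrix G and length-2k vector g
# per group, then chained through the moment structure (within block
# A+C+D+E, cross block alpha A + C + delta D) and the Cholesky
# parameterization (dF/dX = (G_A + G_A') X etc.).

# accumulate dF/dSigma and dF/dmu for one group's patterns
group_moment_grad <- function(pats, mu, sigma) {
  p2 <- length(mu)
  G <- matrix(0, p2, p2)
  g <- numeric(p2)
  val <- 0
  for (pat in pats) {
    o <- pat$obs
    R <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Q <- chol2inv(R)
    d <- pat$mean - mu[o]
    Qd <- Q %*% d
    val <- val + pat$n * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) +
                          sum(Q * pat$S) + drop(crossprod(d, Qd)))
    G[o, o] <- G[o, o] + pat$n * (Q - Q %*% (pat$S + tcrossprod(d)) %*% Q)
    g[o] <- g[o] - 2 * pat$n * Qd
  }
  list(val = val, G = G, g = g)
}

# chain a group's moment gradient through the biometric structure, adding
# into per-sex-set accumulators for the component matrices and means
chain_biometric <- function(acc, G, g, zyg, k) {
  i1 <- seq_len(k); i2 <- k + i1
  Gw <- G[i1, i1] + G[i2, i2]
  Gx <- G[i1, i2] + G[i2, i1]      # both cross blocks carry the component
  sh <- share_coef(zyg)
  acc$A <- acc$A + Gw + sh[["A"]] * Gx
  acc$C <- acc$C + Gw + Gx
  acc$D <- acc$D + Gw + sh[["D"]] * Gx
  acc$E <- acc$E + Gw
  acc$mu <- acc$mu + g[i1] + g[i2]
  acc
}

new_comp_acc <- function(k) {
  z <- matrix(0, k, k)
  list(A = z, C = z, D = z, E = z, mu = numeric(k))
}

# gradient of -2LL w.r.t. the packed theta of a Cholesky model spec;
# returns list(val, grad) or NULL on a non-PD sub-matrix
m2ll_and_grad <- function(theta, spec, pd) {
  k <- spec$k
  paths <- unpack_theta(theta, spec)
  sets <- n_sex_sets(spec)
  accs <- lapply(seq_len(sets), function(i) new_comp_acc(k))
  total <- 0
  moments <- list(male = list(), female = list())
  for (g in names(pd)) {
    sex <- if (group_sex(g) == "M") "male" else "female"
    zyg <- group_zygosity(g)
    if (is.null(moments[[sex]][[zyg]]))
      moments[[sex]][[zyg]] <- implied_moments(paths[[sex]], zyg)
    mom <- moments[[sex]][[zyg]]
    gg <- group_moment_grad(pd[[g]], mom$mean, mom$sigma)
    if (is.null(gg)) return(NULL)
    total <- total + gg$val
    si <- if (sets == 2L && sex == "female") 2L else 1L
    accs[[si]] <- chain_biometric(accs[[si]], gg$G, gg$g, zyg, k)
  }
  slot <- c(A = "X", C = "Y", D = "W", E = "Z")
  grad <- numeric(0)
  for (si in seq_len(sets)) {
    p <- paths[[if (si == 1L) "male" else "female"]]
    acc <- accs[[si]]
    for (comp in spec$components) {
      M <- p[[slot[[comp]]]]
      GA <- acc[[comp]]
      dX <- (GA + t(GA)) %*% M
      grad <- c(grad, lower_to_vec(dX))
    }
    grad <- c(grad, acc$mu)
  }
  list(val = total, grad = grad)
}

# objective/gradient pair for nlminb, sharing the last evaluation
make_objective <- function(spec, pd) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evalf <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return()
    res <- m2ll_and_grad(theta, spec, pd)
    cache$theta <- theta
    if (is.null(res) || !is.finite(res$val)) {
      cache$val <- 1e10
      cache$grad <- rep(0, length(theta))
    } else {
      cache$val <- res$val
      cache$grad <- res$grad
    }
  }
  list(
    fn = function(theta) { evalf(theta); cache$val },
    gr = function(theta) { evalf(theta); cache$grad }
  )
}
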