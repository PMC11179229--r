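# Restricted likelihood machinery for the multi-trait Kronecker model
#
#   vec(Y') ~ N((X kron I_T) beta,  K kron Sigma_T + I_n kron diag(sigma_R))
#
# with trait-specific fixed coefficients. Two exact evaluation paths:
#
# * complete data: eigendecompose K once (K = U D U'), rotate Y and X by
#   U', then simultaneously diagonalize (Sigma_T, Sigma_R) so every
#   rotated observation row has a diagonal covariance; the likelihood
#   and GLS solves then decompose into T independent weighted
#   regressions and cost O(nT) per evaluation.
# * missing trait cells: the exact restricted likelihood of the observed
#   cells of the dense (nT x nT) covariance. Cubic in the number of
#   observed cells; intended for panel-scale data, not genome-scale.

# Simultaneous diagonalization: returns Q with Q' diag(sigma_R) Q = I and
# Q' Sigma_T Q = diag(lambda).
simdiag_cov <- function(Sigma_T, sigma_R) {
  s <- 1 / sqrt(sigma_R)
  M <- Sigma_T * tcrossprod(s)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  list(Q = s * e$vectors, lambda = pmax(e$values, 0))
}

# Negative REML log-likelihood, complete-data rotated form.
# Yt = U'Y (n x T), Xt = U'X (n x p), d = eigenvalues of K.
kron_negll_rotated <- function(Sigma_T, sigma_R, Yt, Xt, d) {
  n <- nrow(Yt); T_ <- ncol(Yt); p <- ncol(Xt)
  sd_ <- simdiag_cov(Sigma_T, sigma_R)
  dl <- outer(d, sd_$lambda)            # n x T
  if (min(dl) <= -1 + 1e-12) return(1e10)
  Z <- Yt %*% sd_$Q
  W <- 1 / (dl + 1)
  ldV <- sum(log1p(dl)) + n * sum(log(sigma_R))
  ldXVX <- -p * sum(log(sigma_R))
  rss <- 0
  for (t in seq_len(T_)) {
    w <- W[, t]
    XtW <- Xt * w
    A <- crossprod(XtW, Xt)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(1e10)
    b <- crossprod(XtW, Z[, t])
    beta <- backsolve(cA, forwardsolve(t(cA), b))
    r <- Z[, t] - Xt %*% beta
    rss <- rss + sum(w * r^2)
    ldXVX <- ldXVX + 2 * sum(log(diag(cA)))
  }
  0.5 * (ldV + ldXVX + rss + (n - p) * T_ * log(2 * pi))
}

# Negative REML log-likelihood on the observed cells of the dense
# covariance (exact under missing trait values).
kron_negll_dense <- function(Sigma_T, sigma_R, Y, X, K) {
  n <- nrow(Y); T_ <- ncol(Y)
  v <- as.vector(t(Y))
  obs <- !is.na(v)
  V <- kronecker(K, Sigma_T) + diag(rep(sigma_R, n))
  Xf <- kronecker(X, diag(T_))
  V <- V[obs, obs, drop = FALSE]
  Xf <- Xf[obs, , drop = FALSE]
  v <- v[obs]
  q <- ncol(Xf)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(1e10)
  Vi_X <- backsolve(cV, forwardsolve(t(cV), Xf))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), v))
  XVX <- crossprod(Xf, Vi_X)
  cX <- tryCatch(chol(XVX), error = function(e) NULL)
  if (is.null(cX)) return(1e10)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(Xf, Vi_y)))
  r <- v - Xf %*% beta
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
           sum(r * Vi_r) + (length(v) - q) * log(2 * pi))
}

#' Restricted log-likelihood of the multi-trait Kronecker model
#'
#' Exact REML log-likelihood of a line x trait matrix under the
#' no-marker covariance K (x) Sigma_T + I (x) Sigma_R with trait-specific
#' fixed effects X. Exposed mainly for verification; model fitting goes
#' through [fit_null_model()].
#'
#' @param Y n x T trait matrix (`NA` = missing cell).
#' @param K n x n relationship matrix.
#' @param Sigma_T T x T genetic covariance between traits.
#' @param sigma_R length-T diagonal residual variances.
#' @param X n x p fixed-effect design (default intercept only); each
#'   column gets a trait-specific coefficient.
#' @return REML log-likelihood (scalar).
#' @export
kron_loglik <- function(Y, K, Sigma_T, sigma_R, X = NULL) {
  Y <- as.matrix(Y)
  if (is.null(X)) X <- matrix(1, nrow(Y), 1)
  X <- as.matrix(X)
  if (anyNA(Y)) {
    -kron_negll_dense(Sigma_T, sigma_R, Y, X, unclass(K))
  } else {
    e <- eigen(unclass(K), symmetric = TRUE)
    -kron_negll_rotated(Sigma_T, sigma_R, crossprod(e$vectors, Y),
                        crossprod(e$vectors, X), e$values)
  }
}

# Analytic REML score for the complete-data rotated likelihood.
#
# With V_i = d_i Sigma_T + Sigma_R and P the REML projection, the score
# for a covariance direction Vdot is
#   d loglik / d theta = -1/2 [ tr(V^-1 Vdot)
#                               - tr(S^-1 X'V^-1 Vdot V^-1 X)
#                               - a' Vdot a ],  a = V^-1 r.
# In the simultaneously diagonalized basis (Q' Sigma_R Q = I,
# Q' Sigma_T Q = diag(lambda)) every term collapses to contractions of a
# few T x T matrices accumulated over the n rotated observations, so the
# full gradient costs about as much as one likelihood evaluation.
kron_negll_grad_rotated <- function(par, structure, Yt, Xt, d) {
  n <- nrow(Yt); T_ <- ncol(Yt); p <- ncol(Xt)
  th <- struct_unpack(par, structure, T_)
  sd_ <- simdiag_cov(th$Sigma_T, th$sigma_R)
  Q <- sd_$Q
  W <- 1 / (outer(d, sd_$lambda) + 1)
  Z <- Yt %*% Q
  Rrot <- matrix(0, n, T_)
  c1 <- c0 <- s1 <- s0 <- numeric(T_)
  for (t in seq_len(T_)) {
    w <- W[, t]
    XtW <- Xt * w
    Mi <- solve(crossprod(XtW, Xt))
    beta <- Mi %*% crossprod(XtW, Z[, t])
    Rrot[, t] <- Z[, t] - Xt %*% beta
    s1[t] <- sum(Mi * crossprod(Xt * (d * w^2), Xt))
    s0[t] <- sum(Mi * crossprod(Xt * w^2, Xt))
    c1[t] <- sum(d * w)
    c0[t] <- sum(w)
  }
  WR <- W * Rrot                       # rows: w_i o (Q' r_i)
  Phi1 <- crossprod(WR * sqrt(d))
  Phi0 <- crossprod(WR)
  A1 <- c1 - s1
  A0 <- c0 - s0
  # helper gradients; "gr_lam(v)": d/dLambda[, b] for rank-one updates
  # u v' + v u' with u ranging over rows of Q
  gr_lam <- function(v) as.numeric(Q %*% (A1 * v - Phi1 %*% v))
  diagQ2 <- function(A, Phi) {         # per-row t: sum_s A_s Q[t,s]^2 - q_t' Phi q_t
    as.numeric(Q^2 %*% A - rowSums((Q %*% Phi) * Q))
  }
  if (structure == "FA1") {
    L <- matrix(par[1:T_], T_, 1)
    psi <- exp(par[T_ + 1:T_])
    v1 <- crossprod(Q, L[, 1])
    g <- c(gr_lam(v1),
           0.5 * psi * diagQ2(A1, Phi1),
           0.5 * th$sigma_R * diagQ2(A0, Phi0))
  } else if (structure == "FA2") {
    L <- matrix(0, T_, 2)
    L[, 1] <- par[1:T_]
    L[2:T_, 2] <- par[T_ + 1:(T_ - 1)]
    psi <- exp(par[2 * T_ - 1 + 1:T_])
    v1 <- crossprod(Q, L[, 1])
    v2 <- crossprod(Q, L[, 2])
    g <- c(gr_lam(v1), gr_lam(v2)[2:T_],
           0.5 * psi * diagQ2(A1, Phi1),
           0.5 * th$sigma_R * diagQ2(A0, Phi0))
  } else {
    nl <- T_ * (T_ + 1) / 2
    Lc <- matrix(0, T_, T_)
    Lc[lower.tri(Lc, diag = TRUE)] <- par[1:nl]
    diag(Lc) <- exp(diag(Lc))
    gL <- matrix(0, T_, T_)
    for (b in seq_len(T_)) {
      vb <- crossprod(Q, Lc[, b])
      gL[b:T_, b] <- gr_lam(vb)[b:T_]
    }
    diag(gL) <- diag(gL) * diag(Lc)    # log-diagonal chain rule
    g <- c(gL[lower.tri(gL, diag = TRUE)],
           0.5 * th$sigma_R * diagQ2(A0, Phi0))
  }
  g
}

# Core fitter: REML for one covariance structure, optional covariates.
# Returns parameter estimates plus the rotated-space pieces needed for
# downstream GLS (coefficients and their covariance at the optimum).
kron_reml_fit <- function(Y, K, structure, X = NULL, starts = NULL,
                          iter_max = 500, rel_tol = 1e-10) {
  Y <- as.matrix(Y)
  n <- nrow(Y); T_ <- ncol(Y)
  if (T_ < 2 && structure != "UNS") structure <- "UNS"  # degenerate guard
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  K <- unclass(K)
  complete <- !anyNA(Y)
  if (complete) {
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < -1e-6) stop("kinship matrix is not positive semi-definite")
    Yt <- crossprod(e$vectors, Y)
    Xt <- crossprod(e$vectors, X)
    d <- pmax(e$values, 0)
    obj <- function(par) {
      th <- struct_unpack(par, structure, T_)
      kron_negll_rotated(th$Sigma_T, th$sigma_R, Yt, Xt, d)
    }
    grad <- function(par) kron_negll_grad_rotated(par, structure, Yt, Xt, d)
  } else {
    obj <- function(par) {
      th <- struct_unpack(par, structure, T_)
      kron_negll_dense(th$Sigma_T, th$sigma_R, Y, X, K)
    }
    grad <- NULL
  }
  if (is.null(starts)) {
    S <- stats::cov(Y, use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    S <- (S + t(S)) / 2
    vy <- pmax(diag(S), 1e-4)
    starts <- list(struct_start(S / 2 + diag(1e-4, T_), 0.5 * vy, structure))
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, obj, gradient = grad,
                    control = list(iter.max = iter_max,
                                   eval.max = 4 * iter_max,
                                   rel.tol = rel_tol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10)
    stop("REML optimization failed for structure ", structure)
  th <- struct_unpack(best$par, structure, T_)
  out <- list(Sigma_T = th$Sigma_T, sigma_R = th$sigma_R,
              loglik = -best$objective, k = struct_npar(structure, T_),
              structure = structure, par = best$par,
              convergence = best$convergence, n = n, T = T_, p = p)
  # GLS fixed effects and their covariance at the optimum
  if (complete) {
    gl <- kron_gls_coefs(th$Sigma_T, th$sigma_R, Yt, Xt, d)
  } else {
    gl <- kron_gls_dense(th$Sigma_T, th$sigma_R, Y, X, K)
  }
  out$coef <- gl$coef          # p x T (covariate by trait)
  out$coef_vcov <- gl$vcov     # list over covariates: T x T covariance
  out
}

# GLS coefficients in the rotated complete-data space. Returns the p x T
# coefficient matrix (original trait basis) and, per covariate, the T x T
# covariance across traits of that covariate's coefficients.
kron_gls_coefs <- function(Sigma_T, sigma_R, Yt, Xt, d) {
  T_ <- ncol(Yt); p <- ncol(Xt)
  sd_ <- simdiag_cov(Sigma_T, sigma_R)
  Z <- Yt %*% sd_$Q
  W <- 1 / (outer(d, sd_$lambda) + 1)
  Bt <- matrix(0, p, T_)
  Ainv <- vector("list", T_)
  for (t in seq_len(T_)) {
    XtW <- Xt * W[, t]
    A <- crossprod(XtW, Xt)
    Ai <- solve(A)
    Bt[, t] <- Ai %*% crossprod(XtW, Z[, t])
    Ainv[[t]] <- Ai
  }
  Qinv_t <- solve(t(sd_$Q))            # maps transformed coefs back
  coef <- t(Qinv_t %*% t(Bt))          # p x T in original basis
  vcov <- lapply(seq_len(p), function(j) {
    Dj <- diag(vapply(Ainv, function(a) a[j, j], numeric(1)), T_)
    Qinv_t %*% Dj %*% t(Qinv_t)
  })
  list(coef = coef, vcov = vcov)
}

# Dense observed-cell GLS (missing trait cells): exact coefficients and
# full covariance.
kron_gls_dense <- function(Sigma_T, sigma_R, Y, X, K) {
  n <- nrow(Y); T_ <- ncol(Y); p <- ncol(X)
  v <- as.vector(t(Y)); obs <- !is.na(v)
  V <- kronecker(K, Sigma_T) + diag(rep(sigma_R, n))
  Xf <- kronecker(X, diag(T_))
  cV <- chol(V[obs, obs, drop = FALSE])
  Vi_X <- backsolve(cV, forwardsolve(t(cV), Xf[obs, , drop = FALSE]))
  XVX <- crossprod(Xf[obs, , drop = FALSE], Vi_X)
  Vb <- solve(XVX)
  beta <- Vb %*% crossprod(Xf[obs, , drop = FALSE],
                           backsolve(cV, forwardsolve(t(cV), v[obs])))
  coef <- matrix(beta, p, T_, byrow = TRUE)
  vcov <- lapply(seq_len(p), function(j) {
    idx <- (j - 1) * T_ + seq_len(T_)
    Vb[idx, idx, drop = FALSE]
  })
  list(coef = coef, vcov = vcov)
}
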