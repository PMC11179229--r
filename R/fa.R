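#' Factor-analytic trait covariance
#'
#' Builds Sigma_T = Lambda Lambda' + diag(Psi), the rank-q
#' factor-analytic parameterization of a between-trait genetic
#' covariance. For order 2 the identifiability constraint
#' `Lambda[1, 2] = 0` is imposed (rotational invariance of the loadings
#' leaves the covariance unchanged; fixing the first trait's second
#' loading pins one rotation).
#'
#' @param loadings T x q numeric matrix (q = 1 or 2).
#' @param psi length-T non-negative specific variances.
#' @return T x T symmetric PSD matrix.
#' @examples
#' fa_covariance(matrix(c(1, 1), 2, 1), psi = c(0, 0))
#' @export
fa_covariance <- function(loadings, psi) {
  loadings <- as.matrix(loadings)
  q <- ncol(loadings)
  if (!q %in% c(1, 2)) stop("factor-analytic order must be 1 or 2")
  if (length(psi) != nrow(loadings)) stop("psi length must match trait count")
  if (any(psi < 0)) stop("specific variances must be non-negative")
  if (q == 2 && abs(loadings[1, 2]) > 1e-12)
    stop("FA2 identifiability constraint violated: Lambda[1,2] must be 0")
  tcrossprod(loadings) + diag(psi, nrow(loadings))
}

# --- covariance-structure parameter packing ------------------------------
# Each structure maps an unconstrained parameter vector to
# (Sigma_T, sigma_R). Specific variances and residual variances live on
# the log scale; UNS uses a Cholesky factor with log-diagonal. Parameter
# counts: FA1 3T, FA2 4T-1, UNS T(T+1)/2 + T.

struct_npar <- function(structure, T_) {
  switch(structure,
         FA1 = 3L * T_,
         FA2 = 4L * T_ - 1L,
         UNS = T_ * (T_ + 1L) / 2L + T_,
         stop("unknown covariance structure: ", structure))
}

struct_unpack <- function(par, structure, T_) {
  if (structure == "FA1") {
    L <- matrix(par[1:T_], T_, 1)
    psi <- exp(par[T_ + 1:T_])
    sigma_R <- exp(par[2 * T_ + 1:T_])
    Sigma_T <- tcrossprod(L) + diag(psi, T_)
  } else if (structure == "FA2") {
    L <- matrix(0, T_, 2)
    L[, 1] <- par[1:T_]
    L[2:T_, 2] <- par[T_ + 1:(T_ - 1)]
    psi <- exp(par[2 * T_ - 1 + 1:T_])
    sigma_R <- exp(par[3 * T_ - 1 + 1:T_])
    Sigma_T <- tcrossprod(L) + diag(psi, T_)
  } else if (structure == "UNS") {
    nl <- T_ * (T_ + 1) / 2
    L <- matrix(0, T_, T_)
    L[lower.tri(L, diag = TRUE)] <- par[1:nl]
    diag(L) <- exp(diag(L))
    sigma_R <- exp(par[nl + 1:T_])
    Sigma_T <- tcrossprod(L)
  } else stop("unknown covariance structure: ", structure)
  list(Sigma_T = (Sigma_T + t(Sigma_T)) / 2, sigma_R = sigma_R)
}

# Starting parameter vector from a target (Sigma_T0, sigma_R0): FA
# families are seeded by eigen-truncation of Sigma_T0.
struct_start <- function(Sigma_T0, sigma_R0, structure) {
  T_ <- nrow(Sigma_T0)
  lg <- function(x) log(pmax(x, 1e-6))
  if (structure == "UNS") {
    S <- Sigma_T0 + diag(1e-4, T_)
    L <- t(chol(S))
    d <- diag(L)
    L[upper.tri(L, diag = TRUE)] <- 0
    diag(L) <- log(d)
    c(L[lower.tri(L, diag = TRUE)], lg(sigma_R0))
  } else {
    q <- if (structure == "FA1") 1 else 2
    e <- eigen(Sigma_T0, symmetric = TRUE)
    lam <- pmax(e$values[1:q], 1e-4)
    L <- e$vectors[, 1:q, drop = FALSE] %*% diag(sqrt(lam), q)
    if (q == 2) { # rotate so L[1,2] = 0 (Givens on the two columns)
      th <- atan2(L[1, 2], L[1, 1])
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      L <- L %*% R
      L[1, 2] <- 0
    }
    psi <- pmax(diag(Sigma_T0) - rowSums(L^2), 1e-4)
    if (q == 1) c(L[, 1], lg(psi), lg(sigma_R0))
    else c(L[, 1], L[2:T_, 2], lg(psi), lg(sigma_R0))
  }
}
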