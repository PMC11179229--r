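# Independent brute-force oracles used across the suite. These are
# deliberately naive re-derivations (dense algebra, explicit loops,
# enumeration) kept separate from the package's computational paths.

# Dense multivariate-normal restricted log-likelihood built from the
# explicit (nT x nT) Kronecker covariance, using generic solve() and
# determinant() throughout.
oracle_kron_reml_loglik <- function(Y, K, Sigma_T, sigma_R, X = NULL) {
  n <- nrow(Y); T_ <- ncol(Y)
  if (is.null(X)) X <- matrix(1, n, 1)
  v <- as.vector(t(Y))
  obs <- !is.na(v)
  V <- kronecker(unclass(K), Sigma_T) + diag(rep(sigma_R, n))
  Xf <- kronecker(as.matrix(X), diag(T_))
  V <- V[obs, obs, drop = FALSE]
  Xf <- Xf[obs, , drop = FALSE]
  v <- v[obs]
  Vi <- solve(V)
  XVX <- t(Xf) %*% Vi %*% Xf
  beta <- solve(XVX, t(Xf) %*% Vi %*% v)
  r <- v - Xf %*% beta
  -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(XVX, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% Vi %*% r) +
            (length(v) - ncol(Xf)) * log(2 * pi))
}

# Dense GLS fixed-effect solve for intercept + one SNP, trait-specific
# coefficients; returns per-trait marker effects, their covariance, and
# the joint Wald statistic.
oracle_gls_snp <- function(Y, x, K, Sigma_T, sigma_R) {
  n <- nrow(Y); T_ <- ncol(Y)
  v <- as.vector(t(Y))
  V <- kronecker(unclass(K), Sigma_T) + diag(rep(sigma_R, n))
  Xf <- cbind(kronecker(matrix(1, n, 1), diag(T_)),
              kronecker(matrix(x, n, 1), diag(T_)))
  Vi <- solve(V)
  XVX <- t(Xf) %*% Vi %*% Xf
  beta <- solve(XVX, t(Xf) %*% Vi %*% v)
  Vb <- solve(XVX)
  a <- beta[T_ + seq_len(T_)]
  Va <- Vb[T_ + seq_len(T_), T_ + seq_len(T_)]
  list(alpha = a, vcov = Va, wald = drop(t(a) %*% solve(Va) %*% a))
}

# Textbook VanRaden relationship: explicit double loop over line pairs.
oracle_vanraden <- function(calls) {
  n <- nrow(calls)
  p <- colMeans(calls) / 2
  poly <- p > 0 & p < 1
  calls <- calls[, poly, drop = FALSE]
  p <- p[poly]
  denom <- 2 * sum(p * (1 - p))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sum((calls[i, ] - 2 * p) * (calls[j, ] - 2 * p)) / denom
  K
}

# Two-sided Fisher exact probability of a 2x2 table by full
# hypergeometric enumeration: sum of P(table) over all tables with the
# observed margins whose probability is <= the observed one.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  N <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct REML optimizer for a tiny one-way random-effects layout
# (line random + fixed blocks): dense V = sg2 * Z Z' + se2 * I.
oracle_tiny_reml <- function(y, line, block) {
  Z <- outer(line, sort(unique(line)), "==") * 1
  X <- stats::model.matrix(~ factor(block))
  negll <- function(th) {
    sg2 <- exp(th[1]); se2 <- exp(th[2])
    V <- sg2 * tcrossprod(Z) + se2 * diag(length(y))
    Vi <- solve(V)
    XVX <- t(X) %*% Vi %*% X
    beta <- solve(XVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    0.5 * (determinant(V)$modulus[1] + determinant(XVX)$modulus[1] +
             drop(t(r) %*% Vi %*% r))
  }
  opt <- stats::optim(c(0, 0), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(sigma2_g = exp(opt$par[1]), sigma2_e = exp(opt$par[2]),
       negll = opt$value)
}

# Small complete panel + aligned trait matrix for model-level tests.
make_test_panel <- function(n_lines = 120, n_chrom = 3, snps = 80,
                            n_traits = 3, seed = 99, ...) {
  cfg <- sim_config(n_lines = n_lines, n_chrom = n_chrom,
                    snps_per_chrom = snps, n_traits = n_traits,
                    seed = seed, ...)
  pan <- simulate_panel(cfg)
  G <- recode_to_minor(impute_mode(pan$genotypes))
  list(cfg = cfg, G = G, K = vanraden_grm(G), values = pan$values)
}

# Dense restricted negative log-likelihood at given variance components
# for the same tiny layout (up to the additive constant used above).
oracle_tiny_reml_negll <- function(y, line, block, sg2, se2) {
  Z <- outer(line, sort(unique(line)), "==") * 1
  X <- stats::model.matrix(~ factor(block))
  V <- sg2 * tcrossprod(Z) + se2 * diag(length(y))
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  beta <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  0.5 * (determinant(V)$modulus[1] + determinant(XVX)$modulus[1] +
           drop(t(r) %*% Vi %*% r))
}
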