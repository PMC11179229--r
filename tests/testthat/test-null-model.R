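test_that("factor-analytic covariance builds and enforces its constraint", {
  expect_equal(fa_covariance(matrix(0, 4, 1), rep(1, 4)), diag(4))
  expect_equal(fa_covariance(matrix(c(1, 1), 2, 1), c(0, 0)),
               matrix(1, 2, 2))
  L <- matrix(c(1, 2, 3, 0, 1, -1), 3, 2)
  expect_equal(fa_covariance(L, c(0.1, 0.2, 0.3)),
               tcrossprod(L) + diag(c(0.1, 0.2, 0.3)))
  Lbad <- L; Lbad[1, 2] <- 0.5
  expect_error(fa_covariance(Lbad, rep(0.1, 3)), "identifiability")
  expect_error(fa_covariance(L, c(-1, 0, 0)), "non-negative")
})

test_that("FA2 family can reproduce a rank-2-plus-diagonal covariance", {
  set.seed(3)
  L <- matrix(rnorm(8), 4, 2); L[1, 2] <- 0
  psi <- runif(4, 0.1, 0.5)
  S_true <- fa_covariance(L, psi)
  # least-squares projection via a direct optimizer over the FA2 family
  unpack <- function(par) {
    M <- matrix(0, 4, 2); M[, 1] <- par[1:4]; M[2:4, 2] <- par[5:7]
    fa_covariance(M, exp(par[8:11]))
  }
  obj <- function(par) sum((unpack(par) - S_true)^2)
  opt <- stats::optim(c(L[, 1], L[2:4, 2], log(psi)), obj,
                      method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(opt$value, 1e-10)
})

test_that("parameter counts follow the covariance structure", {
  for (T_ in c(3, 6, 8)) {
    Y <- matrix(rnorm(20 * T_), 20, T_)
    expect_equal(mtgwas:::struct_npar("FA1", T_), 3 * T_)
    expect_equal(mtgwas:::struct_npar("FA2", T_), 4 * T_ - 1)
    expect_equal(mtgwas:::struct_npar("UNS", T_), T_ * (T_ + 1) / 2 + T_)
    # pack/unpack round trip preserves the covariance
    par <- mtgwas:::struct_start(diag(T_) + 0.3, rep(0.5, T_), "UNS")
    th <- mtgwas:::struct_unpack(par, "UNS", T_)
    expect_equal(th$Sigma_T, diag(T_) + 0.3 + diag(1e-4, T_), tolerance = 1e-8)
  }
})

test_that("restricted likelihood matches the dense Kronecker oracle", {
  set.seed(21)
  n <- 6; T_ <- 3
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  K <- (K + t(K)) / 2 + diag(0.05, n)
  Y <- matrix(rnorm(n * T_), n, T_)
  Sigma_T <- crossprod(matrix(rnorm(T_ * T_), T_)) / T_
  sigma_R <- runif(T_, 0.3, 1)
  # complete data
  expect_equal(kron_loglik(Y, K, Sigma_T, sigma_R),
               oracle_kron_reml_loglik(Y, K, Sigma_T, sigma_R),
               tolerance = 1e-8)
  # with covariates
  X <- cbind(1, rnorm(n))
  expect_equal(kron_loglik(Y, K, Sigma_T, sigma_R, X = X),
               oracle_kron_reml_loglik(Y, K, Sigma_T, sigma_R, X = X),
               tolerance = 1e-8)
  # missing trait cells
  Ym <- Y; Ym[1, 2] <- NA; Ym[4, 1] <- NA; Ym[6, 3] <- NA
  expect_equal(kron_loglik(Ym, K, Sigma_T, sigma_R),
               oracle_kron_reml_loglik(Ym, K, Sigma_T, sigma_R),
               tolerance = 1e-8)
})

test_that("null-model fits are permutation invariant and nested in likelihood", {
  pan <- make_test_panel(n_lines = 100, snps = 60, n_traits = 4, seed = 42)
  Y <- standardize_traits(pan$values)
  fit <- fit_null_model(Y, pan$K)
  ll <- stats::setNames(fit$candidates$loglik, fit$candidates$structure)
  expect_gte(ll[["UNS"]] + 1e-4, ll[["FA2"]])
  expect_gte(ll[["FA2"]] + 1e-4, ll[["FA1"]])
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$k)
  # joint permutation of rows leaves the estimates unchanged
  set.seed(1)
  perm <- sample(nrow(Y))
  Kp <- structure(unclass(pan$K)[perm, perm], class = class(pan$K))
  fit_p <- fit_null_model(Y[perm, ], Kp, structures = fit$structure)
  expect_equal(fit_p$Sigma_T, fit$Sigma_T, tolerance = 1e-4)
  expect_equal(fit_p$sigma_R, fit$sigma_R, tolerance = 1e-4)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-5)
})

test_that("structure selection minimizes AIC with ties to fewer parameters", {
  mk <- function(structure, loglik, k)
    list(structure = structure, loglik = loglik, k = k, n = 10, T = 4,
         Sigma_T = diag(4), sigma_R = rep(1, 4), coef = matrix(0, 1, 4))
  fits <- list(FA1 = mk("FA1", -50, 12), FA2 = mk("FA2", -45, 15),
               UNS = mk("UNS", -47.5, 14))
  expect_equal(select_structure(fits)$structure, "FA2")  # AICs 124, 120, 123
  # exact AIC tie FA1 vs UNS -> FA1 (fewer parameters)
  fits2 <- list(FA1 = mk("FA1", -50, 12), UNS = mk("UNS", -48, 14))
  expect_equal(select_structure(fits2)$structure, "FA1")
  fits_bad <- list(a = mk("FA1", -50, 12),
                   b = modifyList(mk("UNS", -48, 14), list(T = 5)))
  expect_error(select_structure(fits_bad), "different trait sets")
})

test_that("UNS REML recovers a generating covariance on one large panel", {
  set.seed(9)
  n <- 500; T_ <- 3
  pan <- make_test_panel(n_lines = n, n_chrom = 10, snps = 60, n_traits = T_,
                         seed = 55, n_founders = 32)
  K <- unclass(pan$K)
  Ks <- K / mean(diag(K))
  ST <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  sR <- rep(0.3, 3)
  Lk <- t(chol(Ks + diag(1e-6, n)))
  rmse <- replicate(3, {
    Y <- Lk %*% matrix(rnorm(n * T_), n, T_) %*% chol(ST) +
      matrix(rnorm(n * T_), n, T_) %*% diag(sqrt(sR))
    fit <- fit_null_model(Y, pan$K, structures = "UNS")
    # estimates are on the kinship scale (mean diag 2): Sigma_T absorbs 1/2
    c(sqrt(mean((fit$Sigma_T * mean(diag(K)) - ST)^2)),
      sqrt(mean((fit$sigma_R - sR)^2)))
  })
  expect_lt(mean(rmse[1, ]), 0.15)
  expect_lt(mean(rmse[2, ]), 0.15)
})

test_that("without genetic signal the fitted genetic covariance collapses", {
  set.seed(13)
  pan <- make_test_panel(n_lines = 400, n_chrom = 2, snps = 80, n_traits = 3,
                         seed = 66)
  Y <- matrix(rnorm(400 * 3), 400, 3)  # i.i.d. rows, K arbitrary
  fit <- fit_null_model(Y, pan$K, structures = "UNS")
  expect_lt(sqrt(sum(fit$Sigma_T^2)), 0.06)
  expect_equal(fit$sigma_R, rep(1, 3), tolerance = 0.12)
})

test_that("null fit handles missing trait cells exactly", {
  pan <- make_test_panel(n_lines = 45, snps = 40, n_traits = 3, seed = 17)
  Y <- standardize_traits(pan$values)
  Ym <- Y
  set.seed(2)
  Ym[cbind(sample(45, 6), sample(3, 6, TRUE))] <- NA
  fit <- fit_null_model(Ym, pan$K, structures = "FA1")
  # the reported likelihood must equal the dense oracle at the estimates
  expect_equal(fit$loglik,
               oracle_kron_reml_loglik(Ym, pan$K, fit$Sigma_T, fit$sigma_R),
               tolerance = 1e-6)
})

test_that("analytic REML score matches central finite differences", {
  set.seed(3)
  n <- 40; T_ <- 4
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  K <- (K + t(K)) / 2 + diag(0.1, n)
  Y <- matrix(rnorm(n * T_), n, T_)
  X <- cbind(1, rnorm(n))
  e <- eigen(K, symmetric = TRUE)
  Yt <- crossprod(e$vectors, Y)
  Xt <- crossprod(e$vectors, X)
  d <- pmax(e$values, 0)
  fd <- function(f, par, h = 1e-6) vapply(seq_along(par), function(j) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (f(pp) - f(pm)) / (2 * h)
  }, numeric(1))
  for (s in c("FA1", "FA2", "UNS")) {
    set.seed(10)
    par <- rnorm(mtgwas:::struct_npar(s, T_), 0, 0.4)
    f <- function(p) {
      th <- mtgwas:::struct_unpack(p, s, T_)
      mtgwas:::kron_negll_rotated(th$Sigma_T, th$sigma_R, Yt, Xt, d)
    }
    ga <- mtgwas:::kron_negll_grad_rotated(par, s, Yt, Xt, d)
    expect_equal(ga, fd(f, par), tolerance = 1e-5)
  }
})
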