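test_that("Bonferroni threshold follows the LD-extent test count", {
  expect_equal(bonferroni_threshold(0.05, 150e3, 150e3), -log10(0.05),
               tolerance = 1e-12)                       # one test -> 1.301
  expect_equal(round(bonferroni_threshold(0.05, 150e3, 150e3), 3), 1.301)
  expect_equal(bonferroni_threshold(0.05, 5000 * 150e3, 150e3), 5)
  expect_equal(round(bonferroni_threshold(0.05, 659.2e6, 150e3), 2), 4.94)
  expect_error(bonferroni_threshold(0), "alpha")
})

test_that("GLS scan equals the dense Kronecker oracle on a tiny instance", {
  set.seed(2)
  n <- 8; T_ <- 2
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  K <- (K + t(K)) / 2 + diag(0.1, n)
  Y <- matrix(rnorm(n * T_), n, T_)
  x1 <- c(0, 2, 2, 0, 2, 0, 0, 2)
  x2 <- c(2, 2, 0, 0, 0, 2, 0, 2)
  G <- geno_matrix(cbind(s1 = x1, s2 = x2),
                   data.frame(id = c("s1", "s2"), chrom = c("1", "2"),
                              pos = c(10, 20)))
  ST <- matrix(c(1, .4, .4, .8), 2)
  sR <- c(.5, .7)
  loco <- list("1" = structure(K, class = c("kinship_matrix", "matrix")),
               "2" = structure(K, class = c("kinship_matrix", "matrix")))
  sc <- mt_scan(Y, G, list(Sigma_T = ST, sigma_R = sR), loco)
  for (s in 1:2) {
    orc <- oracle_gls_snp(Y, G$calls[, s], K, ST, sR)
    expect_equal(as.numeric(sc[s, c("eff_trait1", "eff_trait2")]),
                 as.numeric(orc$alpha), tolerance = 1e-10)
    expect_equal(sc$wald[s], orc$wald, tolerance = 1e-10)
  }
  expect_equal(sc$minus_log10_p,
               -log10(pchisq(sc$wald, df = 2, lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("scan handles missing trait cells through the dense path", {
  set.seed(5)
  n <- 10; T_ <- 2
  K <- diag(n) + 0.2
  Y <- matrix(rnorm(n * T_), n, T_)
  Y[3, 1] <- NA; Y[7, 2] <- NA
  x <- sample(c(0, 2), n, TRUE)
  G <- geno_matrix(cbind(s1 = x),
                   data.frame(id = "s1", chrom = "1", pos = 5))
  ST <- diag(2) * 0.6; sR <- c(1, 1)
  loco <- list("1" = structure(K, class = c("kinship_matrix", "matrix")))
  sc <- mt_scan(Y, G, list(Sigma_T = ST, sigma_R = sR), loco)
  expect_equal(nrow(sc), 1)
  expect_true(is.finite(sc$minus_log10_p))
})

test_that("monomorphic SNPs are skipped with a log entry", {
  set.seed(6)
  n <- 12
  Y <- matrix(rnorm(n * 2), n, 2)
  G <- geno_matrix(cbind(s1 = rep(0, n), s2 = sample(c(0, 2), n, TRUE)),
                   data.frame(id = c("s1", "s2"), chrom = "1", pos = c(1, 2)))
  loco <- list("1" = structure(diag(n), class = c("kinship_matrix", "matrix")))
  expect_message(sc <- mt_scan(Y, G, list(Sigma_T = diag(2), sigma_R = c(1, 1)),
                               loco), "skipped")
  expect_equal(sc$snp, "s2")
  expect_true("s1" %in% attr(sc, "skipped"))
})

test_that("with diagonal covariances the joint Wald is the sum of per-trait stats", {
  set.seed(7)
  n <- 60; T_ <- 3
  pan <- make_test_panel(n_lines = n, snps = 30, n_traits = T_, seed = 23)
  Y <- standardize_traits(pan$values)
  ST <- diag(c(0.5, 0.7, 0.3))
  sR <- c(0.6, 0.5, 0.9)
  loco <- loco_grm_all(pan$G)
  sc <- mt_scan(Y, pan$G, list(Sigma_T = ST, sigma_R = sR), loco)
  # per-trait single-trait GLS under the same diagonal covariance
  for (r in sample(nrow(sc), 4)) {
    snp <- sc$snp[r]
    x <- pan$G$calls[, snp]
    Kc <- unclass(loco[[sc$chrom[r]]])
    w_sum <- 0
    for (t in seq_len(T_)) {
      V <- ST[t, t] * Kc + sR[t] * diag(n)
      Vi <- solve(V)
      X <- cbind(1, x)
      XVX <- t(X) %*% Vi %*% X
      b <- solve(XVX, t(X) %*% Vi %*% Y[, t])
      w_sum <- w_sum + b[2]^2 / solve(XVX)[2, 2]
    }
    expect_equal(sc$wald[r], w_sum, tolerance = 1e-8)
  }
})

test_that("scan p-values are invariant to joint line permutation", {
  pan <- make_test_panel(n_lines = 50, snps = 25, n_traits = 3, seed = 33)
  set.seed(77)
  Y <- standardize_traits(pan$values + matrix(rnorm(150, sd = 0.7), 50, 3))
  nf <- fit_null_model(Y, pan$K, structures = "FA1")
  loco <- loco_grm_all(pan$G)
  sc <- mt_scan(Y, pan$G, nf, loco)
  set.seed(4)
  perm <- sample(nrow(Y))
  Gp <- geno_matrix(pan$G$calls[perm, ], pan$G$map)
  locop <- lapply(loco, function(k)
    structure(unclass(k)[perm, perm], class = class(k)))
  scp <- mt_scan(Y[perm, ], Gp, nf, locop)
  expect_equal(scp$minus_log10_p, sc$minus_log10_p, tolerance = 1e-6)
})

test_that("association classification respects the boundary rules", {
  rec <- data.frame(snp = c("a", "b", "c", "d"), chrom = "1", pos = 1:4,
                    minus_log10_p = c(5.1, 4.5, 3.9, 4.94))
  cls <- classify_associations(rec, threshold_sig = 4.94, threshold_sug = 4.0)
  expect_equal(as.character(cls$classification),
               c("significant", "suggestive", "none", "significant"))
  counts <- attr(cls, "counts")
  expect_equal(unname(counts[c("significant", "suggestive", "none")]),
               c(2L, 1L, 1L), ignore_attr = TRUE)
  empty <- classify_associations(rec[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(classify_associations(rec, threshold_sig = 3, threshold_sug = 4))
})

test_that("variance explained follows the genotype-frequency formula", {
  v <- variance_explained(0.5, 0.5, 1)
  expect_equal(v$V_m, 0.25)
  expect_equal(v$percent, 25)
  expect_equal(variance_explained(3.7, 0, 1)$percent, 0)
  expect_equal(variance_explained(3.7, 1, 2)$percent, 0)
  # Monte-Carlo: Var(x * alpha) over inbred genotypes matches alpha^2 4p(1-p)
  set.seed(10)
  for (p in c(0.1, 0.35)) {
    x <- sample(c(0, 2), 1e5, TRUE, prob = c(1 - p, p))
    alpha <- 0.8
    expect_equal(stats::var(x * alpha), alpha^2 * 4 * p * (1 - p),
                 tolerance = 0.02)
  }
})

test_that("full REML refit agrees with the scan on a well-powered hit", {
  set.seed(19)
  n <- 300
  cfg <- sim_config(n_lines = n, n_chrom = 3, snps_per_chrom = 60,
                    n_traits = 3, seed = 91,
                    sigma_T_true = diag(0.4, 3), sigma_R_true = rep(0.4, 3))
  G <- simulate_genotypes(cfg)
  j <- which(compute_maf(G)$maf > 0.3)[3]
  cfg$qtl_list <- list(list(snp = j, effects = c(0.5, 0.5, 0)))
  vals <- simulate_genetic_values(G, cfg)
  Y <- vals + matrix(rnorm(n * 3, sd = sqrt(0.4)), n, 3)
  K <- vanraden_grm(G)
  nf <- fit_null_model(Y, K, structures = "UNS")
  rf <- refit_snp(Y, G$calls[, j], K, structure = "UNS", null_fit = nf)
  expect_false(rf$gls_fallback)
  # effects on the two affected traits are positive and near truth
  expect_gt(min(rf$effects$effect[1:2]), 0.3)
  expect_lt(abs(rf$effects$effect[3]), 0.2)
  expect_equal(rf$effects$favorable_allele[1], "minor")
  # CI excludes zero for true effects, covers zero for the null trait
  expect_gt(rf$effects$ci_low[1], 0)
  expect_true(rf$effects$ci_low[3] < 0 && rf$effects$ci_high[3] > 0)
  # step-2 GLS estimates agree within 10%
  loco <- loco_grm_all(G)
  sc <- mt_scan(Y, G, nf, loco)
  row <- sc[sc$snp == G$map$id[j], ]
  for (t in 1:2) {
    gls_eff <- row[[paste0("eff_trait", t)]]
    expect_lt(abs(gls_eff - rf$effects$effect[t]) / abs(rf$effects$effect[t]),
              0.10)
  }
  # variance explained uses the null-model phenotypic variance
  p2 <- mean(G$calls[, j]) / 2
  vp <- diag(nf$Sigma_T) + nf$sigma_R
  expect_equal(rf$effects$pct_var_explained,
               as.numeric(100 * rf$effects$effect^2 * 4 * p2 * (1 - p2) / vp),
               tolerance = 1e-10)
})
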