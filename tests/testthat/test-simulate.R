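test_that("genotype simulation is seed-deterministic and properly coded", {
  cfg <- sim_config(n_lines = 40, n_chrom = 2, snps_per_chrom = 50,
                    n_traits = 2, seed = 7, missing_rate = 0.03)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$calls, G2$calls)
  expect_identical(G1$map, G2$map)
  expect_true(all(G1$calls %in% c(0, 2) | is.na(G1$calls)))
  expect_true(all(diff(order(G1$map$chrom, G1$map$pos)) == 1))
  # MAF spectrum respects maf_min
  info <- compute_maf(impute_mode(G1))
  expect_true(all(info$maf >= cfg$maf_min - 0.05))  # imputation can shift slightly
  info_raw <- compute_maf(simulate_genotypes(sim_config(n_lines = 200, n_chrom = 1,
                                                        snps_per_chrom = 100,
                                                        n_traits = 2, seed = 5)))
  expect_true(all(info_raw$maf >= 0.025))
})

test_that("degenerate panels are refused", {
  expect_error(simulate_genotypes(sim_config(n_lines = 0, n_traits = 2)),
               "degenerate panel")
})

test_that("without recombination every line equals one founder haplotype", {
  cfg <- sim_config(n_lines = 30, n_chrom = 1, snps_per_chrom = 40,
                    n_founders = 2, ld_segment_bp = 1e15, maf_min = 0.05,
                    n_traits = 2, seed = 6)
  G <- simulate_genotypes(cfg)
  expect_gt(ncol(G$calls), 5)
  # two complementary haplotypes only -> every pairwise r2 is 1
  cr <- suppressWarnings(cor(G$calls))
  expect_true(all(abs(cr^2 - 1) < 1e-12))
  expect_lte(nrow(unique(G$calls)), 2)
})

test_that("panel LD decays with the configured 150 kb extent", {
  cfg <- sim_config(n_lines = 500, n_chrom = 2, snps_per_chrom = 200,
                    n_traits = 2, seed = 11)
  G <- simulate_genotypes(cfg)
  j <- which(G$map$chrom == "1")
  cr <- suppressWarnings(cor(G$calls[, j]))^2
  d <- abs(outer(G$map$pos[j], G$map$pos[j], "-"))
  ut <- upper.tri(d)
  dd <- d[ut]; rr <- cr[ut]
  ok <- !is.na(rr)
  dd <- dd[ok]; rr <- rr[ok]
  bg <- mean(rr[dd > 2e6])
  # far pairs sit at the unlinked background
  expect_lt(mean(rr[dd > 6e5]), 0.15)
  expect_lt(bg, 0.05)
  fitL <- stats::optimize(function(L)
    sum((rr - (bg + (1 - bg) * exp(-dd / L)))^2), c(1e4, 1e6))$minimum
  expect_gt(fitL, 150e3 * 0.7)
  expect_lt(fitL, 150e3 * 1.3)
})

test_that("mean VanRaden diagonal on a big inbred panel is close to 2", {
  cfg <- sim_config(n_lines = 1000, n_chrom = 2, snps_per_chrom = 150,
                    n_traits = 2, seed = 31)
  G <- simulate_genotypes(cfg)
  K <- vanraden_grm(G)
  expect_lt(abs(mean(diag(K)) - 2), 0.1)
})

test_that("genetic values honor QTL effects and the background covariance", {
  pan <- make_test_panel(n_lines = 60, snps = 40, seed = 14)
  # no QTLs, zero covariance -> all-zero matrix
  cfg0 <- sim_config(n_lines = 60, n_chrom = 3, snps_per_chrom = 40,
                     n_traits = 3, seed = 14,
                     sigma_T_true = matrix(0, 3, 3),
                     sigma_R_true = rep(0.5, 3))
  vals0 <- simulate_genetic_values(pan$G, cfg0)
  expect_true(all(vals0 == 0))
  # one QTL with effect (1, 0, 0): class difference 2 on trait 1 exactly
  # when the background is silent
  j <- which(compute_maf(pan$G)$maf > 0.3)[1]
  cfg1 <- sim_config(n_lines = 60, n_chrom = 3, snps_per_chrom = 40,
                     n_traits = 3, seed = 14,
                     qtl_list = list(list(snp = j, effects = c(1, 0, 0))),
                     sigma_T_true = matrix(0, 3, 3))
  vals1 <- simulate_genetic_values(pan$G, cfg1)
  g <- pan$G$calls[, j]
  expect_equal(mean(vals1[g == 2, 1]) - mean(vals1[g == 0, 1]), 2, tolerance = 1e-9)
  expect_true(all(vals1[, 2:3] == 0))
  expect_lt(max(abs(colMeans(vals1))), 1e-9)
  # effect-vector length mismatch errors
  expect_error(sim_config(n_traits = 3,
                          qtl_list = list(list(snp = 1, effects = c(1, 0)))),
               "length")
})

test_that("simulated genetic correlation matches the target covariance", {
  ST <- matrix(c(1, 0.5, 0.5, 1), 2)
  cfg <- sim_config(n_lines = 2000, n_chrom = 1, snps_per_chrom = 120,
                    n_traits = 2, sigma_T_true = ST,
                    sigma_R_true = c(0.5, 0.5), seed = 77)
  G <- simulate_genotypes(cfg)
  vals <- simulate_genetic_values(G, cfg)
  # rows share the panel kinship, so decorrelate with the known K before
  # estimating the trait-trait correlation (Monte-Carlo check of the
  # matrix-normal construction)
  K <- unclass(vanraden_grm(G))
  Ks <- K / mean(diag(K)) + diag(1e-6, nrow(K))
  W <- backsolve(chol(Ks), vals, transpose = TRUE)
  expect_lt(abs(cor(W[, 1], W[, 2]) - 0.5), 0.05)
  # raw sample correlation is noisier under kinship but still near target
  expect_lt(abs(cor(vals[, 1], vals[, 2]) - 0.5), 0.15)
})

test_that("trial simulation reproduces design structure and exact values", {
  vals <- stats::setNames(seq(-2, 2, length.out = 20), paste0("L", 1:20))
  # sigma = 0 everywhere -> plot value is mu + line value exactly
  d0 <- design_spec("rcbd", sigma_rep = 0, sigma_block = 0, sigma_e = 0)
  recs <- simulate_trial(vals, d0, mu = 1, seed = 1)
  expect_equal(recs$value, 1 + unname(vals[recs$line]))
  # augmented design: every block holds both checks plus unique test lines
  da <- design_spec("augmented", n_block = 5)
  ra <- simulate_trial(vals, da, seed = 2)
  for (b in unique(ra$block)) {
    inb <- ra[ra$block == b, ]
    expect_setequal(inb$line[inb$is_check], c("ATF8", "ATF10"))
    expect_false(anyDuplicated(inb$line[!inb$is_check]) > 0)
  }
  expect_false(anyDuplicated(ra$line[!ra$is_check]) > 0)
  # capacity guard
  dcap <- design_spec("augmented", n_block = 2, block_size = 3)
  expect_error(simulate_trial(vals, dcap), "capacity")
  # missing plots honored
  dm <- design_spec("rcbd", missing_plot_rate = 0.2)
  rm_ <- simulate_trial(vals, dm, seed = 3)
  expect_lt(nrow(rm_), 60)
})

test_that("balanced RCBD line means recover truth with SE sigma_e/sqrt(r)", {
  vals <- stats::setNames(rep(0, 8), paste0("L", 1:8))
  d <- design_spec("rcbd", n_rep = 3, sigma_rep = 0, sigma_e = 0.9)
  errs <- replicate(1000, {
    recs <- simulate_trial(vals, d)
    mean(tapply(recs$value, recs$line, mean))  # mean of line means, truth 0
  })
  # each line mean has SE sigma_e/sqrt(3); the average over 8 lines
  # scales it by 1/sqrt(8)
  expect_equal(stats::sd(errs), 0.9 / sqrt(3) / sqrt(8), tolerance = 0.08)
  one <- replicate(600, {
    recs <- simulate_trial(vals[1:2], d)
    tapply(recs$value, recs$line, mean)[["L1"]]
  })
  expect_equal(stats::sd(one), 0.9 / sqrt(3), tolerance = 0.06)
})

test_that("full panel simulation is deterministic including trait missingness", {
  cfg <- sim_config(n_lines = 50, n_chrom = 2, snps_per_chrom = 40,
                    n_traits = 3, trait_missing_rate = 0.1, seed = 9)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$values, p2$values)
  expect_gt(sum(is.na(p1$values)), 0)
})
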