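#' Configuration for the synthetic sorghum-like association panel
#'
#' Defaults emulate the panel the package targets: ~272 inbred lines, 10
#' chromosomes, LD extent around 150 kb, eight correlated traits measured
#' in three experiment designs (lattice for grain yield, RCBD for the 2D
#' root/performance traits, augmented with two checks for the 3D traits).
#' SNP density is scaled to desk size (250 pre-filter SNPs per
#' chromosome); chromosome length defaults to 65.92 Mb so the simulated
#' ten-chromosome genome totals the 659.2 Mb used for the Bonferroni
#' threshold.
#'
#' @param n_lines number of inbred lines.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param snps_per_chrom SNPs drawn per chromosome before MAF filtering.
#' @param n_founders size of the founder haplotype pool.
#' @param ld_segment_bp mean founder-segment length in bp; controls the
#'   LD decay length of the panel.
#' @param maf_min SNPs below this minor-allele frequency are dropped at
#'   generation time.
#' @param missing_rate fraction of genotype calls set missing uniformly
#'   at random.
#' @param n_traits number of traits.
#' @param qtl_list list of pleiotropic QTLs, each `list(snp = <index or
#'   id>, effects = <length n_traits vector>)`; effects are per unit of
#'   the \{0,2\} allele code.
#' @param sigma_T_true T x T polygenic-background genetic covariance
#'   (symmetric PSD). Default: a two-factor structure with mostly
#'   positive loadings, echoing the positive trait correlations typical
#'   of root/performance trait sets.
#' @param sigma_R_true length-T residual variances.
#' @param trait_missing_rate fraction of line x trait values set missing
#'   ("not scored in a given line").
#' @param designs named list mapping each trait name to a [design_spec()].
#' @param seed integer seed; fixed seed implies bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 272, n_chrom = 10, chrom_length_bp = 65.92e6,
                       snps_per_chrom = 250, n_founders = 16,
                       ld_segment_bp = 150e3, maf_min = 0.025,
                       missing_rate = 0, n_traits = 8,
                       qtl_list = list(),
                       sigma_T_true = NULL, sigma_R_true = NULL,
                       trait_missing_rate = 0,
                       designs = NULL, seed = 1L) {
  if (is.null(sigma_T_true)) sigma_T_true <- default_sigma_T(n_traits)
  if (is.null(sigma_R_true)) sigma_R_true <- rep(0.5, n_traits)
  stopifnot(n_founders >= 2, snps_per_chrom >= 1, maf_min >= 0, maf_min <= 0.5,
            length(sigma_R_true) == n_traits, all(sigma_R_true >= 0),
            nrow(sigma_T_true) == n_traits)
  if (max(abs(sigma_T_true - t(sigma_T_true))) > 1e-8)
    stop("sigma_T_true must be symmetric")
  ev <- eigen(sigma_T_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("sigma_T_true must be positive semi-definite")
  for (q in qtl_list)
    if (length(q$effects) != n_traits) stop("QTL effect vector length must equal n_traits")
  cfg <- list(n_lines = n_lines, n_chrom = n_chrom,
              chrom_length_bp = chrom_length_bp,
              snps_per_chrom = snps_per_chrom, n_founders = n_founders,
              ld_segment_bp = ld_segment_bp, maf_min = maf_min,
              missing_rate = missing_rate, n_traits = n_traits,
              qtl_list = qtl_list, sigma_T_true = sigma_T_true,
              sigma_R_true = sigma_R_true,
              trait_missing_rate = trait_missing_rate,
              designs = designs, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default 8-trait genetic covariance: rank-2 factor structure plus
# specific variances, scaled to unit diagonal-ish magnitudes.
default_sigma_T <- function(T_) {
  l1 <- seq(0.8, 0.4, length.out = T_)
  l2 <- 0.4 * rep_len(c(0, 1, -1), T_)
  S <- tcrossprod(l1) + tcrossprod(l2) + diag(0.2, T_)
  S
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_lines, "lines,", x$n_chrom, "chromosomes x",
      x$snps_per_chrom, "SNPs,", x$n_traits, "traits,",
      length(x$qtl_list), "QTL(s), seed", x$seed, "\n")
  invisible(x)
}

#' Simulate an inbred genotype panel with tunable LD
#'
#' Two-layer founder mosaic. Two complementary deep ancestral haplotypes
#' differ at every site; each founder haplotype is a segment-wise mosaic
#' of the two (founder-specific mixture weight, so panel allele
#' frequencies spread out); each line is in turn a segment-wise mosaic of
#' the founder pool, picked with skewed per-chromosome usage weights
#' (limited local haplotype diversity, as in a diversity panel). All
#' segment lengths are exponential. Allele correlation at distance d
#' needs both the line-level and the founder-level segment to survive,
#' and r-squared is the squared correlation, so the internal segment
#' mean is a calibrated multiple (3x) of `ld_segment_bp`; the fitted
#' decay length of the panel-level mean r-squared curve then matches
#' `ld_segment_bp` to within sampling error.
#' Genotypes are coded \{0,2\} (fully inbred); SNPs with
#' minor-allele frequency below `maf_min` are dropped; codes are then
#' oriented so that 2 is the panel minor allele.
#'
#' @param cfg a [sim_config()].
#' @return [geno_matrix()]; map positions are 1-based bp sorted within
#'   chromosome.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_lines < 1) stop("degenerate panel: n_lines = 0")
  set.seed(cfg$seed)
  seg_mean <- 3 * cfg$ld_segment_bp
  len <- cfg$chrom_length_bp
  breakpoints <- function() {
    nseg <- ceiling(len / seg_mean * 1.5) + 10
    br <- cumsum(stats::rexp(nseg, rate = 1 / seg_mean))
    while (br[length(br)] < len)
      br <- c(br, br[length(br)] + cumsum(stats::rexp(nseg, rate = 1 / seg_mean)))
    br
  }
  calls_list <- vector("list", cfg$n_chrom)
  map_list <- vector("list", cfg$n_chrom)
  for (c_ in seq_len(cfg$n_chrom)) {
    pos <- sort(sample.int(len, cfg$snps_per_chrom))
    m <- length(pos)
    z <- stats::rbinom(m, 1, 0.5)        # deep haplotype A; B = 1 - z
    # founder pool: mosaic of the two deep haplotypes, founder-specific
    # mixture weight spreads the panel MAF spectrum
    pi_f <- stats::runif(cfg$n_founders, 0.05, 0.95)
    founders <- matrix(0L, cfg$n_founders, m)
    for (f in seq_len(cfg$n_founders)) {
      seg <- findInterval(pos, breakpoints()) + 1L
      st <- stats::rbinom(max(seg), 1, pi_f[f])
      founders[f, ] <- (z + st[seg]) %% 2L
    }
    if (all(apply(founders, 2, function(a) length(unique(a)) == 1)))
      stop("degenerate panel: all founders identical at every site")
    # skewed founder usage (few locally common haplotypes)
    w <- stats::rgamma(cfg$n_founders, 0.4)
    w <- w / sum(w)
    calls <- matrix(0, cfg$n_lines, m)
    for (i in seq_len(cfg$n_lines)) {
      seg <- findInterval(pos, breakpoints()) + 1L
      f <- sample.int(cfg$n_founders, max(seg), replace = TRUE, prob = w)
      calls[i, ] <- 2 * founders[cbind(f[seg], seq_len(m))]
    }
    calls_list[[c_]] <- calls
    map_list[[c_]] <- data.frame(id = sprintf("S%d_%d", c_, pos),
                                 chrom = as.character(c_), pos = pos,
                                 stringsAsFactors = FALSE)
  }
  calls <- do.call(cbind, calls_list)
  map <- do.call(rbind, map_list)
  dup <- duplicated(paste(map$chrom, map$pos))
  calls <- calls[, !dup, drop = FALSE]
  map <- map[!dup, , drop = FALSE]
  rownames(calls) <- sprintf("L%03d", seq_len(cfg$n_lines))
  G <- geno_matrix(calls, map)
  G <- recode_to_minor(G)
  info <- compute_maf(G)
  keep <- !is.na(info$maf) & info$maf >= cfg$maf_min
  G <- subset_geno(G, snps = which(keep))
  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(G$calls))
    G$calls[sample.int(length(G$calls), nmiss)] <- NA
  }
  G
}

#' Simulate line genetic values with pleiotropic QTLs
#'
#' Returns X A + U where X holds the (column-centered) QTL genotype
#' codes, A the per-trait QTL effects, and U is a matrix-normal polygenic
#' background with row covariance proportional to the panel kinship
#' (scaled to unit mean diagonal) and column covariance `sigma_T_true`.
#' Columns are centered.
#'
#' @param G [geno_matrix()] for the panel (QTL columns must be complete).
#' @param cfg a [sim_config()]; uses `qtl_list`, `sigma_T_true`, `seed`.
#' @return n x T numeric matrix of genetic values, rows named by line.
#' @export
simulate_genetic_values <- function(G, cfg) {
  stopifnot(inherits(G, "geno_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(G$calls)
  T_ <- cfg$n_traits
  vals <- matrix(0, n, T_)
  if (length(cfg$qtl_list)) {
    idx <- vapply(cfg$qtl_list, function(q) {
      j <- if (is.character(q$snp)) match(q$snp, G$map$id) else as.integer(q$snp)
      if (is.na(j) || j < 1 || j > ncol(G$calls)) stop("QTL index outside SNP map")
      j
    }, integer(1))
    A <- do.call(rbind, lapply(cfg$qtl_list, function(q) as.numeric(q$effects)))
    X <- G$calls[, idx, drop = FALSE]
    if (anyNA(X)) stop("QTL genotype columns must be complete")
    vals <- vals + scale(X, scale = FALSE) %*% A
  }
  if (any(cfg$sigma_T_true != 0)) {
    Gc <- if (anyNA(G$calls)) impute_mode(G) else G
    K <- unclass(vanraden_grm(Gc))
    Ks <- K / mean(diag(K)) + diag(1e-6, n)
    Lk <- t(chol(Ks))
    ev <- eigen(cfg$sigma_T_true, symmetric = TRUE)
    Lt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), T_) %*% t(ev$vectors)
    U <- Lk %*% matrix(stats::rnorm(n * T_), n, T_) %*% Lt
    vals <- vals + U
  }
  vals <- scale(vals, scale = FALSE)
  attr(vals, "scaled:center") <- NULL
  rownames(vals) <- rownames(G$calls)
  colnames(vals) <- paste0("trait", seq_len(T_))
  vals
}

#' Experiment design specification for stage-1 trials
#'
#' Declares one of the three supported designs and its structural and
#' simulation parameters. Fixed/random declarations follow the standard
#' trial models: lattice = replicate fixed, incomplete block random
#' within replicate, check fixed; RCBD = block (replicate) fixed;
#' augmented = block random, check fixed. The line effect is random or
#' fixed per fit, not per design.
#'
#' @param kind `"lattice"`, `"rcbd"` or `"augmented"`.
#' @param n_rep replicates (lattice/RCBD; default 3).
#' @param n_block incomplete blocks per replicate (lattice, default 9) or
#'   total blocks (augmented, default 14).
#' @param block_size lines per incomplete block (lattice); default splits
#'   the panel evenly.
#' @param checks character vector of check names (lattice and augmented).
#' @param sigma_rep,sigma_block,sigma_e standard deviations of the
#'   simulated replicate, block and plot-error effects (trait units).
#' @param missing_plot_rate fraction of plots dropped at random when
#'   simulating.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(kind = c("lattice", "rcbd", "augmented"),
                        n_rep = 3, n_block = NULL, block_size = NULL,
                        checks = NULL,
                        sigma_rep = 0.3, sigma_block = 0.5, sigma_e = 0.7,
                        missing_plot_rate = 0) {
  kind <- match.arg(kind)
  if (is.null(n_block)) n_block <- switch(kind, lattice = 9, rcbd = NA, augmented = 14)
  if (is.null(checks))
    checks <- switch(kind, lattice = c("ATF13", "ATF14"), rcbd = character(),
                     augmented = c("ATF8", "ATF10"))
  structure(list(kind = kind, n_rep = n_rep, n_block = n_block,
                 block_size = block_size, checks = checks,
                 sigma_rep = sigma_rep, sigma_block = sigma_block,
                 sigma_e = sigma_e, missing_plot_rate = missing_plot_rate),
            class = "design_spec")
}

#' Simulate plot-level trial records for one trait
#'
#' Generates y = mu + rep + block + (check or line value) + error under
#' the declared design. Replicate and block effects are drawn from
#' centered normals with the design's standard deviations; checks get
#' fixed values `check_values` (default 0).
#'
#' @param values named numeric vector of true line genetic values.
#' @param design a [design_spec()].
#' @param mu overall mean.
#' @param check_values named numeric vector of check means (default all 0).
#' @param seed optional integer seed.
#' @return data.frame of class `trial_records` with columns `line`,
#'   `rep`, `block`, `is_check`, `value`.
#' @export
simulate_trial <- function(values, design, mu = 0, check_values = NULL, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(seed)) set.seed(seed)
  lines <- names(values)
  if (is.null(lines)) lines <- names(values) <- paste0("L", seq_along(values))
  n <- length(values)
  checks <- design$checks
  if (is.null(check_values)) check_values <- stats::setNames(rep(0, length(checks)), checks)
  recs <- switch(design$kind,
    lattice = {
      if (!is.null(design$block_size) &&
          n > design$n_block * design$block_size)
        stop("design capacity exceeded: too many lines for the lattice")
      bsz <- ceiling(n / design$n_block)
      out <- list()
      for (r in seq_len(design$n_rep)) {
        perm <- sample(lines)
        blk <- rep(seq_len(design$n_block), each = bsz, length.out = n)
        df <- data.frame(line = perm, rep = paste0("R", r),
                         block = paste0("B", blk), is_check = FALSE)
        if (length(checks)) {
          chk <- expand.grid(line = checks, block = paste0("B", seq_len(design$n_block)),
                             stringsAsFactors = FALSE)
          chk <- data.frame(line = chk$line, rep = paste0("R", r),
                            block = chk$block, is_check = TRUE)
          df <- rbind(df, chk)
        }
        out[[r]] <- df
      }
      do.call(rbind, out)
    },
    rcbd = {
      do.call(rbind, lapply(seq_len(design$n_rep), function(r)
        data.frame(line = lines, rep = paste0("R", r), block = paste0("R", r),
                   is_check = FALSE)))
    },
    augmented = {
      if (!is.null(design$block_size) &&
          n > design$n_block * design$block_size)
        stop("design capacity exceeded: too many lines for the augmented design")
      blk <- rep(seq_len(design$n_block), length.out = n)
      df <- data.frame(line = sample(lines), rep = "R1",
                       block = paste0("B", blk), is_check = FALSE)
      chk <- expand.grid(line = checks, block = paste0("B", seq_len(design$n_block)),
                         stringsAsFactors = FALSE)
      rbind(df, data.frame(line = chk$line, rep = "R1", block = chk$block,
                           is_check = TRUE))
    })
  rep_lev <- unique(recs$rep)
  rep_eff <- stats::setNames(stats::rnorm(length(rep_lev), 0, design$sigma_rep), rep_lev)
  blk_lev <- unique(paste(recs$rep, recs$block))
  blk_eff <- stats::setNames(stats::rnorm(length(blk_lev), 0, design$sigma_block), blk_lev)
  if (design$kind == "rcbd") blk_eff[] <- 0  # block == replicate in the RCBD
  gen <- ifelse(recs$is_check, check_values[recs$line], values[recs$line])
  recs$value <- mu + rep_eff[recs$rep] + blk_eff[paste(recs$rep, recs$block)] +
    gen + stats::rnorm(nrow(recs), 0, design$sigma_e)
  if (design$missing_plot_rate > 0) {
    keep <- stats::runif(nrow(recs)) >= design$missing_plot_rate
    recs <- recs[keep, , drop = FALSE]
  }
  rownames(recs) <- NULL
  class(recs) <- c("trial_records", "data.frame")
  recs
}

#' Simulate a complete multi-trait panel study
#'
#' Convenience wrapper: genotypes, line genetic values, and observed
#' line-level phenotypes (genetic values plus per-trait residual noise
#' with variances `sigma_R_true`, emulating adjusted means from a
#' trial). Trait missingness is applied to both value matrices.
#' Trial-level simulation is left to [simulate_trial()] per trait when
#' plot-level data are wanted.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` ([geno_matrix()]), `values` (true
#'   genetic values) and `phenotypes` (values + residual noise), both
#'   line x trait with `NA`s when `trait_missing_rate > 0`.
#' @export
simulate_panel <- function(cfg) {
  G <- simulate_genotypes(cfg)
  vals <- simulate_genetic_values(G, cfg)
  set.seed(cfg$seed + 2L)
  pheno <- vals + matrix(stats::rnorm(length(vals)),
                         nrow(vals)) %*% diag(sqrt(cfg$sigma_R_true),
                                              ncol(vals))
  dimnames(pheno) <- dimnames(vals)
  if (cfg$trait_missing_rate > 0) {
    miss <- stats::runif(length(vals)) < cfg$trait_missing_rate
    vals[miss] <- NA
    pheno[miss] <- NA
  }
  list(genotypes = G, values = vals, phenotypes = pheno)
}
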