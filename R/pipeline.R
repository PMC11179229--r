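#' Run configuration for the full association pipeline
#'
#' Collects thresholds and settings with defaults matching the analysis
#' the package implements: MAF 0.01 for panel characterization, MAF
#' 0.025 and missing rate 0.20 for the GWAS set, alpha 0.05, LD extent
#' 150 kb, suggestive threshold 4.0. `genome_length_bp` defaults to the
#' sorghum v2.1 ten-chromosome total (659.2 Mb); set it for your genome
#' — it drives the significance threshold.
#'
#' @param maf_characterization MAF cutoff for the descriptive marker set.
#' @param maf_gwas MAF cutoff for the scan set.
#' @param missing_max maximum SNP missing rate.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param ld_extent_bp average LD extent defining independent tests.
#' @param genome_length_bp total genome length in bp; `NULL` means "sum
#'   of simulated chromosome lengths" when simulating, else the sorghum
#'   default.
#' @param threshold_sug suggestive -log10(p) threshold.
#' @param structures covariance structure candidates for the null model.
#' @param ld_window_bp window for LD neighborhoods around hits.
#' @param seed integer seed for any simulation steps.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `run_config`.
#' @export
run_config <- function(maf_characterization = 0.01, maf_gwas = 0.025,
                       missing_max = 0.20, alpha = 0.05,
                       ld_extent_bp = 150e3, genome_length_bp = NULL,
                       threshold_sug = 4.0,
                       structures = c("FA1", "FA2", "UNS"),
                       ld_window_bp = 2e6, seed = 1L, out_dir = NULL) {
  stopifnot(maf_gwas >= 0, maf_gwas <= 0.5, missing_max >= 0, missing_max <= 1,
            alpha > 0, alpha < 1, ld_extent_bp > 0)
  if (!length(structures)) stop("no covariance structure candidates given")
  structure(list(maf_characterization = maf_characterization,
                 maf_gwas = maf_gwas, missing_max = missing_max,
                 alpha = alpha, ld_extent_bp = ld_extent_bp,
                 genome_length_bp = genome_length_bp,
                 threshold_sug = threshold_sug, structures = structures,
                 ld_window_bp = ld_window_bp, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML path.
#' @export
write_run_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config_yaml
#' @export
read_run_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Run the full multi-trait association pipeline
#'
#' Sequences the whole analysis: SNP filtering, mode imputation and
#' minor-allele orientation, full and leave-one-chromosome-out VanRaden
#' kinships, optional stage-1 trial analysis, trait standardization,
#' null-model fits over the candidate covariance structures with AIC
#' selection, the chromosome-specific GLS scan, classification against
#' the Bonferroni/suggestive thresholds, full-REML refits of hits with
#' Wald tests and variance explained, and LD neighborhoods around the
#' hits. Writes TSV outputs and a JSON run manifest when `cfg$out_dir`
#' is set.
#'
#' @param cfg a [run_config()].
#' @param genotypes a [geno_matrix()] (raw; filtering happens here).
#' @param traits either a line x trait matrix of adjusted means, or
#'   `NULL` when `trials` is given.
#' @param trials optional named list (one element per trait) of
#'   `list(records = <trial records>, design = <design_spec>, transform =
#'   "none"|"log")`; stage-1 models are fitted and their BLUEs used.
#' @return list of class `mtgwas_run` with elements `genotypes`
#'   (filtered, imputed), `kinship`, `loco`, `stage1` (per-trait
#'   `trial_fit`s + heritabilities, when trials given), `traits`
#'   (standardized), `null_fit`, `scan` (classified), `threshold_sig`,
#'   `refits` (per-hit [refit_snp()]), `ld` (data.frame), `manifest`.
#' @export
run_pipeline <- function(cfg, genotypes, traits = NULL, trials = NULL) {
  stopifnot(inherits(cfg, "run_config"), inherits(genotypes, "geno_matrix"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## stage 1 (optional): trial mixed models -> BLUEs + heritability
  stage1 <- NULL
  if (!is.null(trials)) {
    stage1 <- stage("stage1", {
      lapply(trials, function(tr) {
        transform <- if (is.null(tr$transform)) "none" else tr$transform
        fr <- fit_trial(tr$records, tr$design, line_as = "random",
                        transform = transform)
        ff <- fit_trial(tr$records, tr$design, line_as = "fixed",
                        transform = transform)
        list(fit_random = fr, fit_fixed = ff, h2 = cullis_h2(fr))
      })
    })
    lines <- rownames(genotypes$calls)
    traits <- sapply(stage1, function(s) s$fit_fixed$blues[lines])
    rownames(traits) <- lines
  }
  if (is.null(traits)) stop("either traits or trials must be supplied")
  traits <- as.matrix(traits)

  ## genotype filtering / imputation / kinship
  Gf <- stage("filter", filter_snps(genotypes, maf_min = cfg$maf_gwas,
                                    missing_max = cfg$missing_max))
  filter_report <- attr(Gf, "filter_report")
  Gi <- stage("impute", recode_to_minor(impute_mode(Gf)))
  K <- stage("kinship", vanraden_grm(Gi))
  loco <- stage("kinship", loco_grm_all(Gi))

  ## standardize and fit the null model
  Ys <- stage("standardize", standardize_traits(traits))
  null_fit <- stage("null", fit_null_model(Ys, K, structures = cfg$structures))

  ## thresholds
  glen <- cfg$genome_length_bp
  if (is.null(glen)) glen <- 659.2e6
  thr_sig <- bonferroni_threshold(cfg$alpha, glen, cfg$ld_extent_bp)

  ## scan, classify, refit
  scan <- stage("scan", mt_scan(Ys, Gi, null_fit, loco))
  scan <- classify_associations(scan, threshold_sig = thr_sig,
                                threshold_sug = cfg$threshold_sug)
  hits <- scan[scan$classification != "none", , drop = FALSE]
  refits <- stage("refit", {
    out <- lapply(seq_len(nrow(hits)), function(i) {
      refit_snp(Ys, Gi$calls[, hits$snp[i]], K,
                structure = null_fit$structure, null_fit = null_fit)
    })
    names(out) <- hits$snp
    out
  })

  ## LD around hits
  ld <- stage("ld", if (nrow(hits)) ld_neighborhood(Gi, hits$snp,
                                                    window_bp = cfg$ld_window_bp)
              else data.frame())

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtgwas")),
    seed = cfg$seed,
    thresholds = list(maf_gwas = cfg$maf_gwas, missing_max = cfg$missing_max,
                      alpha = cfg$alpha, ld_extent_bp = cfg$ld_extent_bp,
                      genome_length_bp = glen, threshold_sig = thr_sig,
                      threshold_sug = cfg$threshold_sug),
    structures = cfg$structures,
    selected_structure = null_fit$structure,
    counts = list(snps_in = unname(filter_report[["n_in"]]),
                  snps_scanned = nrow(scan),
                  significant = sum(scan$classification == "significant"),
                  suggestive = sum(scan$classification == "suggestive"),
                  lines = nrow(traits), traits = ncol(traits)))

  run <- structure(list(genotypes = Gi, kinship = K, loco = loco,
                        stage1 = stage1, traits = Ys, null_fit = null_fit,
                        scan = scan, threshold_sig = thr_sig,
                        refits = refits, ld = ld, manifest = manifest,
                        config = cfg),
                   class = "mtgwas_run")
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

# TSV/JSON artifacts for a completed run.
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  utils::write.table(as.data.frame(run$scan), fp("scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(run$refits)) {
    eff <- do.call(rbind, lapply(names(run$refits), function(s)
      cbind(snp = s, run$refits[[s]]$effects)))
    utils::write.table(eff, fp("snp_effects.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (nrow(run$ld))
    utils::write.table(run$ld, fp("ld_pairs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(run$stage1)) {
    h2 <- data.frame(trait = names(run$stage1),
                     H2 = vapply(run$stage1, function(s) s$h2$H2, numeric(1)),
                     sigma2_g = vapply(run$stage1, function(s) s$h2$sigma2_g,
                                       numeric(1)))
    utils::write.table(h2, fp("heritability.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_kinship_tsv(run$kinship, fp("kinship.tsv"))
  jsonlite::write_json(run$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mtgwas_run <- function(x, ...) {
  m <- x$manifest
  cat("mtgwas_run:", m$counts$lines, "lines,", m$counts$snps_scanned,
      "SNPs scanned,", m$counts$traits, "traits\n")
  cat("  selected structure:", m$selected_structure,
      "| significance threshold:", sprintf("%.2f", m$thresholds$threshold_sig), "\n")
  cat("  significant:", m$counts$significant,
      "| suggestive:", m$counts$suggestive, "\n")
  invisible(x)
}

#' Summarize a completed pipeline run
#'
#' Per-chromosome counts of significant/suggestive SNPs, the
#' favorable-allele tally (minor vs major across hit x trait
#' combinations with a Wald p below 0.05), per-trait mean variance
#' explained over hits, and the selected covariance structure.
#'
#' @param run an [run_pipeline()] result.
#' @param path optional TSV path for the per-chromosome table.
#' @return list of class `mtgwas_report`: `per_chromosome` (data.frame),
#'   `favorable` (named counts), `mean_pct_var` (per trait),
#'   `structure`.
#' @export
report_summary <- function(run, path = NULL) {
  stopifnot(inherits(run, "mtgwas_run"))
  scan <- run$scan
  chroms <- unique(run$genotypes$map$chrom)
  per_chrom <- data.frame(
    chrom = chroms,
    significant = vapply(chroms, function(ch)
      sum(scan$chrom == ch & scan$classification == "significant"), numeric(1)),
    suggestive = vapply(chroms, function(ch)
      sum(scan$chrom == ch & scan$classification == "suggestive"), numeric(1)),
    row.names = NULL)
  fav <- c(minor = 0, major = 0)
  pct <- NULL
  if (length(run$refits)) {
    eff <- do.call(rbind, lapply(run$refits, `[[`, "effects"))
    sig_eff <- eff[eff$wald_p < 0.05, , drop = FALSE]
    fav <- c(minor = sum(sig_eff$favorable_allele == "minor"),
             major = sum(sig_eff$favorable_allele == "major"))
    pct <- tapply(eff$pct_var_explained, eff$trait, mean)
  }
  out <- structure(list(per_chromosome = per_chrom, favorable = fav,
                        mean_pct_var = pct,
                        structure = run$null_fit$structure),
                   class = "mtgwas_report")
  if (!is.null(path))
    utils::write.table(per_chrom, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' @export
print.mtgwas_report <- function(x, ...) {
  cat("Association summary (structure:", x$structure, ")\n")
  cat("  hits per chromosome:\n")
  print(x$per_chromosome, row.names = FALSE)
  cat("  favorable allele (hit x trait, Wald p < 0.05): minor =",
      x$favorable["minor"], ", major =", x$favorable["major"], "\n")
  if (!is.null(x$mean_pct_var)) {
    cat("  mean % variance explained per trait over hits:\n")
    print(round(x$mean_pct_var, 2))
  }
  invisible(x)
}
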