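#' Genome-wide significance threshold from LD extent
#'
#' Bonferroni threshold on the -log10(p) scale with the effective number
#' of independent tests taken as genome length divided by the average
#' LD extent: -log10(alpha / (genome_length_bp / ld_extent_bp)).
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param genome_length_bp total genome length in bp. Default 659.2 Mb,
#'   the ten-chromosome total of the sorghum v2.1 assembly; override for
#'   other genomes.
#' @param ld_extent_bp average LD extent in bp (default 150 kb).
#' @return threshold on the -log10(p) scale (full precision; display
#'   rounding is the caller's business).
#' @examples
#' round(bonferroni_threshold(), 2)  # 4.94
#' @export
bonferroni_threshold <- function(alpha = 0.05, genome_length_bp = 659.2e6,
                                 ld_extent_bp = 150e3) {
  stopifnot(alpha > 0, genome_length_bp > 0, ld_extent_bp > 0)
  -log10(alpha / (genome_length_bp / ld_extent_bp))
}

#' Chromosome-specific multi-trait GLS association scan
#'
#' Step 2: for every SNP, the trait-specific marker effects alpha_t and
#' per-trait intercepts are estimated by generalized least squares under
#' the frozen null covariance V_c = K_c (x) Sigma_T + I (x) Sigma_R,
#' where K_c is the leave-one-chromosome-out kinship for the SNP's
#' chromosome. The joint Wald statistic alpha' Var(alpha)^-1 alpha is
#' referred to a chi-square with T degrees of freedom.
#'
#' @param Y line x trait matrix of standardized adjusted means.
#' @param G [geno_matrix()] of the scan SNPs (pre-filtered, imputed by
#'   default upstream). Lines must align with `Y` rows.
#' @param null_fit an [fit_null_model()] result (or any list with
#'   `Sigma_T` and `sigma_R`), supplying the frozen covariance.
#' @param loco named list of [loco_grm()] kinships, one per chromosome
#'   present in `G` (see [loco_grm_all()]).
#' @return Object of classes `mt_scan` and `data.frame`: one row per
#'   tested SNP with `snp`, `chrom`, `pos`, `maf`, per-trait effects
#'   (`eff_<trait>`), `wald`, `df` and `minus_log10_p`. Monomorphic or
#'   numerically singular SNPs are dropped with a message; their ids are
#'   kept in `attr(, "skipped")`.
#' @export
mt_scan <- function(Y, G, null_fit, loco) {
  Y <- as.matrix(Y)
  stopifnot(inherits(G, "geno_matrix"))
  n <- nrow(Y); T_ <- ncol(Y)
  if (nrow(G$calls) != n) stop("genotypes and traits must cover the same lines")
  Sigma_T <- null_fit$Sigma_T
  sigma_R <- null_fit$sigma_R
  trait_names <- colnames(Y)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(T_))
  chroms <- unique(G$map$chrom)
  missing_k <- setdiff(chroms, names(loco))
  if (length(missing_k)) stop("no LOCO kinship for chromosome(s): ",
                              paste(missing_k, collapse = ", "))
  complete <- !anyNA(Y)
  res <- vector("list", length(chroms))
  skipped <- character()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    jj <- which(G$map$chrom == ch)
    Xs <- G$calls[, jj, drop = FALSE]
    keep_snp <- apply(Xs, 2, function(x) stats::var(x, na.rm = TRUE) > 0) &
      colSums(!is.na(Xs)) == n
    skipped <- c(skipped, G$map$id[jj][!keep_snp])
    jj <- jj[keep_snp]
    if (!length(jj)) next
    Xs <- G$calls[, jj, drop = FALSE]
    Kc <- unclass(loco[[ch]])
    if (complete) {
      e <- eigen(Kc, symmetric = TRUE)
      U <- e$vectors
      d <- pmax(e$values, 0)
      Yt <- crossprod(U, Y)
      one_t <- crossprod(U, rep(1, n))[, 1]
      Xt <- crossprod(U, Xs)
      sd_ <- simdiag_cov(Sigma_T, sigma_R)
      Z <- Yt %*% sd_$Q
      W <- 1 / (outer(d, sd_$lambda) + 1)
      m <- length(jj)
      atil <- matrix(NA_real_, T_, m)
      vtil <- matrix(NA_real_, T_, m)
      for (t in seq_len(T_)) {
        w <- W[, t]
        a11 <- sum(w * one_t^2)
        a12 <- colSums(Xt * (w * one_t))
        a22 <- colSums(Xt^2 * w)
        b1 <- sum(w * one_t * Z[, t])
        b2 <- colSums(Xt * (w * Z[, t]))
        det <- a11 * a22 - a12^2
        atil[t, ] <- (a11 * b2 - a12 * b1) / det
        vtil[t, ] <- a11 / det
      }
      ok <- colSums(!is.finite(atil)) == 0 & colSums(vtil <= 0) == 0
      wald <- colSums(atil^2 / vtil)
      eff <- t(solve(t(sd_$Q)) %*% atil)     # m x T, original trait basis
    } else {
      m <- length(jj)
      eff <- matrix(NA_real_, m, T_)
      wald <- numeric(m)
      ok <- rep(TRUE, m)
      for (s in seq_len(m)) {
        gl <- tryCatch(
          kron_gls_dense(Sigma_T, sigma_R, Y, cbind(1, Xs[, s]), Kc),
          error = function(e) NULL)
        if (is.null(gl)) { ok[s] <- FALSE; next }
        a <- gl$coef[2, ]
        Va <- gl$vcov[[2]]
        wi <- tryCatch(solve(Va, a), error = function(e) NULL)
        if (is.null(wi)) { ok[s] <- FALSE; next }
        eff[s, ] <- a
        wald[s] <- sum(a * wi)
      }
    }
    skipped <- c(skipped, G$map$id[jj][!ok])
    mlp <- -stats::pchisq(wald, df = T_, lower.tail = FALSE, log.p = TRUE) / log(10)
    p2 <- colMeans(Xs) / 2
    out <- data.frame(snp = G$map$id[jj], chrom = ch, pos = G$map$pos[jj],
                      maf = pmin(p2, 1 - p2), stringsAsFactors = FALSE)
    colnames(eff) <- paste0("eff_", trait_names)
    out <- cbind(out, eff, wald = wald, df = T_, minus_log10_p = mlp)
    res[[ci]] <- out[ok, , drop = FALSE]
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  if (length(skipped)) message(length(skipped), " SNP(s) skipped (monomorphic/singular)")
  structure(out, class = c("mt_scan", "data.frame"),
            skipped = skipped, traits = trait_names)
}

#' @export
print.mt_scan <- function(x, ...) {
  cat("mt_scan:", nrow(x), "SNPs on", length(unique(x$chrom)), "chromosome(s),",
      length(attr(x, "traits")), "traits\n")
  df <- x
  class(df) <- "data.frame"
  if (nrow(df)) {
    top <- utils::head(df[order(-df$minus_log10_p),
                          c("snp", "chrom", "pos", "maf", "minus_log10_p")], 5)
    cat("  top associations:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Manhattan plot of a multi-trait scan
#'
#' @param x an [mt_scan()] result.
#' @param threshold_sig,threshold_sug horizontal reference lines on the
#'   -log10(p) scale (defaults 4.94 and 4.0).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mt_scan <- function(x, threshold_sig = 4.94, threshold_sug = 4.0, ...) {
  chrom <- factor(x$chrom, levels = unique(x$chrom))
  offs <- c(0, cumsum(tapply(x$pos, chrom, max)))
  gx <- x$pos + offs[as.integer(chrom)]
  cols <- c("grey30", "steelblue")[1 + as.integer(chrom) %% 2]
  graphics::plot(gx, x$minus_log10_p, pch = 20, col = cols,
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = threshold_sig, col = "blue")
  graphics::abline(h = threshold_sug, col = "red")
  invisible(x)
}

#' Classify scan records against significance thresholds
#'
#' Significant means -log10(p) >= `threshold_sig`; suggestive means
#' `threshold_sug` <= -log10(p) < `threshold_sig`; everything else is
#' `"none"`. The boundary value sits in the significant class.
#'
#' @param records an [mt_scan()] result (or data.frame with
#'   `minus_log10_p`).
#' @param threshold_sig,threshold_sug thresholds on the -log10(p) scale.
#' @return the records with a `classification` factor column appended;
#'   counts are attached as `attr(, "counts")`.
#' @export
classify_associations <- function(records, threshold_sig = 4.94,
                                  threshold_sug = 4.0) {
  stopifnot(threshold_sug > 0, threshold_sug < threshold_sig)
  cls <- factor(rep("none", nrow(records)),
                levels = c("significant", "suggestive", "none"))
  if (nrow(records)) {
    mlp <- records$minus_log10_p
    cls[mlp >= threshold_sig] <- "significant"
    cls[mlp >= threshold_sug & mlp < threshold_sig] <- "suggestive"
  }
  records$classification <- cls
  attr(records, "counts") <- table(cls)
  records
}

#' Refit one SNP under full REML and test its effects (Wald)
#'
#' Step 3: for a SNP classified significant or suggestive in the scan,
#' the full multi-trait model is re-fitted by REML with the SNP as a
#' trait-specific fixed effect and the *full-genome* kinship, so that all
#' variance components are re-estimated conditional on the fitted SNP.
#' Per-trait Wald tests, normal-approximation 95% confidence intervals
#' (effect +/- 1.96 SE) and favorable-allele calls are reported; the
#' favorable allele is the minor allele when the estimated effect under
#' the \{0,2\} minor-dosage coding is positive.
#'
#' @param Y line x trait matrix of standardized adjusted means.
#' @param snp numeric genotype vector in \{0,2\} aligned to `Y` rows.
#' @param K_full full-genome [vanraden_grm()] kinship.
#' @param structure covariance structure label (usually the one selected
#'   by [fit_null_model()]).
#' @param null_fit optional `mt_null_fit`, used for variance-explained
#'   denominators and as a warm start.
#' @param conf_mult multiplier for the confidence interval (1.96 = 95%).
#' @return Object of class `snp_refit`: data.frame `effects` with one
#'   row per trait (`effect`, `se`, `ci_low`, `ci_high`, `wald_p`,
#'   `favorable_allele`, `pct_var_explained`), plus `Sigma_T`, `sigma_R`,
#'   `loglik`, `p` (allele frequency of the code-2 allele) and
#'   `gls_fallback` (TRUE when the REML refit failed to converge and the
#'   reported effects are the step-2 GLS estimates).
#' @export
refit_snp <- function(Y, snp, K_full, structure = "FA2", null_fit = NULL,
                      conf_mult = 1.96) {
  Y <- as.matrix(Y)
  snp <- as.numeric(snp)
  stopifnot(length(snp) == nrow(Y))
  if (anyNA(snp)) stop("refit requires complete (imputed) SNP calls")
  T_ <- ncol(Y)
  trait_names <- colnames(Y)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(T_))
  X <- cbind(1, snp)
  starts <- NULL
  if (!is.null(null_fit))
    starts <- list(struct_start(null_fit$Sigma_T + diag(1e-4, T_),
                                pmax(null_fit$sigma_R, 1e-4), structure))
  fit <- tryCatch(kron_reml_fit(Y, K_full, structure, X = X, starts = starts),
                  error = function(e) NULL)
  fallback <- is.null(fit)
  if (fallback) {
    if (is.null(null_fit)) stop("REML refit failed and no null fit for GLS fallback")
    warning("REML refit did not converge; falling back to GLS under the null covariance")
    gl <- if (anyNA(Y)) kron_gls_dense(null_fit$Sigma_T, null_fit$sigma_R, Y, X,
                                       unclass(K_full))
          else {
            e <- eigen(unclass(K_full), symmetric = TRUE)
            kron_gls_coefs(null_fit$Sigma_T, null_fit$sigma_R,
                           crossprod(e$vectors, Y), crossprod(e$vectors, X),
                           pmax(e$values, 0))
          }
    Sigma_T <- null_fit$Sigma_T; sigma_R <- null_fit$sigma_R
    loglik <- NA_real_
    coef <- gl$coef; vcv <- gl$vcov
  } else {
    Sigma_T <- fit$Sigma_T; sigma_R <- fit$sigma_R
    loglik <- fit$loglik
    coef <- fit$coef; vcv <- fit$coef_vcov
  }
  alpha <- coef[2, ]
  se <- sqrt(pmax(diag(vcv[[2]]), 0))
  wald_p <- stats::pchisq((alpha / se)^2, df = 1, lower.tail = FALSE)
  p2 <- mean(snp) / 2
  vp <- if (!is.null(null_fit)) diag(null_fit$Sigma_T) + null_fit$sigma_R
        else diag(Sigma_T) + sigma_R
  pct <- vapply(seq_len(T_), function(t)
    variance_explained(alpha[t], p2, vp[t])$percent, numeric(1))
  eff <- data.frame(trait = trait_names, effect = alpha, se = se,
                    ci_low = alpha - conf_mult * se,
                    ci_high = alpha + conf_mult * se,
                    wald_p = wald_p,
                    favorable_allele = ifelse(alpha > 0, "minor", "major"),
                    pct_var_explained = pct, row.names = NULL)
  structure(list(effects = eff, Sigma_T = Sigma_T, sigma_R = sigma_R,
                 mu = coef[1, ], loglik = loglik, p = p2,
                 gls_fallback = fallback),
            class = "snp_refit")
}

#' @export
print.snp_refit <- function(x, ...) {
  cat("snp_refit (full REML", if (x$gls_fallback) "-- GLS fallback" else "",
      "), code-2 allele frequency", sprintf("%.3f", x$p), "\n")
  print(transform(x$effects,
                  effect = round(effect, 4), se = round(se, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4),
                  wald_p = signif(wald_p, 3),
                  pct_var_explained = round(pct_var_explained, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Phenotypic variance explained by a marker
#'
#' V_m = alpha^2 Var(x) with Var(x) = 4 p (1 - p) for the inbred \{0,2\}
#' coding, expressed as a percentage of the null-model phenotypic
#' variance V_pnull (per trait: diag(Sigma_T) + Sigma_R from step 1).
#'
#' @param alpha_hat estimated per-allele-code effect for one trait.
#' @param p frequency of the allele coded 2.
#' @param V_pnull phenotypic variance of that trait under the null model.
#' @return list with `V_m`, `V_pnull` and `percent`.
#' @export
variance_explained <- function(alpha_hat, p, V_pnull) {
  stopifnot(p >= 0, p <= 1, V_pnull > 0)
  V_m <- alpha_hat^2 * 4 * p * (1 - p)
  list(V_m = V_m, V_pnull = V_pnull, percent = 100 * V_m / V_pnull)
}
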