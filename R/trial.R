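#' Fit the stage-1 mixed model for one trait / one trial
#'
#' Fits the single-trait model matching the experiment design:
#' \describe{
#'   \item{lattice}{y = mu + rep (fixed) + block-within-rep (random) +
#'     check (fixed) + line + error}
#'   \item{rcbd}{y = mu + block (fixed) + line + error}
#'   \item{augmented}{y = mu + block (random) + check (fixed) + line + error}
#' }
#' The line effect is `random` to estimate the genetic variance (REML)
#' and produce BLUPs with prediction error variances, or `fixed` to
#' produce adjusted line means (BLUEs) for downstream association
#' analysis. Models with random terms are fitted by REML with
#' [lme4::lmer()]; the fixed-line RCBD reduces to ordinary least squares.
#' The full prediction-error-variance matrix of the line BLUPs is
#' recovered from the mixed-model equations at the REML estimates.
#'
#' @param records data.frame with columns `line`, `rep`, `block`,
#'   `is_check` (logical), `value` (see [simulate_trial()] for the
#'   layout). Missing plots may simply be absent.
#' @param design a [design_spec()]; only `kind` matters for fitting.
#' @param line_as `"random"` or `"fixed"`.
#' @param transform `"none"` or `"log"` (natural log applied to `value`
#'   before fitting; used for right-skewed 3D architecture traits such as
#'   convex hull and median root counts).
#' @return Object of class `trial_fit`: list with `varcomp` (named
#'   vector: `sigma2_g` if line random, `sigma2_block` if the design has
#'   random blocks, `sigma2_e`), `blues` (named vector, line fixed),
#'   `blups` and `pev` (named vector / matrix, line random), `loglik`
#'   (REML), `fixef`, `design`, `line_as`, `n_lines`.
#' @examples
#' d <- design_spec("rcbd", sigma_e = 0.5)
#' recs <- simulate_trial(stats::setNames(stats::rnorm(30), paste0("L", 1:30)),
#'                        d, seed = 7)
#' fit <- fit_trial(recs, d, line_as = "random")
#' cullis_h2(fit)
#' @export
fit_trial <- function(records, design, line_as = c("random", "fixed"),
                      transform = c("none", "log")) {
  line_as <- match.arg(line_as)
  transform <- match.arg(transform)
  stopifnot(inherits(design, "design_spec"))
  need <- c("line", "rep", "block", "is_check", "value")
  if (!all(need %in% names(records))) stop("records must have columns: ",
                                           paste(need, collapse = ", "))
  df <- as.data.frame(records)
  df <- df[!is.na(df$value), , drop = FALSE]
  df$line <- factor(df$line)
  df$rep <- factor(df$rep)
  df$blk <- factor(paste(df$rep, df$block))
  df$is_check <- as.logical(df$is_check)
  test_lines <- sort(unique(as.character(df$line[!df$is_check])))
  if (length(test_lines) < 2) stop("need at least 2 test lines")
  if (transform == "log") {
    if (any(df$value <= 0)) stop("log transform requires positive values")
    df$value <- log(df$value)
  }
  # fixed check structure: one common level for test lines, one per check
  df$checkf <- factor(ifelse(df$is_check, as.character(df$line), ".test"),
                      levels = c(".test", sort(unique(as.character(df$line[df$is_check])))))
  df$tst <- as.numeric(!df$is_check)
  df$entry <- df$line
  has_checks <- any(df$is_check)
  check_confounding(df, design)

  if (line_as == "random") {
    form <- switch(design$kind,
      lattice = value ~ rep + (1 | blk) + (0 + tst | line),
      rcbd = value ~ rep + (0 + tst | line),
      augmented = value ~ (1 | blk) + (0 + tst | line))
    if (has_checks) form <- stats::update(form, . ~ . + checkf)
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                  check.nobs.vs.nRE = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma2_e <- vc$vcov[vc$grp == "Residual"]
    sigma2_g <- vc$vcov[vc$grp == "line"]
    sigma2_b <- if (any(vc$grp == "blk")) vc$vcov[vc$grp == "blk"] else NA_real_
    mme <- line_pev_mme(df, design, sigma2_g = sigma2_g,
                        sigma2_b = sigma2_b, sigma2_e = sigma2_e,
                        has_checks = has_checks)
    out <- list(varcomp = c(sigma2_g = sigma2_g, sigma2_block = sigma2_b,
                            sigma2_e = sigma2_e),
                blues = NULL, blups = mme$blup, pev = mme$pev,
                loglik = as.numeric(stats::logLik(fit)),
                fixef = lme4::fixef(fit), model = fit)
  } else {
    if (design$kind == "rcbd") {
      fit <- stats::lm(value ~ 0 + entry + rep, data = df)
      cf <- stats::coef(fit)
      rep_eff <- c(0, cf[grep("^rep", names(cf))])
      blues <- cf[paste0("entry", test_lines)] + mean(rep_eff)
      sigma2_e <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
      vcmp <- c(sigma2_e = sigma2_e)
    } else {
      form <- switch(design$kind,
        lattice = value ~ 0 + entry + rep + (1 | blk),
        augmented = value ~ 0 + entry + (1 | blk))
      fit <- lme4::lmer(form, data = df, REML = TRUE,
                        control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                    check.nobs.vs.nRE = "ignore"))
      cf <- lme4::fixef(fit)
      rep_eff <- if (design$kind == "lattice") c(0, cf[grep("^rep", names(cf))]) else 0
      blues <- cf[paste0("entry", test_lines)] + mean(rep_eff)
      vc <- as.data.frame(lme4::VarCorr(fit))
      vcmp <- c(sigma2_block = vc$vcov[vc$grp == "blk"],
                sigma2_e = vc$vcov[vc$grp == "Residual"])
    }
    names(blues) <- test_lines
    out <- list(varcomp = vcmp, blues = blues, blups = NULL, pev = NULL,
                loglik = as.numeric(stats::logLik(fit)),
                fixef = if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit),
                model = fit)
  }
  out$design <- design$kind
  out$line_as <- line_as
  out$transform <- transform
  out$n_lines <- length(test_lines)
  class(out) <- "trial_fit"
  out
}

# Refuse designs where line effects cannot be separated from blocks:
# every block holding exactly one test line (and no replication) leaves
# line and block aliased.
check_confounding <- function(df, design) {
  tl <- df[!df$is_check, , drop = FALSE]
  tab <- table(tl$line, tl$blk)
  per_line_blocks <- rowSums(tab > 0)
  per_block_lines <- colSums(tab > 0)
  if (design$kind != "augmented" &&
      all(per_line_blocks <= 1) && all(per_block_lines <= 1))
    stop("non-identifiable design: line effects are confounded with blocks ",
         "(each block holds a single unreplicated line)")
  invisible(TRUE)
}

# Mixed-model equations at fixed variance components; returns line BLUPs
# and the full prediction-error-variance matrix (the inverse-coefficient
# block for the line effects).
line_pev_mme <- function(df, design, sigma2_g, sigma2_b, sigma2_e, has_checks) {
  test_lines <- sort(unique(as.character(df$line[!df$is_check])))
  X <- switch(design$kind,
    lattice = stats::model.matrix(~rep, df),
    rcbd = stats::model.matrix(~rep, df),
    augmented = stats::model.matrix(~1, df))
  if (has_checks) X <- cbind(X, stats::model.matrix(~0 + checkf, df)[, -1, drop = FALSE])
  Zl <- outer(as.character(df$line), test_lines, "==") * df$tst
  colnames(Zl) <- test_lines
  use_blk <- design$kind %in% c("lattice", "augmented") && !is.na(sigma2_b)
  if (use_blk) {
    blocks <- sort(unique(as.character(df$blk)))
    Zb <- outer(as.character(df$blk), blocks, "==") * 1
    Z <- cbind(Zb, Zl)
    ginv <- c(rep(1 / max(sigma2_b, 1e-10), length(blocks)),
              rep(1 / max(sigma2_g, 1e-10), length(test_lines)))
  } else {
    Z <- Zl
    ginv <- rep(1 / max(sigma2_g, 1e-10), length(test_lines))
  }
  y <- df$value
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(ginv) * sigma2_e))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Cinv <- solve(C / sigma2_e)
  sol <- Cinv %*% (rhs / sigma2_e)
  p <- ncol(X)
  li <- (p + ncol(Z) - length(test_lines) + 1):(p + ncol(Z))
  blup <- stats::setNames(as.numeric(sol[li]), test_lines)
  pev <- Cinv[li, li, drop = FALSE]
  dimnames(pev) <- list(test_lines, test_lines)
  list(blup = blup, pev = pev)
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("trial_fit:", x$design, "design,", x$n_lines, "lines, line",
      x$line_as, if (x$transform == "log") "(log scale)" else "", "\n")
  cat("  variance components:\n")
  vc <- x$varcomp[!is.na(x$varcomp)]
  for (nm in names(vc)) cat(sprintf("    %-13s %.4f\n", nm, vc[nm]))
  cat(sprintf("  REML log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.trial_fit <- function(object, ...) {
  if (object$line_as == "fixed") object$blues else object$blups
}

#' @export
logLik.trial_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik", df = NA)
}

#' Cullis generalized heritability
#'
#' H2 = 1 - vbar / (2 sigma_g^2), where vbar is the average variance of a
#' difference between two line BLUPs, computed exactly over all line
#' pairs from the prediction-error-variance matrix:
#' Var(BLUP_i - BLUP_j) = PEV_ii + PEV_jj - 2 PEV_ij. Valid for
#' unbalanced designs where the classical entry-mean formula is not; on a
#' balanced RCBD it reduces to sigma_g^2 / (sigma_g^2 + sigma_e^2 / r).
#'
#' @param fit a [fit_trial()] result with `line_as = "random"`.
#' @return list of class `heritability`: `H2` (clipped to \[0, 1\]),
#'   `vbar_blup`, `sigma2_g`.
#' @export
cullis_h2 <- function(fit) {
  stopifnot(inherits(fit, "trial_fit"))
  if (is.null(fit$pev)) stop("Cullis H2 needs a line-random fit with PEVs")
  sigma2_g <- fit$varcomp[["sigma2_g"]]
  n <- nrow(fit$pev)
  d <- diag(fit$pev)
  # mean over unordered pairs i<j of PEV_ii + PEV_jj - 2 PEV_ij
  vbar <- ((n - 1) * sum(d) - (sum(fit$pev) - sum(d))) / (n * (n - 1) / 2)
  H2 <- if (sigma2_g <= 1e-12) 0 else min(max(1 - vbar / (2 * sigma2_g), 0), 1)
  structure(list(H2 = H2, vbar_blup = vbar, sigma2_g = sigma2_g),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Cullis generalized heritability H2 = %.4f (vbar = %.4f, sigma2_g = %.4f)\n",
              x$H2, x$vbar_blup, x$sigma2_g))
  invisible(x)
}

#' Standardize a line x trait matrix of adjusted means
#'
#' Centers and scales every column to zero mean and unit sample variance
#' (denominator n - 1) over its observed entries; missing entries stay
#' missing. Association scans assume this scaling, so that marker effects
#' are in standardized-trait units.
#'
#' @param blues numeric matrix, lines x traits; `NA` allowed.
#' @return matrix of the same shape.
#' @export
standardize_traits <- function(blues) {
  blues <- as.matrix(blues)
  out <- apply(blues, 2, function(x) {
    obs <- !is.na(x)
    if (sum(obs) < 2) stop("need >= 2 observed values per trait")
    s <- stats::sd(x[obs])
    if (s < 1e-12) stop("zero variance trait cannot be standardized")
    (x - mean(x[obs])) / s
  })
  dimnames(out) <- dimnames(blues)
  out
}
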