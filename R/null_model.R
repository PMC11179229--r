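#' Fit the no-marker multi-trait mixed model
#'
#' Step 1 of the multi-trait association analysis: fits
#' y_it = mu_t + G_it + e_it with genetic covariance
#' Sigma = Sigma_G (x) Sigma_T and diagonal residual Sigma_R (no residual
#' covariance between traits), by REML. The between-trait genetic
#' covariance Sigma_T is parameterized as factor-analytic order 1 or 2,
#' or unstructured (Cholesky). When several structures are requested, the
#' minimum-AIC fit is selected (AIC = -2 loglik + 2k, counting covariance
#' parameters only; all candidates share the same fixed effects, so REML
#' AICs are comparable).
#'
#' With complete data the likelihood is evaluated in O(nT) per iteration
#' through an eigen-rotation of K and a simultaneous diagonalization of
#' (Sigma_T, Sigma_R); with missing trait cells the exact observed-cell
#' restricted likelihood of the dense covariance is used.
#'
#' To keep the nested families consistent, FA2 is additionally started
#' from the FA1 solution and UNS from the best factor-analytic solution;
#' each structure keeps its best converged start.
#'
#' @param Y line x trait matrix of standardized adjusted means (rows
#'   aligned to `K`; `NA` = trait not scored for that line).
#' @param K full-genome [vanraden_grm()] kinship.
#' @param structures character subset of `c("FA1", "FA2", "UNS")`.
#' @return Object of class `mt_null_fit` for the selected structure:
#'   `Sigma_T`, `sigma_R`, `mu` (per-trait intercepts), `loglik`, `k`,
#'   `AIC`, `structure`, plus `candidates` (data.frame of all structures
#'   tried) and `fits` (the per-structure fit objects).
#' @examples
#' \donttest{
#' cfg <- sim_config(n_lines = 120, n_chrom = 3, snps_per_chrom = 80,
#'                   n_traits = 3, seed = 4)
#' pan <- simulate_panel(cfg)
#' K <- vanraden_grm(impute_mode(pan$genotypes))
#' fit <- fit_null_model(standardize_traits(pan$values), K,
#'                       structures = c("FA1", "UNS"))
#' print(fit)
#' }
#' @export
fit_null_model <- function(Y, K, structures = c("FA1", "FA2", "UNS")) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("multi-trait null model needs >= 2 traits")
  if (!length(structures)) stop("no covariance structure candidates given")
  structures <- match.arg(structures, c("FA1", "FA2", "UNS"), several.ok = TRUE)
  if (nrow(Y) != nrow(K)) stop("Y rows must align with kinship")
  fits <- list()
  extra_start <- list()
  for (s in c("FA1", "FA2", "UNS")) {
    if (!s %in% structures) next
    starts <- NULL
    if (!is.null(extra_start[[s]])) {
      S0 <- extra_start[[s]]
      starts <- list(struct_start(S0$Sigma_T + diag(1e-4, ncol(Y)), S0$sigma_R, s))
      # also keep the default data-driven start
      Sc <- stats::cov(Y, use = "pairwise.complete.obs"); Sc[is.na(Sc)] <- 0
      vy <- pmax(diag(Sc), 1e-4)
      starts <- c(starts, list(struct_start((Sc + t(Sc)) / 4 + diag(1e-4, ncol(Y)),
                                            0.5 * vy, s)))
    }
    f <- kron_reml_fit(Y, K, s, starts = starts)
    fits[[s]] <- f
    if (s == "FA1") extra_start[["FA2"]] <- f
    if (s %in% c("FA1", "FA2")) {
      cur <- extra_start[["UNS"]]
      if (is.null(cur) || f$loglik > cur$loglik) extra_start[["UNS"]] <- f
    }
  }
  select_structure(fits)
}

#' Select the minimum-AIC covariance structure
#'
#' @param fits named list of per-structure fits on identical data (as
#'   produced internally by [fit_null_model()]). Ties are broken to the
#'   structure with fewest covariance parameters.
#' @return `mt_null_fit` object for the winning structure.
#' @export
select_structure <- function(fits) {
  if (!length(fits)) stop("no fits to select among")
  Ts <- vapply(fits, function(f) f$T, numeric(1))
  if (length(unique(Ts)) > 1) stop("fits are on different trait sets")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) stop("fits are on different data")
  aic <- vapply(fits, function(f) -2 * f$loglik + 2 * f$k, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(aic, k)
  best <- fits[[ord[1]]]
  out <- list(structure = best$structure, Sigma_T = best$Sigma_T,
              sigma_R = best$sigma_R, mu = drop(best$coef[1, ]),
              loglik = best$loglik, k = best$k,
              AIC = aic[[ord[1]]],
              candidates = data.frame(structure = names(fits),
                                      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                                      k = k, AIC = aic, row.names = NULL),
              fits = fits, n = best$n, T = best$T)
  class(out) <- "mt_null_fit"
  out
}

#' @export
print.mt_null_fit <- function(x, ...) {
  cat("Multi-trait null model (no markers), Kronecker covariance\n")
  cat("  selected structure:", x$structure, "| n =", x$n, "lines, T =", x$T, "traits\n")
  cat(sprintf("  REML loglik = %.3f, k = %d, AIC = %.2f\n", x$loglik, x$k, x$AIC))
  if (nrow(x$candidates) > 1) {
    cat("  candidates:\n")
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.mt_null_fit <- function(object, ...) {
  gcor <- stats::cov2cor(object$Sigma_T + diag(1e-12, object$T))
  structure(list(fit = object, genetic_correlation = gcor,
                 V_pnull = diag(object$Sigma_T) + object$sigma_R),
            class = "summary.mt_null_fit")
}

#' @export
print.summary.mt_null_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-trait phenotypic variance under the null (diag Sigma_T + Sigma_R):\n")
  print(round(x$V_pnull, 4))
  invisible(x)
}

#' @export
logLik.mt_null_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik", df = object$k)
}

#' @export
AIC.mt_null_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$k
}

#' Serialize a null-model fit to JSON
#'
#' @param fit an `mt_null_fit`.
#' @param path output path.
#' @export
write_null_fit_json <- function(fit, path) {
  obj <- list(structure = fit$structure, Sigma_T = unname(fit$Sigma_T),
              sigma_R = unname(fit$sigma_R), mu = unname(fit$mu),
              loglik = fit$loglik, k = fit$k, AIC = fit$AIC)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
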