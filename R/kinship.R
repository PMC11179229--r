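#' VanRaden genomic relationship matrix
#'
#' Computes K = W W' / (2 * sum_j p_j (1 - p_j)) where W is the
#' column-centered call matrix (calls - 2 p_j) and p_j the frequency of
#' the allele coded 2, computed from the (imputed) calls. On a fully
#' inbred panel the expected diagonal is 1 + F = 2.
#'
#' @param G a [geno_matrix()] without missing calls (run [impute_mode()]
#'   first) and with at least two polymorphic SNPs.
#' @param exclude_chrom optional chromosome label; SNPs on that chromosome
#'   are left out of the computation (see [loco_grm()]).
#' @return An object of class `kinship_matrix`: the n x n symmetric
#'   relationship matrix with line ids as dimnames, attributes
#'   `excluded_chrom` and `n_snps`.
#' @export
vanraden_grm <- function(G, exclude_chrom = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (anyNA(G$calls)) stop("kinship requires imputed (complete) genotypes")
  keep <- rep(TRUE, ncol(G$calls))
  if (!is.null(exclude_chrom)) keep <- G$map$chrom != exclude_chrom
  calls <- G$calls[, keep, drop = FALSE]
  p <- colMeans(calls) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 1) stop("no polymorphic SNPs available for kinship")
  calls <- calls[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(calls, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  structure(K, class = c("kinship_matrix", "matrix"),
            excluded_chrom = if (is.null(exclude_chrom)) NA_character_ else exclude_chrom,
            n_snps = ncol(calls), sum2pq = denom)
}

#' Leave-one-chromosome-out kinship
#'
#' VanRaden relationship computed from all SNPs *not* on the given
#' chromosome. Used during the association scan so that the kinship
#' correction never absorbs the signal of the chromosome being tested
#' (avoids proximal contamination / over-correction).
#'
#' @param G a complete [geno_matrix()] spanning more than one chromosome.
#' @param chromosome chromosome label to exclude.
#' @return `kinship_matrix` with attribute `excluded_chrom` set.
#' @export
loco_grm <- function(G, chromosome) {
  stopifnot(inherits(G, "geno_matrix"))
  chroms <- unique(G$map$chrom)
  if (length(chroms) < 2) stop("leave-one-chromosome-out needs >= 2 chromosomes")
  if (!chromosome %in% chroms) stop("unknown chromosome: ", chromosome)
  vanraden_grm(G, exclude_chrom = chromosome)
}

#' All leave-one-chromosome-out kinships
#'
#' @param G a complete [geno_matrix()].
#' @return Named list of `kinship_matrix`, one per chromosome label.
#' @export
loco_grm_all <- function(G) {
  chroms <- unique(G$map$chrom)
  out <- lapply(chroms, function(ch) loco_grm(G, ch))
  names(out) <- chroms
  out
}

#' @export
print.kinship_matrix <- function(x, ...) {
  ex <- attr(x, "excluded_chrom")
  cat("kinship_matrix:", nrow(x), "lines,", attr(x, "n_snps"), "SNPs",
      if (!is.na(ex)) paste0("(chromosome ", ex, " excluded)") else "(full genome)", "\n")
  cat(sprintf("  mean diagonal: %.3f\n", mean(diag(x))))
  invisible(x)
}

#' Write / read a kinship matrix as square TSV
#'
#' @param K `kinship_matrix` (or plain matrix with dimnames).
#' @param path output file.
#' @export
write_kinship_tsv <- function(K, path) {
  df <- data.frame(line = rownames(K), as.data.frame(unclass(K)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @param path file written by [write_kinship_tsv()].
#' @export
read_kinship_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  storage.mode(K) <- "double"
  structure(K, class = c("kinship_matrix", "matrix"),
            excluded_chrom = NA_character_, n_snps = NA_integer_)
}
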