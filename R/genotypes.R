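#' Genotype matrix for an inbred panel
#'
#' Container for biallelic SNP genotypes of fully inbred lines, coded 0
#' (homozygous major allele), 2 (homozygous minor allele) or `NA` (missing).
#' Heterozygote codes are not representable: the panel is assumed fully
#' inbred, as in diversity panels of selfing crops.
#'
#' @param calls numeric matrix, lines x SNPs, values in \{0, 2, NA\}.
#'   Row names are taken as line ids when `line_ids` is missing.
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per SNP column of `calls`. Chromosome labels are strings.
#' @param line_ids character vector of unique line identifiers.
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (matrix with line ids as rownames and SNP ids as colnames) and `map`.
#'   The map is sorted by (chrom, pos) and the columns of `calls` follow it.
#' @examples
#' g <- geno_matrix(rbind(c(0, 2), c(2, 0)),
#'                  data.frame(id = c("s1", "s2"), chrom = "1", pos = c(100, 200)),
#'                  line_ids = c("L1", "L2"))
#' compute_maf(g)
#' @export
geno_matrix <- function(calls, map, line_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(calls)))
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("line ids must be unique")
  if (nrow(map) != ncol(calls)) stop("map rows must match SNP columns")
  bad <- !(calls %in% c(0, 2) | is.na(calls))
  if (any(bad)) stop("genotype calls must be 0, 2 or NA (no heterozygote codes)")
  map <- data.frame(id = as.character(map$id), chrom = as.character(map$chrom),
                    pos = as.integer(map$pos), stringsAsFactors = FALSE)
  if (anyDuplicated(map$id)) stop("SNP ids must be unique")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(line_ids, map$id)
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "lines x", ncol(x$calls), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  mr <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Per-SNP allele frequency and missingness
#'
#' Allele frequencies are computed over non-missing calls only:
#' p = mean(calls)/2 for the allele coded 2, and maf = min(p, 1 - p).
#'
#' @param G a [geno_matrix()].
#' @return data.frame with one row per SNP: `id`, `chrom`, `pos`, `p`
#'   (frequency of the allele coded 2), `maf`, `missing_rate`. SNPs with
#'   all calls missing get `NA` maf.
#' @export
compute_maf <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  n_obs <- colSums(!is.na(G$calls))
  p <- colMeans(G$calls, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  data.frame(G$map,
             p = unname(p),
             maf = unname(pmin(p, 1 - p)),
             missing_rate = unname(1 - n_obs / nrow(G$calls)),
             stringsAsFactors = FALSE)
}

#' Filter SNPs on minor-allele frequency and missing rate
#'
#' Removes SNPs with maf < `maf_min` (strict: a SNP at exactly the
#' threshold is kept) or missing rate > `missing_max`, plus SNPs whose
#' calls are entirely missing. Column order is preserved.
#'
#' @param G a [geno_matrix()].
#' @param maf_min minimum minor-allele frequency to keep, in \[0, 0.5\].
#'   The GWAS default is 0.025; 0.01 is the panel-characterization value.
#' @param missing_max maximum tolerated missing rate (default 0.20).
#' @return Filtered `geno_matrix` with an attribute `filter_report`
#'   (counts removed by each rule).
#' @export
filter_snps <- function(G, maf_min = 0.025, missing_max = 0.20) {
  stopifnot(inherits(G, "geno_matrix"), maf_min >= 0, maf_min <= 0.5)
  info <- compute_maf(G)
  all_missing <- is.na(info$maf)
  low_maf <- !all_missing & info$maf < maf_min
  too_missing <- info$missing_rate > missing_max
  keep <- !(all_missing | low_maf | too_missing)
  if (!any(keep)) warning("no SNPs pass the filters")
  out <- structure(list(calls = G$calls[, keep, drop = FALSE],
                        map = G$map[keep, , drop = FALSE]),
                   class = "geno_matrix")
  rownames(out$map) <- NULL
  attr(out, "filter_report") <- c(n_in = nrow(info), n_kept = sum(keep),
                                  n_low_maf = sum(low_maf),
                                  n_missing = sum(too_missing & !low_maf),
                                  n_all_missing = sum(all_missing))
  out
}

#' Mode imputation of missing genotype calls
#'
#' Each missing call is replaced by the SNP's most frequent non-missing
#' code; ties are broken to the major-allele homozygote (code 0).
#' Deterministic single-pass substitute for nearest-neighbour imputation;
#' adequate because imputation quality is not what downstream inference
#' leans on (filtered SNPs have at most 20% missing calls).
#'
#' @param G a [geno_matrix()].
#' @return `geno_matrix` without missing calls.
#' @export
impute_mode <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  calls <- G$calls
  n_obs <- colSums(!is.na(calls))
  if (any(n_obs == 0)) stop("cannot impute: SNP(s) with all calls missing")
  miss_cols <- which(colSums(is.na(calls)) > 0)
  for (j in miss_cols) {
    x <- calls[, j]
    n2 <- sum(x == 2, na.rm = TRUE)
    n0 <- sum(x == 0, na.rm = TRUE)
    calls[is.na(x), j] <- if (n2 > n0) 2 else 0
  }
  structure(list(calls = calls, map = G$map), class = "geno_matrix")
}

#' Recode calls so that 2 is the minor-allele homozygote
#'
#' The minor allele is defined per SNP within the analyzed panel; columns
#' with frequency of the code-2 allele above 0.5 are flipped (x -> 2 - x).
#' Ties (p = 0.5) keep the existing orientation, i.e. the second-listed
#' (ALT) allele remains coded 2.
#'
#' @param G a [geno_matrix()].
#' @return `geno_matrix` in which every SNP's code 2 is its minor allele.
#' @export
recode_to_minor <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  p <- colMeans(G$calls, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  calls <- G$calls
  calls[, flip] <- 2 - calls[, flip]
  structure(list(calls = calls, map = G$map), class = "geno_matrix")
}

#' Subset a genotype matrix
#'
#' @param G a [geno_matrix()].
#' @param lines line ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @return `geno_matrix` restricted to the requested lines/SNPs.
#' @export
subset_geno <- function(G, lines = NULL, snps = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  calls <- G$calls
  map <- G$map
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, map$id) else snps
    if (anyNA(j)) stop("unknown SNP id(s)")
    calls <- calls[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  if (!is.null(lines)) calls <- calls[lines, , drop = FALSE]
  geno_matrix(calls, map, line_ids = rownames(calls))
}
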