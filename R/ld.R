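#' Squared genotypic correlation between two SNPs
#'
#' LD measured as the squared Pearson correlation of the \{0,2\} genotype
#' codes over pairwise-complete lines. On a fully inbred panel the
#' genotype table coincides with the haplotype table, so this is the
#' classical r-squared.
#'
#' @param g1,g2 numeric genotype vectors in \{0,2,NA\} over the same lines.
#' @return r-squared in \[0,1\]; `NA` with a warning if either vector is
#'   constant after pairwise-complete filtering.
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  x <- g1[ok]; y <- g2[ok]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant genotype vector: r2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Fisher exact p-value for association between two SNPs
#'
#' Two-sided Fisher exact test on the 2 x 2 table of homozygote classes
#' (code 0 vs 2) across the two SNPs, over pairwise-complete lines. The
#' two-sided p-value sums hypergeometric probabilities of all tables at
#' most as probable as the observed one.
#'
#' @inheritParams ld_r2
#' @return p-value in (0, 1\]; `NA` with a warning on a constant vector.
#' @export
ld_fisher_p <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  x <- factor(g1[ok], levels = c(0, 2))
  y <- factor(g2[ok], levels = c(0, 2))
  tab <- table(x, y)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("constant genotype vector: Fisher p undefined")
    return(NA_real_)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' LD neighborhoods around associated SNPs
#'
#' Pairs every focal (associated) SNP with all SNPs within `window_bp`
#' up- and downstream on the same chromosome (closed interval), plus all
#' focal-focal pairs sharing a chromosome regardless of distance, and
#' computes r-squared and the Fisher exact p for each pair.
#'
#' @param G a [geno_matrix()].
#' @param focal_snps character vector of SNP ids present in the map.
#' @param window_bp half-width of the physical window (default 2,000 kb).
#' @return data.frame with `snp_a` (focal), `snp_b`, `chrom`, `dist_bp`,
#'   `r2`, `fisher_p`; one row per unordered pair, focal-focal pairs
#'   included once.
#' @export
ld_neighborhood <- function(G, focal_snps, window_bp = 2e6) {
  stopifnot(inherits(G, "geno_matrix"))
  idx <- match(focal_snps, G$map$id)
  if (anyNA(idx)) stop("focal SNP(s) not in map: ",
                       paste(focal_snps[is.na(idx)], collapse = ", "))
  map <- G$map
  pairs <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    same_chr <- which(map$chrom == map$chrom[i])
    near <- same_chr[abs(map$pos[same_chr] - map$pos[i]) <= window_bp]
    other_focal <- intersect(same_chr, idx)
    cand <- setdiff(union(near, other_focal), i)
    for (j in cand) {
      key <- paste(sort(c(i, j)), collapse = "_")
      both_focal <- j %in% idx
      # emit each unordered pair once; focal listed as snp_a
      if (both_focal && i > j) next
      pairs[[key]] <- c(i = i, j = j)
    }
  }
  if (!length(pairs))
    return(data.frame(snp_a = character(), snp_b = character(),
                      chrom = character(), dist_bp = integer(),
                      r2 = numeric(), fisher_p = numeric()))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    i <- pr["i"]; j <- pr["j"]
    suppressWarnings(data.frame(
      snp_a = map$id[i], snp_b = map$id[j], chrom = map$chrom[i],
      dist_bp = abs(map$pos[j] - map$pos[i]),
      r2 = ld_r2(G$calls[, i], G$calls[, j]),
      fisher_p = ld_fisher_p(G$calls[, i], G$calls[, j]),
      stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}
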