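#' Read genotypes from a VCF file
#'
#' Reads biallelic SNPs from a VCF (plain or gzipped) into the \{0,2\}
#' inbred coding via the ALT-allele dosage: `0/0` (or `0|0`, haploid `0`)
#' maps to 0, `1/1` to 2, `./.` to missing. Heterozygous calls are
#' rejected with an error, or set missing when `het = "missing"` — an
#' inbred panel should not contain them.
#'
#' @param path VCF file.
#' @param het `"error"` (default) or `"missing"`.
#' @return [geno_matrix()] (lines = VCF samples). The code-2 allele is
#'   the VCF ALT allele; run [recode_to_minor()] to orient codes to the
#'   panel minor allele.
#' @export
read_geno_vcf <- function(path, het = c("error", "missing")) {
  het <- match.arg(het)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) stop("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0")] <- 0
  code[gt %in% c("1/1", "1")] <- 2
  is_het <- gt %in% c("0/1", "1/0")
  if (any(is_het)) {
    if (het == "error") stop("heterozygous calls found in an inbred panel (",
                             sum(is_het), "); use het = \"missing\" to mask them")
    code[is_het] <- NA_real_
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0("S", fix[noid, "CHROM"], "_", fix[noid, "POS"])
  geno_matrix(t(code),
              data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         stringsAsFactors = FALSE))
}

#' Write genotypes as a minimal VCF
#'
#' Emits homozygous calls `0/0` / `1/1` (`./.` for missing) with the
#' code-2 allele as ALT. Alleles are written as placeholder A/T since the
#' \{0,2\} coding carries no nucleotide identity.
#'
#' @param G a [geno_matrix()].
#' @param path output path (plain text `.vcf`).
#' @export
write_geno_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  gt <- matrix("./.", ncol(G$calls), nrow(G$calls))
  tc <- t(G$calls)
  gt[tc == 0] <- "0/0"
  gt[tc == 2] <- "1/1"
  body <- cbind(G$map$chrom, G$map$pos, G$map$id, "A", "T", ".", "PASS", ".",
                "GT", gt)
  lines <- c("##fileformat=VCFv4.2",
             "##source=mtgwas",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G$calls)), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genotypes as a TSV matrix with a sidecar map
#'
#' The matrix file holds lines x SNPs \{0,2,NA\} with a `line` id column;
#' the map file holds `id`, `chrom`, `pos`.
#'
#' @param G a [geno_matrix()].
#' @param path matrix TSV path.
#' @param map_path map TSV path (default `<path>.map`).
#' @export
write_geno_tsv <- function(G, path, map_path = paste0(path, ".map")) {
  stopifnot(inherits(G, "geno_matrix"))
  df <- data.frame(line = rownames(G$calls), G$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path, map_path = paste0(path, ".map")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(calls) <- "double"
  rownames(calls) <- df[[1]]
  geno_matrix(calls[, map$id, drop = FALSE], map)
}

#' Read / write plot-level trial records as CSV
#'
#' Columns: `line`, `rep`, `block`, `is_check`, `value` (and optionally
#' `trait`).
#'
#' @param records trial records data.frame.
#' @param path CSV path.
#' @export
write_trial_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "rep", "block", "is_check", "value")
  if (!all(need %in% names(df))) stop("trial CSV must have columns: ",
                                      paste(need, collapse = ", "))
  df$is_check <- as.logical(df$is_check)
  class(df) <- c("trial_records", "data.frame")
  df
}
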