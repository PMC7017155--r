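#' Read a VCF file into a raw variant set
#'
#' Loads all records of a VCF (plain or bgzipped) with their site quality
#' and per-sample genotype calls. Missing calls (`./.` or `.`) are flagged
#' as `NA`, never dropped; multi-allelic records are kept and marked so the
#' downstream biallelic filter can count them.
#'
#' @param path path to a VCF file; GT genotypes and QUAL are required.
#' @return an object of class `raw_variants`: a list with
#'   \itemize{
#'     \item `samples` character vector of sample identifiers,
#'     \item `variants` data frame (`chrom`, `pos`, `id`, `ref`, `alt`,
#'           `qual`, `n_alt`, `biallelic`, `missing_frac`, `maf`),
#'     \item `gt` integer matrix (variants x samples) of alt-allele dosages
#'           0/1/2 with `NA` for missing calls; for non-biallelic records the
#'           dosage refers to the first alternate allele.
#'   }
#' @seealso [filter_variants()], [code_and_impute()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    stop("VCF file does not exist: ", path)
  }
  validate_vcf_structure(path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(v@fix) == 0L) {
    stop("VCF '", path, "' contains no variant records")
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF '", path, "' has no genotype (GT) columns")
  }
  samples <- colnames(gt_raw)[-1L]
  gt_str <- vcfR::extract.gt(v, element = "GT")
  gt <- gt_to_dosage(gt_str)
  alt <- fix$ALT
  n_alt <- ifelse(is.na(alt) | alt == ".", 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = if (is.null(fix$ID)) rep(NA_character_, nrow(fix)) else fix$ID,
    ref = fix$REF,
    alt = alt,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    n_alt = as.integer(n_alt),
    stringsAsFactors = FALSE
  )
  variants$biallelic <- variants$n_alt == 1L
  variants$missing_frac <- rowMeans(is.na(gt))
  variants$maf <- marker_maf(gt)
  out <- list(samples = samples, variants = variants, gt = gt)
  class(out) <- "raw_variants"
  validate_raw_variants(out)
  out
}

## light structural validation before the C-level parser sees the file:
## required because malformed headers are otherwise fatal, and so that
## parse errors can name the offending line
validate_vcf_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) stop("VCF '", path, "' is empty")
  if (!startsWith(lines[1L], "##fileformat=VCF")) {
    stop("parse error in '", path, "' at line 1: missing ##fileformat")
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) {
    stop("parse error in '", path, "': #CHROM header line missing")
  }
  n_fields <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  if (n_fields < 10L) {
    stop("parse error in '", path, "' at line ", hdr,
         ": header has no sample columns")
  }
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    stop("VCF '", path, "' contains no variant records")
  }
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nf != n_fields)
  if (length(bad)) {
    stop("parse error in '", path, "' at line ", hdr + bad[1L],
         ": expected ", n_fields, " fields, found ", nf[bad[1L]])
  }
  invisible(TRUE)
}

## "0/0" -> 0, "0/1"/"1/0"/"0|1" -> 1, "1/1" -> 2, "./." -> NA.
## Alleles > 1 (extra ALTs) count toward the first-alt dosage only when
## equal to 1; such records are removed by the biallelic filter anyway.
gt_to_dosage <- function(gt_str) {
  a1 <- substr(gt_str, 1L, 1L)
  a2 <- substr(gt_str, 3L, 3L)
  haploid <- !is.na(gt_str) & nchar(gt_str) == 1L
  a2[haploid] <- a1[haploid]
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt_str)] <- NA
  storage.mode(d) <- "integer"
  dim(d) <- dim(gt_str)
  dimnames(d) <- dimnames(gt_str)
  d
}

## MAF over non-missing calls only (the only defensible denominator before
## imputation); monomorphic markers report 0.
marker_maf <- function(gt) {
  p <- rowMeans(gt, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

validate_raw_variants <- function(x) {
  stopifnot(
    is.character(x$samples), length(x$samples) >= 1L,
    nrow(x$variants) == nrow(x$gt),
    ncol(x$gt) == length(x$samples),
    all(x$variants$pos >= 0, na.rm = TRUE),
    all(nzchar(x$variants$ref), na.rm = TRUE)
  )
  invisible(x)
}

#' @export
print.raw_variants <- function(x, ...) {
  cat("raw variant set:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  cat("  biallelic:", sum(x$variants$biallelic),
      " mean missing:", signif(mean(x$variants$missing_frac), 3), "\n")
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat("  filtered: removed",
        paste(sprintf("%s=%d", names(rep$removed), unlist(rep$removed)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply marker quality filters
#'
#' Filters a raw variant set on the four GBS quality criteria: biallelic
#' sites only, site quality, per-marker missing-call fraction, and minor
#' allele frequency. All thresholds are inclusive (`maf >= maf_min`,
#' `qual >= qual_min`, `missing <= max_missing`). Filters are applied in the
#' order biallelic, quality, missingness, MAF, with MAF computed over
#' non-missing calls; per-step removal counts are attached as a
#' `filter_report` attribute (retrievable with [filter_report()]).
#'
#' @param raw a `raw_variants` object from [read_vcf()].
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @param qual_min minimum site quality (Phred-scaled).
#' @param max_missing maximum fraction of missing calls per marker, in
#'   `[0, 1]`.
#' @param biallelic_only drop sites with more than one alternate allele.
#' @return the filtered `raw_variants` object. Filtering an already
#'   filtered set removes nothing (idempotence).
#' @export
filter_variants <- function(raw, maf_min = 0.05, qual_min = 40,
                            max_missing = 0.20, biallelic_only = TRUE) {
  stopifnot(inherits(raw, "raw_variants"),
            maf_min >= 0, maf_min <= 0.5,
            max_missing >= 0, max_missing <= 1)
  v <- raw$variants
  keep <- rep(TRUE, nrow(v))
  removed <- list()

  fail_bi <- if (biallelic_only) !v$biallelic else rep(FALSE, nrow(v))
  removed$biallelic <- sum(keep & fail_bi)
  keep <- keep & !fail_bi

  fail_q <- is.na(v$qual) | v$qual < qual_min
  removed$qual <- sum(keep & fail_q)
  keep <- keep & !fail_q

  fail_na <- v$missing_frac > max_missing
  removed$missing <- sum(keep & fail_na)
  keep <- keep & !fail_na

  fail_maf <- is.na(v$maf) | v$maf < maf_min
  removed$maf <- sum(keep & fail_maf)
  keep <- keep & !fail_maf

  if (!any(keep)) {
    stop("all ", nrow(v), " variants removed by filters (",
         paste(sprintf("%s: %d", names(removed), unlist(removed)),
               collapse = ", "), ")")
  }
  out <- raw
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$gt <- raw$gt[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(
    n_input = nrow(v),
    n_retained = sum(keep),
    removed = removed,
    thresholds = list(maf_min = maf_min, qual_min = qual_min,
                      max_missing = max_missing,
                      biallelic_only = biallelic_only)
  )
  out
}

#' Retrieve the filter report of a filtered variant set
#'
#' @param x a `raw_variants` object returned by [filter_variants()].
#' @return a list with input/retained counts and per-criterion removals,
#'   or `NULL` if `x` was never filtered.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Code genotype calls as dosages and mean-impute missing calls
#'
#' Calls are coded as counts of the alternate allele (0/1/2); missing
#' entries are replaced by the per-marker mean dosage over observed calls,
#' so imputed values may be fractional. Input must already be filtered to
#' biallelic sites.
#'
#' @param raw a filtered `raw_variants` object.
#' @return an object of class `dosage_matrix`: list with `dosage`
#'   (samples x markers numeric matrix, no missing entries, values in
#'   `[0, 2]`), `samples`, `markers` and `maf` (per-marker minor allele
#'   frequency over observed calls).
#' @export
code_and_impute <- function(raw) {
  stopifnot(inherits(raw, "raw_variants"))
  if (!all(raw$variants$biallelic)) {
    stop("input contains non-biallelic variants; run filter_variants() first")
  }
  gt <- raw$gt
  n_obs <- rowSums(!is.na(gt))
  if (any(n_obs == 0L)) {
    stop("cannot impute marker(s) with zero observed calls: ",
         paste(utils::head(which(n_obs == 0L), 5L), collapse = ", "))
  }
  mu <- rowMeans(gt, na.rm = TRUE)
  d <- gt
  idx <- which(is.na(d))
  if (length(idx)) {
    d[idx] <- mu[(idx - 1L) %% nrow(d) + 1L]
  }
  markers <- marker_ids(raw$variants)
  dosage <- t(d)
  dimnames(dosage) <- list(raw$samples, markers)
  out <- list(dosage = dosage, samples = raw$samples, markers = markers,
              maf = stats::setNames(marker_maf(gt), markers))
  class(out) <- "dosage_matrix"
  out
}

marker_ids <- function(v) {
  ids <- v$id
  fallback <- paste0(v$chrom, ":", v$pos)
  ifelse(is.na(ids) | ids == "." | ids == "", fallback, ids)
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "markers; MAF in [", signif(min(x$maf), 3), ",",
      signif(max(x$maf), 3), "]\n")
  invisible(x)
}

#' Write a dosage matrix or kinship matrix as tab-delimited text
#'
#' @param x a `dosage_matrix`, or a square kinship matrix with sample
#'   dimnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "dosage_matrix")) x$dosage else x
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path file path.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
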