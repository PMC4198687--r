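# File formats: counts tables and genotype matrices as TSV, minimal
# biallelic VCF ingestion (GT only, via vcfR), and stable result
# serialization.

#' Read a per-variant allele-counts table
#'
#' TSV with a header naming at least `variant_id`, `x1`, `n1`, `x2`, `n2`
#' (optional annotation columns such as `chrom`, `pos` are carried through).
#' Counts are validated row by row; violations are reported with the row and
#' column.
#'
#' @param path Path to a tab-separated file.
#' @return An [allele_counts()]-compatible `data.frame`, rows in file order.
#' @export
read_counts_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "x1", "n1", "x2", "n2")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("counts table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("x1", "n1", "x2", "n2")) {
    v <- tab[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                   as.numeric(v) != round(as.numeric(v)) |
                   as.numeric(v) < 0)
    if (length(bad))
      stop("non-integer or negative count in column '", col, "', row ",
           bad[1], call. = FALSE)
    tab[[col]] <- as.numeric(v)
  }
  bad <- which(tab$x1 > tab$n1 | tab$x2 > tab$n2)
  if (length(bad))
    stop("minor count exceeds total count at row ", bad[1], call. = FALSE)
  bad <- which(tab$n1 <= 0 | tab$n2 <= 0)
  if (length(bad))
    stop("non-positive total allele count at row ", bad[1], call. = FALSE)
  if (anyDuplicated(tab$variant_id))
    warning("duplicate variant_id values in ", path)
  class(tab) <- c("allele_counts", "data.frame")
  tab
}

#' Write a per-variant allele-counts table
#'
#' @param counts An [allele_counts()] object or compatible data.frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  counts <- as_counts_df(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

gt_to_dosage <- function(gt) {
  # "0/0", "0|1", "./." etc. -> ALT-allele dosage
  gt <- sub(":.*", "", gt)
  a <- substr(gt, 1, 1)
  b <- substr(gt, 3, 3)
  ifelse(a %in% c("0", "1") & b %in% c("0", "1"),
         (a == "1") + (b == "1"), NA_real_)
}

#' Read a genotype matrix
#'
#' Two formats:
#' \describe{
#'   \item{`"tsv"`}{first column `subject_id`, second column `cohort`, one
#'     column per variant with codes 0/1/2/NA.}
#'   \item{`"vcf"`}{a minimal biallelic VCF; only the GT field is used,
#'     multi-allelic records are skipped with a warning. `cohort` must be
#'     supplied (one label per VCF sample, in sample order).}
#' }
#' Codes are folded so that 1 counts copies of the allele that is minor in
#' controls.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`.
#' @param cohort Per-subject cohort labels (required for VCF, ignored for
#'   TSV where the file carries them).
#' @param control_cohorts,case_cohort Passed to [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), cohort = NULL,
                           control_cohorts = NULL, case_cohort = "case") {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (ncol(tab) < 3 || names(tab)[1] != "subject_id" ||
        names(tab)[2] != "cohort")
      stop("genotype TSV must start with columns subject_id, cohort",
           call. = FALSE)
    codes <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (!all(codes %in% c(0, 1, 2) | is.na(codes)))
      stop("unknown genotype code (expected 0/1/2/NA)", call. = FALSE)
    rownames(codes) <- tab$subject_id
    cohort <- tab$cohort
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt) | is.na(alt)
    if (any(multi))
      warning(sum(multi), " multi-allelic record(s) skipped")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    ids <- fix[!multi, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[!multi, "CHROM"], ":", fix[!multi, "POS"])[noid]
    # elementwise GT -> dosage, reshaped to subjects x variants
    codes <- matrix(gt_to_dosage(t(gt)), nrow = ncol(gt),
                    dimnames = list(colnames(gt), ids))
    if (is.null(cohort))
      stop("cohort labels are required when reading VCF", call. = FALSE)
    if (length(cohort) != nrow(codes))
      stop("cohort must have one label per VCF sample", call. = FALSE)
  }
  g <- genotype_matrix(codes, cohort, control_cohorts = control_cohorts,
                       case_cohort = case_cohort)
  fold_to_control_minor(g)
}

# Recode variants whose coded allele is the major allele in controls.
fold_to_control_minor <- function(g) {
  ctrl <- g$cohort %in% g$control_cohorts
  if (!any(ctrl)) return(g)
  cc <- g$codes[ctrl, , drop = FALSE]
  f <- colSums(cc, na.rm = TRUE) / (2 * colSums(!is.na(cc)))
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) g$codes[, flip] <- 2 - g$codes[, flip]
  g
}

#' Write a genotype matrix as TSV
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(subject_id = rownames(g$codes), cohort = g$cohort,
                    g$codes, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format p-values for output
#'
#' Six significant digits; scientific notation below 1e-4; values below the
#' double floor are emitted as `"<1e-300"` rather than truncated to 0.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  out <- character(length(p))
  out[is.na(p)] <- "NA"
  tiny <- !is.na(p) & p < 1e-300
  out[tiny] <- "<1e-300"
  sci <- !is.na(p) & !tiny & p < 1e-4
  out[sci] <- formatC(p[sci], format = "e", digits = 5)
  rest <- !is.na(p) & !tiny & !sci
  out[rest] <- formatC(p[rest], format = "fg", digits = 6, flag = "#")
  out
}

#' Write genome-scan results as TSV
#'
#' Stable column order, numeric columns at 6 significant digits, p-value
#' columns through [format_pvalue()]; byte-for-byte reproducible given the
#' same input and configuration.
#'
#' @param results Output of [genome_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(results, path) {
  out <- results
  pcols <- grep("^P_", names(out), value = TRUE)
  for (col in pcols) out[[col]] <- format_pvalue(out[[col]])
  numcols <- names(out)[vapply(out, is.numeric, logical(1))]
  numcols <- setdiff(numcols, c("x1", "n1", "x2", "n2"))
  for (col in numcols) out[[col]] <- formatC(signif(out[[col]], 6),
                                             format = "g", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a QC report as TSV
#'
#' @param report Output of [snp_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- report
  for (col in c("hwe_p_controls", "cohort_het_p"))
    out[[col]] <- format_pvalue(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
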