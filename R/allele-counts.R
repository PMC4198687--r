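# Allele-count containers. Everything downstream works on the allele scale:
# each diploid subject contributes two alleles, so a cohort of m subjects has
# n = 2m alleles.

#' Case/control allele counts for biallelic variants
#'
#' Constructs a validated table of minor-allele counts (`x1`, `x2`) and total
#' allele counts (`n1`, `n2`) for the case and control groups. This is the
#' unit of data every estimator and test in the package consumes. All
#' arguments are recycled to a common length, so a whole scan's worth of
#' variants can be held in one object.
#'
#' @param x1 Minor-allele count(s) in cases (non-negative integers).
#' @param n1 Total allele count(s) in cases (positive integers; `2 *` the
#'   number of genotyped case subjects).
#' @param x2 Minor-allele count(s) in controls.
#' @param n2 Total allele count(s) in controls.
#' @param variant_id Optional variant labels; defaults to `v1, v2, ...`.
#'
#' @return A `data.frame` of class `"allele_counts"` with columns
#'   `variant_id`, `x1`, `n1`, `x2`, `n2`.
#'
#' @examples
#' allele_counts(x1 = 235, n1 = 3852, x2 = 165, n2 = 5876)
#' @export
allele_counts <- function(x1, n1, x2, n2, variant_id = NULL) {
  len <- max(length(x1), length(n1), length(x2), length(n2))
  x1 <- rep_len(as.numeric(x1), len)
  n1 <- rep_len(as.numeric(n1), len)
  x2 <- rep_len(as.numeric(x2), len)
  n2 <- rep_len(as.numeric(n2), len)
  if (is.null(variant_id)) variant_id <- paste0("v", seq_len(len))
  variant_id <- rep_len(as.character(variant_id), len)
  validate_counts(x1, n1, x2, n2)
  structure(
    data.frame(variant_id = variant_id, x1 = x1, n1 = n1, x2 = x2, n2 = n2,
               stringsAsFactors = FALSE),
    class = c("allele_counts", "data.frame")
  )
}

validate_counts <- function(x1, n1, x2, n2) {
  num_ok <- function(v) all(is.finite(v)) && all(v == round(v))
  if (!num_ok(x1) || !num_ok(n1) || !num_ok(x2) || !num_ok(n2))
    stop("allele counts must be finite integers", call. = FALSE)
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("total allele counts n1, n2 must be positive", call. = FALSE)
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2))
    stop("minor-allele counts must satisfy 0 <= x <= n", call. = FALSE)
  invisible(TRUE)
}

# Accept either an allele_counts object or any data.frame carrying the four
# count columns; returns a plain validated data.frame.
as_counts_df <- function(counts) {
  if (is.data.frame(counts)) {
    need <- c("x1", "n1", "x2", "n2")
    if (!all(need %in% names(counts)))
      stop("counts must have columns x1, n1, x2, n2", call. = FALSE)
    validate_counts(counts$x1, counts$n1, counts$x2, counts$n2)
    return(counts)
  }
  stop("counts must be an allele_counts object or a data.frame", call. = FALSE)
}

#' Case and control minor-allele frequencies
#'
#' Maximum-likelihood MAF estimates \eqn{\hat p_1 = x_1/n_1} (cases) and
#' \eqn{\hat p_2 = x_2/n_2} (controls).
#'
#' @param counts An [allele_counts()] object (or data.frame with columns
#'   `x1`, `n1`, `x2`, `n2`).
#' @return A `data.frame` with columns `p1` (case MAF) and `p2` (control MAF).
#' @examples
#' case_control_maf(allele_counts(235, 3852, 165, 5876))
#' @export
case_control_maf <- function(counts) {
  counts <- as_counts_df(counts)
  data.frame(p1 = counts$x1 / counts$n1, p2 = counts$x2 / counts$n2)
}

#' Collapse a genotype matrix to case/control allele counts
#'
#' Sums minor-allele codes over case and control subjects (missing genotypes
#' excluded; each non-missing subject contributes two alleles to the total).
#'
#' @param g A [genotype_matrix()].
#' @return An [allele_counts()] object, one row per variant.
#' @export
allele_counts_from_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  case <- g$cohort == g$case_cohort
  ctrl <- g$cohort %in% g$control_cohorts
  codes_case <- g$codes[case, , drop = FALSE]
  codes_ctrl <- g$codes[ctrl, , drop = FALSE]
  x1 <- colSums(codes_case, na.rm = TRUE)
  n1 <- 2 * colSums(!is.na(codes_case))
  x2 <- colSums(codes_ctrl, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(codes_ctrl))
  keep <- n1 > 0 & n2 > 0
  if (!all(keep))
    warning(sum(!keep), " variant(s) with no called alleles in one group dropped")
  allele_counts(x1[keep], n1[keep], x2[keep], n2[keep],
                variant_id = colnames(g$codes)[keep])
}
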