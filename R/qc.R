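# SNP-level quality control: the four classic microarray exclusion criteria
# (control MAF, call rate, HWE exact test in controls, allele-frequency
# heterogeneity between the two control sub-cohorts).

#' Genotype matrix container
#'
#' Subjects x variants minor-allele dosage codes (0/1/2, `NA` for missing)
#' plus a per-subject cohort label. Controls may be split into sub-cohorts
#' (e.g. two population control panels); the heterogeneity QC criterion
#' compares allele frequencies between them.
#'
#' @param codes Integer matrix, subjects in rows, variants in columns, values
#'   in \{0, 1, 2, NA\}. Row and column names label subjects and variants.
#' @param cohort Character/factor of length `nrow(codes)`; the label in
#'   `case_cohort` marks cases, all other labels are control sub-cohorts
#'   unless `control_cohorts` narrows them.
#' @param control_cohorts Labels treated as controls; default every label
#'   other than `case_cohort`.
#' @param case_cohort Label marking cases, default `"case"`.
#' @return A list of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(codes, cohort, control_cohorts = NULL,
                            case_cohort = "case") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (!all(codes %in% c(0, 1, 2) | is.na(codes)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  cohort <- as.character(cohort)
  if (length(cohort) != nrow(codes))
    stop("cohort must have one label per subject (row)", call. = FALSE)
  if (is.null(rownames(codes))) rownames(codes) <- paste0("s", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("v", seq_len(ncol(codes)))
  if (is.null(control_cohorts))
    control_cohorts <- setdiff(unique(cohort), case_cohort)
  unknown <- setdiff(control_cohorts, unique(cohort))
  if (length(unknown))
    stop("unknown cohort label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(codes = codes, cohort = cohort,
                 control_cohorts = control_cohorts,
                 case_cohort = case_cohort),
            class = "genotype_matrix")
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  if (N <= 0) stop("no genotypes observed", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * N - nA
  m <- min(nA, na)
  het <- seq.int(m %% 2, m, by = 2)
  # conditional probability of each heterozygote count given allele counts,
  # computed on the log scale and renormalized over the support
  logp <- lfactorial(N) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, het)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Conditional exact test of HWE genotype proportions: given the observed
#' allele counts, sums the probabilities of all heterozygote counts (same
#' parity, fixed margins) whose conditional probability does not exceed that
#' of the observed count (point-probability two-sided rule). Used as a
#' genotyping-quality filter; monomorphic variants return p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygous minor, heterozygous,
#'   homozygous major); vectorized.
#' @return Exact p-value(s) in \eqn{[0, 1]}.
#' @examples
#' hwe_exact_test(57, 14, 50)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(all(n_AA >= 0), all(n_Aa >= 0), all(n_aa >= 0))
  mapply(hwe_exact_one, n_AA, n_Aa, n_aa)
}

#' QC thresholds
#'
#' Default cut-offs for [snp_qc()]: control MAF below 0.002, call rate below
#' 95%, HWE exact p in controls below 5.7e-7, and control-cohort
#' allele-frequency heterogeneity (two-proportion score test) p below 5.7e-7.
#'
#' @param maf_min,call_rate_min,hwe_alpha,cohort_het_alpha Numeric cut-offs.
#' @return A named list.
#' @export
qc_thresholds <- function(maf_min = 0.002, call_rate_min = 0.95,
                          hwe_alpha = 5.7e-7, cohort_het_alpha = 5.7e-7) {
  stopifnot(maf_min > 0, maf_min < 1, call_rate_min > 0, call_rate_min <= 1,
            hwe_alpha > 0, hwe_alpha < 1, cohort_het_alpha > 0,
            cohort_het_alpha < 1)
  list(maf_min = maf_min, call_rate_min = call_rate_min,
       hwe_alpha = hwe_alpha, cohort_het_alpha = cohort_het_alpha)
}

#' SNP quality control
#'
#' Applies four exclusion criteria per variant: (1) minor-allele frequency in
#' controls below `maf_min`; (2) call rate (non-missing genotypes over all
#' subjects) below `call_rate_min`; (3) HWE exact-test p-value in controls
#' below `hwe_alpha`; (4) allele-frequency difference between the two control
#' sub-cohorts (pooled-variance two-proportion score test) below
#' `cohort_het_alpha`. All criteria are evaluated for every variant — a
#' variant failing several reports all of them. MAF is folded to the minor
#' allele over controls; missing genotypes are excluded from allele and
#' HWE counts.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] list.
#' @return A `data.frame` with one row per variant: `variant_id`,
#'   `maf_controls`, `call_rate`, `hwe_p_controls`, `cohort_het_p`, the four
#'   `fail_*` flags, `pass` and a comma-separated `fail_reasons` string.
#' @export
snp_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  ctrl <- g$cohort %in% g$control_cohorts
  if (!any(ctrl)) stop("no control subjects", call. = FALSE)
  cc <- g$codes[ctrl, , drop = FALSE]
  n_called <- colSums(!is.na(cc))
  if (any(n_called == 0))
    warning("variant(s) with no called control genotypes: MAF/HWE undefined")
  alt <- colSums(cc, na.rm = TRUE)
  f <- alt / (2 * n_called)
  maf <- pmin(f, 1 - f)
  call_rate <- colSums(!is.na(g$codes)) / nrow(g$codes)
  hwe_p <- vapply(seq_len(ncol(cc)), function(j) {
    v <- cc[, j]
    tab <- c(sum(v == 2, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
             sum(v == 0, na.rm = TRUE))
    if (sum(tab) == 0) return(NA_real_)
    hwe_exact_one(tab[1], tab[2], tab[3])
  }, numeric(1))
  # criterion 4: allele-frequency heterogeneity between the two control
  # sub-cohorts
  if (length(g$control_cohorts) >= 2) {
    if (length(g$control_cohorts) != 2)
      stop("cohort heterogeneity test needs exactly two control sub-cohorts",
           call. = FALSE)
    a <- g$cohort == g$control_cohorts[1]
    b <- g$cohort == g$control_cohorts[2]
    ca <- g$codes[a, , drop = FALSE]; cb <- g$codes[b, , drop = FALSE]
    xa <- colSums(ca, na.rm = TRUE); na_ <- 2 * colSums(!is.na(ca))
    xb <- colSums(cb, na.rm = TRUE); nb_ <- 2 * colSums(!is.na(cb))
    ok <- na_ > 0 & nb_ > 0
    het_p <- rep(NA_real_, ncol(g$codes))
    if (any(ok))
      het_p[ok] <- rd_score_test(data.frame(x1 = xa[ok], n1 = na_[ok],
                                            x2 = xb[ok], n2 = nb_[ok]))$p.value
  } else {
    het_p <- rep(NA_real_, ncol(g$codes))
  }
  fail_maf <- !is.na(maf) & maf < thresholds$maf_min
  fail_maf[is.na(maf)] <- TRUE  # uncallable MAF cannot pass the MAF filter
  fail_call <- call_rate < thresholds$call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_alpha
  fail_het <- !is.na(het_p) & het_p < thresholds$cohort_het_alpha
  reasons <- mapply(function(m, c, h, e)
    paste(c("maf", "call_rate", "hwe", "cohort_het")[c(m, c, h, e)],
          collapse = ","),
    fail_maf, fail_call, fail_hwe, fail_het)
  data.frame(
    variant_id = colnames(g$codes),
    maf_controls = maf, call_rate = call_rate, hwe_p_controls = hwe_p,
    cohort_het_p = het_p,
    fail_maf = fail_maf, fail_call_rate = fail_call, fail_hwe = fail_hwe,
    fail_cohort_het = fail_het,
    pass = !(fail_maf | fail_call | fail_hwe | fail_het),
    fail_reasons = reasons,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify a variant as rare or common by minor-allele frequency
#'
#' Rare iff `maf < cut`; the boundary value is common. Frequencies above 0.5
#' are folded to the minor allele with a warning.
#'
#' @param maf Minor-allele frequency/frequencies in \eqn{[0, 1]}.
#' @param cut MAF cut point, default 0.05.
#' @return Character vector, `"rare"` or `"common"`.
#' @examples
#' classify_rare_common(c(0.049, 0.05))
#' @export
classify_rare_common <- function(maf, cut = 0.05) {
  check_prob(maf, "maf")
  if (any(maf > 0.5)) {
    warning("frequencies above 0.5 folded to the minor allele")
    maf <- pmin(maf, 1 - maf)
  }
  ifelse(maf < cut, "rare", "common")
}
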