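# Per-variant association tests. The three asymptotic tests share the shape
# z = estimate / se, two-sided normal p; each uses the variance convention
# that reproduces the Table-4-style allelic analysis: score (pooled-null)
# variance for the risk difference, the frequency-free variance for h, and
# the Wald variance for log(OR).

test_frame <- function(method, estimate, z, p, n) {
  data.frame(method = rep_len(method, n), estimate = estimate,
             z = z, p.value = p, stringsAsFactors = FALSE)
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Cohen's h association test
#'
#' Tests \eqn{H_0: h = 0} with \eqn{z = \hat h / \sqrt{1/n_1 + 1/n_2}} and a
#' two-sided normal p-value. Because the standard error is free of the allele
#' frequencies, the statistic keeps its nominal size down to rare MAFs.
#'
#' @param counts An [allele_counts()] object or compatible data.frame.
#' @return A `data.frame` with columns `method`, `estimate`, `z`, `p.value`,
#'   one row per variant.
#' @examples
#' h_test(allele_counts(235, 3852, 165, 5876))
#' @export
h_test <- function(counts) {
  counts <- as_counts_df(counts)
  h <- cohens_h(counts$x1 / counts$n1, counts$x2 / counts$n2)
  se <- sqrt(1 / counts$n1 + 1 / counts$n2)
  z <- h / se
  test_frame("h", h, z, two_sided_p(z), nrow(counts))
}

#' Risk-difference (two-proportion score) test
#'
#' Tests \eqn{H_0: p_1 - p_2 = 0} with the pooled-variance score statistic
#' \eqn{z = \hat d / \sqrt{\bar p \bar q (1/n_1 + 1/n_2)}}; its square equals
#' the Pearson chi-square statistic of the 2x2 allele table. Degenerate
#' tables (pooled frequency 0 or 1) return `z = NA`, `p = 1`.
#'
#' @inheritParams h_test
#' @return A `data.frame` as in [h_test()].
#' @export
rd_score_test <- function(counts) {
  counts <- as_counts_df(counts)
  d <- counts$x1 / counts$n1 - counts$x2 / counts$n2
  pbar <- (counts$x1 + counts$x2) / (counts$n1 + counts$n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / counts$n1 + 1 / counts$n2))
  z <- ifelse(se > 0, d / se, NA_real_)
  p <- ifelse(is.na(z), 1, two_sided_p(z))
  test_frame("rd", d, z, p, nrow(counts))
}

#' Allelic odds-ratio Wald test
#'
#' Tests \eqn{H_0: OR = 1} with \eqn{z = \log \widehat{OR} / se(\log
#' \widehat{OR})}. Estimate, statistic and p-value are all `NA` when any cell
#' of the 2x2 allele table is zero (the log-OR and its SE are undefined; no
#' continuity correction is applied) — the exact-test fallback covers those
#' variants.
#'
#' @inheritParams h_test
#' @return A `data.frame` as in [h_test()]; `estimate` is the odds ratio.
#' @export
or_wald_test <- function(counts) {
  counts <- as_counts_df(counts)
  est <- effect_estimates(counts)
  z <- est$log_or / est$se_log_or
  p <- ifelse(is.na(z), NA_real_, two_sided_p(z))
  test_frame("or", est$or, z, p, nrow(counts))
}

#' Fisher's exact test on the 2x2 allele table
#'
#' Two-sided exact p-value by the point-probability rule: the sum of
#' hypergeometric probabilities (margins fixed) of every table at most as
#' probable as the observed one. This is the fallback used when asymptotic
#' normality cannot be trusted (extremely low MAF or empty cells).
#'
#' @inheritParams h_test
#' @return A `data.frame` as in [h_test()]; `estimate` and `z` are `NA`
#'   (the exact test reports a p-value, not an effect estimate).
#' @export
fisher_exact_allelic <- function(counts) {
  counts <- as_counts_df(counts)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$x1[i], counts$n1[i] - counts$x1[i],
                    counts$x2[i], counts$n2[i] - counts$x2[i]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  test_frame("fisher", NA_real_, NA_real_, p, nrow(counts))
}

#' Scan configuration
#'
#' Bundles the tuning knobs shared by [test_variant()] and [genome_scan()].
#'
#' @param alpha_family Family-wise (or FDR) significance level, default 0.05.
#' @param adjustment Multiple-testing adjustment applied across a scan:
#'   `"bonferroni"` (default), `"bh"` or `"none"`.
#' @param maf_fallback_threshold When `min(p1, p2)` falls below this value
#'   (default 0.002) — or any 2x2 cell is zero — the exact test is attached
#'   and used for the significance call.
#' @param rare_common_cut MAF cut separating rare from common variants for
#'   effect-size classification, default 0.05.
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(alpha_family = 0.05,
                        adjustment = c("bonferroni", "bh", "none"),
                        maf_fallback_threshold = 0.002,
                        rare_common_cut = 0.05) {
  adjustment <- match.arg(adjustment)
  stopifnot(alpha_family > 0, alpha_family < 1,
            maf_fallback_threshold > 0, maf_fallback_threshold < 1,
            rare_common_cut > 0, rare_common_cut < 1)
  structure(list(alpha_family = alpha_family, adjustment = adjustment,
                 maf_fallback_threshold = maf_fallback_threshold,
                 rare_common_cut = rare_common_cut),
            class = "scan_config")
}

needs_fallback <- function(counts, threshold) {
  p1 <- counts$x1 / counts$n1
  p2 <- counts$x2 / counts$n2
  zero_cell <- counts$x1 == 0 | counts$x1 == counts$n1 |
    counts$x2 == 0 | counts$x2 == counts$n2
  pmin(p1, p2) < threshold | zero_cell
}

#' Test a single variant with all three effect-size measures
#'
#' Runs the h, risk-difference and odds-ratio tests and, when the asymptotic
#' assumption is shaky (minimum MAF below `maf_fallback_threshold`, or an
#' empty cell), additionally attaches the Fisher exact p-value. The
#' asymptotic p-values are still reported in that case — the exact test
#' validates rather than replaces them.
#'
#' @param counts A single-variant [allele_counts()] object (one row).
#' @param config A [scan_config()].
#' @return A one-row `data.frame` with the estimates, standard errors,
#'   p-values (`P_RD`, `P_h`, `P_OR`), `fallback_used` and `P_exact`.
#' @export
test_variant <- function(counts, config = scan_config()) {
  counts <- as_counts_df(counts)
  if (nrow(counts) != 1)
    stop("test_variant() expects a single variant; use genome_scan()",
         call. = FALSE)
  scan_core(counts, config)
}

# Vectorized core shared by test_variant and genome_scan.
scan_core <- function(counts, config) {
  est <- effect_estimates(counts)
  ht <- h_test(counts); rdt <- rd_score_test(counts); ort <- or_wald_test(counts)
  fb <- needs_fallback(counts, config$maf_fallback_threshold)
  p_exact <- rep(NA_real_, nrow(counts))
  if (any(fb))
    p_exact[fb] <- fisher_exact_allelic(counts[fb, , drop = FALSE])$p.value
  out <- data.frame(
    variant_id = if (is.null(counts$variant_id))
      paste0("v", seq_len(nrow(counts))) else counts$variant_id,
    x1 = counts$x1, n1 = counts$n1, x2 = counts$x2, n2 = counts$n2,
    MAF_cases = est$p1, MAF_controls = est$p2,
    RD = est$d, SE_RD = est$se_d_null, P_RD = rdt$p.value,
    h = est$h, SE_h = est$se_h, P_h = ht$p.value,
    OR = est$or, SE_logOR = est$se_log_or, P_OR = ort$p.value,
    fallback_used = fb, P_exact = p_exact,
    stringsAsFactors = FALSE
  )
  out
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjusted
#' p-values, in input order.
#'
#' @param p Vector of p-values in \eqn{[0, 1]} (`NA` allowed, passed through).
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh")
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Genome scan: test every variant in a counts table
#'
#' Vectorizes [test_variant()] over a whole table, then applies the
#' configured multiple-testing adjustment per measure across the scan and
#' flags significance at the family level. Where the exact-test fallback
#' fired, the significance call for every measure uses the exact p-value.
#' Each variant's h is also classified into a mild/moderate/large band using
#' the rare or common [threshold_scheme()] picked by its control MAF.
#'
#' @param table A `data.frame` with columns `variant_id`, `x1`, `n1`, `x2`,
#'   `n2` (e.g. from [read_counts_table()] or [allele_counts()]).
#' @param config A [scan_config()].
#' @return A `data.frame`, one row per input variant in input order, with
#'   estimate/SE/p-value columns, `fallback_used`, `P_exact`, adjusted
#'   p-values (`P_RD_adj`, `P_h_adj`, `P_OR_adj`), significance flags
#'   (`sig_RD`, `sig_h`, `sig_OR`), `variant_class` and `es_class_h`.
#' @examples
#' tab <- allele_counts(c(235, 30), c(3852, 3852), c(165, 40), c(5876, 5876),
#'                      variant_id = c("rsA", "rsB"))
#' genome_scan(tab, scan_config(adjustment = "bonferroni"))
#' @export
genome_scan <- function(table, config = scan_config()) {
  table <- as_counts_df(table)
  if (nrow(table) == 0) stop("empty counts table", call. = FALSE)
  if (!is.null(table$variant_id) && anyDuplicated(table$variant_id))
    warning("duplicate variant_id values in scan input")
  out <- scan_core(table, config)
  m <- nrow(out)
  adj <- function(p) switch(config$adjustment,
                            none = p,
                            bonferroni = adjust_pvalues(p, "bonferroni"),
                            bh = adjust_pvalues(p, "bh"))
  out$P_RD_adj <- adj(out$P_RD)
  out$P_h_adj <- adj(out$P_h)
  out$P_OR_adj <- adj(out$P_OR)
  # per-test level implied by the family-level adjustment; exact p compared
  # on the same scale
  exact_adj <- adj(ifelse(is.na(out$P_exact), 1, out$P_exact))
  sig <- function(p_adj) {
    s <- ifelse(out$fallback_used, exact_adj, p_adj) <= config$alpha_family
    s & !is.na(s)
  }
  out$sig_RD <- sig(out$P_RD_adj)
  out$sig_h <- sig(out$P_h_adj)
  out$sig_OR <- sig(out$P_OR_adj)
  out$variant_class <- classify_rare_common(pmin(out$MAF_controls,
                                                 1 - out$MAF_controls),
                                            cut = config$rare_common_cut)
  rare_s <- threshold_scheme("rare"); common_s <- threshold_scheme("common")
  out$es_class_h <- ifelse(
    out$variant_class == "rare",
    as.character(classify_effect(out$h, rare_s, scale = "h")),
    as.character(classify_effect(out$h, common_s, scale = "h")))
  out
}
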