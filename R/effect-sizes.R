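# Effect-size kernels on the MAF scale, plus the OR <-> MAF <-> h conversion
# algebra. All functions are vectorized over their probability arguments.

check_prob <- function(p, name, open_upper = FALSE) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1) ||
      (open_upper && any(p >= 1)))
    stop(name, " must lie in [0,1", if (open_upper) ")" else "]", call. = FALSE)
  invisible(p)
}

#' Cohen's h for two proportions
#'
#' The difference of arcsine-square-root transformed minor-allele frequencies,
#' \deqn{h = 2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2},}
#' reported in radians-scale ("arcsine") units. The transform stabilizes the
#' variance: the estimator's asymptotic standard error, \eqn{\sqrt{1/n_1 +
#' 1/n_2}}, does not involve the frequencies, which is what preserves power
#' at rare minor-allele frequencies.
#'
#' @param p1 Case minor-allele frequency, in \eqn{[0, 1]}.
#' @param p2 Control minor-allele frequency, in \eqn{[0, 1]}.
#' @return Numeric vector of h values in \eqn{[-\pi, \pi]}; positive when the
#'   case MAF exceeds the control MAF.
#' @examples
#' cohens_h(0.061, 0.028)  # 0.163
#' @export
cohens_h <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Risk difference of minor-allele frequencies
#'
#' @inheritParams cohens_h
#' @return `p1 - p2`.
#' @export
risk_difference <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  p1 - p2
}

#' Allelic odds ratio
#'
#' \eqn{OR = p_1(1-p_2) / (p_2(1-p_1))} on the allele scale. The ratio is
#' undefined (returned as `NA`) whenever a frequency sits on the boundary
#' (`p1` or `p2` equal to 0 or 1, i.e. any implied 2x2 cell is empty); no
#' continuity correction is applied.
#'
#' @inheritParams cohens_h
#' @return Numeric vector; `NA` where undefined.
#' @examples
#' allelic_odds_ratio(0.061, 0.028)   # 2.255
#' allelic_odds_ratio(0, 0.005)       # NA: empty case cell
#' @export
allelic_odds_ratio <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  out <- p1 * (1 - p2) / (p2 * (1 - p1))
  out[p1 <= 0 | p1 >= 1 | p2 <= 0 | p2 >= 1] <- NA_real_
  out
}

#' Effect estimates and asymptotic standard errors from allele counts
#'
#' Computes, per variant, the three effect-size estimates and their
#' large-sample standard errors:
#' \itemize{
#'   \item `d` (risk difference) with the Wald SE
#'     \eqn{\sqrt{\hat p_1\hat q_1/n_1 + \hat p_2\hat q_2/n_2}} (`se_d_wald`)
#'     and the pooled null (score) SE
#'     \eqn{\sqrt{\bar p\bar q(1/n_1 + 1/n_2)}} (`se_d_null`), where
#'     \eqn{\bar p = (x_1+x_2)/(n_1+n_2)};
#'   \item `h` (Cohen's h) with the frequency-free SE
#'     \eqn{\sqrt{1/n_1 + 1/n_2}} (`se_h`);
#'   \item `log_or` with SE
#'     \eqn{\sqrt{1/x_1 + 1/(n_1-x_1) + 1/x_2 + 1/(n_2-x_2)}} (`se_log_or`);
#'     both are `NA` whenever any 2x2 cell is zero.
#' }
#'
#' @param counts An [allele_counts()] object or compatible data.frame.
#' @return A `data.frame`, one row per variant, with columns `variant_id`
#'   (when present), `p1`, `p2`, `d`, `h`, `or`, `log_or`, `se_d_wald`,
#'   `se_d_null`, `se_h`, `se_log_or`.
#' @examples
#' effect_estimates(allele_counts(235, 3852, 165, 5876))
#' @export
effect_estimates <- function(counts) {
  counts <- as_counts_df(counts)
  x1 <- counts$x1; n1 <- counts$n1; x2 <- counts$x2; n2 <- counts$n2
  p1 <- x1 / n1; p2 <- x2 / n2
  zero_cell <- x1 == 0 | x1 == n1 | x2 == 0 | x2 == n2
  log_or <- ifelse(zero_cell, NA_real_,
                   log(p1) - log1p(-p1) - log(p2) + log1p(-p2))
  se_log_or <- ifelse(zero_cell, NA_real_,
                      sqrt(1 / x1 + 1 / (n1 - x1) + 1 / x2 + 1 / (n2 - x2)))
  pbar <- (x1 + x2) / (n1 + n2)
  out <- data.frame(
    p1 = p1, p2 = p2,
    d = p1 - p2,
    h = 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)),
    or = exp(log_or),
    log_or = log_or,
    se_d_wald = sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2),
    se_d_null = sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2)),
    se_h = sqrt(1 / n1 + 1 / n2),
    se_log_or = se_log_or
  )
  if (!is.null(counts$variant_id))
    out <- cbind(variant_id = counts$variant_id, out,
                 stringsAsFactors = FALSE)
  out
}

#' Case MAF implied by an odds ratio and a control MAF
#'
#' Inverts the allelic odds-ratio definition:
#' \eqn{p_1 = OR\, p_2 / (OR\, p_2 - p_2 + 1)}.
#'
#' @param or Odds ratio(s), strictly positive.
#' @param p2 Control minor-allele frequency in \eqn{[0, 1)}.
#' @return The case MAF `p1` in \eqn{[0, 1)}.
#' @examples
#' or_to_case_maf(3, 0.01)  # 0.02941
#' @export
or_to_case_maf <- function(or, p2) {
  if (any(!is.finite(or)) || any(or <= 0))
    stop("or must be strictly positive", call. = FALSE)
  check_prob(p2, "p2", open_upper = TRUE)
  or * p2 / (or * p2 - p2 + 1)
}

#' Cohen's h implied by an odds ratio at a given control MAF
#'
#' Composes [or_to_case_maf()] with [cohens_h()]: the h value of a variant
#' whose control MAF is `p2` and whose allelic odds ratio is `or`. At fixed
#' `p2` this is strictly increasing in `or`; at fixed `or > 1` it grows with
#' `p2`, which is why OR-equivalent h thresholds depend on the MAF range over
#' which they are averaged.
#'
#' @inheritParams or_to_case_maf
#' @return Numeric vector of h values.
#' @examples
#' h_from_or(3, 0.01)  # 0.1444
#' @export
h_from_or <- function(or, p2) {
  cohens_h(or_to_case_maf(or, p2), p2)
}
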