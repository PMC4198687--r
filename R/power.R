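# Analytic power and sample-size machinery for the allelic two-proportion
# test and the Cohen's h test, under a balanced design with n1 = n2 = n
# allele counts per group. With two alleles per diploid subject, a total of
# N subjects split equally gives N alleles per group, so "per-group allele
# count" and "total subjects" coincide numerically.

#' Analytic power of the two-proportion (risk difference / OR) test
#'
#' Power of the two-sided allelic two-proportion test of \eqn{H_0: p_1 = p_2}
#' at significance level `alpha`, with `n` alleles per group under a balanced
#' design. The alternative is given either as an odds ratio `or` (converted
#' through [or_to_case_maf()]) or directly as the case MAF `p1`.
#'
#' Two variance conventions are available. The default `"hybrid"` form uses
#' the pooled null variance inside the rejection threshold and the
#' alternative (Wald) variance in the denominator:
#' \deqn{power = \Phi\!\Big(\frac{|p_1-p_2|\sqrt n - z_{1-\alpha/2}
#'   \sqrt{2\bar p\bar q}}{\sqrt{p_1q_1 + p_2q_2}}\Big)
#'   + \Phi\!\Big(\frac{-|p_1-p_2|\sqrt n - z_{1-\alpha/2}
#'   \sqrt{2\bar p\bar q}}{\sqrt{p_1q_1 + p_2q_2}}\Big),}
#' with \eqn{\bar p = (p_1+p_2)/2}. The `"wald"` form uses the alternative
#' variance in both places. The two agree closely; at genome-wide alpha they
#' differ by a few subjects in implied sample size.
#'
#' @param n Allele count per group (2 per subject; vectorized).
#' @param p2 Control minor-allele frequency in (0, 1).
#' @param or Alternative odds ratio (> 0); exactly one of `or`, `p1`.
#' @param p1 Alternative case MAF in (0, 1).
#' @param alpha Two-sided significance level, default `5e-8` (genome-wide).
#' @param variance `"hybrid"` (default) or `"wald"`.
#' @return Power in \eqn{[\alpha, 1]}.
#' @examples
#' power_two_proportion(n = 4060, p2 = 0.01, or = 3)  # ~0.80
#' @export
power_two_proportion <- function(n, p2, or = NULL, p1 = NULL, alpha = 5e-8,
                                 variance = c("hybrid", "wald")) {
  variance <- match.arg(variance)
  stopifnot(alpha > 0, alpha < 1, all(n > 0))
  check_prob(p2, "p2", open_upper = TRUE)
  if (is.null(p1) == is.null(or))
    stop("supply exactly one of `or` or `p1`", call. = FALSE)
  if (is.null(p1)) p1 <- or_to_case_maf(or, p2)
  if (any(p1 <= 0 | p1 >= 1 | p2 <= 0))
    stop("alternative MAFs must lie strictly inside (0, 1)", call. = FALSE)
  z <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  d <- abs(p1 - p2)
  v_alt <- sqrt(p1 * (1 - p1) + p2 * (1 - p2))
  pbar <- (p1 + p2) / 2
  v_null <- switch(variance, hybrid = sqrt(2 * pbar * (1 - pbar)),
                   wald = v_alt)
  stats::pnorm((d * sqrt(n) - z * v_null) / v_alt) +
    stats::pnorm((-d * sqrt(n) - z * v_null) / v_alt)
}

#' Analytic power of the Cohen's h test
#'
#' Power of the two-sided test of \eqn{H_0: h = 0} against \eqn{H_1: h =
#' \delta} with `n` alleles per group (balanced design, so \eqn{se(\hat h) =
#' \sqrt{2/n}}):
#' \deqn{power = \Phi(|\delta|\sqrt{n/2} - z_{1-\alpha/2}) +
#'   \Phi(-|\delta|\sqrt{n/2} - z_{1-\alpha/2}).}
#' Given \eqn{\delta} the power involves no allele frequency at all — the
#' practical payoff of variance stabilization. The alternative can be given
#' as `delta` directly or as an `(or, p2)` pair via [h_from_or()].
#'
#' @param n Allele count per group (vectorized).
#' @param delta Alternative h value; exactly one of `delta` or `or`.
#' @param or,p2 Alternative specified as odds ratio at control MAF `p2`.
#' @param alpha Two-sided significance level, default `5e-8`.
#' @return Power in \eqn{[\alpha, 1]}.
#' @examples
#' power_h(n = 4060, or = 3, p2 = 0.01)  # ~0.85
#' @export
power_h <- function(n, delta = NULL, or = NULL, p2 = NULL, alpha = 5e-8) {
  stopifnot(alpha > 0, alpha < 1, all(n > 0))
  if (is.null(delta) == is.null(or))
    stop("supply exactly one of `delta` or `or` (with `p2`)", call. = FALSE)
  if (is.null(delta)) {
    if (is.null(p2)) stop("`p2` is required with `or`", call. = FALSE)
    delta <- h_from_or(or, p2)
  }
  z <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  stats::pnorm(abs(delta) * sqrt(n / 2) - z) +
    stats::pnorm(-abs(delta) * sqrt(n / 2) - z)
}

#' Minimum total sample size for a target power
#'
#' Smallest total subject count (even, split equally between cases and
#' controls; per-group allele count equals the total subject count) whose
#' analytic power reaches `target_power` under the chosen test. The search
#' exploits monotonicity of power in n: exponential bracketing followed by
#' bisection over even totals, so `power(min_n) >= target` and
#' `power(min_n - 2) < target`.
#'
#' @param target_power Target power in (0, 1).
#' @param p2 Control MAF (required for `"two_proportion"`, and for `"h"` when
#'   the alternative is given as `or`).
#' @param or Alternative odds ratio; for `method = "h"` either `or`+`p2` or
#'   `delta`.
#' @param delta Alternative h (method `"h"` only).
#' @param alpha Two-sided significance level, default `5e-8`.
#' @param method `"two_proportion"` or `"h"`.
#' @param variance Variance convention for the two-proportion formula.
#' @return Total number of subjects (even integer).
#' @examples
#' min_sample_size(0.80, p2 = 0.01, or = 3)  # ~4060 total subjects
#' @export
min_sample_size <- function(target_power, p2 = NULL, or = NULL, delta = NULL,
                            alpha = 5e-8,
                            method = c("two_proportion", "h"),
                            variance = c("hybrid", "wald")) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  stopifnot(target_power > 0, target_power < 1)
  pw <- if (method == "two_proportion") {
    if (is.null(p2) || is.null(or))
      stop("two_proportion sizing needs `p2` and `or`", call. = FALSE)
    if (or == 1) stop("alternative is null (or = 1): unreachable target",
                      call. = FALSE)
    function(n) power_two_proportion(n, p2 = p2, or = or, alpha = alpha,
                                     variance = variance)
  } else {
    if (is.null(delta) && !is.null(or)) delta <- h_from_or(or, p2)
    if (is.null(delta))
      stop("h sizing needs `delta` or `or` with `p2`", call. = FALSE)
    if (delta == 0) stop("alternative is null (delta = 0): unreachable target",
                         call. = FALSE)
    function(n) power_h(n, delta = delta, alpha = alpha)
  }
  lo <- 2
  if (pw(lo) >= target_power) return(lo)
  hi <- 4
  while (pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2
    if (hi > 2^31) stop("target power unreachable at feasible sample sizes",
                        call. = FALSE)
  }
  # bisection on even totals: pw(lo) < target <= pw(hi)
  while (hi - lo > 2) {
    mid <- 2 * ((lo + hi) %/% 4)
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Power-ratio surface: Cohen's h versus the two-proportion test
#'
#' Evaluates both analytic powers over a (control MAF, sample size) grid at a
#' fixed alternative odds ratio, using the h alternative \eqn{\delta =}
#' [h_from_or()]`(or, p2)` so both tests target the same underlying effect.
#' On rare-MAF grids the ratio is consistently at least 1 — the h test never
#' loses power to the two-proportion test there.
#'
#' @param p2_grid Control MAF values in (0, 1).
#' @param n_grid Per-group allele counts (positive).
#' @param or Alternative odds ratio.
#' @param alpha Two-sided significance level, default `5e-8`.
#' @param variance Variance convention for the two-proportion power.
#' @return A `data.frame` with columns `p2`, `n`, `power_h`, `power_2prop`,
#'   `ratio`. Degenerate grid values are skipped with a warning.
#' @export
power_ratio_table <- function(p2_grid, n_grid, or, alpha = 5e-8,
                              variance = c("hybrid", "wald")) {
  variance <- match.arg(variance)
  ok_p <- is.finite(p2_grid) & p2_grid > 0 & p2_grid < 1
  ok_n <- is.finite(n_grid) & n_grid > 0
  if (!all(ok_p) || !all(ok_n)) {
    warning("degenerate grid values skipped")
    p2_grid <- p2_grid[ok_p]; n_grid <- n_grid[ok_n]
  }
  if (length(p2_grid) == 0 || length(n_grid) == 0)
    stop("empty grid", call. = FALSE)
  grid <- expand.grid(p2 = p2_grid, n = n_grid)
  grid$power_h <- power_h(grid$n, delta = h_from_or(or, grid$p2),
                          alpha = alpha)
  grid$power_2prop <- power_two_proportion(grid$n, p2 = grid$p2, or = or,
                                           alpha = alpha, variance = variance)
  grid$ratio <- grid$power_h / grid$power_2prop
  grid
}
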