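# Effect-size interpretation: mild / moderate / large bands for Cohen's h
# calibrated against conventional odds-ratio cut points. Cohen's original
# 0.2/0.5/0.8 benchmarks were derived for proportions near 0.5; at GWAS
# minor-allele frequencies virtually no variant reaches |h| = 0.2, so the
# bands here are re-calibrated to the OR cuts practitioners actually use.

#' Effect-size threshold schemes
#'
#' Named band cut points for classifying an effect as mild, moderate or
#' large, on both the h and the log-OR scale. Boundary values fall in the
#' lower band.
#'
#' \describe{
#'   \item{`"common"`}{|h| cuts 0.075 / 0.15; OR cuts 1.2 / 1.5.}
#'   \item{`"rare"`}{|h| cuts 0.05 / 0.1; OR cuts 1.5 / 2.}
#'   \item{`"cohen"`}{the conventional |h| benchmarks 0.2 / 0.5 (no OR
#'     counterpart) — under which essentially every rare GWAS variant is
#'     "mild", the motivation for the re-calibrated schemes.}
#' }
#'
#' @param variant_class `"rare"`, `"common"` or `"cohen"`.
#' @return A list of class `"threshold_scheme"` with elements
#'   `variant_class`, `h_cuts` (mild max, moderate max) and `logor_cuts`.
#' @examples
#' threshold_scheme("rare")
#' @export
threshold_scheme <- function(variant_class = c("rare", "common", "cohen")) {
  variant_class <- match.arg(variant_class)
  sch <- switch(variant_class,
    common = list(h_cuts = c(mild = 0.075, moderate = 0.15),
                  logor_cuts = c(mild = log(1.2), moderate = log(1.5))),
    rare = list(h_cuts = c(mild = 0.05, moderate = 0.1),
                logor_cuts = c(mild = log(1.5), moderate = log(2))),
    cohen = list(h_cuts = c(mild = 0.2, moderate = 0.5),
                 logor_cuts = c(mild = NA_real_, moderate = NA_real_)))
  structure(c(list(variant_class = variant_class), sch),
            class = "threshold_scheme")
}

#' Derive OR-equivalent Cohen's h thresholds over a MAF range
#'
#' For each odds-ratio cut, averages [h_from_or()]`(cut, p2)` over a uniform
#' control-MAF grid on `(p2_range[1], p2_range[2]]`. Because h grows with the
#' MAF at fixed OR, the averaging range matters: a common-variant range
#' (0.05, 0.5] reproduces the 0.075/0.15 bands; low-MAF ranges give smaller
#' equivalents.
#'
#' @param or_cuts Odds-ratio cut points, each > 1.
#' @param p2_range Length-2 numeric, `0 < low < high <= 0.5`.
#' @param grid_step Grid spacing, default 0.001.
#' @return Named numeric vector of mean h values, one per OR cut, increasing
#'   in the cut.
#' @examples
#' derive_h_thresholds(c(1.2, 1.5), c(0.05, 0.5))
#' @export
derive_h_thresholds <- function(or_cuts, p2_range, grid_step = 0.001) {
  stopifnot(length(p2_range) == 2, p2_range[1] > 0,
            p2_range[1] < p2_range[2], p2_range[2] <= 0.5,
            all(or_cuts >= 1), grid_step > 0)
  grid <- seq(p2_range[1] + grid_step, p2_range[2], by = grid_step)
  if (length(grid) == 0) stop("empty MAF grid", call. = FALSE)
  out <- vapply(or_cuts, function(cut) mean(h_from_or(cut, grid)), numeric(1))
  names(out) <- paste0("or", or_cuts)
  out
}

#' Classify an effect estimate as mild, moderate or large
#'
#' Band assignment by absolute value against a [threshold_scheme()], with
#' boundary values falling in the lower band. On the `"or"` scale the value
#' compared is |log(OR)|.
#'
#' @param value Effect estimate(s): h values for `scale = "h"`, log odds
#'   ratios for `scale = "or"`.
#' @param scheme A [threshold_scheme()].
#' @param scale `"h"` or `"or"`.
#' @return Factor with levels `mild`, `moderate`, `large`.
#' @examples
#' classify_effect(0.12, threshold_scheme("rare"), scale = "h")  # large
#' @export
classify_effect <- function(value, scheme = threshold_scheme("rare"),
                            scale = c("h", "or")) {
  scale <- match.arg(scale)
  stopifnot(inherits(scheme, "threshold_scheme"))
  cuts <- if (scale == "h") scheme$h_cuts else scheme$logor_cuts
  if (any(is.na(cuts)))
    stop("scheme '", scheme$variant_class, "' has no cuts on the ", scale,
         " scale", call. = FALSE)
  if (any(is.na(value)))
    stop("estimate undefined on the ", scale, " scale", call. = FALSE)
  a <- abs(value)
  factor(ifelse(a <= cuts[["mild"]], "mild",
                ifelse(a <= cuts[["moderate"]], "moderate", "large")),
         levels = c("mild", "moderate", "large"))
}
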