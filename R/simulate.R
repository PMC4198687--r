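# Monte-Carlo machinery: synthetic case-control allele counts under
# Hardy-Weinberg binomial sampling, pseudo case-control splits, null
# calibration (bias / MSE / type I error) and empirical power.

# Run code with a reproducible, self-contained RNG state. When seed is NULL
# the global stream is used as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulation specification
#'
#' Parameters of a synthetic case-control panel. Allele counts are drawn by
#' binomial sampling on the allele scale (each subject contributes two
#' independent alleles, i.e. genotypes in Hardy-Weinberg proportions):
#' \eqn{x_2 \sim Bin(2 m_2, p_2)} for controls and \eqn{x_1 \sim Bin(2 m_1,
#' p_1)} for cases, with \eqn{p_1} derived from the alternative odds ratio
#' via [or_to_case_maf()] (`or_alt = 1` gives a null panel).
#'
#' Defaults mirror a pseudo case-control calibration design: arms of 1,480
#' and 1,458 subjects (a homogeneous control pool of 2,938 split at random),
#' and a common-MAF spectrum uniform on (0.05, 0.5).
#'
#' @param n_variants Number of variants per replicate.
#' @param n_case_subjects,n_control_subjects Subjects per arm.
#' @param maf Fixed control MAF, or a vector recycled across variants.
#'   Exactly one of `maf`, `maf_range`.
#' @param maf_range Length-2 range; control MAFs drawn uniformly from it.
#' @param or_alt Alternative allelic odds ratio; 1 (default) for null panels.
#' @param n_replicates Number of independent replicates of the whole panel.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `"sim_spec"`.
#' @examples
#' sim_spec(n_variants = 100, seed = 1)
#' @export
sim_spec <- function(n_variants, n_case_subjects = 1480,
                     n_control_subjects = 1458, maf = NULL,
                     maf_range = c(0.05, 0.5), or_alt = 1,
                     n_replicates = 1, seed = NULL) {
  stopifnot(n_variants >= 1, n_case_subjects >= 1, n_control_subjects >= 1,
            n_replicates >= 1, or_alt > 0)
  if (!is.null(maf)) {
    check_prob(maf, "maf", open_upper = TRUE)
    maf_range <- NULL
  } else {
    stopifnot(length(maf_range) == 2, maf_range[1] > 0,
              maf_range[1] < maf_range[2], maf_range[2] < 1)
  }
  structure(list(n_variants = as.integer(n_variants),
                 n_case_subjects = as.integer(n_case_subjects),
                 n_control_subjects = as.integer(n_control_subjects),
                 maf = maf, maf_range = maf_range, or_alt = or_alt,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "sim_spec")
}

#' Simulate case/control allele counts
#'
#' Draws the panel described by a [sim_spec()]: control MAFs per variant
#' (fixed or uniform), case MAFs through the odds-ratio inversion, then
#' binomial allele counts for every variant x replicate cell. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return A `data.frame` with columns `variant`, `replicate`, `p2_true`,
#'   `x1`, `n1`, `x2`, `n2` (counts satisfying the [allele_counts()]
#'   invariants).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n1 <- 2L * spec$n_case_subjects
  n2 <- 2L * spec$n_control_subjects
  with_seed(spec$seed, {
    p2 <- if (!is.null(spec$maf)) rep_len(spec$maf, spec$n_variants)
          else stats::runif(spec$n_variants, spec$maf_range[1],
                            spec$maf_range[2])
    p1 <- or_to_case_maf(spec$or_alt, p2)
    if (any(p1 <= 0 | p1 >= 1))
      stop("case MAF implied by or_alt leaves (0, 1)", call. = FALSE)
    cells <- spec$n_variants * spec$n_replicates
    p2_all <- rep(p2, times = spec$n_replicates)
    p1_all <- rep(p1, times = spec$n_replicates)
    data.frame(
      variant = rep(seq_len(spec$n_variants), times = spec$n_replicates),
      replicate = rep(seq_len(spec$n_replicates), each = spec$n_variants),
      p2_true = p2_all,
      x1 = stats::rbinom(cells, n1, p1_all), n1 = n1,
      x2 = stats::rbinom(cells, n2, p2_all), n2 = n2
    )
  })
}

#' Pseudo case-control split
#'
#' Randomly partitions a pool of (homogeneous, e.g. all-control) subjects
#' into pseudo-cases and pseudo-controls — a guaranteed-null design for
#' calibrating type I error on real genotypes. The split is disjoint and
#' exhaustive and deterministic given `seed`.
#'
#' @param x Total subject count, or a [genotype_matrix()] whose subjects are
#'   split.
#' @param n_pseudo_cases Number of subjects assigned to the pseudo-case arm
#'   (must be less than the total).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with integer index vectors `pseudo_case` and
#'   `pseudo_control` (into the subject pool).
#' @examples
#' pseudo_case_control(2938, 1480, seed = 1)
#' @export
pseudo_case_control <- function(x, n_pseudo_cases, seed = NULL) {
  n <- if (inherits(x, "genotype_matrix")) nrow(x$codes) else as.integer(x)
  stopifnot(n >= 2, n_pseudo_cases >= 1)
  if (n_pseudo_cases >= n)
    stop("n_pseudo_cases must be smaller than the subject pool", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(n, n_pseudo_cases)
    list(pseudo_case = sort(idx),
         pseudo_control = setdiff(seq_len(n), idx))
  })
}

measure_pvals <- function(counts) {
  list(rd = rd_score_test(counts)$p.value,
       h = h_test(counts)$p.value,
       log_or = or_wald_test(counts)$p.value)
}

#' Null calibration: bias, MSE and type I error of the three measures
#'
#' Simulates a null panel (`or_alt = 1`) and reports, for each effect-size
#' measure (risk difference, Cohen's h, log odds ratio): the bias (grand
#' mean of estimates over all variant x replicate cells; the true value is
#' 0), the MSE (grand mean of squared estimates), the empirical type I error
#' (fraction of the measure's own asymptotic tests rejecting at `level`) and
#' the number of cells where the measure is undefined (zero cells, log-OR
#' only; excluded from its bias/MSE and type I error).
#'
#' Cohen's h makes a sharp prediction here: its null MSE is \eqn{1/n_1 +
#' 1/n_2} whatever the MAF spectrum — the variance-stabilization property.
#'
#' @param spec A [sim_spec()] with `or_alt = 1`.
#' @param level Nominal test level, default 0.05.
#' @return A `data.frame` with one row per measure (`rd`, `h`, `log_or`) and
#'   columns `bias`, `mse`, `type1_rate`, `n_undefined`, `n_cells`; the spec
#'   and seed are attached as attributes.
#' @export
null_calibration <- function(spec, level = 0.05) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$or_alt != 1)
    stop("null_calibration() requires or_alt = 1", call. = FALSE)
  counts <- simulate_counts(spec)
  est <- effect_estimates(counts)
  pv <- measure_pvals(counts)
  one <- function(e, p) {
    def <- !is.na(e)
    data.frame(bias = mean(e[def]), mse = mean(e[def]^2),
               type1_rate = mean(p[def] < level),
               n_undefined = sum(!def), n_cells = length(e))
  }
  out <- rbind(one(est$d, pv$rd), one(est$h, pv$h), one(est$log_or, pv$log_or))
  out <- cbind(measure = c("rd", "h", "log_or"), out)
  attr(out, "spec") <- spec
  attr(out, "level") <- level
  out
}

#' Empirical power of the three measures
#'
#' Simulates a panel under the alternative given by `spec$or_alt` and
#' reports, per measure, the fraction of variant x replicate cells whose
#' asymptotic test rejects at `level`, with a binomial standard error.
#' Undefined log-OR cells count as non-rejections (a zero cell cannot be
#' declared significant by the Wald OR test — the practical power cost of
#' the OR at rare MAFs).
#'
#' @param spec A [sim_spec()].
#' @param level Nominal test level, default 0.05.
#' @return A `data.frame` with columns `measure`, `power`, `se`,
#'   `n_undefined`, `n_cells`.
#' @export
empirical_power <- function(spec, level = 0.05) {
  stopifnot(inherits(spec, "sim_spec"))
  counts <- simulate_counts(spec)
  pv <- measure_pvals(counts)
  one <- function(p) {
    rej <- !is.na(p) & p < level
    pw <- mean(rej)
    data.frame(power = pw, se = sqrt(pw * (1 - pw) / length(p)),
               n_undefined = sum(is.na(p)), n_cells = length(p))
  }
  out <- rbind(one(pv$rd), one(pv$h), one(pv$log_or))
  cbind(measure = c("rd", "h", "log_or"), out)
}
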