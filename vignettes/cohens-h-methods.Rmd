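---
title: "Cohen's h for rare-variant case-control association: model, power and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohen's h for rare-variant case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohenh)
```

## The problem and the model

In a case-control study of a biallelic SNP with minor allele A, let $p_1 =
P(A\mid \text{case})$ and $p_2 = P(A\mid \text{control})$ be the
minor-allele frequencies (MAFs), estimated from $n_1$ and $n_2$ observed
alleles (two per genotyped diploid subject). Three effect-size measures are
in routine use:

* the risk difference $d = p_1 - p_2$,
* the allelic odds ratio $OR = p_1(1-p_2) / (p_2(1-p_1))$,
* Cohen's h, $h = 2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2}$.

The arcsine square root is the classical variance-stabilizing transform for
a binomial proportion: $\operatorname{Var}(2\arcsin\sqrt{\hat p}) \approx
1/n$ regardless of $p$. Consequently
$$ se(\hat h) = \sqrt{1/n_1 + 1/n_2}, $$
free of both frequencies, while the Wald standard error of
$\log\widehat{OR}$, $\sqrt{1/x_1 + 1/(n_1-x_1) + 1/x_2 + 1/(n_2-x_2)}$,
explodes as minor-allele counts shrink and is undefined the moment a cell
is empty. This is the entire story of the package: at MAFs below a few
percent the h statistic keeps its nominal size and loses far less power
than the OR-based Wald test, while remaining a plain two-sample z-test.

### Variance conventions

Each asymptotic test here is $z = \text{estimate}/se$ with a two-sided
normal p-value, but the choice of $se$ differs by measure:

* `rd_score_test()` uses the pooled-null (score) variance
  $\bar p\bar q(1/n_1 + 1/n_2)$, $\bar p = (x_1+x_2)/(n_1+n_2)$ — its square
  is exactly the Pearson chi-square of the 2×2 allele table;
* `h_test()` uses the frequency-free $1/n_1 + 1/n_2$;
* `or_wald_test()` uses the Wald variance of the log odds ratio.

With these conventions the three tests reproduce, from the published MAF
pairs of the motivating coronary-artery-disease analysis, the published
ordering and magnitude of the three p-values (RD < h < OR at the strongest
rare signal). That agreement is what pinned the conventions; the package
does not implement a Wald RD test or a score OR test.

## Exact-test fallback

Asymptotic normality is not trustworthy when the expected minor-allele
count is a handful. `test_variant()`/`genome_scan()` therefore attach a
two-sided Fisher exact p-value (point-probability rule on the 2×2 allele
table) whenever `min(p1, p2) < maf_fallback_threshold` (default 0.002,
configurable) **or** any table cell is zero — zero cells break the OR and
its SE outright. The asymptotic p-values are still reported (the exact test
validates rather than replaces them), but the significance flag defers to
the exact p-value where the fallback fired. No continuity or Haldane
correction is ever applied to the OR: an undefined OR is reported as `NA`,
matching how such variants are tabulated in practice.

## Power and sample size

For a balanced design ($n$ alleles per group; with equal arms the total
subject count equals the per-group allele count) the h test has power
$$ \Phi\!\big(|\delta|\sqrt{n/2} - z_{1-\alpha/2}\big) +
   \Phi\!\big(-|\delta|\sqrt{n/2} - z_{1-\alpha/2}\big), $$
which given $\delta$ involves no allele frequency at all. The alternative
$\delta$ is usually derived from a target odds ratio $c$ at control MAF
$p_2$ through $p_1 = c\,p_2/(c\,p_2 - p_2 + 1)$ and `h_from_or()`.

The two-proportion power formula is exposed in two variance conventions.
The default `"hybrid"` form uses the pooled null variance
$\sqrt{2\bar p\bar q}$ inside the rejection threshold and the alternative
variance $\sqrt{p_1q_1 + p_2q_2}$ in the denominator; the `"wald"` form
uses the alternative variance in both places. At $\alpha = 5\times10^{-8}$,
$p_2 = 0.01$, $OR = 3$ the hybrid form needs 4,058 total subjects for 80%
power and the Wald form 4,042 — a 0.4% spread. The hybrid form is the
default because it is the standard score-test-based design formula and
lands on the published 4,060-subject worked example to within rounding of
that design grid; since the printed example pins the convention only to
within ~20 subjects, both are kept available via the `variance` argument.

`min_sample_size()` searches even total subject counts (equal arms) by
exponential bracketing plus bisection, exploiting monotonicity of power in
$n$; tests verify it against a plain linear scan. Normal quantiles at
genome-wide $\alpha$ come from `qnorm(alpha/2, lower.tail = FALSE)`, which
is accurate deep in the tail, so no special tail machinery is needed.

## Effect-size interpretation

Cohen's conventional benchmarks for h (0.2 / 0.5 / 0.8) were calibrated
for proportions near one half; at GWAS MAFs almost no variant ever reaches
$|h| = 0.2$, so they classify everything as "mild". The package therefore
ships OR-anchored band schemes (`threshold_scheme()`):

* common variants — $|h| \le 0.075$ mild, $\le 0.15$ moderate
  (OR anchors 1.2 and 1.5);
* rare variants — $|h| \le 0.05$ mild, $\le 0.1$ moderate
  (OR anchors 1.5 and 2);
* `"cohen"` — the conventional 0.2 / 0.5 benchmarks, kept for comparison.

Boundary values fall in the lower band. `derive_h_thresholds()` re-derives
OR-equivalent h cuts by averaging `h_from_or(cut, p2)` over a uniform MAF
grid (step 0.001). The averaging behind the published rare cuts is
under-specified: a uniform average over (0.002, 0.05] gives 0.068 / 0.125
rather than 0.05 / 0.1, consistent with the published values reflecting a
low-MAF-skewed empirical spectrum rather than a uniform one. For that
reason the shipped schemes are fixed constants — classification never
depends on the re-derivation — and `derive_h_thresholds()` is provided as
an exploration tool whose common-range output (0.078 / 0.177 vs 0.075 /
0.15) is within 20% of the published bands.

## Quality control

`snp_qc()` applies four per-SNP exclusion criteria, all evaluated for
every variant (no short-circuiting, so a bad variant reports every reason):

1. control MAF < 0.002 (below which a cohort of ~3,000 has under 3 expected
   carriers of any genotype);
2. call rate < 95% over all subjects;
3. Hardy–Weinberg exact-test p < 5.7×10⁻⁷ in controls;
4. allele-frequency difference between the two control sub-cohorts
   (pooled-variance two-proportion score test, the same convention as the
   RD test) p < 5.7×10⁻⁷.

The HWE test is the conditional exact test: given the observed allele
counts, heterozygote counts of matching parity are enumerated and all
outcomes no more probable than the observed one are summed
(point-probability rule, with a 10⁻⁷ relative tie tolerance). Probabilities
are computed on the log scale and renormalized over the support, so margins
in the tens of thousands are handled without overflow. Missing genotypes
are excluded from allele and genotype counts; call rate is non-missing over
total subjects; MAF is folded to the minor allele over controls.

## Synthetic data and Monte-Carlo calibration

The generator (`sim_spec()` / `simulate_counts()`) draws allele counts
directly: $x_2 \sim \mathrm{Bin}(2m_2, p_2)$, $x_1 \sim \mathrm{Bin}(2m_1,
p_1)$ with $p_1$ from the odds-ratio inversion. This is exactly
Hardy–Weinberg sampling of genotypes followed by allele counting, i.e. the
model under which all the asymptotics above are derived. Defaults encode
the calibration design the package targets: arms of 1,480 and 1,458
subjects (a homogeneous pool of 2,938 controls split at random into
pseudo-cases and pseudo-controls — `pseudo_case_control()` performs the
split on real genotype matrices) and a common-MAF spectrum uniform on
(0.05, 0.5).

`null_calibration()` reports, per measure, the bias (grand mean of
estimates over variant × replicate cells; the truth is 0), the MSE (grand
mean of squares) and the empirical type I error of each measure's own
asymptotic test at the nominal level, without the exact fallback — the
point is to calibrate the asymptotics. Undefined log-OR cells are counted
and excluded from the OR's summaries ("bias per replication" could also be
read as a per-replication mean before averaging; the grand mean used here
is identical in expectation). Under this null the stabilized prediction is
sharp: $\mathrm{MSE}(\hat h) = 1/2960 + 1/2916 \approx 0.00068$ whatever
the MAF spectrum, while $\mathrm{MSE}(\log\widehat{OR})$ at rare MAFs is an
order of magnitude larger. `empirical_power()` is the same machinery under
`or_alt != 1`, with undefined-OR cells counted as non-rejections — the
real-world power cost of the OR at rare MAFs.

What the generator does **not** emulate: linkage disequilibrium between
variants, population stratification, genotyping error and differential
missingness, and realistic site-frequency spectra from demography and
selection. Passing calibration here shows the statistics behave as derived
under ideal binomial sampling; it does not certify behaviour on structured
real cohorts, where the same tests are known to inflate slightly for rare
variants.

## Problem sizes and numerical choices

The shipped test-suite and acceptance runs use: 2×10⁵ null cells for
calibration targets (Monte-Carlo SE of a 0.05 rejection rate ≈ 0.0005;
of the h MSE ≈ 2×10⁻⁶), 2×10⁴ replicates for analytic-vs-empirical power
cross-checks, exhaustive enumeration up to 2×2 margin totals of 60 and HWE
genotype totals of 50, and all randomness routed through per-spec seeds
(`with_seed` keeps the global RNG stream untouched). P-values are never
rounded to zero on output: values below 10⁻³⁰⁰ serialize as `"<1e-300"`,
values below 10⁻⁴ in scientific notation, everything at six significant
digits, so result files are byte-reproducible.

## Known limitations

* Allelic tests only: no genotypic trend test, dominance/recessive codings,
  covariates, or stratified (CMH) analysis.
* The exact fallback uses the plain (not mid-p) Fisher rule; QC uses the
  plain (not mid-p) HWE exact test.
* Power formulas assume equal arms; unequal designs are out of scope.
* Burden/collapsing joint tests of rare-variant sets are out of scope — the
  package is a single-marker toolkit intended, among other things, to feed
  such analyses.
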