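test_that("power collapses to alpha under the null alternative", {
  for (a in c(0.05, 5e-8)) {
    expect_equal(power_two_proportion(500, p2 = 0.2, or = 1, alpha = a), a,
                 tolerance = 1e-10)
    expect_equal(power_h(500, delta = 0, alpha = a), a, tolerance = 1e-10)
  }
})

test_that("the genome-wide design worked example reproduces", {
  # OR = 3 at control MAF 0.01, 2,030 subjects per arm (4,060 alleles/group)
  p_2prop <- power_two_proportion(4060, p2 = 0.01, or = 3, alpha = 5e-8)
  expect_gte(p_2prop, 0.80)
  expect_lt(p_2prop, 0.82)
  p_h <- power_h(4060, or = 3, p2 = 0.01, alpha = 5e-8)
  expect_equal(p_h, 0.85, tolerance = 0.01)
  # the h test dominates at this rare MAF
  expect_gt(p_h, p_2prop)
  # wald variance convention is close but not identical
  p_wald <- power_two_proportion(4060, p2 = 0.01, or = 3, alpha = 5e-8,
                                 variance = "wald")
  expect_equal(p_wald, 0.804, tolerance = 0.002)
  expect_false(isTRUE(all.equal(p_2prop, p_wald)))
})

test_that("power is strictly increasing in n and in effect size", {
  ns <- seq(500, 6000, by = 500)
  expect_true(all(diff(power_two_proportion(ns, p2 = 0.01, or = 2,
                                            alpha = 5e-8)) > 0))
  expect_true(all(diff(power_h(ns, delta = 0.1, alpha = 5e-8)) > 0))
  ors <- seq(1.2, 4, by = 0.2)
  pw <- vapply(ors, function(o)
    power_two_proportion(2000, p2 = 0.01, or = o, alpha = 5e-8), numeric(1))
  expect_true(all(diff(pw) > 0))
  deltas <- seq(0.02, 0.3, by = 0.02)
  expect_true(all(diff(power_h(2000, delta = deltas, alpha = 5e-8)) > 0))
})

test_that("h and two-proportion powers agree in the small-effect limit", {
  # delta-method equivalence at p2 = 0.3 with OR -> 1+
  p2 <- 0.3; or <- 1.02; n <- 2e6
  ph <- power_h(n, or = or, p2 = p2, alpha = 0.05)
  p2p <- power_two_proportion(n, p2 = p2, or = or, alpha = 0.05)
  expect_equal(ph, p2p, tolerance = 0.01)
})

test_that("analytic power matches empirical rejection rates", {
  z99 <- 2.576
  # two-proportion test at alpha 0.05, p2 = 0.2, OR = 2, 200 alleles/group
  an <- power_two_proportion(200, p2 = 0.2, or = 2, alpha = 0.05)
  set.seed(314)
  reps <- 20000
  p1 <- or_to_case_maf(2, 0.2)
  x1 <- rbinom(reps, 200, p1); x2 <- rbinom(reps, 200, 0.2)
  emp <- mean(rd_score_test(data.frame(x1 = x1, n1 = 200, x2 = x2,
                                       n2 = 200))$p.value < 0.05)
  expect_lt(abs(emp - an), z99 * sqrt(an * (1 - an) / reps) + 0.005)
  # h test at alpha 0.05, delta = 0.1, 2,000 alleles/group
  anh <- power_h(2000, delta = 0.1, alpha = 0.05)
  p2 <- 0.1
  p1 <- sin((0.1 + 2 * asin(sqrt(p2))) / 2)^2  # MAF pair realizing delta = 0.1
  x1 <- rbinom(reps, 2000, p1); x2 <- rbinom(reps, 2000, p2)
  emph <- mean(h_test(data.frame(x1 = x1, n1 = 2000, x2 = x2,
                                 n2 = 2000))$p.value < 0.05)
  expect_lt(abs(emph - anh), z99 * sqrt(anh * (1 - anh) / reps) + 0.005)
})

test_that("minimum sample size search agrees with a linear-scan oracle", {
  cases <- list(
    list(target = 0.8, p2 = 0.05, or = 2, alpha = 1e-4,
         method = "two_proportion"),
    list(target = 0.9, p2 = 0.2, or = 1.5, alpha = 0.05,
         method = "two_proportion"),
    list(target = 0.5, delta = 0.15, alpha = 0.001, method = "h"),
    list(target = 0.8, delta = 0.08, alpha = 0.05, method = "h")
  )
  for (cs in cases) {
    got <- min_sample_size(cs$target, p2 = cs$p2, or = cs$or,
                           delta = cs$delta, alpha = cs$alpha,
                           method = cs$method)
    powfun <- if (cs$method == "two_proportion") {
      function(n) power_two_proportion(n, p2 = cs$p2, or = cs$or,
                                       alpha = cs$alpha)
    } else {
      function(n) power_h(n, delta = cs$delta, alpha = cs$alpha)
    }
    expect_equal(got, min_n_oracle(cs$target, powfun))
    expect_gte(powfun(got), cs$target)
    if (got > 2) expect_lt(powfun(got - 2), cs$target)
  }
})

test_that("minimum sample size round-trips across a target grid", {
  for (target in c(0.5, 0.8, 0.9)) {
    n <- min_sample_size(target, p2 = 0.01, or = 3, alpha = 5e-8)
    expect_gte(power_two_proportion(n, p2 = 0.01, or = 3, alpha = 5e-8),
               target)
    expect_lt(power_two_proportion(n - 2, p2 = 0.01, or = 3, alpha = 5e-8),
              target)
    nh <- min_sample_size(target, delta = 0.13, alpha = 5e-8, method = "h")
    expect_gte(power_h(nh, delta = 0.13, alpha = 5e-8), target)
    expect_lt(power_h(nh - 2, delta = 0.13, alpha = 5e-8), target)
  }
  # a target barely above alpha is met at the smallest admissible size
  expect_equal(min_sample_size(0.051, p2 = 0.3, or = 1.5, alpha = 0.05), 2)
  expect_error(min_sample_size(0.8, p2 = 0.01, or = 1), "unreachable")
  expect_error(min_sample_size(0.8, delta = 0, method = "h"), "unreachable")
})

test_that("power ratio of h versus two-proportion exceeds 1 on rare grids", {
  tab <- power_ratio_table(p2_grid = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05),
                           n_grid = c(1000, 2000, 4000, 6000, 10000),
                           or = 3, alpha = 5e-8)
  expect_true(all(tab$ratio >= 1))
  expect_equal(nrow(tab), 30)
  # null alternative: both powers are alpha, ratio 1
  tab0 <- power_ratio_table(c(0.01, 0.03), c(1000, 4000), or = 1,
                            alpha = 5e-8)
  expect_equal(tab0$ratio, rep(1, 4), tolerance = 1e-9)
  # the single worked design point: ~0.85 / ~0.80
  tab1 <- power_ratio_table(0.01, 4060, or = 3, alpha = 5e-8)
  expect_equal(tab1$ratio, 1.067, tolerance = 0.01)
  expect_warning(power_ratio_table(c(0.01, 0), c(1000), or = 3), "degenerate")
})
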