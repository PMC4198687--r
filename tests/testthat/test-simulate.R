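test_that("simulation is reproducible given a seed", {
  spec <- sim_spec(n_variants = 50, n_replicates = 3, seed = 123)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(a, b)
  c <- simulate_counts(sim_spec(n_variants = 50, n_replicates = 3,
                                seed = 124))
  expect_false(identical(a$x1, c$x1))
  # seeded runs do not disturb the global RNG stream
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(simulate_counts(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("null draws have binomial moments at the specified MAF", {
  spec <- sim_spec(n_variants = 1e5, n_case_subjects = 100,
                   n_control_subjects = 100, maf = 0.1, or_alt = 1,
                   seed = 2024)
  counts <- simulate_counts(spec)
  se1 <- sqrt(0.1 * 0.9 / (200 * 1e5))
  expect_lt(abs(mean(counts$x1 / counts$n1) - 0.1), 3 * se1)
  expect_lt(abs(mean(counts$x2 / counts$n2) - 0.1), 3 * se1)
  expect_true(all(counts$n1 == 200 & counts$n2 == 200))
})

test_that("alternative draws concentrate on the OR-implied case MAF", {
  spec <- sim_spec(n_variants = 1e5, n_case_subjects = 1000,
                   n_control_subjects = 1000, maf = 0.01, or_alt = 3,
                   seed = 31)
  counts <- simulate_counts(spec)
  p1 <- or_to_case_maf(3, 0.01)
  expect_lt(abs(mean(counts$x1 / counts$n1) - p1),
            3 * sqrt(p1 * (1 - p1) / (2000 * 1e5)))
  # mean of the defined per-draw ORs agrees with an independent binomial
  # resampling oracle within Monte-Carlo error
  est <- effect_estimates(counts)
  set.seed(1234)
  ox1 <- rbinom(1e5, 2000, p1); ox2 <- rbinom(1e5, 2000, 0.01)
  o_def <- ox1 > 0 & ox1 < 2000 & ox2 > 0 & ox2 < 2000
  oracle_or <- (ox1[o_def] / (2000 - ox1[o_def])) /
    (ox2[o_def] / (2000 - ox2[o_def]))
  mean_or <- mean(est$or, na.rm = TRUE)
  se_comb <- sqrt(var(oracle_or) / sum(o_def) +
                    var(est$or, na.rm = TRUE) / sum(!is.na(est$or)))
  expect_lt(abs(mean_or - mean(oracle_or)), 4 * se_comb)
})

test_that("pseudo case-control split is a seeded exhaustive partition", {
  split <- pseudo_case_control(2938, 1480, seed = 1)
  expect_length(split$pseudo_case, 1480)
  expect_length(split$pseudo_control, 1458)
  expect_equal(sort(c(split$pseudo_case, split$pseudo_control)), 1:2938)
  expect_identical(split, pseudo_case_control(2938, 1480, seed = 1))
  expect_false(identical(split$pseudo_case,
                         pseudo_case_control(2938, 1480, seed = 2)$pseudo_case))
  expect_error(pseudo_case_control(100, 100), "smaller")
})

test_that("null calibration recovers bias ~ 0, stabilized MSE, nominal size", {
  spec <- sim_spec(n_variants = 2e5, seed = 55)  # 1,480 / 1,458 subject arms
  rep <- null_calibration(spec, level = 0.05)
  expect_equal(rep$measure, c("rd", "h", "log_or"))
  h_row <- rep[rep$measure == "h", ]
  expect_lt(abs(h_row$bias), 0.001)
  expect_equal(h_row$mse, 1 / 2960 + 1 / 2916, tolerance = 0.02)
  expect_true(all(abs(rep$type1_rate - 0.05) < 0.01))
  expect_true(all(rep$mse >= rep$bias^2))
  expect_equal(h_row$n_undefined, 0)
})

test_that("stabilized h MSE is MAF-free while log-OR MSE blows up when rare", {
  mse_of <- function(maf_lo, maf_hi, seed) {
    null_calibration(sim_spec(n_variants = 3e4, maf_range = c(maf_lo, maf_hi),
                              seed = seed))
  }
  at_01 <- null_calibration(sim_spec(n_variants = 3e4, maf = 0.1, seed = 61))
  at_04 <- null_calibration(sim_spec(n_variants = 3e4, maf = 0.4, seed = 62))
  ratio <- at_01$mse[at_01$measure == "h"] / at_04$mse[at_04$measure == "h"]
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  rare <- mse_of(0.002, 0.05, 63)
  expect_gt(rare$mse[rare$measure == "log_or"],
            10 * rare$mse[rare$measure == "h"])
})

test_that("degenerate single-cell calibration reduces to the raw estimate", {
  spec <- sim_spec(n_variants = 1, maf = 0.3, seed = 8)
  counts <- simulate_counts(spec)
  rep <- null_calibration(spec)
  est <- effect_estimates(counts)
  expect_equal(rep$bias[rep$measure == "h"], est$h)
  expect_equal(rep$mse[rep$measure == "h"], est$h^2)
  expect_true(all(rep$type1_rate %in% c(0, 1)))
  expect_error(null_calibration(sim_spec(n_variants = 5, or_alt = 2)),
               "or_alt = 1")
})

test_that("empirical power tracks the analytic formulas and monotonicity", {
  # p2 = 0.2, OR = 2, 1,000 subjects/arm (2,000 alleles/group), alpha 0.05
  spec <- sim_spec(n_variants = 2e4, n_case_subjects = 1000,
                   n_control_subjects = 1000, maf = 0.2, or_alt = 2,
                   seed = 71)
  emp <- empirical_power(spec, level = 0.05)
  an_h <- power_h(2000, or = 2, p2 = 0.2, alpha = 0.05)
  got_h <- emp$power[emp$measure == "h"]
  expect_lt(abs(got_h - an_h), 3 * sqrt(an_h * (1 - an_h) / 2e4) + 0.005)
  # deliberately null spec: power recovers the level
  null_emp <- empirical_power(sim_spec(n_variants = 2e4, maf = 0.2,
                                       seed = 72), level = 0.05)
  expect_true(all(abs(null_emp$power - 0.05) < 0.01))
  # power grows with sample size
  pw_at <- vapply(c(200, 600, 1800), function(m) {
    e <- empirical_power(sim_spec(n_variants = 5e3, n_case_subjects = m,
                                  n_control_subjects = m, maf = 0.05,
                                  or_alt = 2, seed = 73 + m), level = 0.05)
    e$power[e$measure == "h"]
  }, numeric(1))
  expect_true(all(diff(pw_at) > 0))
})
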