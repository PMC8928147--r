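test_that("cohen's d uses the equal-weight pooled SD", {
  expect_equal(round(cohens_d(17.3, 3.7, 22.6, 4.6)$d, 2), 1.27)
  expect_equal(round(cohens_d(3.2, 0.6, 3.4, 0.5)$d, 4), 0.3621)
  expect_equal(round(cohens_d(70.1, 21.7, 82.6, 21.2)$d, 2), 0.58)
  expect_equal(cohens_d(0.9, 0.1, 0.9, 0.1)$d, 0)
  expect_equal(cohens_d(1, 2, 5, 2)$pooled_sd, 2)
  expect_error(cohens_d(1, 0, 2, 1), "positive")
})

test_that("t-test power matches stats::power.t.test", {
  # power.t.test drops the opposite-tail rejection mass, so two-sided
  # comparisons agree only to ~1e-3 at small n; one-sided is exact.
  for (d in c(0.3, 0.8)) for (n in c(10, 40)) {
    spec <- power_spec("t_test", effect = d, alpha_level = 0.05, tails = "two")
    mine <- power_posthoc(spec, n, n)$achieved_power
    ref <- stats::power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05,
                               type = "two.sample")$power
    expect_gte(mine, ref)
    expect_lt(mine - ref, 5e-3)  # the dropped tail is tiny
  }
  spec1 <- power_spec("t_test", effect = 0.5, tails = "one")
  ref1 <- stats::power.t.test(n = 30, delta = 0.5, sd = 1, sig.level = 0.05,
                              type = "two.sample", alternative = "one.sided")$power
  expect_equal(power_posthoc(spec1, 30, 30)$achieved_power, ref1, tolerance = 1e-8)
})

test_that("wmw power shrinks ncp and df by the A.R.E. and degenerates to t at are = 1", {
  spec <- power_spec("wmw", effect = 0.5, alpha_level = 0.05, tails = "one")
  sol <- power_posthoc(spec, 53, 53)
  expect_equal(sol$noncentrality, 0.5 * sqrt((3 / pi) * 53 * 53 / 106),
               tolerance = 1e-12)
  expect_equal(sol$df, 104 * 3 / pi, tolerance = 1e-12)
  expect_equal(round(sol$achieved_power, 3), 0.803)
  # t power dominates wmw power under the normal-parent A.R.E.
  tspec <- power_spec("t_test", effect = 0.5, tails = "one")
  for (d in c(0.2, 0.5, 1)) for (n in c(10, 30, 80)) {
    s1 <- power_spec("wmw", effect = d, tails = "one")
    s2 <- power_spec("t_test", effect = d, tails = "one")
    expect_lte(power_posthoc(s1, n, n)$achieved_power,
               power_posthoc(s2, n, n)$achieved_power + 1e-12)
  }
  # are = 1 (forced via t_test spec) equals the wmw machinery at are = 1
  w <- power_spec("wmw", effect = 0.7, tails = "two")
  w$are <- 1
  t <- power_spec("t_test", effect = 0.7, tails = "two")
  expect_equal(power_posthoc(w, 20, 20)$achieved_power,
               power_posthoc(t, 20, 20)$achieved_power, tolerance = 1e-12)
})

test_that("a null effect gives power equal to alpha (one-tailed)", {
  spec <- power_spec("wmw", effect = 0, alpha_level = 0.05, tails = "one")
  expect_equal(power_posthoc(spec, 50, 50)$achieved_power, 0.05, tolerance = 1e-10)
})

test_that("power increases in n and in d; sample_size inverts power_posthoc", {
  spec <- power_spec("wmw", effect = 0.4, tails = "one")
  p <- vapply(c(10, 20, 40, 80), function(n)
    power_posthoc(spec, n, n)$achieved_power, numeric(1))
  expect_true(all(diff(p) > 0))
  pd <- vapply(c(0.2, 0.4, 0.8), function(d) {
    s <- power_spec("wmw", effect = d, tails = "one")
    power_posthoc(s, 30, 30)$achieved_power
  }, numeric(1))
  expect_true(all(diff(pd) > 0))
  for (target in c(0.8, 0.9)) {
    sol <- sample_size(spec, target)
    expect_gte(sol$achieved_power, target)
    expect_lt(power_posthoc(spec, sol$n1 - 1, sol$n2 - 1)$achieved_power, target)
  }
  expect_error(sample_size(power_spec("wmw", effect = 0), 0.8), "unattainable")
})

test_that("table-4 style a-priori wmw solution is reproduced", {
  spec <- power_spec("wmw", effect = 0.5, alpha_level = 0.05, tails = "one",
                     allocation_ratio = 1)
  sol <- sample_size(spec, 0.8)
  expect_equal(sol$n_total, 106)
  expect_equal(sol$n1, 53)
  expect_equal(round(sol$achieved_power, 3), 0.803)
})

test_that("large-sample power agrees with the normal approximation", {
  # closed form: power = Phi(d*sqrt(are*n/2) - z_{1-alpha}) for one tail
  for (d in c(0.2, 0.4)) {
    n <- 400
    spec <- power_spec("wmw", effect = d, tails = "one")
    approx <- pnorm(d * sqrt((3 / pi) * n / 2) - qnorm(0.95))
    expect_equal(power_posthoc(spec, n, n)$achieved_power, approx,
                 tolerance = 0.005)
  }
  # doubling d shrinks required N about fourfold
  n1 <- sample_size(power_spec("wmw", effect = 0.2, tails = "one"), 0.8)$n_total
  n2 <- sample_size(power_spec("wmw", effect = 0.4, tails = "one"), 0.8)$n_total
  expect_equal(n1 / n2, 4, tolerance = 0.08)
})

test_that("anova sizing searches the total N with lambda = f^2 N", {
  spec <- power_spec("anova", effect = 0.38, alpha_level = 0.01, groups = 2)
  sol <- sample_size(spec, 0.8)
  expect_equal(sol$n_total, 85)
  expect_equal(sol$n1, 42.5)
  direct <- 1 - pf(qf(0.99, 1, 83), 1, 83, ncp = 0.38^2 * 85)
  expect_equal(sol$achieved_power, direct, tolerance = 1e-12)
  expect_lt(1 - pf(qf(0.99, 1, 82), 1, 82, ncp = 0.38^2 * 84), 0.8)
})

test_that("sample_size_curve orders N inversely with effect and flags d = 0", {
  spec <- power_spec("wmw", effect = 1, alpha_level = 0.05, tails = "one")
  cv <- sample_size_curve(c(pd = 1.27, shannon = 0.3621, chao1 = 0.58, simpson = 0),
                          spec, 0.8)
  attainable <- cv[cv$attainable, ]
  expect_true(all(diff(attainable$n_total[order(attainable$effect)]) < 0))
  expect_false(cv$attainable[cv$label == "simpson"])
  expect_equal(cv$n_total[cv$label == "simpson"], Inf)
  single <- sample_size_curve(c(x = 0.5), spec, 0.8)
  expect_equal(nrow(single), 1L)
})
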