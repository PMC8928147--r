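test_that("kruskal-wallis reproduces direct rank arithmetic and eta-squared", {
  # groups (1,2,3) vs (4,5,6): ranks 1..6, mean ranks 2 and 5
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  h_direct <- 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7
  expect_equal(kw$h, h_direct, tolerance = 1e-12)
  expect_equal(kw$df, 1L)
  expect_equal(kw$eta_squared, (h_direct - 2 + 1) / (6 - 2), tolerance = 1e-12)
  expect_equal(kw$p_value,
               stats::kruskal.test(c(1, 2, 3, 4, 5, 6),
                                   factor(rep(c("a", "b"), each = 3)))$p.value)
})

test_that("kruskal-wallis handles complete ties and is rank-invariant", {
  kw <- kruskal_wallis(rep(2.5, 8), rep(c("a", "b"), 4))
  expect_equal(kw$h, 0)
  expect_equal(kw$p_value, 1)
  set.seed(31)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(v, g)$h, kruskal_wallis(exp(v), g)$h,
               tolerance = 1e-12)
})

test_that("two-group kruskal-wallis reports equal-weight cohen's d", {
  v1 <- c(1, 2, 3, 4)
  v2 <- c(3, 5, 7, 9)
  kw <- kruskal_wallis(c(v1, v2), rep(c("a", "b"), each = 4))
  expect_equal(kw$cohens_d,
               abs(mean(v1) - mean(v2)) / sqrt((sd(v1)^2 + sd(v2)^2) / 2))
})

test_that("permanova pseudo-F equals classical anova F on univariate euclidean data", {
  set.seed(32)
  for (i in 1:10) {
    k <- sample(2:3, 1)
    n_per <- sample(4:8, 1)
    v <- rnorm(k * n_per, mean = rep(seq_len(k), each = n_per))
    g <- factor(rep(letters[1:k], each = n_per))
    d <- as.matrix(dist(matrix(v, ncol = 1,
                               dimnames = list(paste0("s", seq_along(v)), NULL))))
    pm <- permanova(d, g, permutations = 19, seed = 1)
    f_aov <- summary(stats::aov(v ~ g))[[1]]$`F value`[1]
    expect_equal(pm$pseudo_f, f_aov, tolerance = 1e-8)
    expect_equal(pm$ss_between + pm$ss_within, pm$ss_total, tolerance = 1e-8)
  }
})

test_that("permanova agrees with vegan::adonis2 and is label/order invariant", {
  set.seed(33)
  x <- random_table(18, 25)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  d <- bray_curtis(x)
  pm <- permanova(d, g, permutations = 99, seed = 5)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$ss_between, ad$SumOfSqs[1], tolerance = 1e-10)
  # group relabeling leaves F unchanged
  g2 <- factor(c("b", "c", "a")[as.integer(g)])
  expect_equal(permanova(d, g2, permutations = 9, seed = 1)$pseudo_f, pm$pseudo_f)
  # sample reordering (named design) leaves F unchanged
  ord <- sample(rownames(d))
  gn <- group_design(as.character(g), rownames(d))
  expect_equal(permanova(d[ord, ord], gn, permutations = 9, seed = 1)$pseudo_f,
               pm$pseudo_f, tolerance = 1e-12)
})

test_that("permutation p-values are seeded, bounded and reproducible", {
  set.seed(34)
  x <- random_table(12, 20)
  g <- factor(rep(c("a", "b"), each = 6))
  d <- jaccard(x)
  p1 <- permanova(d, g, permutations = 199, seed = 7)
  p2 <- permanova(d, g, permutations = 199, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 200)
  expect_lte(p1$p_value, 1)
  expect_error(permanova(d, g, permutations = 0), "at least one permutation")
  expect_error(permanova(d, factor(c("a", rep("b", 11)))), "singleton")
})

test_that("effect sizes follow their defining formulas", {
  expect_equal(cohens_f2_from_f(6.27, 1, 68), 6.27 / 68)
  set.seed(35)
  x <- random_table(16, 30)
  g <- factor(rep(c("a", "b"), each = 8))
  pm <- permanova(bray_curtis(x), g, permutations = 49, seed = 2)
  expect_equal(pm$cohens_f2, pm$ss_between / pm$ss_within)
  ms_w <- pm$ss_within / pm$df_within
  expect_equal(pm$omega_squared,
               (pm$ss_between - pm$df_between * ms_w) / (pm$ss_total + ms_w))
})

test_that("report lines match the standardized single-line format", {
  kw <- structure(list(h = 14.68, df = 1L, p_value = 1e-04, n = 70, k = 2L,
                       eta_squared = 0.2012, cohens_d = 0.58),
                  class = "kw_test")
  expect_equal(report_line(kw), "H(1) = 14.68, p = 0.0001, eta2 = 0.20, d = 0.58")
  pm <- structure(list(pseudo_f = 6.27, df_between = 1L, df_within = 68L,
                       p_value = 1e-04, cohens_f2 = 0.0922),
                  class = "permanova")
  expect_equal(report_line(pm), "F(1, 68) = 6.27, p = 0.0001, f2 = 0.092")
  kw0 <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))
  expect_match(report_line(kw0), "^H\\(1\\) = 0.00, p = 1.0000")
})
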