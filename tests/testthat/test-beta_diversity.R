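test_that("bray-curtis reproduces the defining arithmetic and bounds", {
  x <- rbind(s1 = c(2, 0, 6), s2 = c(1, 3, 4))
  colnames(x) <- paste0("f", 1:3)
  d <- bray_curtis(x)
  expect_equal(unname(d["s1", "s2"]), 1 - 2 * 5 / 16)
  ident <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  colnames(ident) <- paste0("f", 1:3)
  expect_equal(unname(bray_curtis(ident)["a", "b"]), 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 7))
  colnames(disjoint) <- c("f1", "f2")
  expect_equal(unname(bray_curtis(disjoint)["a", "b"]), 1)
  zero <- rbind(a = c(1, 1), b = c(0, 0))
  colnames(zero) <- c("f1", "f2")
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("jaccard works on presence/absence and relates to binary bray-curtis", {
  x <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))
  colnames(x) <- paste0("f", 1:4)
  expect_equal(unname(jaccard(x)["s1", "s2"]), 0.5)
  same <- x[c(1, 1), ]
  rownames(same) <- c("p", "q")
  expect_equal(unname(jaccard(same)["p", "q"]), 0)
  set.seed(21)
  for (i in 1:5) {
    b <- random_table(6, 15, lambda = 0.8) > 0
    storage.mode(b) <- "double"
    bc <- bray_curtis(b)
    expect_equal(jaccard(b), 2 * bc / (1 + bc), tolerance = 1e-12)
  }
})

test_that("unifrac distances match brute-force edge enumeration on random trees", {
  set.seed(22)
  for (i in 1:6) {
    tr <- random_tree(12)
    x <- random_table(4, 12, lambda = 0.9)
    colnames(x) <- tr$tip.label
    uf <- unweighted_unifrac(x, tr)
    wraw <- weighted_unifrac(x, tr)
    wnorm <- weighted_unifrac(x, tr, normalized = TRUE)
    for (a in 1:3) for (b in (a + 1):4) {
      expect_equal(uf[a, b],
                   oracle_unifrac_pair(x[a, ], x[b, ], tr), tolerance = 1e-12)
      expect_equal(wraw[a, b],
                   oracle_unifrac_pair(x[a, ], x[b, ], tr, weighted = TRUE),
                   tolerance = 1e-12)
      expect_equal(wnorm[a, b],
                   oracle_unifrac_pair(x[a, ], x[b, ], tr, weighted = TRUE,
                                       normalized = TRUE), tolerance = 1e-12)
    }
    expect_true(all(uf >= 0 & uf <= 1 + 1e-12))
    expect_true(all(wnorm >= 0 & wnorm <= 1 + 1e-12))
  }
})

test_that("unweighted unifrac hits its extremes and ignores abundance", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- rbind(s1 = c(A = 3, B = 1, C = 0, D = 0),
             s2 = c(A = 0, B = 0, C = 2, D = 9))
  expect_equal(unname(unweighted_unifrac(x, tr)["s1", "s2"]), 1)
  same <- x[c(1, 1), ]
  rownames(same) <- c("p", "q")
  expect_equal(unname(unweighted_unifrac(same, tr))[1, 2], 0)
  set.seed(23)
  y <- random_table(5, 12)
  tr2 <- random_tree(12)
  ybin <- (y > 0) + 0
  expect_equal(unweighted_unifrac(y, tr2), unweighted_unifrac(ybin, tr2))
})

test_that("weighted unifrac: star-tree extremes and proportion invariance", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  x <- rbind(s1 = c(A = 10, B = 0, C = 0), s2 = c(A = 0, B = 4, C = 0))
  expect_equal(unname(weighted_unifrac(x, star)["s1", "s2"]), 2)
  expect_equal(unname(weighted_unifrac(x, star, normalized = TRUE)["s1", "s2"]), 1)
  set.seed(24)
  y <- random_table(4, 10)
  tr <- random_tree(10)
  scaled <- sweep(y, 1, c(1, 13, 0.3, 7), "*")  # rescale sample totals
  expect_equal(weighted_unifrac(scaled, tr), weighted_unifrac(y, tr),
               tolerance = 1e-12)
  # bray-curtis is NOT total-invariant
  expect_false(isTRUE(all.equal(bray_curtis(scaled), bray_curtis(y))))
  # identical profiles -> zero
  same <- y[c(1, 1), ]
  rownames(same) <- c("p", "q")
  expect_equal(unname(weighted_unifrac(same, tr))[1, 2], 0)
})

test_that("all metrics return symmetric zero-diagonal matrices in range", {
  set.seed(25)
  x <- random_table(6, 20)
  tr <- random_tree(20)
  for (m in c("braycurtis", "jaccard", "unweighted_unifrac", "weighted_unifrac")) {
    d <- beta_diversity(x, m, tree = tr)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d >= 0))
    if (m != "weighted_unifrac") expect_true(all(d <= 1 + 1e-12))
  }
})

test_that("group centroid distances match direct coordinates for euclidean input", {
  set.seed(26)
  pts <- matrix(rnorm(24), ncol = 2)
  rownames(pts) <- paste0("s", 1:12)
  d <- as.matrix(dist(pts))
  g <- group_design(rep(c("a", "b"), each = 6), rownames(pts))
  res <- group_centroid_distances(d, g)
  direct <- sapply(rownames(pts), function(s) {
    cen <- colMeans(pts[names(g)[g == g[s]], , drop = FALSE])
    sqrt(sum((pts[s, ] - cen)^2))
  })
  expect_equal(unname(res$distances[names(direct)]), unname(direct),
               tolerance = 1e-8)

  # 1-D pair at 0 and 2 in one group: both distances 1
  d2 <- as.matrix(dist(matrix(c(0, 2), ncol = 1,
                              dimnames = list(c("u", "v"), NULL))))
  g2 <- group_design(c("g", "g", "h", "h"), c("u", "v", "w", "z"))
  d4 <- matrix(0, 4, 4, dimnames = list(c("u", "v", "w", "z"),
                                        c("u", "v", "w", "z")))
  d4[1:2, 1:2] <- d2
  d4["w", "z"] <- d4["z", "w"] <- 1
  d4["u", "w"] <- d4["w", "u"] <- 5; d4["u", "z"] <- d4["z", "u"] <- 5
  d4["v", "w"] <- d4["w", "v"] <- 5; d4["v", "z"] <- d4["z", "v"] <- 5
  res2 <- group_centroid_distances(d4, g2)
  expect_equal(unname(res2$distances[c("u", "v")]), c(1, 1), tolerance = 1e-8)

  # identical samples in one group -> zero distances
  same <- matrix(0, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  gsame <- group_design(c("g", "g"), c("p", "q"))
  res3 <- group_centroid_distances(same, gsame)
  expect_equal(unname(res3$distances), c(0, 0), tolerance = 1e-10)
})
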