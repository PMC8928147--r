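#' Resampling scheme for empirical power estimation
#'
#' Defines the grid of per-group sample sizes, the number of resampled
#' replicate datasets per grid point, the significance threshold and the
#' master seed. Defaults follow common practice for retrospective microbiome
#' power calculations: per-group sizes 5 to 50 in steps of 5, K = 1000
#' replicates for univariate (alpha) tests, alpha = 0.01. Multivariate (beta)
#' analyses typically use K = 100 because each replicate runs a permutation
#' test.
#'
#' @param n_grid increasing integer vector of per-group sizes (all >= 2).
#' @param K replicates per grid point.
#' @param alpha_level rejection threshold.
#' @param seed master seed; all replicate draws and permutation streams derive
#'   from it, so a scheme reproduces its curves exactly.
#' @return object of class `"subsample_scheme"`.
#' @export
subsample_scheme <- function(n_grid = seq(5L, 50L, by = 5L), K = 1000L,
                             alpha_level = 0.01, seed = 1L) {
  n_grid <- as.integer(n_grid)
  if (any(n_grid < 2L)) stop("all grid sizes must be >= 2")
  if (is.unsorted(n_grid, strictly = TRUE)) stop("n_grid must be strictly increasing")
  if (K < 1L) stop("K must be >= 1")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in (0, 1)")
  structure(list(n_grid = n_grid, K = as.integer(K),
                 alpha_level = alpha_level, seed = as.integer(seed)),
            class = "subsample_scheme")
}

# one sub-seed per (grid point, replicate); drawing them all from the master
# seed up front makes every replicate an independent reproducible stream.
scheme_seeds <- function(scheme) {
  set.seed(scheme$seed)
  matrix(sample.int(.Machine$integer.max - 1L,
                    length(scheme$n_grid) * scheme$K, replace = TRUE),
         nrow = scheme$K, ncol = length(scheme$n_grid))
}

#' Draw one resampled two-group dataset
#'
#' Draws `n` rows independently and with replacement from each of `x1` and
#' `x2` (which must share the feature set), suffixing sample identifiers with
#' the draw index so the resampled tables have unique ids.
#'
#' @param x1,x2 source count tables with identical feature columns.
#' @param n per-group size.
#' @param seed optional seed for this draw.
#' @return list with resampled `x1`, `x2` and a `design` factor
#'   (levels `group1`, `group2`) over the combined samples.
#' @export
subsample_pair <- function(x1, x2, n, seed = NULL) {
  validate_count_table(x1)
  validate_count_table(x2)
  if (!identical(colnames(x1), colnames(x2)))
    stop("x1 and x2 must share the same feature set (same order)")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  i1 <- sample.int(nrow(x1), n, replace = TRUE)
  i2 <- sample.int(nrow(x2), n, replace = TRUE)
  s1 <- x1[i1, , drop = FALSE]
  s2 <- x2[i2, , drop = FALSE]
  rownames(s1) <- paste0("g1.", rownames(x1)[i1], "_", seq_len(n))
  rownames(s2) <- paste0("g2.", rownames(x2)[i2], "_", seq_len(n))
  design <- group_design(rep(c("group1", "group2"), each = n),
                         c(rownames(s1), rownames(s2)))
  list(x1 = s1, x2 = s2, design = design, idx1 = i1, idx2 = i2)
}

new_power_curve <- function(metric, test, n_grid, K, rejections, alpha_level) {
  epr <- rejections / K
  ci <- t(vapply(rejections, function(r) {
    ct <- stats::binom.test(r, K)
    ct$conf.int
  }, numeric(2)))
  structure(data.frame(metric = metric, test = test, n = n_grid, K = K,
                       rejections = rejections, power = epr,
                       ci_low = ci[, 1L], ci_high = ci[, 2L],
                       stringsAsFactors = FALSE),
            alpha_level = alpha_level, class = c("power_curve", "data.frame"))
}

#' Empirical power of the Kruskal-Wallis test on an alpha metric
#'
#' For each per-group size n in the scheme's grid, K replicate datasets are
#' drawn with replacement from the two source tables; on each replicate the
#' per-sample alpha metric is computed and a two-group Kruskal-Wallis test is
#' run. The empirical power is the fraction of the K replicates rejecting at
#' the scheme's alpha level. Replicates on which the statistic is degenerate
#' (all values tied) count as non-rejections, keeping the denominator K.
#'
#' Because each resampled row is a row of its source table, per-sample alpha
#' values can be computed once on the sources and sliced per replicate; this
#' is the default. `recompute = TRUE` recomputes the metric from each
#' resampled table instead — the two paths agree exactly and the slow one
#' exists as a cross-check.
#'
#' @param x1,x2 source count tables sharing a feature set.
#' @param metric one of `"observed"`, `"pd"`, `"chao1"`, `"shannon"`,
#'   `"simpson"`.
#' @param scheme a [subsample_scheme()].
#' @param tree tree, required iff `metric = "pd"`.
#' @param recompute recompute metric per replicate instead of slicing.
#' @return a `power_curve` data frame: metric, test, n, K, rejections, power,
#'   and a 95% binomial confidence interval.
#' @export
empirical_power_alpha <- function(x1, x2, metric, scheme, tree = NULL,
                                  recompute = FALSE) {
  stopifnot(inherits(scheme, "subsample_scheme"))
  metric <- match.arg(metric, c("observed", "pd", "chao1", "shannon", "simpson"))
  if (!identical(colnames(x1), colnames(x2)))
    stop("x1 and x2 must share the same feature set (same order)")
  if (!recompute) {
    a1 <- alpha_table(x1, metrics = metric, tree = tree)[[metric]]
    a2 <- alpha_table(x2, metrics = metric, tree = tree)[[metric]]
  }
  validate_count_table(x1)
  validate_count_table(x2)
  seeds <- scheme_seeds(scheme)
  rejections <- integer(length(scheme$n_grid))
  for (i in seq_along(scheme$n_grid)) {
    n <- scheme$n_grid[i]
    grp <- rep(c("group1", "group2"), each = n)
    rej <- 0L
    for (k in seq_len(scheme$K)) {
      set.seed(seeds[k, i])
      i1 <- sample.int(nrow(x1), n, replace = TRUE)
      i2 <- sample.int(nrow(x2), n, replace = TRUE)
      if (recompute) {
        s1 <- x1[i1, , drop = FALSE]; rownames(s1) <- paste0("g1.", seq_len(n))
        s2 <- x2[i2, , drop = FALSE]; rownames(s2) <- paste0("g2.", seq_len(n))
        v1 <- alpha_table(s1, metrics = metric, tree = tree)[[metric]]
        v2 <- alpha_table(s2, metrics = metric, tree = tree)[[metric]]
      } else {
        v1 <- a1[i1]
        v2 <- a2[i2]
      }
      kw <- kruskal_wallis(c(v1, v2), grp)
      if (kw$p_value < scheme$alpha_level) rej <- rej + 1L
    }
    rejections[i] <- rej
  }
  new_power_curve(metric, "kruskal_wallis", scheme$n_grid, scheme$K,
                  rejections, scheme$alpha_level)
}

#' Empirical power of PERMANOVA on a beta metric
#'
#' Same resampling engine as [empirical_power_alpha()], with PERMANOVA on the
#' per-replicate distance matrix. By default the full pooled distance matrix
#' is computed once and sliced per replicate — valid because all four metrics
#' depend only on the pair of rows, so the distance between two resampled
#' samples equals the distance between their source rows. `recompute = TRUE`
#' rebuilds the matrix from each resampled table (cross-check path).
#'
#' @inheritParams empirical_power_alpha
#' @param metric one of `"braycurtis"`, `"jaccard"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param n_permutations PERMANOVA permutations per replicate.
#' @param normalized weighted UniFrac flag.
#' @param keep_effects store per-replicate omega-squared and f-squared values
#'   (needed to render multivariate protocols).
#' @return a `power_curve` data frame; if `keep_effects`, an `"effects"`
#'   attribute holds per-grid-point data frames of observed effect sizes.
#' @export
empirical_power_beta <- function(x1, x2, metric, scheme, tree = NULL,
                                 n_permutations = 999, normalized = FALSE,
                                 recompute = FALSE, keep_effects = TRUE) {
  stopifnot(inherits(scheme, "subsample_scheme"))
  metric <- match.arg(metric, c("braycurtis", "jaccard",
                                "unweighted_unifrac", "weighted_unifrac"))
  if (!identical(colnames(x1), colnames(x2)))
    stop("x1 and x2 must share the same feature set (same order)")
  n1s <- nrow(x1)
  if (!recompute) {
    pooled <- rbind(x1, x2)
    rownames(pooled) <- c(paste0("g1_", rownames(x1)), paste0("g2_", rownames(x2)))
    dall <- beta_diversity(pooled, metric, tree = tree, normalized = normalized)
  }
  validate_count_table(x1)
  validate_count_table(x2)
  seeds <- scheme_seeds(scheme)
  rejections <- integer(length(scheme$n_grid))
  effects <- vector("list", length(scheme$n_grid))
  for (i in seq_along(scheme$n_grid)) {
    n <- scheme$n_grid[i]
    grp <- factor(rep(c("group1", "group2"), each = n))
    rej <- 0L
    om <- f2 <- numeric(scheme$K)
    for (k in seq_len(scheme$K)) {
      set.seed(seeds[k, i])
      i1 <- sample.int(nrow(x1), n, replace = TRUE)
      i2 <- sample.int(nrow(x2), n, replace = TRUE)
      perm_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      if (recompute) {
        s1 <- x1[i1, , drop = FALSE]; rownames(s1) <- paste0("g1.", seq_len(n))
        s2 <- x2[i2, , drop = FALSE]; rownames(s2) <- paste0("g2.", seq_len(n))
        dsub <- beta_diversity(rbind(s1, s2), metric, tree = tree,
                               normalized = normalized)
        dimnames(dsub) <- NULL
      } else {
        sel <- c(i1, n1s + i2)
        dsub <- dall[sel, sel]
        dimnames(dsub) <- NULL
      }
      pm <- permanova(dsub, grp, permutations = n_permutations,
                      seed = perm_seed)
      if (pm$p_value < scheme$alpha_level) rej <- rej + 1L
      om[k] <- pm$omega_squared
      f2[k] <- pm$cohens_f2
    }
    rejections[i] <- rej
    effects[[i]] <- data.frame(omega_squared = om, cohens_f2 = f2)
  }
  curve <- new_power_curve(metric, "permanova", scheme$n_grid, scheme$K,
                           rejections, scheme$alpha_level)
  if (keep_effects) {
    names(effects) <- as.character(scheme$n_grid)
    attr(curve, "effects") <- effects
  }
  attr(curve, "n_permutations") <- n_permutations
  attr(curve, "n_taxa") <- ncol(x1)
  curve
}

#' Minimal sample size reaching a power threshold, per curve
#'
#' @param curves a `power_curve` data frame or a list of them (rbind-ed).
#' @param threshold required power (default 0.8).
#' @return data frame with one row per (metric, test): the smallest grid n
#'   whose empirical power reaches the threshold, `reached = FALSE` and
#'   `n_required = NA` when the curve never gets there.
#' @export
power_report <- function(curves, threshold = 0.8) {
  if (is.list(curves) && !is.data.frame(curves))
    curves <- do.call(rbind, curves)
  if (!nrow(curves)) stop("empty curve set")
  key <- interaction(curves$metric, curves$test, drop = TRUE)
  rows <- lapply(split(curves, key), function(cv) {
    cv <- cv[order(cv$n), ]
    hit <- which(cv$power >= threshold)
    data.frame(metric = cv$metric[1L], test = cv$test[1L],
               threshold = threshold,
               n_required = if (length(hit)) cv$n[hit[1L]] else NA_integer_,
               reached = length(hit) > 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
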