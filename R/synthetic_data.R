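#' Specification of a synthetic microbial community
#'
#' Describes a stool-like 16S community at the scale typical of large human
#' gut surveys: 169 samples by 1995 features, a heavily skewed log-normal
#' rank-abundance curve, Dirichlet-multinomial counts (compositional,
#' overdispersed) at negative-binomially distributed sequencing depths, and
#' strong per-sample sparsity (a typical sample shows well under 5% of the
#' feature pool). The default skew/concentration/depth values are calibrated
#' so that the mean per-sample observed richness is around 70 features.
#'
#' @param n_samples number of samples (rows).
#' @param n_features number of features (columns).
#' @param model `"dirichlet_multinomial"` (default) or `"lognormal_counts"`
#'   (independent Poisson-log-normal counts around the expected profile).
#' @param skew standard deviation of the log-normal rank-abundance curve on
#'   the log scale; larger values concentrate the community on fewer taxa.
#' @param theta Dirichlet concentration: per-sample proportions are drawn from
#'   Dirichlet(theta * p). Smaller values give stronger sample-to-sample
#'   variation and sparser samples.
#' @param depth_mean,depth_dispersion negative-binomial mean and size of the
#'   per-sample sequencing depth.
#' @param lognormal_sd log-scale noise SD for the `"lognormal_counts"` model.
#' @param sparsity_target optional expected per-sample zero fraction; when
#'   set, [generate_base()] warns if the achieved sparsity misses it by more
#'   than 0.05 and reports the achieved value.
#' @param seed integer seed.
#' @return object of class `"community_spec"`.
#' @export
community_spec <- function(n_samples = 169L, n_features = 1995L,
                           model = c("dirichlet_multinomial", "lognormal_counts"),
                           skew = 2, theta = 20, depth_mean = 5000,
                           depth_dispersion = 10, lognormal_sd = 1,
                           sparsity_target = NULL, seed = 1L) {
  model <- match.arg(model)
  if (n_samples < 2L || n_features < 2L)
    stop("need at least 2 samples and 2 features")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (skew <= 0 || theta <= 0) stop("skew and theta must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features), model = model,
                 skew = skew, theta = theta, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 lognormal_sd = lognormal_sd,
                 sparsity_target = sparsity_target, seed = as.integer(seed)),
            class = "community_spec")
}

#' Dense homogeneous community specification
#'
#' Convenience constructor for the second kind of simulated base community:
#' dense and homogeneous (per-sample observed richness around 70% of the
#' feature pool, Shannon around 6.7, between-sample Bray-Curtis near 0.5 with
#' small spread), the regime in which small systematic differential-abundance
#' shifts become detectable. Uses the Poisson-log-normal count model with a
#' gentle rank-abundance curve.
#'
#' @param n_samples,n_features,seed as in [community_spec()].
#' @return a `"community_spec"`.
#' @export
dense_community_spec <- function(n_samples = 169L, n_features = 1995L,
                                 seed = 1L) {
  community_spec(n_samples = n_samples, n_features = n_features,
                 model = "lognormal_counts", skew = 0.8, depth_mean = 5000,
                 lognormal_sd = 0.8, seed = seed)
}

#' Generate a base community table and a matching random phylogeny
#'
#' Feature proportions are drawn once from the log-normal rank-abundance
#' curve of `spec`; each sample then gets its own composition
#' (Dirichlet-multinomial by default) at its own sequencing depth. The
#' accompanying tree is a random rooted bifurcating pure-birth topology over
#' all features with independent exponential(1) branch lengths — a neutral
#' stand-in whose only role is to carry the phylogenetic metrics.
#'
#' @param spec a [community_spec()].
#' @return list with `table` (samples x features count matrix), `tree`
#'   (`phylo`) and the `spec`.
#' @export
generate_base <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  m <- spec$n_features
  n <- spec$n_samples
  p <- exp(rnorm(m, 0, spec$skew))
  p <- p / sum(p)
  depths <- pmax(rnbinom(n, mu = spec$depth_mean, size = spec$depth_dispersion), 1L)
  counts <- matrix(0, nrow = n, ncol = m,
                   dimnames = list(sprintf("s%03d", seq_len(n)),
                                   sprintf("f%04d", seq_len(m))))
  if (spec$model == "dirichlet_multinomial") {
    for (s in seq_len(n)) {
      w <- rgamma(m, shape = spec$theta * p)
      tot <- sum(w)
      if (tot <= 0) w[which.max(p)] <- 1 else w <- w / tot
      counts[s, ] <- rmultinom(1L, depths[s], w)
    }
  } else {
    for (s in seq_len(n)) {
      lambda <- depths[s] * p * exp(rnorm(m, 0, spec$lognormal_sd) -
                                      spec$lognormal_sd^2 / 2)
      counts[s, ] <- rpois(m, lambda)
    }
  }
  tree <- ape::rphylo(m, birth = 1, death = 0)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1)
  tree$tip.label <- colnames(counts)
  if (!is.null(spec$sparsity_target)) {
    achieved <- mean(counts == 0)
    if (abs(achieved - spec$sparsity_target) > 0.05)
      warning(sprintf("achieved sparsity %.3f misses target %.3f",
                      achieved, spec$sparsity_target))
  }
  validate_count_table(counts)
  list(table = counts, tree = tree, spec = spec)
}

#' Scenario 1: presence/absence perturbation
#'
#' Returns a copy of `x` in which `round(fraction_removed * m)` features,
#' chosen uniformly at random, are set to zero in every sample — a global
#' removal, so the perturbed table's feature support is a strict subset of
#' the original's while feature set and ordering are preserved.
#'
#' @param x source count table.
#' @param fraction_removed fraction of features to remove, in (0, 1).
#' @param seed optional seed for the feature choice.
#' @return perturbed count table with attribute `"removed_features"`.
#' @export
apply_presence_absence <- function(x, fraction_removed, seed = NULL) {
  validate_count_table(x)
  if (fraction_removed <= 0 || fraction_removed >= 1)
    stop("fraction_removed must be in (0, 1)")
  m <- ncol(x)
  k <- round(fraction_removed * m)
  if (k >= m) stop("would remove all features")
  if (!is.null(seed)) set.seed(seed)
  removed <- sort(sample.int(m, k))
  x2 <- x
  x2[, removed] <- 0
  attr(x2, "removed_features") <- colnames(x)[removed]
  x2
}

#' Scenario 2: differential abundance perturbation
#'
#' Returns a copy of `x` in which a uniformly chosen set of
#' `round(affected_fraction * m)` features is multiplied by
#' `1 + fold_increase_percent/100` in every sample. Presence/absence structure
#' is preserved exactly (a zero stays zero, a positive count stays positive),
#' which is why purely presence/absence metrics cannot see this perturbation.
#'
#' @param x source count table.
#' @param fold_increase_percent percent abundance increase (> 0).
#' @param affected_fraction fraction of features affected (default 1/4).
#' @param seed optional seed for the feature choice.
#' @return perturbed count table (real-valued) with attribute
#'   `"affected_features"`.
#' @export
apply_differential_abundance <- function(x, fold_increase_percent,
                                         affected_fraction = 0.25, seed = NULL) {
  validate_count_table(x)
  if (fold_increase_percent <= 0) stop("fold_increase_percent must be positive")
  if (affected_fraction <= 0 || affected_fraction > 1)
    stop("affected_fraction must be in (0, 1]")
  m <- ncol(x)
  k <- round(affected_fraction * m)
  if (!is.null(seed)) set.seed(seed)
  affected <- sort(sample.int(m, k))
  x2 <- x
  x2[, affected] <- x2[, affected] * (1 + fold_increase_percent / 100)
  attr(x2, "affected_features") <- colnames(x)[affected]
  x2
}

#' Generate a two-group dataset with a prescribed alpha-metric effect size
#'
#' Produces a pair of community tables whose realized Cohen's d on the chosen
#' alpha metric is within `tol` (relative) of `target_d`. Group 2 is generated
#' from the same spec with its rank-abundance skew scaled by a factor found by
#' bisection (larger skew lowers diversity); group 2 uses `seed + 1` so the
#' factor is the only thing the search moves. With `target_d = 0` both groups
#' are drawn from the identical spec (differing only in seed) and no search is
#' performed.
#'
#' @param spec a [community_spec()] for group 1.
#' @param target_d requested Cohen's d (>= 0).
#' @param metric alpha metric on which the effect is measured.
#' @param tol relative tolerance on the realized d (default 0.15).
#' @param max_iter bisection iterations.
#' @return list with `x1`, `x2`, `tree` (from group 1, shared), `realized_d`,
#'   `skew_factor`.
#' @export
two_group_alpha_effect <- function(spec, target_d, metric = "shannon",
                                   tol = 0.15, max_iter = 40L) {
  stopifnot(inherits(spec, "community_spec"))
  if (target_d < 0) stop("target_d must be nonnegative")
  base <- generate_base(spec)
  vals1 <- alpha_table(base$table, metrics = metric, tree = base$tree)[[metric]]
  gen2 <- function(factor) {
    s2 <- spec
    s2$skew <- spec$skew * factor
    s2$seed <- spec$seed + 1L
    generate_base(s2)$table
  }
  realized <- function(x2) {
    vals2 <- alpha_table(x2, metrics = metric, tree = base$tree)[[metric]]
    cohens_d(mean(vals1), sd(vals1), mean(vals2), sd(vals2))$d
  }
  if (target_d == 0) {
    x2 <- gen2(1)
    return(list(x1 = base$table, x2 = x2, tree = base$tree,
                realized_d = realized(x2), skew_factor = 1))
  }
  lo <- 1
  hi <- 1.05
  x2 <- gen2(hi)
  d_hi <- realized(x2)
  iter <- 0L
  while (d_hi < target_d) {
    hi <- hi * 1.5
    if (hi > 16 || (iter <- iter + 1L) > max_iter)
      stop("unattainable target effect after max iterations")
    x2 <- gen2(hi)
    d_hi <- realized(x2)
  }
  for (it in seq_len(max_iter)) {
    if (abs(d_hi - target_d) <= tol * target_d) break
    mid <- (lo + hi) / 2
    x2_mid <- gen2(mid)
    d_mid <- realized(x2_mid)
    if (d_mid < target_d) lo <- mid else { hi <- mid; x2 <- x2_mid; d_hi <- d_mid }
  }
  if (abs(d_hi - target_d) > tol * target_d)
    stop("unattainable target effect after max iterations")
  list(x1 = base$table, x2 = x2, tree = base$tree, realized_d = d_hi,
       skew_factor = hi)
}
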