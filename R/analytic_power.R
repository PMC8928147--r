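#' Cohen's d for a two-group comparison
#'
#' \eqn{d = |m_1 - m_2| / s_p} with the equal-weight pooled SD
#' \eqn{s_p = \sqrt{(s_1^2 + s_2^2)/2}}. The equal-weight (rather than
#' sample-size weighted) pooling is the convention used when effect sizes are
#' read off published "mean (SD)" pilot tables whose group sizes differ.
#'
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (> 0).
#' @return object of class `"effect_size_d"`: list with the inputs, the pooled
#'   SD and `d`.
#' @examples
#' cohens_d(17.3, 3.7, 22.6, 4.6)$d  # 1.27: gut vs oral phylogenetic diversity
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  structure(list(mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
                 pooled_sd = pooled, d = abs(mean1 - mean2) / pooled),
            class = "effect_size_d")
}

#' @export
print.effect_size_d <- function(x, ...) {
  cat(sprintf("Cohen's d = %.4f  (means %.4g vs %.4g, pooled SD %.4g)\n",
              x$d, x$mean1, x$mean2, x$pooled_sd))
  invisible(x)
}

#' Specification of an analytic power calculation
#'
#' Captures the test family and its fixed parameters. For `"wmw"`
#' (Wilcoxon-Mann-Whitney, equivalently the two-group Kruskal-Wallis) the
#' asymptotic relative efficiency (A.R.E.) method is used: the noncentrality
#' parameter and the degrees of freedom of the corresponding t test are both
#' multiplied by the A.R.E. of the WMW test against the t test — 3/pi for a
#' normal parent distribution, or the distribution-free lower bound 0.864
#' (`parent = "min"`).
#'
#' @param test `"t_test"`, `"wmw"` or `"anova"`.
#' @param effect Cohen's d (t/wmw) or Cohen's f (anova); nonnegative.
#' @param alpha_level type-I error rate in (0, 1).
#' @param tails `"one"` or `"two"` (t/wmw only; the F test is one-sided).
#' @param groups number of groups (anova only).
#' @param allocation_ratio n2/n1 for two-sample designs.
#' @param parent parent distribution for the WMW A.R.E.: `"normal"` (3/pi) or
#'   `"min"` (0.864).
#' @return object of class `"power_spec"`.
#' @export
power_spec <- function(test = c("wmw", "t_test", "anova"), effect,
                       alpha_level = 0.05, tails = c("one", "two"),
                       groups = 2L, allocation_ratio = 1,
                       parent = c("normal", "min")) {
  test <- match.arg(test)
  tails <- match.arg(tails)
  parent <- match.arg(parent)
  if (!is.numeric(effect) || effect < 0) stop("effect must be nonnegative")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in (0, 1)")
  if (groups < 2) stop("at least two groups")
  if (allocation_ratio <= 0) stop("allocation ratio must be positive")
  are <- switch(test, t_test = 1, wmw = switch(parent, normal = 3 / pi, min = 0.864),
                anova = NA_real_)
  structure(list(test = test, effect = effect, alpha_level = alpha_level,
                 tails = tails, groups = as.integer(groups),
                 allocation_ratio = allocation_ratio, parent = parent,
                 are = are),
            class = "power_spec")
}

# power of the noncentral-t machinery shared by t_test and wmw
t_family_power <- function(d, n1, n2, alpha, tails, are) {
  nn <- n1 + n2
  ncp <- d * sqrt(are * n1 * n2 / nn)
  df <- (nn - 2) * are
  if (df <= 0) stop("sample sizes too small: nonpositive degrees of freedom")
  if (tails == "one") {
    crit <- qt(1 - alpha, df)
    power <- 1 - pt(crit, df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    power <- 1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
  }
  list(power = power, ncp = ncp, df = df, critical = crit)
}

anova_power_total <- function(f, n_total, groups, alpha) {
  df1 <- groups - 1
  df2 <- n_total - groups
  if (df2 <= 0) stop("sample sizes too small: nonpositive degrees of freedom")
  lambda <- f^2 * n_total
  crit <- qf(1 - alpha, df1, df2)
  list(power = 1 - pf(crit, df1, df2, ncp = lambda), ncp = lambda,
       df = c(df1, df2), critical = crit)
}

#' Post-hoc (achieved) power at given group sizes
#'
#' For `"t_test"`: noncentral-t power with
#' \eqn{ncp = d\sqrt{n_1 n_2 / N}}, \eqn{df = N - 2}. For `"wmw"`: the same
#' machinery with ncp and df both scaled by the A.R.E. For `"anova"`
#' (balanced or not, `n2` defaults to `n1` and `N = n1 + n2` for two groups;
#' for `groups > 2` pass the per-group size as `n1`): noncentral-F power with
#' \eqn{\lambda = f^2 N}, df \eqn{(g - 1, N - g)}.
#'
#' @param spec a [power_spec()].
#' @param n1 group-1 size (per-group size for anova).
#' @param n2 group-2 size; defaults to `n1` (ignored for anova with
#'   `groups > 2`).
#' @return object of class `"power_solution"`.
#' @export
power_posthoc <- function(spec, n1, n2 = n1) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$test == "anova") {
    n_total <- spec$groups * n1
    res <- anova_power_total(spec$effect, n_total, spec$groups, spec$alpha_level)
    return(power_solution(spec, kind = "post_hoc", n1 = n1, n2 = n1,
                          n_total = n_total, power = res$power, ncp = res$ncp,
                          df = res$df, critical = res$critical))
  }
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  res <- t_family_power(spec$effect, n1, n2, spec$alpha_level, spec$tails, spec$are)
  power_solution(spec, kind = "post_hoc", n1 = n1, n2 = n2, n_total = n1 + n2,
                 power = res$power, ncp = res$ncp, df = res$df,
                 critical = res$critical)
}

power_solution <- function(spec, kind, n1, n2, n_total, power, ncp, df,
                           critical, target_power = NA_real_) {
  structure(list(spec = spec, kind = kind, n1 = n1, n2 = n2, n_total = n_total,
                 achieved_power = power, noncentrality = ncp, df = df,
                 critical_value = critical, target_power = target_power),
            class = "power_solution")
}

#' @export
print.power_solution <- function(x, ...) {
  cat(sprintf("%s power analysis (%s)\n",
              switch(x$kind, a_priori = "A priori", post_hoc = "Post hoc", x$kind),
              x$spec$test))
  cat(sprintf("  effect = %.4g, alpha = %.3g, tails = %s\n",
              x$spec$effect, x$spec$alpha_level, x$spec$tails))
  cat(sprintf("  n1 = %.4g, n2 = %.4g, total N = %.4g\n", x$n1, x$n2, x$n_total))
  cat(sprintf("  ncp = %.4f, critical = %.4f, df = %s\n",
              x$noncentrality, x$critical_value,
              paste(format(round(x$df, 2)), collapse = ", ")))
  cat(sprintf("  achieved power = %.4f\n", x$achieved_power))
  invisible(x)
}

#' A-priori sample size for a target power
#'
#' For the two-sample tests the search runs over integer group sizes
#' respecting the allocation ratio (`n2 = round(ratio * n1)`), returning the
#' smallest design whose achieved power reaches the target — so the reported
#' "actual power" slightly exceeds the request. For the anova test the search
#' follows the omnibus one-way convention of searching the smallest *total* N
#' (noncentrality \eqn{f^2 N}), and the per-group size reported is `N / g`,
#' possibly fractional.
#'
#' @param spec a [power_spec()] with a positive effect.
#' @param target_power requested power, in (alpha_level, 1).
#' @param max_n search cap on the per-group size.
#' @return a `"power_solution"` with `kind = "a_priori"`.
#' @export
sample_size <- function(spec, target_power = 0.8, max_n = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$effect <= 0)
    stop("unattainable power: effect size is zero")
  if (target_power <= spec$alpha_level || target_power >= 1)
    stop("target_power must lie in (alpha_level, 1)")
  if (spec$test == "anova") {
    n_total <- spec$groups + 1
    repeat {
      res <- anova_power_total(spec$effect, n_total, spec$groups, spec$alpha_level)
      if (res$power >= target_power) break
      n_total <- n_total + 1
      if (n_total > max_n) stop("sample size search exceeded max_n")
    }
    per_group <- n_total / spec$groups
    return(power_solution(spec, kind = "a_priori", n1 = per_group,
                          n2 = per_group, n_total = n_total, power = res$power,
                          ncp = res$ncp, df = res$df, critical = res$critical,
                          target_power = target_power))
  }
  n1 <- 2
  repeat {
    n2 <- max(2, round(spec$allocation_ratio * n1))
    res <- t_family_power(spec$effect, n1, n2, spec$alpha_level, spec$tails,
                          spec$are)
    if (res$power >= target_power) break
    n1 <- n1 + 1
    if (n1 > max_n) stop("sample size search exceeded max_n")
  }
  power_solution(spec, kind = "a_priori", n1 = n1, n2 = n2, n_total = n1 + n2,
                 power = res$power, ncp = res$ncp, df = res$df,
                 critical = res$critical, target_power = target_power)
}

#' Required sample size across a set of named effect sizes
#'
#' One row per effect (e.g. the Cohen's d obtained from each alpha metric on
#' the same pilot data): the total N a study would need to reach the target
#' power with that metric. Zero effects are reported as unattainable
#' (infinite N).
#'
#' @param effects named numeric vector of effect sizes.
#' @param spec template [power_spec()]; its `effect` field is replaced by each
#'   entry in turn.
#' @param target_power requested power.
#' @return data frame with columns `label`, `effect`, `n1`, `n2`, `n_total`,
#'   `achieved_power`, `attainable`.
#' @export
sample_size_curve <- function(effects, spec, target_power = 0.8) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(names(effects))) names(effects) <- paste0("effect", seq_along(effects))
  rows <- lapply(names(effects), function(lbl) {
    e <- effects[[lbl]]
    if (e <= 0)
      return(data.frame(label = lbl, effect = e, n1 = Inf, n2 = Inf,
                        n_total = Inf, achieved_power = NA_real_,
                        attainable = FALSE, stringsAsFactors = FALSE))
    s <- spec
    s$effect <- e
    sol <- sample_size(s, target_power)
    data.frame(label = lbl, effect = e, n1 = sol$n1, n2 = sol$n2,
               n_total = sol$n_total, achieved_power = sol$achieved_power,
               attainable = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
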