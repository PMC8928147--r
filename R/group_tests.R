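#' Kruskal-Wallis test with standardized effect sizes
#'
#' Wraps [stats::kruskal.test()] (midrank ties, the standard tie correction,
#' chi-square reference distribution with k - 1 df) and adds the effect sizes
#' used when reporting microbiome group comparisons: the rank eta-squared
#' \eqn{\eta^2 = (H - k + 1)/(N - k)} and, for two-group designs, Cohen's d
#' computed from the group means and SDs with the equal-weight pooled SD (see
#' [cohens_d()]).
#'
#' When every observation is identical the statistic is undefined under the
#' tie correction; the test then reports H = 0, p = 1 (a non-rejection).
#'
#' @param values numeric observations (e.g. one alpha metric per sample).
#' @param design group labels: a factor/character vector aligned with
#'   `values`, or a named factor from [group_design()] when `values` is named.
#' @return object of class `"kw_test"`: list with `h`, `df`, `p_value`, `n`,
#'   `k`, `eta_squared`, `cohens_d` (two groups, else `NA`).
#' @export
kruskal_wallis <- function(values, design) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (!is.null(names(values)) && !is.null(names(design)) &&
      all(names(values) %in% names(design)))
    design <- design[names(values)]
  g <- factor(as.character(design))
  if (length(g) != length(values)) stop("values and design differ in length")
  if (nlevels(g) < 2L) stop("at least two groups are required")
  if (any(table(g) < 1L)) stop("empty group")
  n <- length(values)
  k <- nlevels(g)
  if (length(unique(values)) == 1L) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  eta2 <- (h - k + 1) / (n - k)
  d <- NA_real_
  if (k == 2L) {
    v1 <- values[g == levels(g)[1L]]
    v2 <- values[g == levels(g)[2L]]
    s1 <- sd(v1); s2 <- sd(v2)
    d <- if (s1 > 0 || s2 > 0)
      abs(mean(v1) - mean(v2)) / sqrt((s1^2 + s2^2) / 2) else 0
  }
  structure(list(h = h, df = k - 1L, p_value = p, n = n, k = k,
                 eta_squared = eta2, cohens_d = d),
            class = "kw_test")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA for a one-factor design. Sums of squares
#' follow the distance-based decomposition
#' \eqn{SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{SS_B = SS_T - SS_W}, and the pseudo-F statistic is
#' \eqn{F = (SS_B/(g-1)) / (SS_W/(n-g))}. The p-value uses the
#' \eqn{(b + 1)/(k + 1)} convention (the observed statistic counts as one
#' permutation), so the smallest attainable p is \eqn{1/(k+1)} and p = 0 is
#' impossible. Effect sizes: Cohen's \eqn{f^2 = SS_B / SS_W} and
#' \eqn{\omega^2 = (SS_B - (g-1) MS_W) / (SS_T + MS_W)}.
#'
#' The permutation test assumes exchangeability under the null; duplicated
#' samples created by resampling with replacement are permuted as ordinary
#' units (see the package vignette for the implied caveat).
#'
#' @param d distance matrix (full symmetric, labelled) or `dist` object.
#' @param design group labels: named factor covering the samples of `d`, or a
#'   plain factor aligned with its rows.
#' @param permutations number of label permutations (default 9999).
#' @param seed optional integer seed for the permutation stream.
#' @return object of class `"permanova"`: list with `pseudo_f`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ss_total`, `p_value`,
#'   `n_permutations`, `cohens_f2`, `omega_squared`.
#' @export
permanova <- function(d, design, permutations = 9999, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (permutations < 1) stop("at least one permutation is required")
  if (!is.null(names(design))) {
    if (!all(names(design) %in% rownames(d)))
      stop("design samples missing from distance matrix")
    d <- d[names(design), names(design)]
  } else if (length(design) != nrow(d)) {
    stop("design length does not match the distance matrix")
  }
  g <- factor(as.character(design))
  n <- nrow(d)
  if (nlevels(g) < 2L) stop("at least two groups are required")
  sizes <- table(g)
  if (any(sizes < 2L)) stop("singleton group(s): ",
                            paste(names(sizes)[sizes < 2L], collapse = ", "))
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ss_within_for <- function(members_by_level) {
    tot <- 0
    for (lev in names(members_by_level)) {
      idx <- members_by_level[[lev]]
      tot <- tot + sum(d2[idx, idx]) / (2 * length(idx))
    }
    tot
  }
  ss_w <- ss_within_for(split(seq_len(n), g))
  ss_b <- ss_total - ss_w
  df_b <- nlevels(g) - 1L
  df_w <- n - nlevels(g)
  f_obs <- (ss_b / df_b) / (ss_w / df_w)

  if (!is.null(seed)) set.seed(seed)
  perm_idx <- vapply(seq_len(permutations), function(i) sample.int(n),
                     integer(n))
  # vectorized within-group SS across permutations: one matmul per group
  ssw_perm <- numeric(permutations)
  gi <- as.integer(g)
  perm_labels <- matrix(gi[perm_idx], n, permutations)
  for (lev in seq_len(nlevels(g))) {
    z <- (perm_labels == lev) + 0
    ssw_perm <- ssw_perm + colSums(z * (d2 %*% z)) / (2 * sizes[lev])
  }
  f_perm <- ((ss_total - ssw_perm) / df_b) / (ssw_perm / df_w)
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + permutations)
  ms_w <- ss_w / df_w
  structure(list(pseudo_f = f_obs, df_between = df_b, df_within = df_w,
                 ss_between = ss_b, ss_within = ss_w, ss_total = ss_total,
                 p_value = p, n_permutations = permutations,
                 cohens_f2 = ss_b / ss_w,
                 omega_squared = (ss_b - df_b * ms_w) / (ss_total + ms_w),
                 n = n, g = nlevels(g)),
            class = "permanova")
}

#' Cohen's f-squared from a printed pseudo-F and its degrees of freedom
#'
#' \eqn{f^2 = F \cdot df_B / df_W}: algebraically identical to
#' \eqn{SS_B/SS_W}, usable when only the test statistic is reported.
#'
#' @param f pseudo-F statistic.
#' @param df_between,df_within its degrees of freedom.
#' @return numeric f-squared.
#' @export
cohens_f2_from_f <- function(f, df_between, df_within) {
  if (f < 0) stop("F must be nonnegative")
  f * df_between / df_within
}

#' One-line APA-style report of a test result
#'
#' Formats a [kruskal_wallis()] or [permanova()] result as the standardized
#' single line recommended for reporting microbiome group comparisons, e.g.
#' `"H(1) = 14.68, p = 0.0001, eta2 = 0.20, d = 0.58"` or
#' `"F(1, 68) = 6.27, p = 0.0001, f2 = 0.092"`.
#'
#' @param x a `"kw_test"` or `"permanova"` object.
#' @param ... unused.
#' @return character scalar.
#' @export
report_line <- function(x, ...) UseMethod("report_line")

#' @rdname report_line
#' @export
report_line.kw_test <- function(x, ...) {
  line <- sprintf("H(%d) = %.2f, p = %.4f, eta2 = %.2f",
                  x$df, x$h, x$p_value, x$eta_squared)
  if (x$k == 2L && !is.na(x$cohens_d))
    line <- paste0(line, sprintf(", d = %.2f", x$cohens_d))
  line
}

#' @rdname report_line
#' @export
report_line.permanova <- function(x, ...) {
  sprintf("F(%d, %d) = %.2f, p = %.4f, f2 = %.3f",
          x$df_between, x$df_within, x$pseudo_f, x$p_value, x$cohens_f2)
}

#' @export
print.kw_test <- function(x, ...) {
  cat("Kruskal-Wallis rank sum test\n")
  cat(" ", report_line(x), "\n")
  cat(sprintf("  N = %d samples in %d groups\n", x$n, x$k))
  invisible(x)
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (one factor)\n")
  cat(" ", report_line(x), "\n")
  cat(sprintf("  SS_between = %.4f, SS_within = %.4f, SS_total = %.4f\n",
              x$ss_between, x$ss_within, x$ss_total))
  cat(sprintf("  omega2 = %.4f, %d permutations\n",
              x$omega_squared, x$n_permutations))
  invisible(x)
}
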