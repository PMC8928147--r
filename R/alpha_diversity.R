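#' Alpha diversity metrics
#'
#' Per-sample community summaries used throughout the power machinery:
#' observed richness, Faith's phylogenetic diversity (PD), the bias-corrected
#' Chao1 richness estimator, Shannon's entropy (natural logarithm) and
#' Simpson's index. Simpson defaults to the Gini-Simpson form
#' \eqn{1 - \sum p_i^2}, which lives in \[0, 1\] and increases with diversity;
#' the inverse (\eqn{1/\sum p_i^2}) and dominance (\eqn{\sum p_i^2}) forms are
#' selectable.
#'
#' Chao1 is the bias-corrected estimator
#' \eqn{s + F_1 (F_1 - 1) / (2 (F_2 + 1))} where \eqn{F_1}, \eqn{F_2} are the
#' singleton and doubleton counts: it is defined for \eqn{F_2 = 0} and reduces
#' to the observed richness when there are no singletons. It requires integer
#' counts.
#'
#' Faith's PD is the sum of branch lengths of the subtree spanning the
#' observed taxa, including the path to the root of the supplied rooted tree
#' (so a single observed taxon contributes its full root path).
#'
#' @param x numeric vector of nonnegative abundances for one sample (named by
#'   feature for `faith_pd`), or a count table for `alpha_table`.
#' @param tree rooted `phylo` tree with branch lengths; tips are features.
#' @param form Simpson form: `"gini"` (default), `"inverse"`, `"dominance"`.
#' @return a single numeric value per sample.
#' @seealso [alpha_table()] for whole-table computation.
#' @name alpha_diversity
NULL

check_abundance_vector <- function(x, require_positive = FALSE) {
  if (!is.numeric(x)) stop("abundances must be numeric")
  if (anyNA(x) || any(!is.finite(x))) stop("abundances must be finite")
  if (any(x < 0)) stop("negative abundance")
  if (require_positive && sum(x) <= 0) stop("all-zero sample")
  invisible(x)
}

#' @rdname alpha_diversity
#' @export
observed_richness <- function(x) {
  check_abundance_vector(x)
  sum(x > 0)
}

#' @rdname alpha_diversity
#' @export
chao1 <- function(x) {
  check_abundance_vector(x)
  if (any(abs(x - round(x)) > 1e-8))
    stop("Chao1 requires integer counts")
  x <- round(x)
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha_diversity
#' @export
shannon <- function(x) {
  check_abundance_vector(x, require_positive = TRUE)
  as.numeric(vegan::diversity(rbind(x), index = "shannon"))
}

#' @rdname alpha_diversity
#' @export
simpson <- function(x, form = c("gini", "inverse", "dominance")) {
  form <- match.arg(form)
  check_abundance_vector(x, require_positive = TRUE)
  gini <- as.numeric(vegan::diversity(rbind(x), index = "simpson"))
  switch(form, gini = gini, inverse = 1 / (1 - gini), dominance = 1 - gini)
}

#' @rdname alpha_diversity
#' @export
faith_pd <- function(x, tree) {
  check_abundance_vector(x)
  if (is.null(names(x))) stop("faith_pd needs feature names on the abundance vector")
  xm <- matrix(x, nrow = 1L, dimnames = list("s", names(x)))
  xm <- match_tree_features(xm, tree)
  if (!setequal(colnames(xm), names(x)))
    stop("observed features missing from tree")
  es <- edge_sample_abundance(xm, tree)
  sum(es$lengths[es$abundance[, 1L] > 0])
}

#' Alpha diversity for a whole count table
#'
#' @param x count table (samples x features).
#' @param metrics subset of
#'   `c("observed", "pd", "chao1", "shannon", "simpson")`.
#' @param tree rooted tree, required iff `"pd"` is requested.
#' @param simpson_form passed to [simpson()].
#' @return data frame with a `sample_id` column and one column per metric.
#' @export
alpha_table <- function(x, metrics = c("observed", "pd", "chao1", "shannon", "simpson"),
                        tree = NULL, simpson_form = "gini") {
  validate_count_table(x)
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  for (m in metrics) {
    out[[m]] <- switch(
      m,
      observed = as.numeric(rowSums(x > 0)),
      chao1 = apply(x, 1L, chao1),
      shannon = {
        if (any(rowSums(x) <= 0)) stop("all-zero sample")
        as.numeric(vegan::diversity(x, index = "shannon"))
      },
      simpson = {
        if (any(rowSums(x) <= 0)) stop("all-zero sample")
        gini <- as.numeric(vegan::diversity(x, index = "simpson"))
        switch(simpson_form, gini = gini, inverse = 1 / (1 - gini),
               dominance = 1 - gini)
      },
      pd = {
        if (is.null(tree)) stop("pd requires a tree")
        xm <- match_tree_features(x, tree)
        es <- edge_sample_abundance(xm, tree)
        as.numeric(crossprod(es$abundance > 0, es$lengths))
      }
    )
  }
  out
}

#' Per-group mean and standard deviation of alpha metrics
#'
#' Summaries use the sample standard deviation (n - 1 denominator), matching
#' the usual "mean (SD)" pilot-study tables that feed effect-size estimation.
#'
#' @param alpha data frame from [alpha_table()].
#' @param design named factor from [group_design()] covering the samples.
#' @return data frame with group, metric, n, mean, sd.
#' @export
alpha_summary <- function(alpha, design) {
  if (!all(alpha$sample_id %in% names(design)))
    stop("design does not cover all samples")
  g <- design[alpha$sample_id]
  metrics <- setdiff(colnames(alpha), "sample_id")
  res <- lapply(metrics, function(m) {
    agg_mean <- tapply(alpha[[m]], g, mean)
    agg_sd <- tapply(alpha[[m]], g, sd)
    agg_n <- tapply(alpha[[m]], g, length)
    data.frame(group = names(agg_mean), metric = m,
               n = as.integer(agg_n), mean = as.numeric(agg_mean),
               sd = as.numeric(agg_sd), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
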