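#' Beta diversity dissimilarity matrices
#'
#' Pairwise dissimilarities between all samples of a count table, returned as
#' full symmetric matrices with sample identifiers. Four metrics are
#' supported:
#'
#' * `bray_curtis()`: \eqn{1 - 2\sum_f \min(x_{if}, x_{jf}) /
#'   (\sum_f x_{if} + \sum_f x_{jf})}, computed on abundances as given (no
#'   normalization to proportions).
#' * `jaccard()`: one minus shared-over-union feature counts, on
#'   presence/absence.
#' * `unweighted_unifrac()`: the branch length leading exclusively to taxa of
#'   one of the two samples, divided by the branch length leading to taxa of
#'   either sample.
#' * `weighted_unifrac()`: \eqn{\sum_i b_i |A_i/A_T - B_i/B_T|} over branches,
#'   where \eqn{A_i/A_T} is the proportion of sample A's reads descending
#'   through branch \eqn{i}. The absolute value makes the sum a distance. By
#'   default the raw (non-normalized) form is returned; with
#'   `normalized = TRUE` it is divided by \eqn{\sum_i b_i (A_i/A_T + B_i/B_T)},
#'   bounding it by 1.
#'
#' @param x count table (samples x features); no all-zero samples.
#' @param tree rooted `phylo` tree with branch lengths (UniFrac metrics).
#' @param normalized logical, weighted UniFrac only.
#' @param prune drop table features absent from the tree (see
#'   [match_tree_features()]).
#' @return symmetric numeric matrix with zero diagonal.
#' @name beta_diversity_metrics
NULL

check_no_empty_samples <- function(x) {
  empty <- rowSums(x) <= 0
  if (any(empty))
    stop("all-zero sample(s): ", paste(rownames(x)[empty], collapse = ", "))
  invisible(x)
}

#' @rdname beta_diversity_metrics
#' @export
bray_curtis <- function(x) {
  validate_count_table(x)
  check_no_empty_samples(x)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' @rdname beta_diversity_metrics
#' @export
jaccard <- function(x) {
  validate_count_table(x)
  check_no_empty_samples(x)
  as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE))
}

#' @rdname beta_diversity_metrics
#' @export
unweighted_unifrac <- function(x, tree, prune = FALSE) {
  validate_count_table(x)
  check_no_empty_samples(x)
  x <- match_tree_features(x, tree, prune = prune)
  es <- edge_sample_abundance(x, tree)
  # samples x edges matrix of branch lengths present in each sample
  u <- t((es$abundance > 0) * es$lengths)
  num <- as.matrix(vegan::vegdist(u, method = "manhattan"))  # unshared length
  rs <- rowSums(u)
  union_len <- (outer(rs, rs, "+") + num) / 2                # either-sample length
  d <- ifelse(union_len > 0, num / union_len, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' @rdname beta_diversity_metrics
#' @export
weighted_unifrac <- function(x, tree, normalized = FALSE, prune = FALSE) {
  validate_count_table(x)
  check_no_empty_samples(x)
  x <- match_tree_features(x, tree, prune = prune)
  es <- edge_sample_abundance(x, tree)
  prop <- sweep(es$abundance, 2L, es$totals, "/")
  w <- t(prop * es$lengths)                                  # samples x edges
  d <- as.matrix(vegan::vegdist(w, method = "manhattan"))
  if (normalized) {
    rs <- rowSums(w)
    denom <- outer(rs, rs, "+")
    d <- ifelse(denom > 0, d / denom, 0)
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Dispatch a beta diversity metric by name
#'
#' @param x count table.
#' @param metric one of `"braycurtis"`, `"jaccard"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param tree tree for the UniFrac pair.
#' @param normalized weighted UniFrac normalization flag.
#' @param prune see [match_tree_features()].
#' @return symmetric dissimilarity matrix.
#' @export
beta_diversity <- function(x, metric = c("braycurtis", "jaccard",
                                         "unweighted_unifrac", "weighted_unifrac"),
                           tree = NULL, normalized = FALSE, prune = FALSE) {
  metric <- match.arg(metric)
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac") && is.null(tree))
    stop(metric, " requires a tree")
  switch(metric,
         braycurtis = bray_curtis(x),
         jaccard = jaccard(x),
         unweighted_unifrac = unweighted_unifrac(x, tree, prune = prune),
         weighted_unifrac = weighted_unifrac(x, tree, normalized = normalized,
                                             prune = prune))
}

#' Distances of samples to their group centroid
#'
#' Embeds the dissimilarity matrix by principal-coordinate decomposition
#' (keeping negative-eigenvalue axes as imaginary coordinates) and measures
#' each sample's distance to its group centroid as the square root of the
#' real-axis squared distance minus the imaginary-axis squared distance,
#' clipped at zero — the standard dispersion-analysis convention for
#' semi-metric dissimilarities, as implemented by [vegan::betadisper()].
#'
#' @param d distance matrix covering `names(design)`.
#' @param design named factor from [group_design()].
#' @return list with `distances` (named per-sample vector) and `group_means`.
#' @export
group_centroid_distances <- function(d, design) {
  validate_distance_matrix(d)
  if (!all(names(design) %in% rownames(d)))
    stop("design samples missing from distance matrix")
  d <- d[names(design), names(design)]
  sizes <- table(design)
  if (any(sizes < 2))
    warning("group(s) of size 1: centroid distance is 0 for ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  if (max(d) <= 1e-12) {
    dist_to_centroid <- setNames(rep(0, nrow(d)), rownames(d))
  } else {
    bd <- vegan::betadisper(as.dist(d), group = design, type = "centroid")
    dist_to_centroid <- bd$distances
  }
  list(distances = dist_to_centroid,
       group_means = tapply(dist_to_centroid, design, mean))
}
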