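#' Validate a community count table
#'
#' A count table is a plain numeric matrix with samples as rows and features
#' (ASVs/OTUs) as columns, unique sample identifiers as row names and unique
#' feature identifiers as column names, and nonnegative finite entries.
#' Abundances may be non-integral (perturbed or normalized tables are allowed;
#' metrics that require integer counts, such as Chao1, check separately).
#'
#' @param x matrix to validate.
#' @return `x`, invisibly unchanged, if valid; otherwise an error is thrown.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (samples x features)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have sample row names and feature column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicated sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicated feature identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("count table contains non-finite values")
  if (any(x < 0))
    stop("count table contains negative values")
  invisible(x)
}

#' Read a tab-separated count table
#'
#' The first row holds identifiers (first cell is an arbitrary corner label),
#' the first column holds identifiers, remaining cells are numeric. Amplicon
#' tables circulate in both orientations; the default expects samples as rows,
#' `features_as_rows = TRUE` transposes on read.
#'
#' @param path file path.
#' @param features_as_rows logical; if `TRUE` the file stores one feature per
#'   row and the table is transposed after reading.
#' @return a validated samples x features numeric matrix.
#' @export
read_count_table <- function(path, features_as_rows = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("count table file needs an id column and at least one data column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(raw)[-1L]
  if (anyDuplicated(cn))
    stop("duplicated identifiers in header: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw), dimnames = list(ids, cn))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                 ids[bad[1L]], cn[bad[2L]]))
  }
  if (features_as_rows) num <- t(num)
  validate_count_table(num)
  num
}

#' Write a count table as TSV
#'
#' @param x validated count table (samples as rows).
#' @param path output file.
#' @param features_as_rows write transposed (one feature per row).
#' @param id_label corner label for the identifier column.
#' @export
write_count_table <- function(x, path, features_as_rows = FALSE,
                              id_label = if (features_as_rows) "feature_id" else "sample_id") {
  validate_count_table(x)
  if (features_as_rows) x <- t(x)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Branch lengths are mandatory: a tree with any missing branch length is
#' rejected rather than silently treated as zero-length.
#'
#' @param path Newick file path.
#' @return an [ape::read.tree()] `phylo` object, validated.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick file: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file: no tree found")
  validate_tree(tree)
  tree
}

#' Validate a phylogenetic tree for diversity computations
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly, if valid.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; branch lengths are mandatory")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing branch lengths; branch lengths are mandatory")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  invisible(tree)
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

#' Validate a distance matrix
#'
#' Distance matrices are full square numeric matrices with matching unique row
#' and column sample identifiers, symmetric to within `tol`, zero diagonal and
#' nonnegative entries.
#'
#' @param d matrix to validate.
#' @param tol absolute symmetry tolerance.
#' @return `d`, invisibly, if valid.
#' @export
validate_distance_matrix <- function(d, tol = 1e-10) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distance matrix must be a square numeric matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    stop("distance matrix must carry sample identifiers")
  if (!identical(rownames(d), colnames(d)))
    stop("row and column identifiers differ")
  if (anyDuplicated(rownames(d))) stop("duplicated sample identifiers")
  if (max(abs(d - t(d))) > tol)
    stop("matrix is asymmetric beyond tolerance ", format(tol))
  if (any(abs(diag(d)) > tol)) stop("diagonal is not zero")
  if (any(d < -tol)) stop("negative dissimilarities")
  invisible(d)
}

#' Read / write square labelled distance matrices
#'
#' TSV layout: header row of sample ids (after a corner label), one labelled
#' row per sample. Symmetry is enforced on read: after validation the matrix
#' is replaced by `(d + t(d))/2` with an exactly zero diagonal.
#'
#' @param path file path.
#' @param tol symmetry tolerance.
#' @return a validated symmetric matrix.
#' @export
read_distance_matrix <- function(path, tol = 1e-10) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  ids <- raw[[1L]]
  cn <- colnames(raw)[-1L]
  if (length(cn) != length(ids)) stop("distance matrix file is not square")
  if (!identical(ids, cn)) stop("row and column labels differ or are reordered")
  d <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  d <- matrix(d, nrow = length(ids), dimnames = list(ids, ids))
  if (anyNA(d)) stop("malformed numeric cell in distance matrix")
  validate_distance_matrix(d, tol = tol)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' @rdname read_distance_matrix
#' @param d validated distance matrix.
#' @export
write_distance_matrix <- function(d, path, tol = 1e-10) {
  validate_distance_matrix(d, tol = tol)
  df <- data.frame(rownames(d), format(d, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(d))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group designs
#'
#' A group design maps each sample identifier to exactly one group label. It
#' is stored as a named factor (names are sample ids).
#'
#' @param labels character or factor of group labels.
#' @param sample_ids sample identifiers; defaults to `names(labels)`.
#' @return named factor.
#' @export
group_design <- function(labels, sample_ids = names(labels)) {
  if (is.null(sample_ids)) stop("sample identifiers are required")
  if (anyDuplicated(sample_ids)) stop("duplicated sample identifiers in design")
  if (length(sample_ids) != length(labels)) stop("labels and sample ids differ in length")
  if (anyNA(labels)) stop("missing group labels")
  f <- factor(as.character(labels))
  names(f) <- sample_ids
  f
}

#' Read a two-column (sample_id, group) TSV
#'
#' @param path file path.
#' @return named factor as from [group_design()].
#' @export
read_group_design <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("group file needs two columns: sample_id, group")
  group_design(df[[2L]], df[[1L]])
}

#' @rdname read_group_design
#' @param design named factor.
#' @export
write_group_design <- function(design, path) {
  df <- data.frame(sample_id = names(design), group = as.character(design),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check feature/tree agreement, optionally pruning
#'
#' Features present in the table but absent from the tree are an error by
#' default; with `prune = TRUE` those features are dropped from the table
#' (silent intersection hides bugs, so pruning is always explicit).
#'
#' @param x count table.
#' @param tree `phylo` tree whose tips are feature identifiers.
#' @param prune drop table features missing from the tree instead of erroring.
#' @return possibly pruned count table.
#' @export
match_tree_features <- function(x, tree, prune = FALSE) {
  validate_count_table(x)
  validate_tree(tree)
  missing <- setdiff(colnames(x), tree$tip.label)
  if (length(missing)) {
    if (!prune)
      stop("features absent from tree: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
           "; use prune = TRUE to drop them explicitly")
    x <- x[, setdiff(colnames(x), missing), drop = FALSE]
  }
  x
}
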