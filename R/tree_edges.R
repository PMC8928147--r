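# Internal edge-level machinery shared by Faith's PD and the UniFrac pair.
#
# For a rooted tree, every edge partitions the tips into descendants and
# non-descendants. Both PD and UniFrac reduce to sums over edges of functions
# of the abundance mass descending through the edge, so a sparse edge x tip
# indicator matrix turns per-sample computation into one matrix product.

# edges x tips sparse indicator (entry 1 iff the tip descends from the edge's
# child node), plus the matching edge length vector.
edge_tip_matrix <- function(tree) {
  validate_tree(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  sets <- vector("list", ntip + nnode)
  sets[seq_len(ntip)] <- as.list(seq_len(ntip))
  ne <- nrow(tr$edge)
  edge_sets <- vector("list", ne)
  for (e in seq_len(ne)) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    edge_sets[[e]] <- sets[[child]]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  lens <- lengths(edge_sets)
  P <- Matrix::sparseMatrix(
    i = rep.int(seq_len(ne), lens),
    j = unlist(edge_sets),
    x = 1,
    dims = c(ne, ntip),
    dimnames = list(NULL, tr$tip.label)
  )
  list(indicator = P, lengths = tr$edge.length)
}

# edges x samples matrix of abundance descending through each edge, for the
# (already tree-matched) count table. Tips absent from the table count zero.
edge_sample_abundance <- function(x, tree, edges = edge_tip_matrix(tree)) {
  tips <- colnames(edges$indicator)
  xt <- matrix(0, nrow = length(tips), ncol = nrow(x),
               dimnames = list(tips, rownames(x)))
  xt[colnames(x), ] <- t(x)
  E <- as.matrix(edges$indicator %*% xt)
  list(abundance = E, lengths = edges$lengths, totals = rowSums(x))
}
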