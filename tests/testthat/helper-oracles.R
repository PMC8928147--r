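# Independent brute-force oracles. These deliberately avoid the package's
# edge-matrix machinery: descent is decided through ape::nodepath root-to-tip
# paths, and distances are accumulated edge by edge.

# tips (indices) descending from each edge's child node
oracle_edge_tips <- function(tree) {
  root <- length(tree$tip.label) + 1L
  paths <- lapply(seq_along(tree$tip.label),
                  function(t) ape::nodepath(tree, from = root, to = t))
  lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2L]
    which(vapply(paths, function(p) child %in% p, logical(1L)))
  })
}

oracle_faith_pd <- function(x, tree) {
  obs <- which(x > 0)
  tipidx <- match(names(x)[obs], tree$tip.label)
  et <- oracle_edge_tips(tree)
  on_path <- vapply(et, function(tips) any(tipidx %in% tips), logical(1L))
  sum(tree$edge.length[on_path])
}

oracle_unifrac_pair <- function(xi, xj, tree, weighted = FALSE,
                                normalized = FALSE) {
  et <- oracle_edge_tips(tree)
  b <- tree$edge.length
  ai <- xi[tree$tip.label]
  aj <- xj[tree$tip.label]
  if (!weighted) {
    in_i <- vapply(et, function(t) any(ai[t] > 0), logical(1L))
    in_j <- vapply(et, function(t) any(aj[t] > 0), logical(1L))
    unshared <- xor(in_i, in_j)
    either <- in_i | in_j
    if (!any(either)) return(0)
    return(sum(b[unshared]) / sum(b[either]))
  }
  pi <- ai / sum(ai)
  pj <- aj / sum(aj)
  wi <- vapply(et, function(t) sum(pi[t]), numeric(1L))
  wj <- vapply(et, function(t) sum(pj[t]), numeric(1L))
  raw <- sum(b * abs(wi - wj))
  if (!normalized) return(raw)
  raw / sum(b * (wi + wj))
}

# random fixtures -------------------------------------------------------------

random_tree <- function(n_tips, labels = paste0("f", seq_len(n_tips))) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- labels
  tr
}

random_table <- function(n_samples, n_features, lambda = 3,
                         sample_prefix = "s") {
  m <- matrix(rpois(n_samples * n_features, lambda),
              nrow = n_samples,
              dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                              paste0("f", seq_len(n_features))))
  # guarantee no all-zero samples
  empty <- rowSums(m) == 0
  m[empty, 1L] <- 1
  m
}

small_spec <- function(seed = 1L, n_samples = 30L, n_features = 120L) {
  community_spec(n_samples = n_samples, n_features = n_features,
                 depth_mean = 800, seed = seed)
}
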