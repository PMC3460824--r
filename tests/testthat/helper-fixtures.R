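# Small fixed trees used across tests
cherry_plus_one <- function() parse_newick("((A:1,B:1):1,C:2);")
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# uniform proximity matrix over n named species
uniform_proximity <- function(n, labels = sprintf("s%03d", seq_len(n))) {
  w <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(w) <- 0
  w
}

# random binary incidence matrix with guaranteed non-constant columns
random_incidence <- function(n_sp, n_col, p = 0.4,
                             labels = sprintf("s%03d", seq_len(n_sp))) {
  repeat {
    X <- matrix(rbinom(n_sp * n_col, 1, p), n_sp, n_col,
                dimnames = list(labels, sprintf("c%02d", seq_len(n_col))))
    cs <- colSums(X)
    if (all(cs > 0 & cs < n_sp)) return(X)
  }
}

# independent path-based patristic distance: depth_i + depth_j - 2 depth_mrca
patristic_by_paths <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  mrca <- ape::mrca(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- depth[i] + depth[j] - 2 * depth[mrca[i, j]]
  }
  d
}

# all weak compositions of `total` into `k` parts (for simplex grid search)
compositions <- function(total, k) {
  if (k == 1L) return(matrix(total, 1L, 1L))
  out <- NULL
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Colless imbalance for a binary tree
colless <- function(tree) {
  b <- ape::balance(tree)
  sum(abs(b[, 1] - b[, 2]))
}
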