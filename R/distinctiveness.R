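# Preorder traversal helper: rows of tree$edge sorted so that each edge is
# visited after the edge leading to its parent.
.preorder_edges <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  idx <- rev(seq_len(nrow(tr$edge)))
  list(edge = tr$edge[idx, , drop = FALSE],
       length = tr$edge.length[idx])
}

# number of tips below each node (tips count themselves)
.tips_below_count <- function(tree) {
  n <- ape::Ntip(tree)
  cnt <- c(rep(1L, n), rep(0L, tree$Nnode))
  tr <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(tr$edge)))
    cnt[tr$edge[i, 1L]] <- cnt[tr$edge[i, 1L]] + cnt[tr$edge[i, 2L]]
  cnt
}

#' Evolutionary distinctiveness (fair proportion)
#'
#' Each branch's length is divided equally among the tips descending from
#' it; a tip's ED is the sum of its shares along the root-to-tip path.
#' ED scores sum to the tree's total PD.
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector (one value per tip, in My).
#' @export
ed_scores <- function(tree) {
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (n == 1L) return(stats::setNames(faith_pd(tree), tree$tip.label))
  cnt <- .tips_below_count(tree)
  pre <- .preorder_edges(tree)
  acc <- numeric(n + tree$Nnode)
  for (i in seq_len(nrow(pre$edge))) {
    par <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
    acc[ch] <- acc[par] + pre$length[i] / cnt[ch]
  }
  stats::setNames(acc[seq_len(n)], tree$tip.label)
}

#' Equal-splits distinctiveness
#'
#' Each branch's length is halved (more generally, divided by the number
#' of children) at every node passed on the way down to a tip. At a
#' polytomy the division is by the actual number of children. ES scores
#' sum to the tree's total PD.
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector (one value per tip, in My).
#' @export
es_scores <- function(tree) {
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (n == 1L) return(stats::setNames(faith_pd(tree), tree$tip.label))
  nchild <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  pre <- .preorder_edges(tree)
  acc <- numeric(n + tree$Nnode)
  for (i in seq_len(nrow(pre$edge))) {
    par <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
    acc[ch] <- acc[par] / nchild[par] + pre$length[i]
  }
  # acc at an internal node already includes its own stem; when passing to
  # children everything accumulated so far is split among them
  stats::setNames(acc[seq_len(n)], tree$tip.label)
}

#' Quadratic-entropy originality weights
#'
#' The tip-weight vector maximizing Rao's quadratic entropy
#' `Q(w) = w' D w / 2` on the patristic distance matrix `D` over the
#' probability simplex. Tips carrying the phylogeny's deep, isolated
#' branches receive high weight; redundant tips may receive weight zero.
#' Solved by an active-set method exploiting that `D` is conditionally
#' negative definite for tree metrics (the problem is concave on the
#' simplex).
#'
#' @param tree A `phylo` object with at least 2 tips.
#' @param tol Convergence/KKT tolerance.
#' @return Named numeric vector of nonnegative weights summing to 1, with
#'   attribute `objective` (the maximal quadratic entropy).
#' @export
qe_scores <- function(tree, tol = 1e-9) {
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (n < 2L) stop("QE originality needs at least 2 tips", call. = FALSE)
  D <- patristic_matrix(tree)
  w <- .max_rao_simplex(D, tol = tol)
  structure(stats::setNames(w$weights, tree$tip.label),
            objective = w$objective)
}

# Active-set maximization of w' D w / 2 over the simplex.
# On the current support S, stationarity gives D_SS w_S = mu * 1, sum = 1.
.max_rao_simplex <- function(D, tol = 1e-9, max_iter = 500L) {
  n <- nrow(D)
  support <- seq_len(n)
  w <- rep(0, n)
  solve_support <- function(S) {
    Dss <- D[S, S, drop = FALSE]
    v <- tryCatch(solve(Dss, rep(1, length(S))),
                  error = function(e) MASS::ginv(Dss) %*% rep(1, length(S)))
    v <- as.numeric(v)
    if (abs(sum(v)) < tol) return(rep(1 / length(S), length(S)))
    v / sum(v)
  }
  for (iter in seq_len(max_iter)) {
    ws <- solve_support(support)
    # drop negative-weight tips one at a time (most negative first)
    while (any(ws < -tol)) {
      if (length(support) <= 2L) { ws <- pmax(ws, 0); ws <- ws / sum(ws); break }
      support <- support[-which.min(ws)]
      ws <- solve_support(support)
    }
    w[] <- 0
    w[support] <- pmax(ws, 0)
    w <- w / sum(w)
    # KKT: excluded tips must not increase the objective; gradient (Dw)_j
    g <- as.numeric(D %*% w)
    mu <- mean(g[support])
    outside <- setdiff(seq_len(n), support)
    viol <- outside[g[outside] > mu + 1e-8]
    if (!length(viol)) {
      if (max(abs(g[support] - mu)) > 1e-6 && length(support) > 1L)
        warning("QE solver: interior gradient equalization not met to 1e-6",
                call. = FALSE)
      return(list(weights = w, objective = sum(w * g) / 2))
    }
    support <- sort(c(support, viol[which.max(g[viol])]))
  }
  stop("QE originality optimizer failed to converge after ", max_iter,
       " iterations", call. = FALSE)
}

#' All three distinctiveness indices as a table
#'
#' @param tree A `phylo` object (>= 2 tips).
#' @return A data.frame with columns `species`, `ed`, `es`, `qe`.
#' @export
distinctiveness_scores <- function(tree) {
  data.frame(species = tree$tip.label,
             ed = as.numeric(ed_scores(tree)[tree$tip.label]),
             es = as.numeric(es_scores(tree)[tree$tip.label]),
             qe = as.numeric(qe_scores(tree)[tree$tip.label]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation between distinctiveness and extinction risk
#'
#' Rank-based (midranks on both sides) correlation between each
#' distinctiveness index and the ordinal risk rank, computed on the
#' species shared between the two inputs.
#'
#' @param scores A data.frame from [distinctiveness_scores()] (columns
#'   `species` plus one or more index columns).
#' @param risk Named category vector without DD (use [apply_dd_scenario()]
#'   to include DD species as LC or CR).
#' @return Named numeric vector of Spearman rho per index (`NA` with a
#'   warning when risk has zero variance).
#' @export
distinctiveness_risk_correlation <- function(scores, risk) {
  rr <- risk_rank(risk)
  common <- intersect(scores$species, names(rr))
  if (length(common) < 3L)
    stop("need at least 3 shared species", call. = FALSE)
  if (length(unique(rr[common])) == 1L) {
    warning("risk has zero variance; correlation not computable", call. = FALSE)
    idx <- setdiff(names(scores), "species")
    return(stats::setNames(rep(NA_real_, length(idx)), idx))
  }
  idx <- setdiff(names(scores), "species")
  rows <- match(common, scores$species)
  vapply(idx, function(j)
    stats::cor(scores[[j]][rows], rr[common], method = "spearman"),
    1.0)
}
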