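#' Faith's phylogenetic diversity
#'
#' Sum of all branch lengths of the tree (or clade subtree, which excludes
#' the stem branch above the clade's MRCA).
#'
#' @param tree A `phylo` object.
#' @return Total branch length (same units as the tree, typically My).
#' @examples
#' faith_pd(parse_newick("((A:1,B:1):1,C:2);"))  # 5
#' @export
faith_pd <- function(tree) {
  tree <- validate_phylogeny(tree)
  sum(tree$edge.length)
}

# Per-edge expected-loss terms L_b * prod_{tips below b} p_ext, vectorised
# over K probability columns. Returns an n_edge x K matrix in tree$edge order.
.edge_loss_terms <- function(tree, P) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  K <- ncol(P)
  logp <- matrix(0, nn, K)
  logp[seq_len(n), ] <- log(P)
  for (i in seq_len(nrow(tr$edge))) {
    logp[tr$edge[i, 1L], ] <- logp[tr$edge[i, 1L], ] + logp[tr$edge[i, 2L], ]
  }
  # back in the original edge order: term for edge e uses its child node
  loss <- exp(logp[tree$edge[, 2L], , drop = FALSE]) * tree$edge.length
  loss
}

.match_probs <- function(tree, p_ext) {
  if (is.null(names(p_ext)))
    stop("p_ext must be named by species", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(p_ext))
  if (length(missing))
    stop("missing extinction probabilities for: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  p <- p_ext[tree$tip.label]
  if (any(p < 0 | p > 1))
    stop("extinction probabilities must be in [0, 1]", call. = FALSE)
  p
}

#' Expected future phylogenetic diversity
#'
#' Under independent per-species extinctions, a branch survives if at least
#' one tip descending from it survives, so
#' `expPD = sum_b L_b * (1 - prod_{i below b} p_i)`.
#'
#' @param tree A `phylo` object.
#' @param p_ext Named numeric vector of per-species extinction
#'   probabilities covering all tips.
#' @return Expected surviving branch length.
#' @export
expected_pd <- function(tree, p_ext) {
  tree <- validate_phylogeny(tree)
  p <- .match_probs(tree, p_ext)
  faith_pd(tree) - sum(.edge_loss_terms(tree, matrix(p, ncol = 1L)))
}

#' Relative expected loss of phylogenetic diversity
#'
#' `PDloss = (PD - expPD) / PD`, the expected fraction of current
#' phylogenetic diversity lost over the model horizon.
#'
#' @inheritParams expected_pd
#' @return A list of class `pdloss` with elements `pd`, `exp_pd`,
#'   `pd_loss`.
#' @examples
#' tr <- parse_newick("(A:1);")
#' pd_loss(tr, extinction_probabilities(c(A = "CR")))$pd_loss  # 0.97
#' @export
pd_loss <- function(tree, p_ext) {
  tree <- validate_phylogeny(tree)
  pd <- faith_pd(tree)
  if (pd <= 0)
    stop("PDloss is undefined for a tree with zero total branch length",
         call. = FALSE)
  ep <- expected_pd(tree, p_ext)
  structure(list(pd = pd, exp_pd = ep, pd_loss = (pd - ep) / pd),
            class = "pdloss")
}

#' @export
print.pdloss <- function(x, ...) {
  cat(sprintf("PD = %.6g, expPD = %.6g, PDloss = %.4f (%.2f%%)\n",
              x$pd, x$exp_pd, x$pd_loss, 100 * x$pd_loss))
  invisible(x)
}

# nodes (internal + tip numbers) properly descending from `node`
.descendant_nodes <- function(tree, node) {
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  todo <- node
  out <- integer(0)
  while (length(todo)) {
    ch <- children[[as.character(todo[[1L]])]]
    todo <- c(todo[-1L], ch[ch > ape::Ntip(tree)])
    out <- c(out, ch)
  }
  out
}

# logical index over tree$edge rows: edges strictly inside the clade
# (child is a proper descendant of the clade MRCA; stem edge excluded)
.clade_edge_mask <- function(tree, tips) {
  if (setequal(tips, tree$tip.label))
    return(rep(TRUE, nrow(tree$edge)))
  idx <- match(tips, tree$tip.label)
  if (length(tips) == 1L) return(tree$edge[, 2L] == idx)
  mrca <- ape::getMRCA(tree, tips)
  desc <- .descendant_nodes(tree, mrca)
  tree$edge[, 2L] %in% desc
}

#' Permutation test of PDloss against phylogeny-independent extinction
#'
#' Tests H0: the observed PDloss equals what is expected if extinction
#' probabilities were assigned to species independently of phylogeny.
#' Probabilities are shuffled across *all* tips of the full tree (global
#' shuffle); for each permutation PDloss is recomputed for each requested
#' clade on its stem-excluded subtree. The two-tailed p-value compares
#' absolute deviations from the permutation-null mean,
#' `p = (1 + #{|null - m| >= |obs - m|}) / (n_perm + 1)`, and the reported
#' direction is the sign of `obs - m` (`+`: more loss than random,
#' `-`: less).
#'
#' @inheritParams expected_pd
#' @param clades Named list of tip-label vectors (e.g. orders), or `NULL`
#'   for a single whole-tree test.
#' @param n_perm Number of permutations (default 200).
#' @param seed Optional integer seed for reproducibility.
#' @param within_clades If `TRUE`, shuffle probabilities within each clade
#'   instead of globally (non-default variant).
#' @return An object of class `pdloss_test`: list with a result `table`
#'   (clade, n_species, pd, exp_pd, pd_loss, p_value, direction), the
#'   per-clade `null` matrix, `n_perm` and `seed`.
#' @export
pdloss_permutation_test <- function(tree, p_ext, clades = NULL, n_perm = 200,
                                    seed = NULL, within_clades = FALSE) {
  tree <- validate_phylogeny(tree)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  p <- .match_probs(tree, p_ext)
  n <- ape::Ntip(tree)
  if (is.null(clades)) clades <- list(all = tree$tip.label)
  small <- vapply(clades, length, 1L) < 2L
  if (any(small))
    warning("clade(s) with fewer than 2 tips: ",
            paste(names(clades)[small], collapse = ", "), call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  P <- matrix(0, n, n_perm + 1L)
  P[, 1L] <- p
  if (within_clades) {
    idx_by_clade <- lapply(clades, function(tp) match(tp, tree$tip.label))
    for (k in seq_len(n_perm)) {
      pk <- p
      for (ii in idx_by_clade) pk[ii] <- pk[sample(ii)]
      P[, k + 1L] <- pk
    }
  } else {
    for (k in seq_len(n_perm)) P[, k + 1L] <- p[sample.int(n)]
  }

  loss <- .edge_loss_terms(tree, P)  # n_edge x (n_perm + 1)
  masks <- lapply(clades, function(tp) .clade_edge_mask(tree, tp))
  pd_clade <- vapply(masks, function(m) sum(tree$edge.length[m]), 1.0)
  if (any(pd_clade <= 0))
    stop("clade(s) with zero branch length: ",
         paste(names(clades)[pd_clade <= 0], collapse = ", "), call. = FALSE)

  stat <- t(vapply(masks, function(m) colSums(loss[m, , drop = FALSE]), numeric(n_perm + 1L)))
  stat <- stat / pd_clade  # clade x (n_perm + 1) matrix of PDloss values
  obs <- stat[, 1L]
  null <- stat[, -1L, drop = FALSE]
  m <- rowMeans(null)
  pval <- (1 + rowSums(abs(null - m) >= abs(obs - m))) / (n_perm + 1)
  tab <- data.frame(
    clade = names(clades),
    n_species = vapply(clades, length, 1L),
    pd = pd_clade,
    exp_pd = pd_clade * (1 - obs),
    pd_loss = obs,
    p_value = pval,
    direction = ifelse(obs >= m, "+", "-"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, null = null, n_perm = n_perm, seed = seed,
                 within_clades = within_clades),
            class = "pdloss_test")
}

#' @export
print.pdloss_test <- function(x, ...) {
  cat("PDloss permutation test (", x$n_perm, " permutations, ",
      if (x$within_clades) "within-clade" else "global", " shuffle)\n",
      sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Write a PDloss test table to CSV
#' @param x A `pdloss_test`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdloss_table <- function(x, file) {
  utils::write.csv(x$table, file, row.names = FALSE)
  invisible(file)
}
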