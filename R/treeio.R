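#' Parse a Newick string into a validated rooted phylogeny
#'
#' Wraps [ape::read.tree()] and enforces the invariants the rest of the
#' package relies on: a single root, non-empty unique tip labels, and a
#' branch length on every non-root edge.
#'
#' @param text Newick string (semicolon-terminated).
#' @param impute_missing_lengths If `TRUE`, edges without a branch length
#'   are assigned length 0 instead of raising an error.
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' faith_pd(tr)
#' @export
parse_newick <- function(text, impute_missing_lengths = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: unparsable string", call. = FALSE)
  validate_phylogeny(tr, impute_missing_lengths = impute_missing_lengths)
}

#' Read a phylogeny from a Newick file
#'
#' @param file Path to a Newick file containing a single tree.
#' @inheritParams parse_newick
#' @return A validated `phylo` object.
#' @export
read_phylogeny <- function(file, impute_missing_lengths = FALSE) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""),
               impute_missing_lengths = impute_missing_lengths)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Path to write to; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to file.
#' @export
write_phylogeny <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the invariants of a rooted phylogeny
#'
#' @param tree A `phylo` object.
#' @inheritParams parse_newick
#' @return The tree, invisibly unchanged (lengths possibly imputed).
#' @export
validate_phylogeny <- function(tree, impute_missing_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  tree$tip.label <- trimws(tree$tip.label)
  if (ape::Ntip(tree) < 1L) stop("tree must have at least one tip", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty tip labels are not allowed", call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (!impute_missing_lengths)
      stop("tree has no branch lengths (set impute_missing_lengths = TRUE to use 0)",
           call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!impute_missing_lengths)
      stop("missing branch lengths on ", sum(is.na(tree$edge.length)),
           " edge(s)", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  # exactly one root: every node except one has exactly one parent
  parent_count <- tabulate(tree$edge[, 2L], nbins = ape::Ntip(tree) + tree$Nnode)
  if (any(parent_count > 1L))
    stop("a node has more than one parent; not a tree", call. = FALSE)
  if (sum(parent_count == 0L) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  tree
}

#' Patristic distance matrix
#'
#' Tip-to-tip path lengths: the sum of branch lengths along the unique path
#' connecting two tips.
#'
#' @param tree A `phylo` object.
#' @return A symmetric numeric matrix with zero diagonal, rows/columns
#'   named by tip label.
#' @export
patristic_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  if (ape::Ntip(tree) == 1L) {
    d <- matrix(0, 1L, 1L, dimnames = list(tree$tip.label, tree$tip.label))
    return(d)
  }
  stats::cophenetic(tree)
}

#' Extract the subtree spanned by a monophyletic tip set
#'
#' Returns the rooted subtree below the most recent common ancestor of
#' `tips`. The stem branch above the MRCA is excluded, so [faith_pd()] of
#' the result is the branch length strictly inside the clade.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels forming a complete clade.
#' @return A `phylo` object.
#' @export
clade_subtree <- function(tree, tips) {
  tree <- validate_phylogeny(tree)
  tips <- trimws(tips)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (setequal(tips, tree$tip.label)) return(tree)
  if (length(tips) == 1L) {
    # degenerate clade: single tip with its pendant branch
    i <- match(tips, tree$tip.label)
    len <- tree$edge.length[tree$edge[, 2L] == i]
    return(parse_newick(sprintf("(%s:%.10g);", tips, len)))
  }
  mrca <- ape::getMRCA(tree, tips)
  below <- tips_below(tree, mrca)
  extra <- setdiff(below, tips)
  if (length(extra))
    stop("tip set is not monophyletic; MRCA also spans: ",
         paste(extra, collapse = ", "), call. = FALSE)
  ape::extract.clade(tree, mrca)
}

#' Tip labels descending from a node
#' @param tree A `phylo` object.
#' @param node Internal node number (or tip number, returning its label).
#' @return Character vector of tip labels.
#' @export
tips_below <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  # iterative descent; robust to polytomies and large trees
  todo <- node
  out <- integer(0)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(todo)) {
    cur <- todo[[1L]]
    todo <- todo[-1L]
    ch <- children[[as.character(cur)]]
    tips <- ch[ch <= n]
    out <- c(out, tips)
    todo <- c(todo, ch[ch > n])
  }
  tree$tip.label[out]
}

#' Read a clade map (e.g. order membership) from CSV
#'
#' Two columns, `clade` and `species`. Every species must be a tree tip and
#' each clade must be monophyletic on the supplied tree (validated).
#'
#' @param file CSV path.
#' @param tree A `phylo` object used for validation; species absent from the
#'   tree are dropped with a warning.
#' @return A named list of character vectors (tip labels per clade).
#' @export
read_clade_map <- function(file, tree) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("clade", "species") %in% names(df)))
    stop("clade map CSV needs columns 'clade' and 'species'", call. = FALSE)
  cm <- split(trimws(df$species), df$clade)
  validate_clade_map(cm, tree)
}

#' Validate a clade map against a tree
#'
#' @param clades Named list of tip-label vectors.
#' @param tree A `phylo` object.
#' @return The clade map with unmatched species dropped (warning emitted).
#' @export
validate_clade_map <- function(clades, tree) {
  tree <- validate_phylogeny(tree)
  out <- lapply(names(clades), function(nm) {
    sp <- trimws(clades[[nm]])
    unmatched <- setdiff(sp, tree$tip.label)
    if (length(unmatched)) {
      warning("clade '", nm, "': dropping ", length(unmatched),
              " species not in tree: ",
              paste(utils::head(unmatched, 5L), collapse = ", "),
              if (length(unmatched) > 5L) ", ..." else "", call. = FALSE)
      sp <- setdiff(sp, unmatched)
    }
    if (length(sp) >= 2L) {
      mrca <- ape::getMRCA(tree, sp)
      extra <- setdiff(tips_below(tree, mrca), sp)
      if (length(extra))
        stop("clade '", nm, "' is not monophyletic; also spans: ",
             paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
    }
    sp
  })
  names(out) <- names(clades)
  out[vapply(out, length, 1L) > 0L]
}
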