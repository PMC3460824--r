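# common container for permutation-test results
.new_perm_result <- function(statistic, observed, null, p_value, direction,
                             n_perm, seed, alternative, extra = list()) {
  structure(c(list(statistic = statistic, observed = observed, null = null,
                   p_value = p_value, direction = direction, n_perm = n_perm,
                   seed = seed, alternative = alternative), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%s, %d permutations, direction %s)\n",
              x$statistic, x$observed, x$p_value, x$alternative, x$n_perm,
              x$direction))
  invisible(x)
}

# (1 + count) / (1 + n_perm) permutation p-value
.perm_p <- function(obs, null, alternative) {
  n_perm <- length(null)
  count <- switch(alternative,
                  greater = sum(null >= obs),
                  less = sum(null <= obs),
                  two.sided = {
                    m <- mean(null)
                    sum(abs(null - m) >= abs(obs - m))
                  })
  (1 + count) / (1 + n_perm)
}

#' Phi coefficients between threat occurrence vectors
#'
#' For two binary vectors with joint counts `n11, n10, n01, n00`,
#' `phi = (n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)` — the
#' product-moment correlation of the 0/1 vectors, insensitive to how many
#' species each threat affects. Constant columns yield `NA` entries.
#'
#' @param threats Binary species-by-threat matrix.
#' @return Symmetric matrix of Phi coefficients with unit diagonal.
#' @export
phi_matrix <- function(threats) {
  X <- validate_incidence(threats, classes = NULL)
  if (nrow(X) < 2L) stop("need at least 2 species", call. = FALSE)
  n <- nrow(X)
  n11 <- crossprod(X)
  cs <- colSums(X)
  num <- n * n11 - cs %o% cs
  den <- sqrt(cs * (n - cs))
  phi <- num / (den %o% den)
  constant <- cs == 0L | cs == n
  phi[constant, ] <- NA_real_
  phi[, constant] <- NA_real_
  diag(phi) <- 1
  if (any(constant))
    warning("constant threat column(s) give undefined Phi: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
  phi
}

#' Threat diversity per species
#'
#' Number of distinct major threat classes recorded for each species
#' (row sums of the incidence matrix).
#'
#' @param threats Binary species-by-threat matrix.
#' @return Named integer vector.
#' @export
threat_counts <- function(threats) {
  X <- validate_incidence(threats, classes = NULL)
  stats::setNames(as.integer(rowSums(X)), rownames(X))
}

#' Validate a proximity matrix
#'
#' @param w Symmetric nonnegative species-by-species matrix, zero
#'   diagonal, named rows/columns.
#' @return The matrix, with class `proximity`.
#' @export
validate_proximity <- function(w) {
  w <- as.matrix(w)
  if (is.null(rownames(w))) stop("proximity matrix must be named", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-12)
    stop("proximity matrix must be symmetric (tolerance 1e-12)", call. = FALSE)
  if (any(w < 0)) stop("proximities must be nonnegative", call. = FALSE)
  diag(w) <- 0
  if (all(w == 0))
    stop("proximity matrix needs at least one positive off-diagonal entry",
         call. = FALSE)
  class(w) <- c("proximity", class(w))
  w
}

#' Build a proximity matrix from a tree or a label incidence matrix
#'
#' Phylogenetic proximities are `(d_max - d_ij) / d_max` from patristic
#' distances; geographic and habitat proximities are Jaccard similarities
#' of the species' label sets. Species with an empty label set get a zero
#' row (logged as a warning).
#'
#' @param kind `"phylogenetic"`, `"geographic"` or `"habitat"`.
#' @param tree A `phylo` object (phylogenetic kind).
#' @param labels Binary species-by-label matrix (geographic/habitat kinds).
#' @return A `proximity` matrix with a `kind` attribute.
#' @export
build_proximity <- function(kind = c("phylogenetic", "geographic", "habitat"),
                            tree = NULL, labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "phylogenetic") {
    if (is.null(tree)) stop("tree required for phylogenetic proximity",
                            call. = FALSE)
    d <- patristic_matrix(tree)
    w <- (max(d) - d) / max(d)
  } else {
    if (is.null(labels)) stop("label incidence required for ", kind,
                              " proximity", call. = FALSE)
    X <- validate_incidence(labels, classes = NULL)
    rs <- rowSums(X)
    if (any(rs == 0))
      warning(sum(rs == 0), " species with empty label set get zero proximity",
              call. = FALSE)
    inter <- X %*% t(X)
    union <- outer(rs, rs, "+") - inter
    w <- ifelse(union > 0, inter / union, 0)
  }
  diag(w) <- 0
  w <- validate_proximity(w)
  attr(w, "kind") <- kind
  w
}

#' Moran's I autocorrelation with permutation inference
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the mean-centered values and
#' `S0` the sum of all weights. The null distribution is obtained by
#' shuffling the values across species; by default the test is one-tailed
#' for positive autocorrelation.
#'
#' @param values Named numeric vector (e.g. threat counts per species).
#' @param w A proximity/weight matrix over the same species.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A `perm_test` with the observed I, null vector and p-value.
#' @export
morans_i <- function(values, w, n_perm = 999, seed = NULL,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  w <- validate_proximity(w)
  if (!is.null(names(values))) {
    if (!all(rownames(w) %in% names(values)))
      stop("values missing for some species in the proximity matrix",
           call. = FALSE)
    values <- values[rownames(w)]
  }
  n <- length(values)
  if (n != nrow(w)) stop("length mismatch between values and proximities",
                         call. = FALSE)
  if (stats::sd(values) == 0)
    stop("Moran's I is undefined for constant values", call. = FALSE)
  S0 <- sum(w)
  stat <- function(z) as.numeric(crossprod(z, w %*% z)) * n / (S0 * sum(z^2))
  z <- values - mean(values)
  obs <- stat(z)
  if (!is.null(seed)) set.seed(seed)
  Z <- vapply(seq_len(n_perm), function(k) z[sample.int(n)], numeric(n))
  null <- colSums(Z * (w %*% Z)) * n / (S0 * sum(z^2))
  .new_perm_result("I", obs, null, .perm_p(obs, null, alternative),
                   if (obs >= mean(null)) "+" else "-",
                   n_perm, seed, alternative)
}

# Structure-respecting restricted permutation of `values`.
# Positions are filled in random order; the probability of placing a
# remaining value v at position j grows with the centered proximity of j to
# already-filled positions holding values similar in rank to v:
#   P(v at j) \propto exp(strength * sum_k c[j,k] * s(v, v_k))
# with c = w - mean(off-diagonal w) and s(u,v) = 1 - |rank u - rank v|/(n-1).
# With uniform proximities c == 0 and the draw is a free permutation.
.restricted_permutation <- function(values, w, strength = 1) {
  n <- length(values)
  cmat <- w
  off <- cmat[row(cmat) != col(cmat)]
  cmat <- cmat - mean(off)
  diag(cmat) <- 0
  if (max(abs(cmat)) < 1e-12) return(sample(values))
  r <- rank(values, ties.method = "average")
  S <- 1 - abs(outer(r, r, "-")) / max(n - 1, 1)  # value-similarity matrix
  pos_order <- sample.int(n)
  placed_pos <- integer(0)
  placed_val <- integer(0)     # indices into `values`
  remaining <- seq_len(n)
  out <- numeric(n)
  for (j in pos_order) {
    if (length(placed_pos) == 0L) {
      pick <- sample(remaining, 1L)
    } else {
      score <- as.numeric(S[remaining, placed_val, drop = FALSE] %*%
                            cmat[j, placed_pos])
      pr <- exp(strength * (score - max(score)))
      pick <- remaining[sample.int(length(remaining), 1L, prob = pr)]
    }
    out[j] <- values[pick]
    placed_pos <- c(placed_pos, j)
    placed_val <- c(placed_val, pick)
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Rank correlation with structure-corrected permutation inference
#'
#' The observed statistic is the Spearman correlation (midranks) between
#' `x` and `y`. The null is generated by restricted permutations of `y`
#' that preferentially keep similar values at proximal species, so the
#' test accounts for phylogenetic, geographic, or habitat non-independence
#' rather than assuming exchangeability. With uniform (or absent)
#' proximities the null reduces to free permutation.
#'
#' @param x,y Named numeric vectors over the same species (e.g. threat
#'   counts and risk ranks).
#' @param w Optional `proximity` matrix; `NULL` or an all-equal matrix
#'   gives the free-permutation test.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param strength Weighting strength of the restricted sampler.
#' @return A `perm_test` with the observed Spearman r.
#' @export
corrected_rank_correlation <- function(x, y, w = NULL, n_perm = 999,
                                       seed = NULL,
                                       alternative = c("two.sided", "greater", "less"),
                                       strength = 1) {
  alternative <- match.arg(alternative)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
    if (!is.null(w)) w <- w[common, common]
  }
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  if (!is.null(w)) {
    w <- validate_proximity(w)
    off <- w[row(w) != col(w)]
    if (all(off == 0)) {
      warning("degenerate proximities; falling back to free permutation",
              call. = FALSE)
      w <- NULL
    }
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  obs <- stats::cor(rx, ry)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    yp <- if (is.null(w)) y[sample.int(n)] else
      .restricted_permutation(y, w, strength)
    stats::cor(rx, rank(yp, ties.method = "average"))
  }, 1.0)
  .new_perm_result("r", obs, null, .perm_p(obs, null, alternative),
                   if (obs >= mean(null)) "+" else "-",
                   n_perm, seed, alternative)
}

#' Test for a shift in mean threat count between two risk groups
#'
#' Compares the mean of a discrete count variable between two groups
#' (e.g. species in two adjacent risk categories). The statistic
#' `T = (mean_B - mean_A) / sd_perm` is the raw mean difference divided by
#' its standard deviation under permutation of the group labels. Inference
#' is exact (exhaustive enumeration of label assignments) when their
#' number does not exceed `exact_limit`, otherwise Monte-Carlo with
#' `n_perm` draws; a `proximity` matrix switches the Monte-Carlo draws to
#' the restricted sampler.
#'
#' @param x Named numeric vector of counts.
#' @param groups Factor/character vector over the same species with
#'   exactly 2 levels; the second level plays the "higher risk" role B.
#' @param w Optional `proximity` matrix for restricted permutations.
#' @param n_perm Monte-Carlo permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default; B exceeds A), `"less"` or
#'   `"two.sided"`.
#' @param exact_limit Maximum number of label assignments enumerated
#'   exhaustively.
#' @param strength Restricted-sampler strength.
#' @return A `perm_test` with statistic `T` and an `exact` flag.
#' @export
mean_shift_test <- function(x, groups, w = NULL, n_perm = 999, seed = NULL,
                            alternative = c("greater", "less", "two.sided"),
                            exact_limit = 1e6, strength = 1) {
  alternative <- match.arg(alternative)
  if (!is.null(names(x)) && !is.null(names(groups))) {
    common <- intersect(names(x), names(groups))
    x <- x[common]; groups <- groups[common]
    if (!is.null(w)) w <- w[common, common]
  }
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly 2 levels", call. = FALSE)
  nB <- sum(g == levels(g)[2L])
  nA <- sum(g == levels(g)[1L])
  if (nA == 0L || nB == 0L) stop("both groups must be non-empty", call. = FALSE)
  n <- length(x)
  diff_for <- function(bmask) mean(x[bmask]) - mean(x[!bmask])
  obs_diff <- diff_for(g == levels(g)[2L])

  n_assign <- choose(n, nB)
  exact <- is.null(w) && n_assign <= exact_limit
  if (exact) {
    combs <- utils::combn(n, nB)
    diffs <- apply(combs, 2L, function(idx) {
      m <- logical(n); m[idx] <- TRUE; diff_for(m)
    })
    sd_perm <- stats::sd(diffs)
    Tobs <- if (sd_perm > 0) obs_diff / sd_perm else 0
    Ts <- if (sd_perm > 0) diffs / sd_perm else diffs
    count <- switch(alternative,
                    greater = sum(Ts >= Tobs),
                    less = sum(Ts <= Tobs),
                    two.sided = sum(abs(Ts - mean(Ts)) >= abs(Tobs - mean(Ts))))
    p <- count / length(Ts)  # exhaustive: observed assignment is included
    return(.new_perm_result("T", Tobs, Ts, p,
                            if (obs_diff >= 0) "+" else "-",
                            length(Ts), seed, alternative,
                            extra = list(exact = TRUE)))
  }
  if (!is.null(seed)) set.seed(seed)
  gnum <- as.integer(g == levels(g)[2L])
  diffs <- vapply(seq_len(n_perm), function(k) {
    gp <- if (is.null(w)) gnum[sample.int(n)] else
      .restricted_permutation(gnum, w, strength)
    diff_for(gp == 1L)
  }, 1.0)
  sd_perm <- stats::sd(diffs)
  Tobs <- if (sd_perm > 0) obs_diff / sd_perm else 0
  Ts <- if (sd_perm > 0) diffs / sd_perm else diffs
  .new_perm_result("T", Tobs, Ts, .perm_p(Tobs, Ts, alternative),
                   if (obs_diff >= 0) "+" else "-",
                   n_perm, seed, alternative,
                   extra = list(exact = FALSE))
}

#' Order-level correlation between mean threat count and PDloss
#'
#' Pairs each clade's mean threat count with its PDloss and reports the
#' Pearson correlation (raw and rank-transformed) with its t statistic on
#' `n - 2` degrees of freedom.
#'
#' @param clades Named list of tip-label vectors.
#' @param counts Named threat-count vector over species.
#' @param pdloss_by_clade Named numeric vector of PDloss per clade.
#' @return A list with `mean_counts`, `pd_loss`, and per-variant
#'   `r`, `t`, `df`, `p`.
#' @export
order_level_correlation <- function(clades, counts, pdloss_by_clade) {
  common <- intersect(names(clades), names(pdloss_by_clade))
  if (length(common) < 3L) stop("need at least 3 clades", call. = FALSE)
  mc <- vapply(common, function(nm) {
    sp <- intersect(clades[[nm]], names(counts))
    if (!length(sp)) stop("no counted species in clade ", nm, call. = FALSE)
    mean(counts[sp])
  }, 1.0)
  pl <- pdloss_by_clade[common]
  if (stats::sd(mc) == 0 || stats::sd(pl) == 0)
    stop("correlation undefined: constant clade values", call. = FALSE)
  corr_with_t <- function(a, b) {
    r <- stats::cor(a, b)
    df <- length(a) - 2L
    if (df < 1L) stop("need at least 3 clades for a t test", call. = FALSE)
    t <- r * sqrt(df / (1 - r^2))
    list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  list(mean_counts = mc, pd_loss = pl,
       pearson = corr_with_t(mc, pl),
       rank = corr_with_t(rank(mc), rank(pl)))
}
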