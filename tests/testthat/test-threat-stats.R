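test_that("Phi coefficients match correlation and their symmetry invariances", {
  X <- cbind(a = c(1, 1, 0, 0, 1), b = c(1, 1, 0, 0, 1),
             c = c(0, 0, 1, 1, 0))
  rownames(X) <- paste0("s", 1:5)
  phi <- phi_matrix(X)
  expect_equal(phi["a", "b"], 1)
  expect_equal(phi["a", "c"], -1)   # complementary columns
  expect_true(all(diag(phi) == 1))

  set.seed(31)
  Y <- random_incidence(40, 6)
  phiY <- phi_matrix(Y)
  expect_equal(phiY[lower.tri(phiY)], cor(Y)[lower.tri(phiY)],
               tolerance = 1e-12)
  expect_equal(phiY, t(phiY))
  # relabeling 0/1 in both vectors simultaneously leaves phi unchanged
  expect_equal(phi_matrix(1L - Y), phiY, tolerance = 1e-12)

  const <- cbind(Y, allzero = 0L)
  expect_warning(pc <- phi_matrix(const), "constant")
  expect_true(all(is.na(pc["allzero", colnames(Y)])))
})

test_that("threat counts are row sums bounded by the number of classes", {
  X <- rbind(none = rep(0L, 11), all = rep(1L, 11))
  colnames(X) <- threat_classes()
  expect_equal(unname(threat_counts(X)), c(0L, 11L))
  set.seed(32)
  Y <- random_incidence(20, 7)
  expect_equal(unname(threat_counts(Y)), unname(rowSums(Y)))
})

test_that("Moran's I matches closed forms and an independent implementation", {
  set.seed(33)
  n <- 15
  W <- uniform_proximity(n)
  v <- stats::setNames(rnorm(n), rownames(W))
  mi <- morans_i(v, W, n_perm = 99, seed = 1)
  expect_equal(mi$observed, -1 / (n - 1), tolerance = 1e-12)

  # two-block weights with block-constant values: direct formula oracle
  Wb <- matrix(0, 10, 10, dimnames = list(paste0("s", 1:10), paste0("s", 1:10)))
  Wb[1:5, 1:5] <- 1; Wb[6:10, 6:10] <- 1; diag(Wb) <- 0
  vb <- stats::setNames(rep(c(0, 1), each = 5), rownames(Wb))
  z <- vb - mean(vb)
  oracle <- 0
  for (i in 1:10) for (j in 1:10) oracle <- oracle + Wb[i, j] * z[i] * z[j]
  oracle <- unname((10 / sum(Wb)) * oracle / sum(z^2))
  mb <- morans_i(vb, Wb, n_perm = 99, seed = 2)
  expect_equal(mb$observed, oracle, tolerance = 1e-12)
  expect_equal(mb$observed,
               ape::Moran.I(as.numeric(vb), Wb)$observed, tolerance = 1e-10)

  # determinism and the permutation-null expectation -1/(n-1)
  m1 <- morans_i(vb, Wb, n_perm = 499, seed = 9)
  m2 <- morans_i(vb, Wb, n_perm = 499, seed = 9)
  expect_identical(m1$null, m2$null)
  expect_lt(abs(mean(m1$null) - (-1 / 9)), 4 * sd(m1$null) / sqrt(499))
  expect_error(morans_i(stats::setNames(rep(1, 10), rownames(Wb)), Wb),
               "constant")
})

test_that("corrected rank correlation reduces to the free test under uniform proximities", {
  set.seed(34)
  n <- 6
  x <- stats::setNames(c(3, 1, 4, 1, 5, 9), paste0("s", 1:n))
  y <- stats::setNames(c(2, 7, 1, 8, 2, 8), paste0("s", 1:n))
  W <- uniform_proximity(n, names(x))
  res <- corrected_rank_correlation(x, y, w = W, n_perm = 10000, seed = 3)
  # exhaustive free-permutation null over all 6! arrangements
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(ix) length(unique(ix)) == n), ]
  rx <- rank(x)
  exact <- apply(perms, 1, function(ix) cor(rx, rank(y[ix])))
  # total-variation distance between sampled and exhaustive null
  br <- sort(unique(round(exact, 10)))
  p_exact <- table(factor(round(exact, 10), levels = br)) / length(exact)
  p_mc <- table(factor(round(res$null, 10), levels = br)) / length(res$null)
  expect_lt(0.5 * sum(abs(p_exact - p_mc)), 0.05)

  # p-value agrees with the exhaustive two-sided construction; the null is
  # discrete, so mass at the |deviation| boundary dominates the tolerance
  m <- mean(exact)
  p_exh <- mean(abs(exact - m) >= abs(res$observed - m))
  expect_lt(abs(res$p_value - p_exh), 0.05)
})

test_that("corrected rank correlation honors its contracts", {
  set.seed(35)
  n <- 20
  x <- stats::setNames(rpois(n, 3), sprintf("s%03d", 1:n))
  y <- 2 * x + 1  # strictly increasing function of x
  res <- corrected_rank_correlation(x, stats::setNames(y, names(x)),
                                    n_perm = 99, seed = 4)
  expect_equal(res$observed, 1)
  expect_equal(res$direction, "+")

  # degenerate proximities fall back to free permutation with a warning
  w0 <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  expect_error(corrected_rank_correlation(x, y, w = w0), "positive")

  # structured proximities give a valid, deterministic null
  tr <- simulate_tree(n, seed = 6)
  w <- build_proximity("phylogenetic", tree = tr)
  xs <- stats::setNames(rpois(n, 3) + seq_len(n) %% 3, tr$tip.label)
  ys <- stats::setNames(rnorm(n), tr$tip.label)
  r1 <- corrected_rank_correlation(xs, ys, w = w, n_perm = 49, seed = 11)
  r2 <- corrected_rank_correlation(xs, ys, w = w, n_perm = 49, seed = 11)
  expect_identical(r1$null, r2$null)
  expect_gte(r1$p_value, 1 / 50)
})

test_that("mean-shift test matches exhaustive enumeration on small groups", {
  x <- stats::setNames(c(1, 2, 2, 3, 5, 6, 7), paste0("s", 1:7))
  g <- stats::setNames(c("A", "A", "A", "A", "B", "B", "B"), names(x))
  res <- mean_shift_test(x, g, alternative = "greater")
  expect_true(res$exact)
  # independent bitmask oracle over all C(7,3) assignments
  diffs <- c()
  for (mask in 0:(2^7 - 1)) {
    b <- as.logical(bitwAnd(mask, 2^(0:6)))
    if (sum(b) == 3L) diffs <- c(diffs, mean(x[b]) - mean(x[!b]))
  }
  obs_diff <- mean(x[g == "B"]) - mean(x[g == "A"])
  expect_equal(res$p_value, mean(diffs >= obs_diff - 1e-12),
               tolerance = 1e-12)
  expect_equal(res$observed, obs_diff / sd(diffs), tolerance = 1e-10)

  # strictly separated groups attain the minimum p
  expect_equal(res$p_value, 1 / choose(7, 3), tolerance = 1e-12)

  # identical group distributions: T = 0, p large
  x2 <- stats::setNames(c(1, 1, 1, 2, 2, 2, 1, 1, 1, 2, 2, 2), paste0("t", 1:12))
  g2 <- stats::setNames(rep(c("A", "B"), each = 6), names(x2))
  res2 <- mean_shift_test(x2, g2, alternative = "greater")
  expect_equal(res2$observed, 0, tolerance = 1e-10)
  expect_gt(res2$p_value, 0.4)
  expect_error(mean_shift_test(x, stats::setNames(rep("A", 7), names(x))),
               "2 levels")
})

test_that("order-level correlation reports r, t, df and guards boundaries", {
  set.seed(36)
  tr <- simulate_tree(60, imbalance = 0.4)
  clades <- deep_clades(tr, 8)
  counts <- stats::setNames(rpois(60, 3), tr$tip.label)
  pl <- stats::setNames(runif(length(clades)), names(clades))
  res <- order_level_correlation(clades, counts, pl)
  mc <- res$mean_counts
  # covariance-formula oracle
  r_manual <- sum((mc - mean(mc)) * (pl - mean(pl))) /
    sqrt(sum((mc - mean(mc))^2) * sum((pl - mean(pl))^2))
  expect_equal(res$pearson$r, r_manual, tolerance = 1e-12)
  expect_equal(res$pearson$df, length(clades) - 2L)
  expect_equal(res$pearson$t,
               r_manual * sqrt((length(clades) - 2) / (1 - r_manual^2)),
               tolerance = 1e-10)

  # perfectly aligned means give r = 1
  res1 <- order_level_correlation(clades, counts,
                                  stats::setNames(mc, names(clades)))
  expect_equal(res1$pearson$r, 1, tolerance = 1e-12)
  expect_error(order_level_correlation(clades[1:2], counts, pl[1:2]),
               "at least 3")
})

test_that("proximity builders produce valid similarity structures", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  w <- build_proximity("phylogenetic", tree = tr)
  expect_equal(w["A", "C"], 0)        # maximally distant pair
  expect_gt(w["A", "B"], 0)
  expect_true(all(diag(w) == 0))

  L <- rbind(A = c(1, 1, 0), B = c(1, 1, 0), C = c(0, 0, 1))
  colnames(L) <- paste0("a", 1:3)
  wj <- build_proximity("geographic", labels = L)
  expect_equal(wj["A", "B"], 1)       # identical label sets
  expect_equal(wj["A", "C"], 0)

  set.seed(37)
  Lr <- random_incidence(15, 4)
  Lr[rowSums(Lr) == 0, 1] <- 1L  # every species needs at least one label
  wr <- build_proximity("habitat", labels = Lr)
  expect_true(all(wr >= 0 & wr <= 1))
  expect_equal(wr, t(wr))
  expect_true(all(diag(wr) == 0))
  L0 <- rbind(Lr, empty = rep(0L, 4))
  expect_warning(build_proximity("geographic", labels = L0), "empty label")
})
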