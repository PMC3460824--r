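test_that("DPCoA handles the trivial geometries correctly", {
  tr <- parse_newick("(A:1,B:1);")
  D <- patristic_matrix(tr)
  # two threats affecting identical species sets: coincident centroids
  X <- matrix(c(1, 1, 1, 1), 2, 2,
              dimnames = list(c("A", "B"), c("t1", "t2")))
  res <- dpcoa(X, D)
  expect_equal(res$total_inertia, 0, tolerance = 1e-10)

  # two threats on two distinct species: centroid distance = species distance
  X2 <- diag(2)
  dimnames(X2) <- list(c("A", "B"), c("t1", "t2"))
  res2 <- dpcoa(X2, D, transform = "none")
  expect_equal(length(res2$eigenvalues), 1L)
  sep <- abs(res2$row_coords["t1", 1] - res2$row_coords["t2", 1])
  expect_equal(sep, D["A", "B"], tolerance = 1e-10)
})

test_that("DPCoA between-threat inertia equals the Rao decomposition", {
  set.seed(23)
  for (rep in 1:3) {
    tr <- simulate_tree(25, imbalance = 0.3)
    X <- random_incidence(25, 6, labels = tr$tip.label)
    D <- patristic_matrix(tr)
    res <- dpcoa(X, D)  # sqrt transform: embedded squared distances = D
    keep <- rownames(X)[rowSums(X) > 0]
    Xa <- X[keep, , drop = FALSE]
    nt <- colSums(Xa)
    w <- nt / sum(nt)
    P <- sweep(Xa, 2, nt, "/")
    Dsq <- D[keep, keep]
    Q <- function(p) 0.5 * sum((p %o% p) * Dsq)
    between <- Q(as.numeric(P %*% w)) -
      sum(vapply(seq_along(w), function(t) w[t] * Q(P[, t]), 1.0))
    expect_equal(res$total_inertia, between, tolerance = 1e-8)
    # centroid contraction: between-threat <= total species inertia
    expect_lte(res$total_inertia, res$species_inertia + 1e-10)
  }
})

test_that("DPCoA drops unaffected species and empty threats per contract", {
  set.seed(24)
  tr <- simulate_tree(12)
  X <- random_incidence(12, 4, labels = tr$tip.label)
  X[1:3, ] <- 0L             # unaffected species
  X <- cbind(X, empty = 0L)
  expect_warning(res <- dpcoa(X, patristic_matrix(tr)), "empty threat")
  expect_equal(nrow(res$col_coords), sum(rowSums(X) > 0))
  expect_equal(nrow(res$row_coords), 4L)
})

test_that("correspondence analysis reproduces chi-square geometry", {
  # rank-1 table: perfect independence, zero inertia
  outer_tab <- outer(c(2, 3, 5), c(1, 4, 2, 3))
  res0 <- correspondence_analysis(outer_tab)
  expect_equal(res0$total_inertia, 0, tolerance = 1e-12)

  # perfectly opposed 2x2 block table: single axis with inertia 1
  res1 <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(length(res1$eigenvalues), 1L)
  expect_equal(res1$total_inertia, 1, tolerance = 1e-10)
  expect_lt(res1$row_coords[1, 1] * res1$row_coords[2, 1], 0)

  # chi-square oracle on random tables
  set.seed(25)
  for (rep in 1:3) {
    tab <- matrix(rpois(20, 6), 5, 4)
    res <- correspondence_analysis(tab)
    chi2 <- suppressWarnings(chisq.test(tab)$statistic)
    expect_equal(res$total_inertia, unname(chi2) / sum(tab),
                 tolerance = 1e-10)
  }
})

test_that("CA agrees with an independent implementation and its transition formulas", {
  set.seed(26)
  tab <- matrix(rpois(24, 8) + 1, 6, 4,
                dimnames = list(paste0("r", 1:6), paste0("c", 1:4)))
  res <- correspondence_analysis(tab)
  ref <- vegan::cca(tab)
  expect_equal(res$eigenvalues, unname(ref$CA$eig)[seq_along(res$eigenvalues)],
               tolerance = 1e-8)
  # row and column clouds carry the same per-axis inertia
  P <- tab / sum(tab)
  r <- rowSums(P); cc <- colSums(P)
  row_inertia <- colSums(res$row_coords^2 * r)
  col_inertia <- colSums(res$col_coords^2 * cc)
  expect_equal(row_inertia, col_inertia, tolerance = 1e-8)
  expect_equal(unname(row_inertia), res$eigenvalues, tolerance = 1e-8)
})

test_that("CA drops zero margins with a warning and keeps the contract", {
  tab <- rbind(c(5, 2, 0), c(0, 0, 0), c(1, 4, 0))
  expect_warning(res <- correspondence_analysis(tab), "all-zero")
  expect_equal(nrow(res$row_coords), 2L)
  expect_equal(nrow(res$col_coords), 2L)
  expect_error(suppressWarnings(correspondence_analysis(matrix(0, 2, 2))),
               "grand total")
})

test_that("threat-by-label tables count species having both attributes", {
  X <- matrix(c(1, 0, 1, 1), 2, 2,
              dimnames = list(c("A", "B"), c("t1", "t2")))
  L <- matrix(c(1, 0, 1, 1), 2, 2,
              dimnames = list(c("A", "B"), c("a1", "a2")))
  tab <- build_threat_by_label_table(X, L)
  # brute-force oracle
  oracle <- matrix(0L, 2, 2, dimnames = dimnames(tab))
  for (t in colnames(X)) for (a in colnames(L))
    for (s in c("A", "B"))
      oracle[t, a] <- oracle[t, a] + X[s, t] * L[s, a]
  expect_equal(unclass(tab), unclass(oracle))

  # one species, one threat, two areas -> row of [1, 1]
  one <- build_threat_by_label_table(
    matrix(1, 1, 1, dimnames = list("A", "t")),
    matrix(1, 1, 2, dimnames = list("A", c("x", "y"))))
  expect_equal(as.numeric(one), c(1, 1))
  expect_error(build_threat_by_label_table(
    matrix(1, 1, 1, dimnames = list("A", "t")),
    matrix(1, 1, 1, dimnames = list("Z", "x"))), "no shared species")

  set.seed(27)
  X2 <- random_incidence(15, 5)
  L2 <- random_incidence(15, 3)
  tab2 <- build_threat_by_label_table(X2, L2)
  oracle2 <- matrix(0L, 5, 3, dimnames = dimnames(tab2))
  for (t in seq_len(5)) for (a in seq_len(3)) for (s in seq_len(15))
    oracle2[t, a] <- oracle2[t, a] + X2[s, t] * L2[s, a]
  expect_equal(unclass(tab2), unclass(oracle2))
})
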