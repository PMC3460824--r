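test_that("ED follows fair-proportion arithmetic and conserves PD", {
  tr <- parse_newick("((A:1,B:1):2,C:4);")
  ed <- ed_scores(tr)
  expect_equal(unname(ed[c("A", "B", "C")]), c(2, 2, 4))
  # star tree: ED is the own branch length
  star <- parse_newick("(a:1,b:2,c:3);")
  expect_equal(unname(ed_scores(star)[c("a", "b", "c")]), c(1, 2, 3))
  set.seed(14)
  for (rep in 1:3) {
    big <- simulate_tree(35, imbalance = runif(1, 0, 0.6))
    expect_equal(sum(ed_scores(big)), faith_pd(big), tolerance = 1e-9)
  }
})

test_that("ES generalizes equal splits to polytomies and conserves PD", {
  tr <- parse_newick("((A:1,B:1):2,C:4);")
  es <- es_scores(tr)
  expect_equal(unname(es[c("A", "B", "C")]), c(2, 2, 4))  # = ED on a cherry
  # polytomy: the stem is divided by the actual number of children (3)
  poly <- parse_newick("((A:1,B:1,C:1):3,D:4);")
  es_p <- es_scores(poly)
  expect_equal(unname(es_p["A"]), 1 + 3 / 3)
  expect_equal(sum(es_p), faith_pd(poly), tolerance = 1e-12)
  set.seed(15)
  big <- simulate_tree(35)
  expect_equal(sum(es_scores(big)), faith_pd(big), tolerance = 1e-9)
})

test_that("ED and ES agree with an independent reference implementation", {
  set.seed(16)
  tr <- simulate_tree(25, imbalance = 0.3)
  ref_ed <- picante::evol.distinct(tr, type = "fair.proportion")
  ref_es <- picante::evol.distinct(tr, type = "equal.splits")
  expect_equal(unname(ed_scores(tr)[ref_ed$Species]), ref_ed$w,
               tolerance = 1e-8)
  expect_equal(unname(es_scores(tr)[ref_es$Species]), ref_es$w,
               tolerance = 1e-8)
})

test_that("QE weights solve the simplex maximization of quadratic entropy", {
  # two tips: symmetric optimum regardless of branch lengths
  expect_equal(as.numeric(qe_scores(parse_newick("(A:1,B:9);"))), c(0.5, 0.5))
  # symmetric balanced ultrametric 4-tip tree: uniform weights
  expect_equal(as.numeric(qe_scores(balanced4())), rep(0.25, 4))

  # brute-force grid oracle on a fixed 4-tip tree (resolution 0.02)
  tr4 <- parse_newick("((A:1,B:3):2,(C:2,D:1):4);")
  D <- patristic_matrix(tr4)
  grid <- compositions(50L, 4L) / 50
  vals <- apply(grid, 1, function(w) 0.5 * sum((w %o% w) * D))
  w <- qe_scores(tr4)
  expect_gte(attr(w, "objective"), max(vals) - 1e-9)
  expect_lt(abs(attr(w, "objective") - max(vals)), 1e-3)

  # coarser grid on a random 6-tip tree: solver must dominate every point
  set.seed(17)
  tr6 <- simulate_tree(6)
  D6 <- patristic_matrix(tr6)
  grid6 <- compositions(20L, 6L) / 20
  vals6 <- apply(grid6, 1, function(w) 0.5 * sum((w %o% w) * D6))
  w6 <- qe_scores(tr6)
  expect_gte(attr(w6, "objective"), max(vals6) - 1e-9)
})

test_that("QE optimum satisfies KKT gradient equalization on the support", {
  set.seed(18)
  for (rep in 1:5) {
    tr <- simulate_tree(sample(5:12, 1), imbalance = runif(1, 0, 0.5))
    w <- qe_scores(tr)
    D <- patristic_matrix(tr)
    g <- as.numeric(D %*% w)
    sup <- w > 1e-8
    mu <- mean(g[sup])
    # supported tips sit at equal average distance to the assemblage
    expect_lt(max(abs(g[sup] - mu)), 1e-6)
    # excluded tips cannot improve the objective
    if (any(!sup)) expect_true(all(g[!sup] <= mu + 1e-6))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("all three indices are uniform on an equal-branch star tree", {
  star <- parse_newick("(a:2,b:2,c:2,d:2);")
  expect_true(all(abs(ed_scores(star) - 2) < 1e-12))
  expect_true(all(abs(es_scores(star) - 2) < 1e-12))
  expect_true(all(abs(qe_scores(star) - 0.25) < 1e-8))
})

test_that("risk correlation is Spearman with midranks and flags degeneracies", {
  set.seed(19)
  tr <- simulate_tree(20)
  scores <- distinctiveness_scores(tr)
  risk <- stats::setNames(sample(iucn_categories(), 20, replace = TRUE),
                          tr$tip.label)
  rho <- distinctiveness_risk_correlation(scores, risk)
  # textbook oracle: Pearson product-moment on midranks
  rr <- risk_rank(risk)[scores$species]
  manual <- function(x) {
    rx <- rank(x); ry <- rank(rr)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(unname(rho["ed"]), manual(scores$ed), tolerance = 1e-10)
  expect_equal(unname(rho["qe"]), manual(scores$qe), tolerance = 1e-10)

  # scores that are a strictly increasing function of risk rank give rho = 1
  inc <- data.frame(species = scores$species, ed = 2 * rr + 1)
  expect_equal(unname(distinctiveness_risk_correlation(inc, risk)["ed"]), 1,
               tolerance = 1e-10)
  # constant risk: not computable
  const <- stats::setNames(rep("LC", 20), tr$tip.label)
  expect_warning(out <- distinctiveness_risk_correlation(scores, const),
                 "zero variance")
  expect_true(all(is.na(out)))
  expect_error(distinctiveness_risk_correlation(scores[1:2, ], risk),
               "at least 3")
})
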