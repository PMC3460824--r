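#' Simulate an ultrametric pure-birth tree with tunable imbalance
#'
#' A Yule process conditioned on `n_species` tips: waiting times between
#' speciations are exponential with rate `birth * k` over `k` extant
#' lineages, and the splitting lineage is drawn proportionally to a
#' heritable weight. At every split the two daughters inherit weights
#' `(1 + imbalance)` and `(1 - imbalance)` times the parent's, so
#' `imbalance = 0` recovers the uniform Yule pick while values near 1
#' concentrate future splits in one lineage and produce the heavy
#' imbalance characteristic of the mammal tree.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth Speciation rate (events per My per lineage).
#' @param imbalance Imbalance knob in \[0, 1).
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with tips `s001`, `s002`, ...
#' @export
simulate_tree <- function(n_species, birth = 1, imbalance = 0, seed = NULL) {
  stopifnot(n_species >= 2, birth > 0, imbalance >= 0, imbalance < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_species)
  # lineage records; event e creates internal node n + e
  parent_event <- integer(2L * n)   # event that created each lineage
  weight <- numeric(2L * n)
  n_lin <- 2L
  parent_event[1:2] <- 1L
  weight[1:2] <- c(1 + imbalance, 1 - imbalance)
  active <- c(1L, 2L)
  ev_time <- numeric(n - 1L)
  ev_time[1L] <- 0
  split_of <- integer(n - 1L)       # event index that split each lineage (0 = tip)
  t_now <- 0
  e <- 1L
  while (length(active) < n) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1L, rate = birth * k)
    e <- e + 1L
    ev_time[e] <- t_now
    pick <- if (k == 1L) active else
      active[sample.int(k, 1L, prob = weight[active])]
    split_of[e] <- pick
    ch <- n_lin + 1:2
    parent_event[ch] <- e
    weight[ch] <- weight[pick] * c(1 + imbalance, 1 - imbalance)
    n_lin <- n_lin + 2L
    active <- c(setdiff(active, pick), ch)
  }
  T_total <- t_now + stats::rexp(1L, rate = birth * n)

  tips <- active[order(active)]
  edge <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  row <- 0L
  for (ee in 2:(n - 1L)) {       # internal edges (none when n == 2)
    if (n < 3L) break
    row <- row + 1L
    pe <- parent_event[split_of[ee]]
    edge[row, ] <- c(n + pe, n + ee)
    elen[row] <- ev_time[ee] - ev_time[pe]
  }
  for (i in seq_along(tips)) {   # pendant edges
    row <- row + 1L
    pe <- parent_event[tips[i]]
    edge[row, ] <- c(n + pe, i)
    elen[row] <- T_total - ev_time[pe]
  }
  tr <- structure(list(edge = edge, edge.length = elen, Nnode = n - 1L,
                       tip.label = sprintf("s%03d", seq_len(n))),
                  class = "phylo")
  tr <- stats::reorder(tr, "cladewise")
  validate_phylogeny(tr)
}

#' Simulate phylogenetically structured threat incidences
#'
#' Each threat's presence/absence arises from a liability-threshold model:
#' a standardized liability is a mixture `sqrt(signal) * z_BM +
#' sqrt(1 - signal) * z_iid` of a Brownian-motion trait evolved on the
#' tree and independent noise, and the species whose liabilities exceed
#' the empirical `1 - prevalence` quantile carry the threat, so every
#' threat column matches its target prevalence and is never degenerate.
#' `signal = 1` gives fully phylogenetic threats, `signal = 0`
#' independent of the tree.
#'
#' @param tree A `phylo` object.
#' @param n_threats Number of threat columns (11 gives the canonical
#'   threat-class names).
#' @param signal Phylogenetic signal in \[0, 1\], recycled per threat.
#' @param prevalence Target prevalence in (0, 1), recycled per threat.
#' @param seed Optional integer seed.
#' @return Binary species-by-threat incidence matrix.
#' @export
simulate_threats <- function(tree, n_threats = 11, signal = 0.5,
                             prevalence = 0.2, seed = NULL) {
  tree <- validate_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  signal <- rep_len(signal, n_threats)
  prevalence <- rep_len(prevalence, n_threats)
  stopifnot(all(signal >= 0 & signal <= 1),
            all(prevalence > 0 & prevalence < 1))
  C <- stats::cov2cor(ape::vcv(tree))
  R <- chol(C + diag(1e-10, n))
  X <- matrix(0L, n, n_threats)
  for (j in seq_len(n_threats)) {
    z_bm <- as.numeric(crossprod(R, stats::rnorm(n)))
    liab <- sqrt(signal[j]) * z_bm + sqrt(1 - signal[j]) * stats::rnorm(n)
    X[, j] <- as.integer(liab > stats::quantile(liab, 1 - prevalence[j]))
  }
  rownames(X) <- tree$tip.label
  colnames(X) <- if (n_threats == 11L) threat_classes() else
    sprintf("threat_%02d", seq_len(n_threats))
  X
}

# baseline Red-List-like category marginals used by simulate_risk
.risk_marginals <- function() c(LC = 0.64, NT = 0.06, VU = 0.12,
                                EN = 0.10, CR = 0.08)

#' Simulate extinction-risk categories coupled to threat diversity
#'
#' Ordinal categories come from a proportional-odds model: a logistic
#' latent variable `slope * scale(counts) + logistic noise` is cut at
#' thresholds chosen so that at `slope = 0` the marginal category
#' frequencies approximate Red-List-like proportions (64% LC, 6% NT,
#' 12% VU, 10% EN, 8% CR). A `dd_fraction` of species is then relabelled
#' DD independently of everything else.
#'
#' @param counts Named threat-count vector (from [threat_counts()]).
#' @param slope Coupling of risk to threat count (0 = independent).
#' @param dd_fraction Fraction of species relabelled data deficient.
#' @param seed Optional integer seed.
#' @return Named category vector (LC/NT/VU/EN/CR/DD).
#' @export
simulate_risk <- function(counts, slope = 1, dd_fraction = 0, seed = NULL) {
  stopifnot(dd_fraction >= 0, dd_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(counts)
  z <- if (stats::sd(counts) > 0) as.numeric(scale(counts)) else numeric(n)
  cuts <- stats::qlogis(cumsum(.risk_marginals())[1:4])
  latent <- slope * z + stats::rlogis(n)
  cat_idx <- findInterval(latent, cuts) + 1L
  risk <- iucn_categories()[cat_idx]
  names(risk) <- names(counts)
  if (dd_fraction > 0) {
    dd <- sample.int(n, size = round(dd_fraction * n))
    risk[dd] <- "DD"
  }
  validate_risk(risk)
}

#' Deepest disjoint subclades covering all tips
#'
#' Repeatedly splits the group whose root node is closest to the tree
#' root until `k` disjoint clades cover all tips — synthetic "orders"
#' guaranteeing per-clade tests always have material.
#'
#' @param tree A `phylo` object.
#' @param k Number of clades requested (the result can be smaller on tiny
#'   trees).
#' @return Named list of tip-label vectors (`order_01`, ...).
#' @export
deep_clades <- function(tree, k) {
  tree <- validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  root <- n + 1L
  groups <- tree$edge[tree$edge[, 1L] == root, 2L]
  repeat {
    if (length(groups) >= k) break
    internal <- groups[groups > n]
    if (!length(internal)) break
    split_node <- internal[which.min(depth[internal])]
    ch <- tree$edge[tree$edge[, 1L] == split_node, 2L]
    groups <- c(setdiff(groups, split_node), ch)
  }
  groups <- groups[order(depth[groups])]
  out <- lapply(groups, function(g) tips_below(tree, g))
  names(out) <- sprintf("order_%02d", seq_along(out))
  out
}

# multinomial label assignment linked to clade home labels and threat load
.simulate_labels <- function(tree, clades, counts, n_labels, assoc,
                             prefix, extra_rate = 0.15) {
  n <- ape::Ntip(tree)
  labels <- sprintf("%s_%02d", prefix, seq_len(n_labels))
  home <- stats::setNames(rep_len(seq_len(n_labels), length(clades)),
                          names(clades))
  clade_of <- stats::setNames(rep(names(clades)[1L], n),
                              tree$tip.label)
  for (nm in names(clades)) clade_of[clades[[nm]]] <- nm
  cnt_scaled <- if (stats::sd(counts) > 0) as.numeric(scale(counts[tree$tip.label]))
                else numeric(n)
  X <- matrix(0L, n, n_labels, dimnames = list(tree$tip.label, labels))
  for (i in seq_len(n)) {
    wts <- rep(1, n_labels)
    wts[home[clade_of[i]]] <- exp(assoc)           # clade-linked primary label
    primary <- sample.int(n_labels, 1L, prob = wts)
    X[i, primary] <- 1L
    # extra labels, more for heavily threatened species (threat link)
    p_extra <- min(0.9, extra_rate * exp(0.3 * assoc * cnt_scaled[i]))
    extras <- stats::runif(n_labels) < p_extra
    X[i, extras] <- 1L
  }
  X
}

#' Generate a complete synthetic dataset
#'
#' Composes the tree, threat, risk, and label simulators into a bundle
#' that passes every reader's validation: an imbalanced ultrametric
#' phylogeny, phylogenetically structured threat incidences, risk
#' categories coupled to threat diversity, synthetic orders, and
#' geographic-area and habitat incidences linked to clades and threat
#' load.
#'
#' @param n_species Number of species (default 300).
#' @param n_threats Number of threat classes (default 11).
#' @param birth Speciation rate.
#' @param imbalance Tree imbalance knob in \[0, 1).
#' @param signal Per-threat phylogenetic signal in \[0, 1\].
#' @param prevalence Per-threat prevalence in (0, 1).
#' @param risk_slope Coupling of risk category to threat count.
#' @param dd_fraction Fraction of data-deficient species.
#' @param n_areas,n_habitats Numbers of geographic areas and habitats.
#' @param label_assoc Clade/threat association strength of labels.
#' @param n_orders Number of synthetic orders (deep clades).
#' @param seed Optional integer seed (controls the whole bundle).
#' @param dir Optional directory; when given the bundle is written there
#'   (Newick + CSV + JSON manifest).
#' @return A list of class `synthetic_dataset` with elements `tree`,
#'   `risk`, `threats`, `areas`, `habitats`, `clades`, `params`.
#' @export
generate_dataset <- function(n_species = 300, n_threats = 11, birth = 1,
                             imbalance = 0.3, signal = 0.5, prevalence = 0.2,
                             risk_slope = 1, dd_fraction = 0.1,
                             n_areas = 8, n_habitats = 6, label_assoc = 1.5,
                             n_orders = 6, seed = NULL, dir = NULL) {
  stopifnot(n_species >= 3)
  if (!is.null(seed)) set.seed(seed)
  params <- list(n_species = n_species, n_threats = n_threats, birth = birth,
                 imbalance = imbalance, signal = signal,
                 prevalence = prevalence, risk_slope = risk_slope,
                 dd_fraction = dd_fraction, n_areas = n_areas,
                 n_habitats = n_habitats, label_assoc = label_assoc,
                 n_orders = n_orders, seed = seed)
  tree <- simulate_tree(n_species, birth = birth, imbalance = imbalance)
  threats <- simulate_threats(tree, n_threats = n_threats, signal = signal,
                              prevalence = prevalence)
  counts <- threat_counts(threats)
  risk <- simulate_risk(counts, slope = risk_slope,
                        dd_fraction = dd_fraction)
  clades <- deep_clades(tree, n_orders)
  areas <- .simulate_labels(tree, clades, counts, n_areas, label_assoc,
                            "area")
  habitats <- .simulate_labels(tree, clades, counts, n_habitats,
                               label_assoc, "habitat")
  ds <- structure(list(tree = tree, risk = risk, threats = threats,
                       areas = areas, habitats = habitats, clades = clades,
                       params = params),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", ape::Ntip(x$tree), "species,",
      ncol(x$threats), "threats,", length(x$clades), "orders,",
      ncol(x$areas), "areas,", ncol(x$habitats), "habitats\n")
  invisible(x)
}

#' Write a synthetic dataset bundle to a directory
#'
#' Emits `tree.nwk`, `risk.csv`, `threats.csv`, `areas.csv`,
#' `habitats.csv`, `clades.csv` and a `manifest.json` recording seed and
#' parameters — the same formats the package readers consume.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylogeny(ds$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(species = names(ds$risk),
                              category = as.character(ds$risk)),
                   file.path(dir, "risk.csv"), row.names = FALSE)
  write_incidence(ds$threats, file.path(dir, "threats.csv"))
  write_incidence(ds$areas, file.path(dir, "areas.csv"))
  write_incidence(ds$habitats, file.path(dir, "habitats.csv"))
  cm <- data.frame(clade = rep(names(ds$clades),
                               vapply(ds$clades, length, 1L)),
                   species = unlist(ds$clades, use.names = FALSE))
  utils::write.csv(cm, file.path(dir, "clades.csv"), row.names = FALSE)
  jsonlite::write_json(ds$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir Directory containing the bundle.
#' @return A `synthetic_dataset`-shaped list (validated).
#' @export
read_dataset <- function(dir) {
  tree <- read_phylogeny(file.path(dir, "tree.nwk"))
  ds <- list(
    tree = tree,
    risk = read_risk(file.path(dir, "risk.csv")),
    threats = read_incidence(file.path(dir, "threats.csv")),
    areas = read_incidence(file.path(dir, "areas.csv")),
    habitats = read_incidence(file.path(dir, "habitats.csv")),
    clades = read_clade_map(file.path(dir, "clades.csv"), tree),
    params = if (file.exists(file.path(dir, "manifest.json")))
      jsonlite::read_json(file.path(dir, "manifest.json"),
                          simplifyVector = TRUE) else NULL
  )
  structure(ds, class = "synthetic_dataset")
}
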