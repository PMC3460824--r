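# md5 of a serialized R object, used to stamp outputs with the config
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Restrict a tree to the species present in a risk assessment
#'
#' Species found in only one of the two inputs are dropped with a warning
#' naming how many were unmatched on each side.
#'
#' @param tree A `phylo` object.
#' @param risk Named category vector.
#' @return List with the pruned `tree` and matching `risk`.
#' @export
match_tree_risk <- function(tree, risk) {
  tree <- validate_phylogeny(tree)
  risk <- validate_risk(risk)
  common <- intersect(tree$tip.label, names(risk))
  if (length(common) < 2L)
    stop("fewer than 2 species shared between tree and risk table",
         call. = FALSE)
  drop_tree <- setdiff(tree$tip.label, common)
  drop_risk <- setdiff(names(risk), common)
  if (length(drop_tree) || length(drop_risk))
    warning("dropping unmatched species: ", length(drop_tree),
            " from tree, ", length(drop_risk), " from risk table",
            call. = FALSE)
  if (length(drop_tree)) tree <- ape::keep.tip(tree, common)
  list(tree = tree, risk = risk[common])
}

#' Run the full three-stage analysis pipeline
#'
#' Executes, on one dataset: (1) whole-tree and per-clade PDloss with
#' permutation tests under the three data-deficient scenarios, plus
#' distinctiveness indices and their risk correlations; (2) DPCoA of
#' threats on the phylogeny and correspondence analyses of threats by
#' areas (optionally per area subset) and by habitats; (3) Phi
#' coefficients, Moran's tests of threat counts under the three proximity
#' structures, structure-corrected count-risk correlations under the
#' standard filters, mean-shift tests between adjacent risk categories,
#' and the order-level threats-versus-PDloss correlation. All outputs are
#' written under `out_dir` and indexed in `summary.json`, which also
#' records the seed and a hash of the configuration.
#'
#' @param data A `synthetic_dataset` (from [generate_dataset()] or
#'   [read_dataset()]): list with `tree`, `risk`, `threats`, `areas`,
#'   `habitats`, `clades`.
#' @param out_dir Output directory.
#' @param model Extinction-probability model (default [iucn50()]).
#' @param dd_scenarios Data-deficient scenarios to run.
#' @param n_perm_pdloss,n_perm_moran,n_perm_corr Permutation counts.
#' @param seed Integer seed controlling every stochastic stage.
#' @param area_groups Optional named list of area-label subsets (e.g.
#'   `list(land = ..., marine = ...)`) each analysed by its own CA.
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(data, out_dir, model = iucn50(),
                         dd_scenarios = c("exclude", "as_LC", "as_CR"),
                         n_perm_pdloss = 200, n_perm_moran = 999,
                         n_perm_corr = 999, seed = 1, area_groups = NULL) {
  stopifnot(all(c("tree", "risk", "threats") %in% names(data)))
  config <- list(model = unclass(model), dd_scenarios = dd_scenarios,
                 n_perm_pdloss = n_perm_pdloss, n_perm_moran = n_perm_moran,
                 n_perm_corr = n_perm_corr, seed = seed,
                 area_groups = area_groups)
  hash <- .config_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config_hash = hash, seed = seed, outputs = list())
  emit <- function(stage, name, path) {
    # index paths relative to out_dir so summaries are location-independent
    rel <- if (startsWith(path, paste0(out_dir, "/")))
      substring(path, nchar(out_dir) + 2L) else path
    summary$outputs[[stage]] <<- c(summary$outputs[[stage]],
                                   stats::setNames(list(rel), name))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  clades <- data$clades

  ## ---- first analysis: expected PD loss -------------------------------
  pdloss_exclude <- NULL
  run_stage("pdloss", {
    d1 <- file.path(out_dir, "pdloss")
    dir.create(d1, showWarnings = FALSE)
    for (sc in dd_scenarios) {
      risk_sc <- apply_dd_scenario(data$risk, sc)
      m <- match_tree_risk(data$tree, risk_sc)
      p <- extinction_probabilities(m$risk, model)
      cl <- if (!is.null(clades))
        validate_clade_map(lapply(clades, intersect, m$tree$tip.label),
                           m$tree) else NULL
      whole <- pdloss_permutation_test(m$tree, p, clades = NULL,
                                       n_perm = n_perm_pdloss, seed = seed)
      res <- whole
      if (!is.null(cl)) {
        per_clade <- pdloss_permutation_test(m$tree, p, clades = cl,
                                             n_perm = n_perm_pdloss,
                                             seed = seed + 1L)
        res$table <- rbind(whole$table, per_clade$table)
      }
      f <- file.path(d1, paste0("pdloss_", sc, ".csv"))
      utils::write.csv(cbind(res$table, config_hash = hash), f,
                       row.names = FALSE)
      emit("pdloss", sc, f)
      if (sc == "exclude") pdloss_exclude <- res$table
    }
  })

  ## ---- distinctiveness -------------------------------------------------
  run_stage("distinctiveness", {
    d <- file.path(out_dir, "distinctiveness")
    dir.create(d, showWarnings = FALSE)
    cors <- list()
    for (sc in dd_scenarios) {
      risk_sc <- apply_dd_scenario(data$risk, sc)
      m <- match_tree_risk(data$tree, risk_sc)
      scores <- distinctiveness_scores(m$tree)
      if (sc == dd_scenarios[[1L]]) {
        f <- file.path(d, "scores.csv")
        utils::write.csv(scores, f, row.names = FALSE)
        emit("distinctiveness", "scores", f)
      }
      cors[[sc]] <- as.list(distinctiveness_risk_correlation(scores, m$risk))
    }
    f <- file.path(d, "risk_correlations.json")
    jsonlite::write_json(list(config_hash = hash, spearman = cors), f,
                         auto_unbox = TRUE, digits = NA)
    emit("distinctiveness", "risk_correlations", f)
  })

  ## ---- second analysis: ordination ------------------------------------
  run_stage("ordination", {
    d <- file.path(out_dir, "ordination")
    dir.create(d, showWarnings = FALSE)
    common <- intersect(data$tree$tip.label, rownames(data$threats))
    D <- patristic_matrix(ape::keep.tip(data$tree, common))
    dp <- dpcoa(data$threats[common, , drop = FALSE], D)
    emit("ordination", "dpcoa",
         write_ordination(dp, file.path(d, "dpcoa"))[1L])
    if (!is.null(data$areas)) {
      tabs <- list(areas_all = build_threat_by_label_table(data$threats,
                                                           data$areas))
      for (g in names(area_groups)) {
        sub <- data$areas[, intersect(colnames(data$areas),
                                      area_groups[[g]]), drop = FALSE]
        tabs[[paste0("areas_", g)]] <-
          build_threat_by_label_table(data$threats, sub)
      }
      for (nm in names(tabs)) {
        ca <- correspondence_analysis(tabs[[nm]])
        emit("ordination", nm,
             write_ordination(ca, file.path(d, paste0("ca_", nm)))[1L])
      }
    }
    if (!is.null(data$habitats)) {
      ca <- correspondence_analysis(
        build_threat_by_label_table(data$threats, data$habitats))
      emit("ordination", "habitats",
           write_ordination(ca, file.path(d, "ca_habitats"))[1L])
    }
  })

  ## ---- third analysis: threat diversity -------------------------------
  run_stage("threat_stats", {
    d <- file.path(out_dir, "threat_stats")
    dir.create(d, showWarnings = FALSE)
    f <- file.path(d, "phi.csv")
    utils::write.csv(phi_matrix(data$threats), f)
    emit("threat_stats", "phi", f)

    risk_nodd <- apply_dd_scenario(data$risk, "exclude")
    m <- match_tree_risk(data$tree, risk_nodd)
    sp <- m$tree$tip.label
    counts <- threat_counts(data$threats)[sp]
    rr <- risk_rank(m$risk)

    prox <- list(phylogenetic = build_proximity("phylogenetic",
                                                tree = m$tree))
    if (!is.null(data$areas))
      prox$geographic <- build_proximity("geographic",
                                         labels = data$areas[sp, , drop = FALSE])
    if (!is.null(data$habitats))
      prox$habitat <- build_proximity("habitat",
                                      labels = data$habitats[sp, , drop = FALSE])

    tests <- list()
    for (k in names(prox)) {
      mi <- morans_i(counts, prox[[k]], n_perm = n_perm_moran,
                     seed = seed + 2L)
      tests[[paste0("moran_", k)]] <-
        list(statistic = mi$observed, p = mi$p_value, direction = mi$direction,
             n_perm = mi$n_perm, seed = mi$seed, filter = "none")
    }
    filters <- list(all = sp,
                    no_LC = sp[m$risk != "LC"],
                    threatened_only = sp[counts > 0])
    for (fl in names(filters)) {
      keep <- filters[[fl]]
      if (length(keep) < 5L || stats::sd(counts[keep]) == 0 ||
          stats::sd(rr[keep]) == 0) next
      for (k in names(prox)) {
        ct <- corrected_rank_correlation(counts[keep], rr[keep],
                                         w = prox[[k]][keep, keep],
                                         n_perm = n_perm_corr,
                                         seed = seed + 3L)
        tests[[paste0("corr_", k, "_", fl)]] <-
          list(statistic = ct$observed, p = ct$p_value,
               direction = ct$direction, n_perm = ct$n_perm, seed = ct$seed,
               filter = fl)
      }
    }
    cats <- iucn_categories()
    for (i in seq_len(4L)) {
      pair <- cats[i + 0:1]
      in_pair <- sp[m$risk %in% pair]
      if (length(unique(m$risk[in_pair])) < 2L) next
      ms <- mean_shift_test(counts[in_pair],
                            factor(m$risk[in_pair], levels = pair),
                            n_perm = n_perm_corr, seed = seed + 4L)
      tests[[paste0("shift_", pair[1L], "_", pair[2L])]] <-
        list(statistic = ms$observed, p = ms$p_value, direction = ms$direction,
             n_perm = ms$n_perm, seed = ms$seed, filter = "all",
             exact = ms$exact)
    }
    if (!is.null(pdloss_exclude) && !is.null(clades)) {
      pl <- stats::setNames(pdloss_exclude$pd_loss, pdloss_exclude$clade)
      pl <- pl[names(pl) != "all"]
      if (length(pl) >= 3L) {
        oc <- order_level_correlation(clades, threat_counts(data$threats), pl)
        tests$order_level <- list(
          pearson = oc$pearson, rank = oc$rank, filter = "none")
      }
    }
    f <- file.path(d, "tests.json")
    jsonlite::write_json(list(config_hash = hash, tests = tests), f,
                         auto_unbox = TRUE, digits = NA)
    emit("threat_stats", "tests", f)
  })

  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
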