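# End-to-end pipeline: simulate -> separate -> featurise -> preprocess ->
# cluster -> select -> validate.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()].
#' @param archetypes list of [phenotype_archetype()].
#' @param resp_band,cardiac_band spectral bands (Hz) for [decompose()].
#' @param thresholds [vq_thresholds()] for unit classification.
#' @param registry feature registry data.frame.
#' @param groupings named list of candidate [peep_grouping()]s for the
#'   sensitivity analysis; defaults to all contiguous partitions of the
#'   trial steps into 2-4 groups of >= 2 steps.
#' @param linkages linkage methods entered in the sensitivity analysis.
#' @param k_max largest candidate number of clusters.
#' @param k optional override of the stopping-rule choice.
#' @param alpha_select selection level for feature discrimination (99%
#'   confidence by default).
#' @param alpha_external significance level for external validation (95%).
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       archetypes = default_archetypes(),
                       resp_band = resp_band_default,
                       cardiac_band = cardiac_band_default,
                       thresholds = vq_thresholds(),
                       registry = default_feature_registry(),
                       groupings = candidate_groupings(cohort$peep_steps),
                       linkages = c("ward", "single", "complete", "average"),
                       k_max = 6,
                       k = NULL,
                       alpha_select = 0.01,
                       alpha_external = 0.05) {
  structure(
    list(cohort = cohort, archetypes = archetypes, resp_band = resp_band,
         cardiac_band = cardiac_band, thresholds = thresholds,
         registry = registry, groupings = groupings, linkages = linkages,
         k_max = k_max, k = k, alpha_select = alpha_select,
         alpha_external = alpha_external),
    class = "run_config"
  )
}

#' Write / read the scalar part of a run configuration as YAML
#'
#' Serialises the cohort settings, bands, thresholds, grouping definitions,
#' linkages and alphas. Archetypes and the feature registry are
#' reconstructed from package defaults on read (custom ones must be set
#' programmatically).
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    cohort = unclass(config$cohort),
    resp_band = config$resp_band,
    cardiac_band = config$cardiac_band,
    thresholds = config$thresholds,
    groupings = lapply(config$groupings, unclass),
    linkages = config$linkages,
    k_max = config$k_max, k = config$k,
    alpha_select = config$alpha_select,
    alpha_external = config$alpha_external
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- do.call(cohort_config, y$cohort)
  groupings <- lapply(y$groupings, function(g) {
    peep_grouping(g, steps = cc$peep_steps)
  })
  run_config(cohort = cc, resp_band = unlist(y$resp_band),
             cardiac_band = unlist(y$cardiac_band),
             thresholds = do.call(vq_thresholds, y$thresholds),
             groupings = groupings, linkages = unlist(y$linkages),
             k_max = y$k_max, k = y$k,
             alpha_select = y$alpha_select,
             alpha_external = y$alpha_external)
}

#' Name clusters from their discriminative feature profile
#'
#' Heuristic, advisory labelling: the cluster with the highest mean of dead
#' space fraction plus wasted perfusion is called `unmatched V'/Q`; among
#' the remaining clusters the one with the highest log10 V'/Q-ratio
#' dispersion is `mismatched V'/Q`; the rest are `inhomogeneous
#' ventilation`. Exact ties, or fewer than two clusters, leave clusters
#' numbered (with a warning). Labels are metadata only and never feed back
#' into the analysis.
#'
#' @param table per-level feature table.
#' @param assignment cluster labels named by patient id.
#' @return named character vector: cluster label -> name.
#' @export
name_clusters <- function(table, assignment) {
  groups <- assignment[match(table$patient_id, names(assignment))]
  ks <- sort(unique(as.integer(groups)))
  numbered <- stats::setNames(paste("cluster", ks), ks)
  if (length(ks) < 2) {
    warning("fewer than 2 clusters: leaving clusters numbered")
    return(numbered)
  }
  need <- c("dead_space_fraction", "wasted_perfusion", "sd_log10_vq_ratio")
  if (!all(need %in% names(table))) {
    warning("naming features missing from table: leaving clusters numbered")
    return(numbered)
  }
  unmatched_score <- tapply(table$dead_space_fraction + table$wasted_perfusion,
                            as.integer(groups), mean)
  disp_score <- tapply(table$sd_log10_vq_ratio, as.integer(groups), mean)
  if (anyDuplicated(unmatched_score)) {
    warning("tied cluster profiles: leaving clusters numbered")
    return(numbered)
  }
  out <- numbered
  unm <- names(which.max(unmatched_score))
  out[unm] <- "unmatched V'/Q"
  rest <- setdiff(names(out), unm)
  if (length(rest)) {
    mis <- rest[which.max(disp_score[rest])]
    out[mis] <- "mismatched V'/Q"
    for (r in setdiff(rest, mis)) out[r] <- "inhomogeneous ventilation"
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()].
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the cohort, separates signals and extracts the feature panel
#' per PEEP step, runs the grouping x linkage sensitivity analysis, then at
#' each level of the selected grouping: scales, computes distances, builds
#' the AGNES tree, selects the number of clusters by stopping rules, cuts,
#' tests features across clusters, names the clusters and compares the
#' external validation variables. The clustering stages never see the
#' archetype truth labels or the validation table; the adjusted Rand index
#' against the truth is computed only in the final report.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for plain-text artifacts (feature
#'   tables, distance matrices, Newick dendrograms, report JSON).
#' @return object of class `run_report`; see Details. Per level:
#'   `assignment`, `k`, `stopping`, `tree`, `ac`, `cluster_names`,
#'   `features` (test results), `external`, `ari`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ratio_cols <- config$registry$name[config$registry$ratio_scaled]

  eit_log("stage simulate: ", config$cohort$n_patients, " patients, seed ",
          config$cohort$seed)
  cohort <- generate_cohort(config$cohort, config$archetypes)

  eit_log("stage separate+featurise: ", length(config$cohort$peep_steps),
          " PEEP steps")
  step_tables <- tryCatch(
    cohort_feature_tables(cohort, config$thresholds, config$registry,
                          config$resp_band, config$cardiac_band),
    error = function(e) stop("featurise stage failed: ", conditionMessage(e)))

  eit_log("stage sensitivity: ", length(config$groupings), " groupings x ",
          length(config$linkages), " linkages")
  sens <- tryCatch(
    sensitivity_analysis(step_tables, config$groupings, config$linkages,
                         ratio_scaled = ratio_cols),
    error = function(e) stop("sensitivity stage failed: ", conditionMessage(e)))

  grouping <- config$groupings[[sens$selected$grouping]]
  linkage <- sens$selected$linkage
  level_tables <- average_steps(step_tables, grouping)

  truth <- stats::setNames(cohort$truth$archetype, cohort$truth$patient_id)
  levels_out <- list()
  for (lv in names(level_tables)) {
    tab <- level_tables[[lv]]
    X <- tryCatch(scale_features(tab, ratio_scaled = ratio_cols),
                  error = function(e) stop("preprocessing stage failed at level ",
                                           lv, ": ", conditionMessage(e)))
    D <- euclidean_dissimilarity(X)
    tree <- agnes_tree(D, linkage)
    stopping <- choose_k(D, tree, min(config$k_max, tree$n - 1), X)
    k <- config$k %||% stopping$chosen_k
    assignment <- cut_tree(tree, k)
    feats <- select_features(tab, assignment, config$alpha_select)
    nm <- tryCatch(name_clusters(tab, assignment),
                   warning = function(w) {
                     eit_log("cluster naming at level ", lv, ": ",
                             conditionMessage(w))
                     suppressWarnings(name_clusters(tab, assignment))
                   })

    phys_level <- peep_level_of(mean(grouping[[lv]]))
    vars <- c(paste0(c("p01_", "dpes_", "dplung_"), phys_level),
              "peepeit", "icu_los")
    validation_lv <- cohort$validation[
      cohort$validation$patient_id %in% names(assignment),
      c("patient_id", vars)]
    external <- compare_external(validation_lv, assignment,
                                 alpha = config$alpha_external)

    ari <- adjusted_rand(as.integer(assignment),
                         truth[names(assignment)])
    levels_out[[lv]] <- list(
      level = lv, peeps = grouping[[lv]], n = nrow(tab),
      tree = tree, ac = agglomerative_coefficient(tree),
      stopping = stopping, k = k, assignment = assignment,
      cluster_names = nm, features = feats, external = external,
      ari = ari, table = tab, scaled = X, dissimilarity = D)
  }

  report <- structure(
    list(levels = levels_out,
         sensitivity = sens,
         selected = sens$selected,
         truth = cohort$truth,
         seed = config$cohort$seed,
         package_version = as.character(utils::packageVersion("eitomics"))),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report_artifacts(report, config, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> grouping '%s', %s linkage | seed %d\n",
              x$selected$grouping, x$selected$linkage, x$seed))
  for (lv in x$levels) {
    cat(sprintf("  level %-14s n=%2d  AC=%.3f  k=%d  ARI=%.3f  selected features=%d\n",
                lv$level, lv$n, lv$ac, lv$k, lv$ari, sum(lv$features$selected)))
  }
  invisible(x)
}

# plain-text artifact dump for a finished run
write_report_artifacts <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_registry(config$registry, file.path(out_dir, "registry.json"))
  for (lv in report$levels) {
    pre <- file.path(out_dir, paste0("level_", lv$level))
    write_feature_table(lv$table, paste0(pre, "_features.csv"))
    write_dissimilarity(lv$dissimilarity, paste0(pre, "_distances.csv"))
    write_newick(lv$tree, paste0(pre, "_dendrogram.nwk"))
    write_heatmap_matrix(lv$scaled, lv$tree, paste0(pre, "_heatmap.csv"))
    utils::write.csv(lv$features, paste0(pre, "_feature_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(lv$external, paste0(pre, "_external.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(patient_id = names(lv$assignment),
                 cluster = as.integer(lv$assignment),
                 name = lv$cluster_names[as.character(as.integer(lv$assignment))]),
      paste0(pre, "_clusters.csv"), row.names = FALSE)
  }
  utils::write.csv(report$sensitivity$table,
                   file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Numeric summary of a run report
#'
#' The deterministic numeric core of a [run_pipeline()] report: selected
#' grouping/linkage, per-level agglomerative coefficients, chosen k,
#' cluster sizes, adjusted Rand index, selected features and external
#' validation p-values. Regenerating a run with the same configuration and
#' seed reproduces this summary exactly.
#'
#' @param report a `run_report`.
#' @return nested list of plain values.
#' @export
report_summary <- function(report) {
  list(
    seed = report$seed,
    selected_grouping = report$selected$grouping,
    selected_linkage = report$selected$linkage,
    mean_ac = report$selected$mean_ac,
    levels = lapply(report$levels, function(lv) {
      list(level = lv$level, n = lv$n, ac = lv$ac, k = lv$k,
           cluster_sizes = as.integer(table(as.integer(lv$assignment))),
           ari = lv$ari,
           selected_features = lv$features$feature[lv$features$selected],
           external_p = stats::setNames(lv$external$p, lv$external$variable))
    })
  )
}
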