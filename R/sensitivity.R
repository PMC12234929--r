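# Sensitivity analysis: agglomerative coefficient over PEEP groupings and
# linkage methods.

#' Clustering-strength sensitivity analysis
#'
#' For every combination of candidate PEEP grouping, level within the
#' grouping and linkage method, averages the per-step feature tables into
#' the level, scales, computes Euclidean distances, builds the AGNES tree
#' and records its agglomerative coefficient. The selected combination is
#' the (grouping, linkage) pair maximising the mean coefficient over that
#' grouping's levels.
#'
#' @param step_tables named list of per-step feature tables.
#' @param groupings named list of [peep_grouping()] objects.
#' @param linkages character vector of linkage methods.
#' @param ratio_scaled passed to [scale_features()].
#' @return object of class `sensitivity_result`: list with `table`
#'   (data.frame grouping/level/linkage/ac), `summary` (mean AC per
#'   grouping x linkage), `selected` (list grouping, linkage), and `trees`
#'   (the merge trees of the selected combination, one per level).
#' @export
sensitivity_analysis <- function(step_tables,
                                 groupings = list(default = default_grouping()),
                                 linkages = c("ward", "single", "complete",
                                              "average"),
                                 ratio_scaled = NULL) {
  stopifnot(length(groupings) >= 1, length(linkages) >= 1)
  if (is.null(names(groupings))) names(groupings) <- seq_along(groupings)
  rows <- list()
  trees <- list()
  for (gn in names(groupings)) {
    level_tables <- average_steps(step_tables, groupings[[gn]])
    scaled <- lapply(level_tables, scale_features, ratio_scaled = ratio_scaled)
    for (lk in linkages) {
      for (lv in names(scaled)) {
        D <- euclidean_dissimilarity(scaled[[lv]])
        tr <- agnes_tree(D, lk)
        trees[[paste(gn, lk, lv, sep = "|")]] <- tr
        rows[[length(rows) + 1]] <- data.frame(
          grouping = gn, level = lv, linkage = lk,
          n = nrow(scaled[[lv]]),
          ac = agglomerative_coefficient(tr),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(ac ~ grouping + linkage, tab, mean)
  best <- agg[order(-agg$ac, agg$grouping, agg$linkage)[1], ]
  sel_levels <- names(groupings[[best$grouping]])
  structure(
    list(table = tab,
         summary = agg,
         selected = list(grouping = best$grouping, linkage = best$linkage,
                         mean_ac = best$ac),
         trees = trees[paste(best$grouping, best$linkage, sel_levels,
                             sep = "|")]),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> selected grouping '%s', %s linkage (mean AC %.3f)\n",
              x$selected$grouping, x$selected$linkage, x$selected$mean_ac))
  invisible(x)
}
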