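# PEEP-step averaging into levels, variable scaling and Euclidean
# dissimilarity.

#' Define a PEEP-step grouping
#'
#' A named partition of the trial's PEEP steps into contiguous groups,
#' each covering at least two steps; adjacent steps in a group are treated
#' like replicates and averaged.
#'
#' @param ... named numeric vectors of PEEP values, e.g.
#'   `low = c(4, 6, 8), intermediate = c(10, 12, 14), high = c(16, 18)`.
#' @param steps the full set of trial steps the groups must come from.
#' @return object of class `peep_grouping` (named list).
#' @export
peep_grouping <- function(..., steps = seq(18, 4, by = -2)) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) &&
      !is.numeric(groups[[1]])) {
    groups <- groups[[1]]
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("every group must be named")
  }
  steps <- sort(steps)
  all_members <- sort(unlist(groups))
  if (anyDuplicated(all_members)) stop("groups must be disjoint")
  if (!all(all_members %in% steps)) stop("groups must be subsets of the trial steps")
  for (nm in names(groups)) {
    g <- sort(groups[[nm]])
    if (length(g) < 2) stop("group '", nm, "' must contain at least 2 steps")
    idx <- match(g, steps)
    if (any(diff(idx) != 1)) {
      stop("group '", nm, "' is not contiguous in pressure")
    }
  }
  structure(lapply(groups, sort), class = "peep_grouping")
}

#' The default grouping of the 18-to-4 trial into three levels
#'
#' low = 4-6-8, intermediate = 10-12-14, high = 16-18 cmH2O.
#' @return a [peep_grouping()].
#' @export
default_grouping <- function() {
  peep_grouping(low = c(4, 6, 8), intermediate = c(10, 12, 14),
                high = c(16, 18))
}

#' All candidate PEEP groupings for the sensitivity analysis
#'
#' Every partition of the (sorted) trial steps into 2-4 contiguous groups
#' of at least 2 steps each. Groups are named `g1` (lowest pressures)
#' upward; the grouping name encodes the group sizes, e.g. `"3+3+2"`.
#'
#' @param steps trial PEEP steps.
#' @return named list of [peep_grouping()] objects.
#' @export
candidate_groupings <- function(steps = seq(18, 4, by = -2)) {
  steps <- sort(steps)
  n <- length(steps)
  compositions <- function(total, parts) {
    if (total < 2 * parts) return(list())
    if (parts == 1) return(list(total))
    out <- list()
    for (first in 2:(total - 2 * (parts - 1))) {
      for (rest in compositions(total - first, parts - 1)) {
        out[[length(out) + 1]] <- c(first, rest)
      }
    }
    out
  }
  all_comp <- list()
  for (p in 2:4) {
    if (n >= 2 * p) all_comp <- c(all_comp, compositions(n, p))
  }
  out <- list()
  for (cmp in all_comp) {
    bounds <- cumsum(c(0, cmp))
    groups <- lapply(seq_along(cmp), function(i) {
      steps[(bounds[i] + 1):bounds[i + 1]]
    })
    names(groups) <- paste0("g", seq_along(cmp))
    nm <- paste(cmp, collapse = "+")
    out[[nm]] <- peep_grouping(groups, steps = steps)
  }
  out
}

#' Average per-step feature tables into PEEP levels
#'
#' For each group of adjacent steps, the level value of a feature is the
#' arithmetic mean over the patient's available steps in that group.
#' Patients missing every step of a group are dropped from that level with
#' a logged note; patients with a partial set of steps are retained using
#' the steps they have.
#'
#' @param step_tables named list of per-step feature tables (names are PEEP
#'   values), as returned by [cohort_feature_tables()].
#' @param grouping a [peep_grouping()].
#' @return named list of per-level feature tables (columns `patient_id`
#'   then features).
#' @export
average_steps <- function(step_tables, grouping) {
  stopifnot(inherits(grouping, "peep_grouping"))
  out <- list()
  for (lv in names(grouping)) {
    present <- intersect(as.character(grouping[[lv]]), names(step_tables))
    if (length(present) == 0) stop("no step tables for group '", lv, "'")
    tabs <- step_tables[present]
    ids <- sort(unique(unlist(lapply(tabs, `[[`, "patient_id"))))
    feat_cols <- setdiff(names(tabs[[1]]), c("patient_id", "peep"))
    rows <- list()
    for (id in ids) {
      per_step <- lapply(tabs, function(tb) {
        tb[tb$patient_id == id, feat_cols, drop = FALSE]
      })
      per_step <- per_step[vapply(per_step, nrow, 0L) == 1]
      if (length(per_step) == 0) next
      if (length(per_step) < length(present)) {
        eit_log("patient ", id, " has ", length(per_step), "/",
                length(present), " steps at level '", lv,
                "'; averaging the available steps")
      }
      avg <- colMeans(do.call(rbind, per_step))
      rows[[id]] <- data.frame(patient_id = id, t(avg),
                               check.names = FALSE, stringsAsFactors = FALSE)
    }
    dropped <- setdiff(ids, names(rows))
    if (length(dropped)) {
      eit_log("patients dropped from level '", lv, "': ",
              paste(dropped, collapse = ", "))
    }
    out[[lv]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out
}

#' Log-transform ratio-scaled variables and z-score all columns
#'
#' Ratio-scaled columns are shifted-log transformed, `log(x + eps)` with
#' `eps` equal to half the smallest positive value of the column (1 when
#' the column is all zeros), then every column is centred and scaled to
#' unit SD. Zero-variance columns are dropped with a logged note before
#' any distance computation.
#'
#' @param table feature table with a `patient_id` column.
#' @param ratio_scaled character vector of column names to log-transform;
#'   defaults to the registry's `ratio_scaled` features.
#' @return numeric matrix (patients x features) with rownames
#'   `patient_id`; attribute `dropped` lists removed constant columns.
#' @export
scale_features <- function(table,
                           ratio_scaled = NULL) {
  if (nrow(table) < 3) stop("at least 3 patients are required for scaling")
  if (is.null(ratio_scaled)) {
    reg <- default_feature_registry()
    ratio_scaled <- reg$name[reg$ratio_scaled]
  }
  feat_cols <- setdiff(names(table), c("patient_id", "peep"))
  X <- as.matrix(table[, feat_cols, drop = FALSE])
  rownames(X) <- table$patient_id
  for (j in intersect(colnames(X), ratio_scaled)) {
    x <- X[, j]
    if (any(x < 0)) {
      stop("ratio-scaled column '", j, "' has negative values")
    }
    pos <- x[x > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1
    X[, j] <- log(x + eps)
  }
  sds <- apply(X, 2, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  dropped <- colnames(X)[constant]
  if (any(constant)) {
    eit_log("dropping ", sum(constant), " zero-variance column(s): ",
            paste(utils::head(dropped, 8), collapse = ", "),
            if (sum(constant) > 8) ", ..." else "")
    X <- X[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  attr(Xs, "dropped") <- dropped
  Xs
}

#' Euclidean dissimilarity matrix between patients
#'
#' @param X scaled matrix (patients x features), no missing values.
#' @return symmetric matrix of Euclidean distances with zero diagonal and
#'   the patient ids as dimnames.
#' @export
euclidean_dissimilarity <- function(X) {
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing values in scaled matrix at: ",
         paste(sprintf("(%s,%s)", rownames(X)[bad[, 1]] %||% bad[, 1],
                       colnames(X)[bad[, 2]] %||% bad[, 2]),
               collapse = ", "))
  }
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Export a dissimilarity matrix as labelled CSV
#' @param D square dissimilarity matrix.
#' @param path file path.
#' @export
write_dissimilarity <- function(D, path) {
  utils::write.csv(D, path, row.names = TRUE)
  invisible(path)
}
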