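# Per-feature cluster discrimination testing and intraclass correlation.

#' Choose between ANOVA and Kruskal-Wallis for a group comparison
#'
#' ANOVA is used iff the Shapiro-Wilk test on the one-way ANOVA residuals
#' and Levene's test for homoscedasticity both fail to reject at alpha
#' (default 0.05); otherwise Kruskal-Wallis. Groups of size one force the
#' non-parametric branch with a warning.
#'
#' @param values numeric vector.
#' @param groups factor-like of the same length (>= 2 non-empty groups).
#' @param alpha significance level of the assumption tests.
#' @return `"anova"` or `"kruskal_wallis"`.
#' @export
choose_test <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  sizes <- table(droplevels(groups))
  if (any(sizes < 2)) {
    warning("group(s) of size < 2: forcing Kruskal-Wallis")
    return("kruskal_wallis")
  }
  fit <- stats::aov(values ~ groups)
  sw <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                 error = function(e) 0)
  lv <- tryCatch(car::leveneTest(values ~ groups)[1, "Pr(>F)"],
                 error = function(e) 0)
  if (sw >= alpha && lv >= alpha) "anova" else "kruskal_wallis"
}

# global p-value of the chosen test
global_p <- function(values, groups, test) {
  groups <- factor(groups)
  if (test == "anova") {
    summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
  } else {
    stats::kruskal.test(values, groups)$p.value
  }
}

#' One-way random-effects intraclass correlation, ICC(1A,1)
#'
#' Single-measurement agreement ICC under a one-way random model, computed
#' from the one-way ANOVA decomposition as
#' `(MSB - MSW) / (MSB + (k0 - 1) * MSW)`, with the unequal-group-size
#' correction `k0 = (N - sum(n_g^2) / N) / (G - 1)`. Estimates above 0.6
#' indicate good and above 0.75 excellent agreement; negative estimates are
#' reported as computed.
#'
#' @param values numeric vector.
#' @param groups factor-like group labels (>= 2 groups, N >= G + 1).
#' @return the ICC estimate; `NA` (flagged by a warning) when both mean
#'   squares are zero.
#' @export
icc_1a1 <- function(values, groups) {
  groups <- droplevels(factor(groups))
  G <- nlevels(groups)
  N <- length(values)
  if (G < 2) stop("need at least 2 groups")
  if (N < G + 1) stop("need at least G + 1 observations")
  ng <- as.numeric(table(groups))
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(ng * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  msb <- ssb / (G - 1)
  msw <- ssw / (N - G)
  if (msb == 0 && msw == 0) {
    warning("ICC undefined: no variance between or within groups")
    return(NA_real_)
  }
  k0 <- (N - sum(ng^2) / N) / (G - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

#' Agreement class of an ICC estimate
#' @param icc ICC estimate.
#' @return `"poor"`, `"good"` (> 0.6) or `"excellent"` (> 0.75).
#' @export
icc_class <- function(icc) {
  ifelse(is.na(icc), NA_character_,
         ifelse(icc > 0.75, "excellent", ifelse(icc > 0.6, "good", "poor")))
}

#' Select features discriminating the clusters
#'
#' Each feature is tested across clusters with ANOVA or Kruskal-Wallis (see
#' [choose_test()]); raw p-values are Bonferroni-corrected over the number
#' of features actually tested (constant features are skipped with a logged
#' note) and a feature is selected iff its adjusted p-value is below
#' `alpha` (default 0.01, i.e. 99% confidence). The ICC(1A,1) intra-cluster
#' consistency is computed for every tested feature as a descriptive
#' companion; it does not participate in selection.
#'
#' @param table feature table (`patient_id` column plus features).
#' @param assignment cluster labels named by patient id (or in table row
#'   order).
#' @param alpha selection level on the adjusted p-value.
#' @return data.frame, sorted by adjusted p: `feature`, `test`, `p_raw`,
#'   `p_adjusted`, `selected`, `icc`, `icc_class`.
#' @export
select_features <- function(table, assignment, alpha = 0.01) {
  feat_cols <- setdiff(names(table), c("patient_id", "peep"))
  if (!is.null(names(assignment)) && "patient_id" %in% names(table)) {
    groups <- assignment[match(table$patient_id, names(assignment))]
  } else {
    stopifnot(length(assignment) == nrow(table))
    groups <- assignment
  }
  if (anyNA(groups)) stop("assignment does not cover all patients in table")
  groups <- factor(as.integer(groups))

  rows <- list()
  for (f in feat_cols) {
    x <- table[[f]]
    if (stats::sd(x) == 0) {
      eit_log("feature '", f, "' is constant; skipped from testing")
      next
    }
    test <- suppressWarnings(choose_test(x, groups))
    p <- global_p(x, groups, test)
    icc <- tryCatch(suppressWarnings(icc_1a1(x, groups)),
                    error = function(e) NA_real_)
    rows[[f]] <- data.frame(feature = f, test = test, p_raw = p, icc = icc,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable (non-constant) features")
  n_tested <- nrow(res)
  res$p_adjusted <- pmin(1, res$p_raw * n_tested)
  res$selected <- res$p_adjusted < alpha
  res$icc_class <- icc_class(res$icc)
  res <- res[order(res$p_adjusted, res$p_raw), c("feature", "test", "p_raw",
                                                 "p_adjusted", "selected",
                                                 "icc", "icc_class")]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  res
}
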