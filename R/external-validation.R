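# External validation: comparison of drive, effort, personalised PEEP and
# outcome variables across clusters.

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics on mean rank differences after a Kruskal-Wallis
#' test, with the standard tie correction; two-sided p-values are
#' Bonferroni-adjusted over the number of pairs.
#'
#' @param values numeric vector.
#' @param groups factor-like group labels.
#' @return data.frame `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups) {
  groups <- droplevels(factor(groups))
  N <- length(values)
  r <- rank(values)
  # tie correction term
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n <- table(groups)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = out["z", ], p_raw = out["p", ],
                    stringsAsFactors = FALSE)
  res$p_adjusted <- pmin(1, res$p_raw * nrow(res))
  rownames(res) <- NULL
  res
}

# Tukey HSD pairwise table in the same layout as dunn_test
tukey_pairs <- function(values, groups) {
  groups <- droplevels(factor(groups))
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(nm, `[`, "", 2),
             group_b = vapply(nm, `[`, "", 1),
             diff = -tk[, "diff"],
             p_adjusted = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare external validation variables across clusters
#'
#' Quantitative variables are compared with ANOVA or Kruskal-Wallis (chosen
#' by [choose_test()]); when the global test is significant at `alpha`
#' (default 0.05, 95% confidence) a post-hoc analysis follows: Tukey's HSD
#' in the parametric case, Dunn's test with Bonferroni correction in the
#' non-parametric case. Categorical variables are compared with a
#' chi-square test on the contingency table.
#'
#' @param validation data.frame of per-patient validation variables with a
#'   `patient_id` column.
#' @param assignment cluster labels named by patient id.
#' @param variables variables to compare; defaults to every column except
#'   `patient_id` and `true_archetype`.
#' @param alpha global significance level.
#' @return data.frame with one row per variable: `variable`, `type`,
#'   `test`, `p`, `significant`; post-hoc tables are attached as the
#'   `posthoc` attribute (named list).
#' @export
compare_external <- function(validation, assignment, variables = NULL,
                             alpha = 0.05) {
  if (is.null(variables)) {
    variables <- setdiff(names(validation), c("patient_id", "true_archetype"))
  }
  groups <- assignment[match(validation$patient_id, names(assignment))]
  if (anyNA(groups)) stop("assignment does not cover all validation patients")
  groups <- factor(as.integer(groups))
  if (any(table(groups) == 0)) stop("empty cluster in assignment")

  rows <- list()
  posthoc <- list()
  for (v in variables) {
    x <- validation[[v]]
    if (is.numeric(x)) {
      test <- suppressWarnings(choose_test(x, groups))
      p <- global_p(x, groups, test)
      if (is.finite(p) && p < alpha) {
        posthoc[[v]] <- if (test == "anova") tukey_pairs(x, groups)
                        else dunn_test(x, groups)
        ph_method <- if (test == "anova") "tukey_hsd" else "dunn_bonferroni"
      } else ph_method <- NA_character_
      rows[[v]] <- data.frame(variable = v, type = "quantitative",
                              test = test, p = p,
                              significant = is.finite(p) && p < alpha,
                              posthoc_method = ph_method,
                              stringsAsFactors = FALSE)
    } else {
      tab <- table(x, groups)
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      rows[[v]] <- data.frame(variable = v, type = "categorical",
                              test = "chi_square", p = p,
                              significant = is.finite(p) && p < alpha,
                              posthoc_method = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "posthoc") <- posthoc
  res
}
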