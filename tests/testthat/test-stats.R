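test_that("choose_test follows the normality/homoscedasticity gate", {
  set.seed(30)
  g <- rep(c("a", "b", "c"), each = 20)
  normal <- rnorm(60)
  expect_identical(choose_test(normal, g), "anova")
  skewed <- rexp(60)^3
  expect_identical(choose_test(skewed, g), "kruskal_wallis")
  hetero <- c(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1), rnorm(20, 0, 20))
  expect_identical(choose_test(hetero, g), "kruskal_wallis")
  expect_warning(choose_test(c(1, 2, 3), c("a", "a", "b")), "size < 2")
  expect_error(choose_test(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("ICC(1A,1) is invariant to shift, scale and group relabelling", {
  set.seed(31)
  g <- rep(letters[1:3], c(4, 6, 5))
  x <- rnorm(15) + c(a = 0, b = 2, c = 4)[g]
  base <- icc_1a1(x, g)
  expect_equal(icc_1a1(x + 100, g), base, tolerance = 1e-12)
  expect_equal(icc_1a1(3 * x, g), base, tolerance = 1e-12)
  relab <- c(a = "z", b = "y", c = "x")[g]
  expect_equal(icc_1a1(x, relab), base, tolerance = 1e-12)
  expect_error(icc_1a1(x, rep("a", 15)), "at least 2 groups")
  expect_warning(icc_1a1(rep(1, 6), rep(c("a", "b"), 3)), "ICC undefined")
  expect_identical(icc_class(c(0.5, 0.7, 0.9, NA)),
                   c("poor", "good", "excellent", NA))
})

test_that("select_features Bonferroni-corrects over tested features only", {
  set.seed(35)
  n <- 24
  cl <- rep(1:2, each = 12)
  tab <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    strong = cl + rnorm(n, 0, 0.1),
                    weak = rnorm(n),
                    flat = 1,
                    stringsAsFactors = FALSE)
  res <- quiet(select_features(tab, cl))
  expect_equal(attr(res, "n_tested"), 2)  # 'flat' skipped
  expect_false("flat" %in% res$feature)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 2), tolerance = 1e-12)
  expect_true(res$selected[res$feature == "strong"])
  expect_false(res$selected[res$feature == "weak"])
  expect_true(res$icc[res$feature == "strong"] > 0.75)
  expect_identical(icc_class(res$icc[res$feature == "strong"]), "excellent")
  # results sorted by adjusted p
  expect_equal(res$feature[1], "strong")
  expect_error(quiet(select_features(tab[, c("patient_id", "flat")], cl)),
               "no testable")
})

test_that("select_features aligns assignments by patient id", {
  set.seed(33)
  tab <- data.frame(patient_id = c("A", "B", "C", "D", "E", "F"),
                    x = c(0, 0, 0, 5, 5, 5) + rnorm(6, 0, 0.01),
                    stringsAsFactors = FALSE)
  shuffled <- stats::setNames(c(2L, 1L, 2L, 1L, 2L, 1L),
                              c("D", "A", "E", "B", "F", "C"))
  res <- quiet(select_features(tab, shuffled))
  expect_true(res$selected[res$feature == "x"])
  expect_error(select_features(tab, stats::setNames(1:6, LETTERS[7:12])),
               "does not cover")
})

test_that("dunn_test reproduces hand-computed rank statistics", {
  # three groups, no ties
  x <- c(1, 2, 3, 10, 11, 12, 30, 31, 32)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- dunn_test(x, g)
  expect_equal(nrow(res), 3)
  N <- 9
  se <- sqrt(N * (N + 1) / 12 * (2 / 3))
  # mean ranks are 2, 5, 8
  expect_equal(res$z[res$group_a == "a" & res$group_b == "b"],
               (2 - 5) / se, tolerance = 1e-12)
  expect_equal(res$z[res$group_a == "a" & res$group_b == "c"],
               (2 - 8) / se, tolerance = 1e-12)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3), tolerance = 1e-12)

  # ties keep the statistic finite through the tie correction
  res_t <- dunn_test(c(1, 1, 1, 2, 2, 2, 2, 3, 3), g)
  expect_true(all(is.finite(res_t$z)))
})

test_that("compare_external runs global tests and post-hocs per variable type", {
  set.seed(34)
  n <- 30
  cl <- stats::setNames(rep(1:3, each = 10), sprintf("P%02d", 1:n))
  validation <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    drive = c(1, 4, 8)[rep(1:3, each = 10)] + rnorm(n, 0, 0.5),
    noise = rnorm(n),
    outcome = factor(rep(c("alive", "dead"), 15)),
    stringsAsFactors = FALSE
  )
  res <- compare_external(validation, cl)
  expect_setequal(res$variable, c("drive", "noise", "outcome"))
  drive_row <- res[res$variable == "drive", ]
  expect_true(drive_row$significant)
  expect_true(drive_row$posthoc_method %in% c("tukey_hsd", "dunn_bonferroni"))
  ph <- attr(res, "posthoc")$drive
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adjusted < 0.05))
  expect_false(res$significant[res$variable == "noise"])
  expect_identical(res$test[res$variable == "outcome"], "chi_square")

  # every patient must be covered, and no cluster may be empty
  expect_error(compare_external(validation, cl[-1]), "does not cover")
})
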