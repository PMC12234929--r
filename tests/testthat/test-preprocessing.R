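test_that("peep_grouping enforces named, disjoint, contiguous groups of >= 2 steps", {
  expect_s3_class(default_grouping(), "peep_grouping")
  expect_error(peep_grouping(c(4, 6), c(8, 10)), "must be named")
  expect_error(peep_grouping(a = c(4, 6), b = c(6, 8)), "disjoint")
  expect_error(peep_grouping(a = c(4, 8)), "not contiguous")
  expect_error(peep_grouping(a = c(4, 6), b = 10), "at least 2 steps")
  expect_error(peep_grouping(a = c(4, 5)), "subsets of the trial steps")
})

test_that("candidate groupings enumerate all contiguous 2-4 part partitions", {
  gs <- candidate_groupings(seq(18, 4, by = -2))
  # ordered compositions of 8 into 2-4 parts of >= 2: 5 + 6 + 1 = 12
  expect_length(gs, 12)
  expect_true("3+3+2" %in% names(gs))
  sizes <- vapply(strsplit(names(gs), "+", fixed = TRUE),
                  function(s) sum(as.integer(s)), numeric(1))
  expect_true(all(sizes == 8))
  for (g in gs) {
    expect_s3_class(g, "peep_grouping")
    expect_setequal(unlist(g), seq(4, 18, by = 2))
  }
  # four steps admit only the 2+2 split
  expect_named(candidate_groupings(c(10, 8, 6, 4)), "2+2")
})

test_that("average_steps takes exact means and retains partial patients", {
  tb <- function(peep, ids, vals) {
    data.frame(patient_id = ids, peep = peep, f1 = vals, f2 = 2 * vals,
               stringsAsFactors = FALSE)
  }
  steps <- list("4" = tb(4, c("A", "B"), c(1, 10)),
                "6" = tb(6, c("A", "B"), c(3, 20)),
                "8" = tb(8, "A", 5))  # B missing at 8
  lv <- quiet(average_steps(steps, peep_grouping(low = c(4, 6, 8))))
  low <- lv$low
  expect_equal(low$f1[low$patient_id == "A"], mean(c(1, 3, 5)))
  expect_equal(low$f2[low$patient_id == "A"], 2 * mean(c(1, 3, 5)))
  # B keeps the mean over its available steps
  expect_equal(low$f1[low$patient_id == "B"], mean(c(10, 20)))

  # a patient absent from every step of the group does not reach the level
  steps2 <- list("4" = tb(4, "A", 1), "6" = tb(6, "A", 3),
                 "8" = tb(8, c("A", "B"), c(5, 9)))
  lv2 <- quiet(average_steps(steps2, peep_grouping(low = c(4, 6))))
  expect_equal(lv2$low$patient_id, "A")

  # a group with no step tables at all is an error
  expect_error(average_steps(steps, peep_grouping(hi = c(16, 18))),
               "no step tables")
})

test_that("scale_features applies the shifted-log rule and standardises", {
  tab <- data.frame(patient_id = c("A", "B", "C", "D"),
                    ratio = c(0, 0.2, 0.4, 0.8),
                    plain = c(-1, 0, 1, 4),
                    flat = 1,
                    stringsAsFactors = FALSE)
  X <- quiet(scale_features(tab, ratio_scaled = "ratio"))
  expect_equal(attr(X, "dropped"), "flat")
  expect_equal(colnames(X), c("ratio", "plain"))
  expect_equal(unname(colMeans(X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), c(1, 1), tolerance = 1e-12)
  # eps = half the smallest positive value (0.1), applied before the z-score
  manual <- log(tab$ratio + 0.1)
  expect_equal(unname(X[, "ratio"]), unname(scale(manual)[, 1]),
               tolerance = 1e-12)
  expect_error(scale_features(tab[1:2, ], ratio_scaled = "ratio"),
               "at least 3 patients")
  expect_error(
    quiet(scale_features(transform(tab, ratio = c(-1, 0, 1, 2)),
                         ratio_scaled = "ratio")),
    "negative values")
})

test_that("z-scoring is idempotent for already-scaled data", {
  set.seed(8)
  tab <- data.frame(patient_id = letters[1:6],
                    x = rnorm(6), y = rnorm(6), stringsAsFactors = FALSE)
  X1 <- scale_features(tab, ratio_scaled = character(0))
  tab2 <- data.frame(patient_id = tab$patient_id, X1,
                     check.names = FALSE, stringsAsFactors = FALSE)
  X2 <- scale_features(tab2, ratio_scaled = character(0))
  expect_equal(unname(X2), unname(X1), tolerance = 1e-12)
})

test_that("euclidean dissimilarity matches stats::dist and rejects NAs", {
  set.seed(9)
  X <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("P", 1:5), paste0("f", 1:4)))
  D <- euclidean_dissimilarity(X)
  expect_equal(unname(D), unname(as.matrix(dist(X))), tolerance = 1e-12)
  expect_equal(rownames(D), rownames(X))
  Xna <- X; Xna[2, 3] <- NA
  expect_error(euclidean_dissimilarity(Xna), "missing values.*P2.*f3")
})
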