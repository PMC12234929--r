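test_that("agnes_tree agrees with stats::hclust for every linkage", {
  set.seed(14)
  hc_method <- c(ward = "ward.D2", single = "single",
                 complete = "complete", average = "average")
  for (rep in 1:10) {
    D <- random_euclidean_d(sample(5:12, 1))
    for (lk in names(hc_method)) {
      tree <- agnes_tree(D, lk)
      hc <- stats::hclust(as.dist(D), method = hc_method[[lk]])
      expect_equal(tree$height, hc$height, tolerance = 1e-9)
      expect_identical(tree$merge, hc$merge)
    }
  }
})

test_that("agglomerative coefficient agrees with cluster::agnes", {
  set.seed(15)
  D <- random_euclidean_d(12)
  for (lk in c("ward", "single", "complete", "average")) {
    ours <- agglomerative_coefficient(agnes_tree(D, lk))
    ref <- cluster::agnes(as.dist(D), method = lk)$ac
    expect_equal(ours, ref, tolerance = 1e-9, label = paste("AC", lk))
  }
})

test_that("dissimilarity input is validated", {
  expect_error(agnes_tree(matrix(1:6, 2, 3)), "square")
  A <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(agnes_tree(A), "symmetric")
  B <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(agnes_tree(B), "non-negative")
  C <- matrix(1, 2, 2)
  expect_error(agnes_tree(C), "zero diagonal")
  expect_error(agnes_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("ties are broken deterministically", {
  # four equidistant pairs: (1,2) and (3,4) both at distance 1
  D <- matrix(5, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  t1 <- agnes_tree(D, "single")
  expect_identical(t1$merge[1, ], c(-1L, -2L))  # smallest leaf pair first
  expect_identical(agnes_tree(D, "single")$merge, t1$merge)
})

test_that("cut_tree yields nested partitions labelled by first appearance", {
  set.seed(16)
  D <- random_euclidean_d(15)
  tree <- agnes_tree(D, "average")
  prev <- cut_tree(tree, 2)
  expect_identical(unclass(prev)[[1]], 1L)
  for (k in 3:6) {
    cur <- cut_tree(tree, k)
    expect_identical(unclass(cur)[[1]], 1L)
    expect_length(unique(as.integer(cur)), k)
    # refinement: items sharing a cluster at k share one at k - 1
    for (g in unique(as.integer(cur))) {
      expect_length(unique(as.integer(prev)[as.integer(cur) == g]), 1)
    }
    prev <- cur
  }
  expect_equal(as.integer(cut_tree(tree, 1)), rep(1L, 15))
  expect_equal(as.integer(cut_tree(tree, 15)), 1:15)
  expect_error(cut_tree(tree, 16))
})

test_that("cut_tree agrees with stats::cutree up to label permutation", {
  set.seed(17)
  D <- random_euclidean_d(20)
  tree <- agnes_tree(D, "ward")
  hc <- stats::hclust(as.dist(D), method = "ward.D2")
  for (k in c(2, 3, 5)) {
    ours <- as.integer(cut_tree(tree, k))
    ref <- unname(stats::cutree(hc, k))
    expect_equal(adjusted_rand(ours, ref), 1)
  }
})

test_that("a zero-height tree has agglomerative coefficient 0", {
  D <- matrix(0, 4, 4)
  expect_identical(agglomerative_coefficient(agnes_tree(D, "complete")), 0)
})

test_that("merge trees convert to hclust and export to Newick", {
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  rownames(D) <- colnames(D) <- c("P1", "P2", "P3", "P4")
  tree <- agnes_tree(D, "single")
  hc <- as.hclust(tree)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$labels, c("P1", "P2", "P3", "P4"))
  nwk <- write_newick(tree)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(c("P1", "P2", "P3", "P4"), grepl, TRUE, x = nwk)))
  p <- tempfile(fileext = ".nwk")
  write_newick(tree, p)
  expect_identical(readLines(p), nwk)
  unlink(p)

  p2 <- tempfile(fileext = ".csv")
  write_merge_table(tree, p2)
  mt <- utils::read.csv(p2)
  expect_equal(mt$height, tree$height)
  unlink(p2)
})

test_that("silhouette widths match the brute-force oracle and cluster::silhouette", {
  set.seed(18)
  D <- random_euclidean_d(12)
  tree <- agnes_tree(D, "ward")
  for (k in 2:4) {
    cl <- as.integer(cut_tree(tree, k))
    sw <- silhouette_widths(D, cl)
    expect_equal(unname(sw$widths), oracle_silhouette(D, cl), tolerance = 1e-12)
    ref <- cluster::silhouette(cl, dmatrix = D)
    expect_equal(sw$mean, mean(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("choose_k finds an unambiguous 3-cluster structure", {
  set.seed(19)
  X <- rbind(matrix(rnorm(20, 0), 10, 2),
             matrix(rnorm(20, 8), 10, 2),
             cbind(rnorm(8, 16), rnorm(8, 0)))
  rownames(X) <- sprintf("P%02d", 1:28)
  D <- euclidean_dissimilarity(X)
  tree <- agnes_tree(D, "ward")
  res <- choose_k(D, tree, 6, X)
  expect_s3_class(res, "stopping_rule_report")
  expect_equal(res$chosen_k, 3)
  expect_equal(nrow(res$votes), 5)
  expect_true(all(res$votes$best_k == 3))
  expect_false(res$tie_broken)
})

test_that("sensitivity analysis selects the strongest grouping x linkage", {
  # two synthetic steps whose features carry an obvious 2-cluster split
  set.seed(20)
  ids <- sprintf("P%02d", 1:12)
  mk <- function(peep) {
    data.frame(patient_id = ids, peep = peep,
               f1 = rep(c(0, 6), each = 6) + rnorm(12, 0, 0.3),
               f2 = rep(c(0, -6), each = 6) + rnorm(12, 0, 0.3),
               stringsAsFactors = FALSE)
  }
  steps <- list("4" = mk(4), "6" = mk(6), "8" = mk(8), "10" = mk(10))
  sens <- quiet(sensitivity_analysis(
    steps, candidate_groupings(c(10, 8, 6, 4)),
    linkages = c("ward", "average"), ratio_scaled = character(0)))
  expect_s3_class(sens, "sensitivity_result")
  expect_equal(nrow(sens$table), 1 * 2 * 2)  # 1 grouping x 2 levels x 2 linkages
  expect_true(all(sens$table$ac > 0.5))
  expect_true(sens$selected$linkage %in% c("ward", "average"))
  expect_length(sens$trees, 2)
})
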