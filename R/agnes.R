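# Agglomerative nesting (AGNES): Lance-Williams hierarchical clustering,
# agglomerative coefficient, dendrogram cutting and exports.

check_dissimilarity <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square dissimilarity matrix")
  }
  if (max(abs(D - t(D))) > 1e-10) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  D
}

#' Agglomerative nesting of a dissimilarity matrix
#'
#' Bottom-up hierarchical clustering: starting from singletons, the two
#' closest clusters under the chosen linkage are merged repeatedly until one
#' cluster remains. Between-cluster distances are updated by the
#' Lance-Williams recurrence. Ward's method follows the "ward.D2"
#' convention: the recurrence runs on squared dissimilarities and merge
#' heights are reported on the original dissimilarity scale, so for
#' Euclidean input the heights match the classical AGNES reference
#' implementation. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster indices (leaves are indexed
#' 1..n in input order, later merges n+1, n+2, ...).
#'
#' @param D symmetric non-negative dissimilarity matrix (or `dist`) with
#'   zero diagonal.
#' @param linkage one of `"ward"`, `"single"`, `"complete"`, `"average"`.
#' @return object of class `merge_tree`: list with `labels`, `merge`
#'   ((n-1) x 2 matrix in hclust convention: negative entries are leaves,
#'   positive entries reference earlier merges), `height`, `order` (leaf
#'   ordering for plotting) and `linkage`.
#' @export
agnes_tree <- function(D, linkage = c("ward", "single", "complete", "average")) {
  linkage <- match.arg(linkage)
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (n < 2) stop("at least 2 items are required")
  labels <- rownames(D) %||% as.character(seq_len(n))

  W <- if (linkage == "ward") D^2 else D
  ids <- seq_len(n)          # cluster index of each active cluster
  sizes <- rep(1L, n)
  code <- -seq_len(n)        # hclust code of each active cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    w <- W
    diag(w) <- Inf
    mval <- min(w)
    cand <- which(w == mval, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (id_a, id_b) pair
    ia <- pmin(ids[cand[, 1]], ids[cand[, 2]])
    ib <- pmax(ids[cand[, 1]], ids[cand[, 2]])
    pick <- order(ia, ib)[1]
    i <- min(cand[pick, ]); j <- max(cand[pick, ])

    height[step] <- if (linkage == "ward") sqrt(mval) else mval
    # hclust row convention: singletons before earlier merges, each in
    # ascending index order
    pair <- c(code[i], code[j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    si <- sizes[i]; sj <- sizes[j]

    others <- setdiff(seq_along(ids), c(i, j))
    newd <- vapply(others, function(k) {
      switch(linkage,
        single = min(W[k, i], W[k, j]),
        complete = max(W[k, i], W[k, j]),
        average = (si * W[k, i] + sj * W[k, j]) / (si + sj),
        ward = {
          sk <- sizes[k]
          ((si + sk) * W[k, i] + (sj + sk) * W[k, j] - sk * W[i, j]) /
            (si + sj + sk)
        })
    }, numeric(1))

    # fold cluster j into i, assign the new cluster index n + step
    W[i, others] <- newd
    W[others, i] <- newd
    W[i, i] <- 0
    sizes[i] <- si + sj
    ids[i] <- n + step
    code[i] <- step
    W <- W[-j, -j, drop = FALSE]
    ids <- ids[-j]; sizes <- sizes[-j]; code <- code[-j]
  }

  ord <- integer(0)
  walk <- function(m) {
    if (m < 0) return(-m)
    c(walk(merge[m, 1]), walk(merge[m, 2]))
  }
  ord <- walk(n - 1)

  structure(
    list(labels = labels, merge = merge, height = height, order = ord,
         linkage = linkage, n = n),
    class = "merge_tree"
  )
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> %d leaves, %s linkage, AC = %.3f\n",
              x$n, x$linkage, agglomerative_coefficient(x)))
  invisible(x)
}

#' Convert a merge tree to an hclust object
#' @param x a `merge_tree`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.merge_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = x$linkage,
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Agglomerative coefficient of a merge tree
#'
#' For each leaf, `m(i)` is the height of its first merge divided by the
#' height of the final merge; the agglomerative coefficient is the mean of
#' `1 - m(i)` over leaves. Values near 1 indicate strong clustering
#' structure. When the final merge height is zero (all items identical) the
#' coefficient is defined as 0.
#'
#' @param tree a [agnes_tree()] result.
#' @return value in \[0, 1\].
#' @export
agglomerative_coefficient <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  h_max <- tree$height[length(tree$height)]
  if (h_max <= 0) return(0)
  first <- numeric(tree$n)
  for (s in seq_along(tree$height)) {
    for (m in tree$merge[s, ]) {
      if (m < 0 && first[-m] == 0) first[-m] <- tree$height[s]
    }
  }
  # leaves merging at height 0 keep first = 0, i.e. m(i) = 0
  mean(1 - first / h_max)
}

#' Cut a merge tree into k clusters
#'
#' Removes the k-1 highest merges (equivalently, applies the first n-k
#' merges) and labels the resulting connected components 1..k in order of
#' first patient appearance.
#'
#' @param tree a `merge_tree`.
#' @param k number of clusters, 1 <= k <= n.
#' @return object of class `cluster_assignment`: named integer vector
#'   (patient id -> cluster label) with attribute `k`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "merge_tree"), k >= 1, k <= tree$n)
  n <- tree$n
  comp <- seq_len(n)
  cluster_members <- as.list(seq_len(n))
  for (s in seq_len(n - k)) {
    members <- unlist(lapply(tree$merge[s, ], function(m) {
      if (m < 0) -m else cluster_members[[n + m]]
    }))
    cluster_members[[n + s]] <- members
    comp[members] <- members[1]
  }
  labels_out <- integer(n)
  nxt <- 0L
  seen <- integer(0)
  for (i in seq_len(n)) {
    root <- comp[i]
    pos <- match(root, seen)
    if (is.na(pos)) {
      seen <- c(seen, root)
      nxt <- nxt + 1L
      pos <- nxt
    }
    labels_out[i] <- pos
  }
  names(labels_out) <- tree$labels
  structure(labels_out, k = as.integer(k), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k =", attr(x, "k"), "\n")
  print(table(cluster = unclass(x)))
  invisible(x)
}

#' Export a dendrogram as a Newick string or file
#'
#' Branch lengths are derived from merge heights (ultrametric tree).
#'
#' @param tree a `merge_tree`.
#' @param path optional file path; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(as.hclust.merge_tree(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Export the merge table as CSV
#' @param tree a `merge_tree`.
#' @param path file path.
#' @export
write_merge_table <- function(tree, path) {
  utils::write.csv(
    data.frame(step = seq_along(tree$height),
               member_a = tree$merge[, 1], member_b = tree$merge[, 2],
               height = tree$height),
    path, row.names = FALSE)
  invisible(path)
}

#' Export the scaled matrix in dendrogram leaf order (heatmap data)
#' @param X scaled matrix (patients x features).
#' @param tree a `merge_tree` on the same patients.
#' @param path file path.
#' @export
write_heatmap_matrix <- function(X, tree, path) {
  utils::write.csv(X[tree$order, , drop = FALSE], path, row.names = TRUE)
  invisible(path)
}
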