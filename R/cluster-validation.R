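# Internal cluster validation: silhouette widths, stopping-rule indices and
# selection of the number of clusters.

#' Silhouette widths of a cluster assignment
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is the mean
#' distance of item i to the other members of its cluster and `b(i)` the
#' smallest mean distance to another cluster. Items in singleton clusters
#' get `s(i) = 0` by convention. Negative widths flag likely
#' misclassification.
#'
#' @param D dissimilarity matrix.
#' @param assignment integer cluster labels (e.g. a [cut_tree()] result).
#' @return list with `widths` (named numeric vector) and `mean`.
#' @export
silhouette_widths <- function(D, assignment) {
  D <- check_dissimilarity(D)
  cl <- as.integer(assignment)
  n <- length(cl)
  stopifnot(nrow(D) == n)
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("silhouette requires at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, cl[i]), function(k2) {
      mean(D[i, cl == k2])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  names(s) <- rownames(D) %||% names(assignment)
  list(widths = s, mean = mean(s))
}

# --- internal validity indices -----------------------------------------

index_calinski_harabasz <- function(X, cl) {
  n <- nrow(X); k <- length(unique(cl))
  grand <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (g in unique(cl)) {
    Xi <- X[cl == g, , drop = FALSE]
    ci <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * sum((ci - grand)^2)
    ssw <- ssw + sum(sweep(Xi, 2, ci)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

index_dunn <- function(D, cl) {
  ks <- unique(cl)
  sep <- Inf; diam <- 0
  for (a in seq_along(ks)) {
    ia <- which(cl == ks[a])
    if (length(ia) > 1) diam <- max(diam, max(D[ia, ia]))
    for (b in seq_len(a - 1)) {
      ib <- which(cl == ks[b])
      sep <- min(sep, min(D[ia, ib]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

index_c <- function(D, cl) {
  n <- nrow(D)
  pairs <- D[upper.tri(D)]
  within <- outer(cl, cl, "==")[upper.tri(D)]
  nw <- sum(within)
  if (nw == 0) return(NA_real_)
  s <- sum(pairs[within])
  sorted <- sort(pairs)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq.int(length(sorted) - nw + 1, length(sorted))])
  if (smax == smin) return(0)
  (s - smin) / (smax - smin)
}

index_davies_bouldin <- function(X, cl) {
  ks <- unique(cl)
  cent <- t(vapply(ks, function(g) colMeans(X[cl == g, , drop = FALSE]),
                   numeric(ncol(X))))
  sig <- vapply(seq_along(ks), function(a) {
    Xi <- X[cl == ks[a], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, cent[a, ])^2)))
  }, numeric(1))
  r <- vapply(seq_along(ks), function(a) {
    max(vapply(setdiff(seq_along(ks), a), function(b) {
      d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
      if (d == 0) Inf else (sig[a] + sig[b]) / d
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Select the number of clusters by stopping rules
#'
#' Cuts the tree at each candidate k in 2..k_max and computes five internal
#' validity indices: mean silhouette width (max), Calinski-Harabasz on the
#' scaled matrix (max), Dunn (max), C-index (min) and Davies-Bouldin (min).
#' Each index votes for its optimal k; the majority wins. A tie between two
#' candidate k values is resolved in favour of the k with fewer negative
#' silhouette widths (fewer apparently misclassified patients).
#'
#' @param D dissimilarity matrix.
#' @param tree the [agnes_tree()] of D.
#' @param k_max largest candidate number of clusters (<= n - 1).
#' @param X the scaled feature matrix the distances were computed from.
#' @return object of class `stopping_rule_report`: list with `votes`
#'   (data.frame index/best_k), `silhouette` (data.frame k, mean_width,
#'   n_negative), `chosen_k` and `tie_broken`.
#' @export
choose_k <- function(D, tree, k_max, X) {
  D <- check_dissimilarity(D)
  stopifnot(k_max <= tree$n - 1, k_max >= 2)
  ks <- 2:k_max
  sil_mean <- numeric(length(ks))
  sil_neg <- integer(length(ks))
  idx <- matrix(NA_real_, length(ks), 5,
                dimnames = list(ks, c("silhouette", "calinski_harabasz",
                                      "dunn", "c_index", "davies_bouldin")))
  for (i in seq_along(ks)) {
    cl <- cut_tree(tree, ks[i])
    sw <- silhouette_widths(D, cl)
    sil_mean[i] <- sw$mean
    sil_neg[i] <- sum(sw$widths < 0)
    idx[i, ] <- c(sw$mean,
                  index_calinski_harabasz(X, cl),
                  index_dunn(D, cl),
                  index_c(D, cl),
                  index_davies_bouldin(X, cl))
  }
  maximise <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  best <- vapply(1:5, function(j) {
    v <- idx[, j]
    if (all(is.na(v))) return(NA_integer_)
    if (maximise[j]) ks[which.max(v)] else ks[which.min(v)]
  }, integer(1))
  votes <- data.frame(index = colnames(idx), best_k = best,
                      stringsAsFactors = FALSE)
  tab <- table(best[!is.na(best)])
  top <- as.integer(names(tab)[tab == max(tab)])
  tie_broken <- FALSE
  if (length(top) > 1) {
    tie_broken <- TRUE
    neg <- sil_neg[match(top, ks)]
    top <- top[order(neg, top)]
  }
  structure(
    list(votes = votes,
         indices = as.data.frame(idx),
         silhouette = data.frame(k = ks, mean_width = sil_mean,
                                 n_negative = sil_neg),
         chosen_k = top[1],
         tie_broken = tie_broken),
    class = "stopping_rule_report"
  )
}

#' @export
print.stopping_rule_report <- function(x, ...) {
  cat("<stopping_rule_report> chosen k =", x$chosen_k,
      if (x$tie_broken) "(tie broken by silhouette misclassification)" else "",
      "\n")
  print(x$votes, row.names = FALSE)
  invisible(x)
}
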