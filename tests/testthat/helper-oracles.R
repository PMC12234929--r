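# Independent brute-force oracles used to cross-check the package's
# clustering machinery, plus small fixture helpers. The oracles recompute
# every quantity from first principles (no Lance-Williams recurrence, no
# shared code paths with the package).

# Brute-force AGNES: at every step all inter-cluster distances are
# recomputed directly from the original dissimilarity matrix. Ward follows
# the ward.D2 convention via the centroid identity on squared Euclidean
# dissimilarities:
#   ||c_A - c_B||^2 = s_AB/(nA nB) - s_AA/(2 nA^2) - s_BB/(2 nB^2)
#   d_ward(A,B)     = sqrt(2 nA nB / (nA + nB) * ||c_A - c_B||^2)
# where s_XY are double sums of squared dissimilarities.
oracle_agnes <- function(D, linkage) {
  D <- as.matrix(D)
  Dsq <- D^2
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cdist <- function(A, B) {
    switch(linkage,
      single = min(D[A, B]),
      complete = max(D[A, B]),
      average = mean(D[A, B]),
      ward = {
        na <- length(A); nb <- length(B)
        d2 <- (2 * na * nb / (na + nb)) *
          (sum(Dsq[A, B]) / (na * nb) -
             sum(Dsq[A, A]) / (2 * na^2) -
             sum(Dsq[B, B]) / (2 * nb^2))
        sqrt(max(d2, 0))
      })
  }
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(1L, 2L); bestd <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        d <- cdist(clusters[[i]], clusters[[j]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    height[step] <- bestd
    pair <- c(codes[i], codes[j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    codes[i] <- step
    clusters[[j]] <- NULL
    codes <- codes[-j]
  }
  list(merge = merge, height = height)
}

# Brute-force silhouette widths from the definition.
oracle_silhouette <- function(D, cl) {
  D <- as.matrix(D)
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Random Euclidean dissimilarity matrix on n points (continuous entries, so
# merge ties have probability zero).
random_euclidean_d <- function(n, dim = 3) {
  X <- matrix(rnorm(n * dim), n, dim)
  as.matrix(stats::dist(X))
}

# Small, fast cohort configuration for unit tests (not the study defaults).
tiny_config <- function(...) {
  cohort_config(n_patients = 3, mixture = rep(1 / 3, 3), seed = 7L,
                grid = c(8, 8), peep_steps = c(10, 8, 6, 4),
                step_duration = 16, ...)
}

# A deterministic vq_maps object built from hand-made component maps.
fake_vq <- function(v, q, mask, thresholds = vq_thresholds()) {
  vq_maps(list(ventilation = v, pulsatility = q, mask = mask,
               peep = 4, patient_id = "T1"), thresholds)
}

quiet <- function(expr) {
  old <- options(eitomics.verbose = FALSE)
  on.exit(options(old))
  expr
}
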