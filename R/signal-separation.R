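# PCA separation of ventilation- and cardiac-frequency EIT signal
# components, and the derived ventilation / pulsatility amplitude maps.

#' Default spectral bands
#'
#' Respiratory band 0.1-0.6 Hz (6-36 breaths/min) and cardiac band
#' 0.8-3.0 Hz (48-180 beats/min) bracket the physiological ranges.
#' @name eit_bands
#' @export
resp_band_default <- c(0.1, 0.6)

#' @rdname eit_bands
#' @export
cardiac_band_default <- c(0.8, 3.0)

#' Remove per-pixel mean and linear trend
#'
#' @param X numeric matrix, pixels x samples.
#' @return matrix of the same shape with each row's least-squares line
#'   subtracted.
#' @export
detrend_pixels <- function(X) {
  n <- ncol(X)
  tc <- seq_len(n) - (n + 1) / 2
  beta <- (X %*% tc) / sum(tc^2)
  X - rowMeans(X) - tcrossprod(beta, tc)
}

# Frequency (Hz) of the dominant periodogram peak of a time series,
# excluding DC.
dominant_frequency <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- floor(n / 2)
  freqs <- (seq_len(half)) * fs / n   # bins 1..half, DC excluded
  freqs[which.max(p[2:(half + 1)])]
}

# Split a time series into its components inside two disjoint bands plus a
# remainder, by masking the discrete Fourier transform. The three parts sum
# to the input exactly.
band_split <- function(x, fs, band_a, band_b) {
  n <- length(x)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)    # two-sided spectrum, symmetric bins
  in_a <- freqs >= band_a[1] & freqs <= band_a[2]
  in_b <- freqs >= band_b[1] & freqs <= band_b[2]
  inv <- function(sel) Re(stats::fft(f * sel, inverse = TRUE)) / n
  a <- inv(in_a)
  b <- inv(in_b)
  list(a = a, b = b, rest = x - a - b)
}

#' Separate ventilation- and cardiac-related signal components
#'
#' Per-pixel linear detrending followed by a principal-component
#' decomposition of the lung-pixel x time matrix. Components are retained
#' up to 99% cumulative explained variance (configurable). Each retained
#' component is labelled respiratory or cardiac by the dominant spectral
#' peak of its temporal score, and its score is split into its
#' respiratory-band, cardiac-band and out-of-band parts by Fourier masking
#' before reconstruction; the out-of-band parts and the discarded
#' components form the residual. Splitting the scores (rather than
#' assigning whole components) keeps the separation exact even when the
#' ventilation and perfusion spatial patterns are correlated, in which case
#' individual principal components mix the two sources. The three
#' reconstructions satisfy `resp + card + residual == detrended input`
#' exactly (off-mask pixels are passed through to the residual).
#'
#' @param recording an [eit_recording()].
#' @param resp_band,cardiac_band disjoint frequency intervals in Hz.
#' @param var_retain cumulative explained-variance retention threshold.
#' @return object of class `eit_decomposition`: list with matrices `resp`,
#'   `card`, `residual` (pixels x samples), counts `n_components_resp`,
#'   `n_components_card` (retained components whose dominant peak lies in
#'   each band), and the recording's `fs`, `mask`, `grid`.
#' @export
decompose <- function(recording,
                      resp_band = resp_band_default,
                      cardiac_band = cardiac_band_default,
                      var_retain = 0.99) {
  stopifnot(inherits(recording, "eit_recording"),
            length(resp_band) == 2, length(cardiac_band) == 2)
  if (max(resp_band) >= min(cardiac_band) && max(cardiac_band) >= min(resp_band)) {
    stop("resp_band and cardiac_band must be disjoint")
  }
  X <- recording$impedance
  m <- as.vector(recording$mask)
  Xd <- detrend_pixels(X)
  Xl <- Xd[m, , drop = FALSE]

  s <- svd(Xl)
  var_share <- s$d^2 / sum(s$d^2)
  n_keep <- which(cumsum(var_share) >= var_retain)[1]
  keep <- seq_len(n_keep)

  cls <- vapply(keep, function(k) {
    f <- dominant_frequency(s$v[, k], recording$fs)
    if (f >= resp_band[1] && f <= resp_band[2]) "resp"
    else if (f >= cardiac_band[1] && f <= cardiac_band[2]) "card"
    else "other"
  }, character(1))

  if (!any(cls == "card")) {
    stop(structure(
      class = c("eitomics_pulsatility_error", "error", "condition"),
      list(message = paste0("pulsatility not resolvable in recording ",
                            recording$patient_id, " at PEEP ",
                            recording$peep,
                            ": no retained component peaks in the cardiac band"),
           call = NULL)))
  }

  V_resp <- matrix(0, ncol(Xl), n_keep)
  V_card <- matrix(0, ncol(Xl), n_keep)
  for (k in keep) {
    sp <- band_split(s$v[, k], recording$fs, resp_band, cardiac_band)
    V_resp[, k] <- sp$a
    V_card[, k] <- sp$b
  }
  reconstruct <- function(V) {
    out <- matrix(0, nrow(X), ncol(X))
    out[m, ] <- s$u[, keep, drop = FALSE] %*% (s$d[keep] * t(V))
    out
  }
  resp <- reconstruct(V_resp)
  card <- reconstruct(V_card)
  residual <- Xd - resp - card

  structure(
    list(resp = resp, card = card, residual = residual,
         n_components_resp = sum(cls == "resp"),
         n_components_card = sum(cls == "card"),
         fs = recording$fs, mask = recording$mask, grid = recording$grid,
         peep = recording$peep, patient_id = recording$patient_id),
    class = "eit_decomposition"
  )
}

# Indices of local maxima above the signal's mid-range (or minima below,
# when sign = -1), at least min_gap samples apart.
find_extrema <- function(w, sign = 1, min_gap = 3) {
  w <- sign * w
  thr <- (max(w) + min(w)) / 2
  n <- length(w)
  cand <- which(w > thr &
                  w >= c(-Inf, w[-n]) &
                  w > c(w[-1], -Inf))
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Per-pixel tidal ventilation map
#'
#' Breaths are detected as peak-trough pairs on the global (mask-summed)
#' respiratory waveform; the per-pixel tidal variation is the mean over
#' breaths of the end-inspiratory minus end-expiratory pixel impedance.
#' Pixels whose mean is negative (anti-phase, paradoxical pixels) are
#' clipped to zero; off-mask pixels are zero.
#'
#' @param resp_signal respiratory reconstruction (pixels x samples), e.g.
#'   `decompose(...)$resp`.
#' @param fs sampling rate (Hz).
#' @param mask logical rows x cols lung mask.
#' @param recording_id identifier used in error messages.
#' @return list with `map` (rows x cols matrix) and `n_breaths_used`.
#' @export
ventilation_map <- function(resp_signal, fs, mask, recording_id = "recording") {
  m <- as.vector(mask)
  w <- colSums(resp_signal[m, , drop = FALSE])
  min_gap <- max(3L, floor(fs / 2))
  peaks <- find_extrema(w, 1, min_gap)
  troughs <- find_extrema(w, -1, min_gap)
  # pair each peak with the nearest preceding trough
  pairs <- lapply(peaks, function(p) {
    tr <- troughs[troughs < p]
    if (length(tr)) c(tr[length(tr)], p) else NULL
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (length(pairs) < 3) {
    stop("fewer than 3 breaths detected on the global waveform of ",
         recording_id)
  }
  diffs <- vapply(pairs, function(pr) resp_signal[, pr[2]] - resp_signal[, pr[1]],
                  numeric(nrow(resp_signal)))
  val <- rowMeans(diffs)
  val[val < 0] <- 0
  val[!m] <- 0
  list(map = matrix(val, nrow(mask), ncol(mask)),
       n_breaths_used = length(pairs))
}

#' Per-pixel cardiac pulsatility map
#'
#' The pulsatility amplitude of each pixel is estimated from the
#' root-mean-square of its cardiac reconstruction as `sqrt(2) * RMS`, the
#' exact amplitude of a sinusoid, making the map invariant to cardiac
#' phase. Off-mask pixels are zero.
#'
#' @param card_signal cardiac reconstruction (pixels x samples).
#' @param fs sampling rate (Hz); kept for interface symmetry.
#' @param mask logical rows x cols lung mask.
#' @return rows x cols matrix of amplitudes.
#' @export
pulsatility_map <- function(card_signal, fs, mask) {
  m <- as.vector(mask)
  centered <- card_signal - rowMeans(card_signal)
  val <- sqrt(2) * sqrt(rowMeans(centered^2))
  val[!m] <- 0
  matrix(val, nrow(mask), ncol(mask))
}

#' Ventilation and pulsatility maps of one recording
#'
#' Convenience wrapper: [decompose()] then [ventilation_map()] and
#' [pulsatility_map()].
#'
#' @inheritParams decompose
#' @return object of class `component_maps`: list with matrices
#'   `ventilation` and `pulsatility` (rows x cols, zero off-mask),
#'   `n_breaths_used`, `n_components_resp`, `n_components_card`, plus
#'   `mask`, `grid`, `peep`, `patient_id`.
#' @export
component_maps <- function(recording,
                           resp_band = resp_band_default,
                           cardiac_band = cardiac_band_default,
                           var_retain = 0.99) {
  dec <- decompose(recording, resp_band, cardiac_band, var_retain)
  vm <- ventilation_map(dec$resp, dec$fs, dec$mask,
                        paste0(dec$patient_id, "@PEEP", dec$peep))
  pm <- pulsatility_map(dec$card, dec$fs, dec$mask)
  structure(
    list(ventilation = vm$map, pulsatility = pm,
         n_breaths_used = vm$n_breaths_used,
         n_components_resp = dec$n_components_resp,
         n_components_card = dec$n_components_card,
         mask = dec$mask, grid = dec$grid,
         peep = dec$peep, patient_id = dec$patient_id),
    class = "component_maps"
  )
}
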