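# Normalised V' and Q maps and per-pixel V'/Q unit classification.

#' Unit classification thresholds
#'
#' @param ventilated_cutoff,perfused_cutoff a pixel counts as ventilated
#'   (perfused) iff its normalised value exceeds this fraction of the map
#'   maximum; default 0.10.
#' @param high_ratio,low_ratio normalised V'/Q ratio bounds: matched pixels
#'   with ratio strictly above `high_ratio` are high-V'/Q units, strictly
#'   below `low_ratio` low-V'/Q units; default 2 and 0.5.
#' @return named list of thresholds.
#' @export
vq_thresholds <- function(ventilated_cutoff = 0.10, perfused_cutoff = 0.10,
                          high_ratio = 2, low_ratio = 0.5) {
  stopifnot(ventilated_cutoff >= 0, ventilated_cutoff < 1,
            perfused_cutoff >= 0, perfused_cutoff < 1,
            high_ratio > low_ratio, low_ratio > 0)
  list(ventilated_cutoff = ventilated_cutoff,
       perfused_cutoff = perfused_cutoff,
       high_ratio = high_ratio, low_ratio = low_ratio)
}

#' Classify lung pixels into V'/Q unit types
#'
#' A pixel is ventilated iff its ventilation fraction exceeds
#' `ventilated_cutoff` times the map maximum, perfused likewise. Units are
#' `dead_space` (ventilated, not perfused), `shunt` (perfused, not
#' ventilated), and for matched pixels (both) the normalised ratio
#' `r = (v / sum(v over matched)) / (q / sum(q over matched))` splits them
#' into `high_vq` (`r > high_ratio`, strict), `low_vq` (`r < low_ratio`,
#' strict) and `normal`. Pixels that are neither ventilated nor perfused
#' (including everything off-mask) are `background`.
#'
#' @param v_frac,q_frac normalised maps (rows x cols), each summing to 1
#'   over the mask.
#' @param thresholds a [vq_thresholds()] list.
#' @param mask logical lung mask.
#' @return character matrix of unit classes.
#' @export
classify_units <- function(v_frac, q_frac, thresholds = vq_thresholds(),
                           mask) {
  if (max(v_frac) == 0 && max(q_frac) == 0) {
    stop("empty functional lung: ventilation and perfusion maps are all zero")
  }
  vent <- mask & (v_frac > thresholds$ventilated_cutoff * max(v_frac))
  perf <- mask & (q_frac > thresholds$perfused_cutoff * max(q_frac))
  cls <- matrix("background", nrow(mask), ncol(mask))
  cls[vent & !perf] <- "dead_space"
  cls[perf & !vent] <- "shunt"
  matched <- vent & perf
  if (any(matched)) {
    rv <- v_frac / sum(v_frac[matched])
    rq <- q_frac / sum(q_frac[matched])
    r <- rv[matched] / rq[matched]
    lab <- ifelse(r > thresholds$high_ratio, "high_vq",
                  ifelse(r < thresholds$low_ratio, "low_vq", "normal"))
    cls[matched] <- lab
  }
  cls
}

#' Build normalised V'/Q maps from component maps
#'
#' Normalises the ventilation and pulsatility maps to fractions of their
#' mask totals and classifies every pixel into a V'/Q unit type.
#'
#' @param maps a [component_maps()] object (or any list with `ventilation`,
#'   `pulsatility`, `mask` matrices).
#' @param thresholds a [vq_thresholds()] list.
#' @return object of class `vq_maps`: `v_frac`, `q_frac` (each summing to 1
#'   over the mask when the map total is positive), `unit_class` character
#'   matrix, `thresholds`, `mask`, plus the per-pixel normalised ratio on
#'   matched pixels in `ratio` (NA elsewhere).
#' @export
vq_maps <- function(maps, thresholds = vq_thresholds()) {
  mask <- maps$mask
  v <- maps$ventilation
  q <- maps$pulsatility
  v[!mask] <- 0
  q[!mask] <- 0
  vt <- sum(v); qt <- sum(q)
  v_frac <- if (vt > 0) v / vt else v
  q_frac <- if (qt > 0) q / qt else q
  cls <- classify_units(v_frac, q_frac, thresholds, mask)

  ratio <- matrix(NA_real_, nrow(mask), ncol(mask))
  matched <- cls %in% c("high_vq", "low_vq", "normal")
  dim(matched) <- dim(cls)
  if (any(matched)) {
    rv <- v_frac / sum(v_frac[matched])
    rq <- q_frac / sum(q_frac[matched])
    ratio[matched] <- rv[matched] / rq[matched]
  }
  structure(
    list(v_frac = v_frac, q_frac = q_frac, unit_class = cls, ratio = ratio,
         thresholds = thresholds, mask = mask,
         peep = maps$peep, patient_id = maps$patient_id),
    class = "vq_maps"
  )
}

#' Four ventral-to-dorsal regions of interest
#'
#' Splits the grid rows into four contiguous horizontal layers of (near)
#' equal span, ordered ventral (ROI1) to dorsal (ROI4).
#'
#' @param rows number of grid rows.
#' @return integer vector of length `rows` with values 1-4.
#' @export
roi_partition <- function(rows) {
  stopifnot(rows >= 4)
  as.integer(ceiling(4 * seq_len(rows) / rows))
}
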