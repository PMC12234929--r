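# The 180-variable regional V'/Q feature panel: registry, per-feature
# computation and full extraction.

vent_perf_stats <- function() {
  # (stat, scopes) pairs for one map; 32 entries per map
  list(
    roi_fraction = paste0("roi", 1:4),
    center_vd   = c("global", paste0("roi", 1:4)),
    center_lr   = "global",
    gi          = c("global", paste0("roi", 1:4)),
    cv          = c("global", paste0("roi", 1:4)),
    active_area = c("global", paste0("roi", 1:4)),
    entropy     = c("global", paste0("roi", 1:4)),
    dorsal_fraction = "global",
    right_fraction  = "global"
  )
}

vq_match_stats <- function() {
  # 22 per-scope statistics evaluated at global + 4 ROI scopes
  c("v_to_dead_space", "v_to_high_vq", "v_to_low_vq", "v_to_normal_vq",
    "v_to_matched",
    "q_to_shunt", "q_to_high_vq", "q_to_low_vq", "q_to_normal_vq",
    "q_to_matched",
    "area_dead_space", "area_shunt", "area_high_vq", "area_low_vq",
    "area_normal_vq", "area_matched",
    "mean_log10_vq_ratio", "sd_log10_vq_ratio", "median_log10_vq_ratio",
    "iqr_log10_vq_ratio", "high_side_fraction", "vq_correlation")
}

# canonical (publication) names for the global-scope V'/Q variables
vq_global_name <- c(
  v_to_dead_space = "dead_space_fraction",
  v_to_high_vq = "ventilation_to_high_vq",
  v_to_low_vq = "ventilation_to_low_vq",
  v_to_normal_vq = "ventilation_to_normal_vq",
  v_to_matched = "ventilation_to_matched",
  q_to_shunt = "wasted_perfusion",
  q_to_high_vq = "perfusion_to_high_vq",
  q_to_low_vq = "perfusion_to_low_vq",
  q_to_normal_vq = "perfusion_to_normal_vq",
  q_to_matched = "perfusion_to_matched"
)

#' Default feature registry
#'
#' The panel of 180 named regional variables extracted from each
#' recording: 64 from the ventilation and perfusion (pulsatility) maps and
#' 116 from their V'/Q matching. Each map contributes per-ROI fractions,
#' centers of distribution (ventral-dorsal and left-right first moments),
#' global-inhomogeneity indices, coefficients of variation, active-area
#' fractions and distribution entropies, at the global and the four
#' ventral-to-dorsal ROI scopes. The V'/Q family contributes, at the same
#' five scopes, the ventilation and perfusion allocated to dead space,
#' shunt, high-, low- and normal-V'/Q units, unit-type area fractions and
#' log10 V'/Q-ratio statistics, plus six whole-lung summaries (dorsal and
#' ventral wasted ventilation/perfusion, a total-wasted fraction and a
#' V'/Q mismatch index). The four headline variables
#' `dead_space_fraction`, `ventilation_to_high_vq`,
#' `perfusion_to_normal_vq` and `dorsal_wasted_perfusion` are all members.
#'
#' `ratio_scaled` flags the strictly non-negative fraction/ratio variables
#' that are log-transformed before z-scoring.
#'
#' @return data.frame with columns `name`, `family` (`vent_perf` or
#'   `vq_match`), `map` (`v`, `q` or `NA`), `stat`, `scope` (`global`,
#'   `roi1`..`roi4`), `ratio_scaled`.
#' @export
default_feature_registry <- function() {
  rows <- list()
  not_ratio <- c("center_vd", "center_lr", "mean_log10_vq_ratio",
                 "median_log10_vq_ratio", "vq_correlation")
  for (map in c("v", "q")) {
    for (stat in names(vent_perf_stats())) {
      for (scope in vent_perf_stats()[[stat]]) {
        nm <- if (scope == "global") paste0(map, "_", stat)
              else paste0(map, "_", stat, "_", scope)
        rows[[length(rows) + 1]] <- data.frame(
          name = nm, family = "vent_perf", map = map, stat = stat,
          scope = scope, ratio_scaled = !(stat %in% not_ratio),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (stat in vq_match_stats()) {
    for (scope in c("global", paste0("roi", 1:4))) {
      nm <- if (scope == "global") {
        if (stat %in% names(vq_global_name)) unname(vq_global_name[stat])
        else stat
      } else paste0(stat, "_", scope)
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, family = "vq_match", map = NA_character_, stat = stat,
        scope = scope, ratio_scaled = !(stat %in% not_ratio),
        stringsAsFactors = FALSE)
    }
  }
  for (stat in c("dorsal_wasted_perfusion", "dorsal_wasted_ventilation",
                 "ventral_wasted_perfusion", "ventral_wasted_ventilation",
                 "total_wasted_fraction", "vq_mismatch_index")) {
    rows[[length(rows) + 1]] <- data.frame(
      name = stat, family = "vq_match", map = NA_character_, stat = stat,
      scope = "global", ratio_scaled = TRUE, stringsAsFactors = FALSE)
  }
  reg <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(reg$name))
  reg
}

#' Write / read a feature registry as JSON
#' @param registry a registry data.frame.
#' @param path file path.
#' @return `read_registry` returns the registry data.frame.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(registry, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

# pixel sets by scope: logical matrix for "global" or "roiK"
scope_mask <- function(scope, mask) {
  if (scope == "global") return(mask)
  k <- as.integer(substring(scope, 4))
  roi <- roi_partition(nrow(mask))
  mask & matrix(roi == k, nrow(mask), ncol(mask))
}

feature_warn <- function(name, why) {
  eit_log("feature '", name, "' ", why, "; value set to 0")
}

# distribution statistics of a fraction map over a pixel set
dist_stat <- function(stat, m, sel, mask, name) {
  tot <- sum(m[sel])
  switch(stat,
    roi_fraction = sum(m[sel]),  # m sums to 1 over mask
    dorsal_fraction = {
      roi <- roi_partition(nrow(mask))
      dorsal <- matrix(roi >= 3, nrow(mask), ncol(mask))
      sum(m[sel & dorsal])
    },
    right_fraction = {
      cols <- ncol(mask)
      right <- matrix(rep(seq_len(cols) > cols / 2, each = nrow(mask)),
                      nrow(mask), cols)
      sum(m[sel & right])
    },
    center_vd = {
      if (tot <= 0) { feature_warn(name, "has zero mass in scope"); return(0) }
      rf <- (matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask)) - 0.5) / nrow(mask)
      sum(m[sel] * rf[sel]) / tot
    },
    center_lr = {
      if (tot <= 0) { feature_warn(name, "has zero mass in scope"); return(0) }
      cf <- (matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE) - 0.5) / ncol(mask)
      sum(m[sel] * cf[sel]) / tot
    },
    gi = {
      if (tot <= 0) { feature_warn(name, "has zero mass in scope"); return(0) }
      x <- m[sel]
      sum(abs(x - stats::median(x))) / sum(x)
    },
    cv = {
      x <- m[sel]
      if (length(x) < 2 || mean(x) <= 0) {
        feature_warn(name, "is degenerate in scope"); return(0)
      }
      stats::sd(x) / mean(x)
    },
    active_area = {
      if (!any(sel) || max(m) <= 0) { feature_warn(name, "has empty scope"); return(0) }
      mean(m[sel] > 0.1 * max(m))
    },
    entropy = {
      x <- m[sel]
      if (tot <= 0 || length(x) < 2) {
        feature_warn(name, "has zero mass in scope"); return(0)
      }
      p <- x[x > 0] / tot
      -sum(p * log(p)) / log(length(x))
    },
    stop("unknown vent_perf stat: ", stat)
  )
}

vq_stat <- function(stat, vq, sel, mask, name) {
  cls <- vq$unit_class
  vent_tot <- sum(vq$v_frac[cls == "dead_space" |
                              cls %in% c("high_vq", "low_vq", "normal")])
  perf_tot <- sum(vq$q_frac[cls == "shunt" |
                              cls %in% c("high_vq", "low_vq", "normal")])
  frac_of <- function(m, classes, total) {
    if (total <= 0) { feature_warn(name, "has zero functional mass"); return(0) }
    sum(m[sel & (cls %in% classes) & !is.na(sel)]) / total
  }
  in_class <- function(classes) sel & matrix(cls %in% classes, nrow(cls), ncol(cls))
  matched_classes <- c("high_vq", "low_vq", "normal")
  switch(stat,
    v_to_dead_space = frac_of(vq$v_frac, "dead_space", vent_tot),
    v_to_high_vq = frac_of(vq$v_frac, "high_vq", vent_tot),
    v_to_low_vq = frac_of(vq$v_frac, "low_vq", vent_tot),
    v_to_normal_vq = frac_of(vq$v_frac, "normal", vent_tot),
    v_to_matched = frac_of(vq$v_frac, matched_classes, vent_tot),
    q_to_shunt = frac_of(vq$q_frac, "shunt", perf_tot),
    q_to_high_vq = frac_of(vq$q_frac, "high_vq", perf_tot),
    q_to_low_vq = frac_of(vq$q_frac, "low_vq", perf_tot),
    q_to_normal_vq = frac_of(vq$q_frac, "normal", perf_tot),
    q_to_matched = frac_of(vq$q_frac, matched_classes, perf_tot),
    area_dead_space = ,
    area_shunt = ,
    area_high_vq = ,
    area_low_vq = ,
    area_normal_vq = ,
    area_matched = {
      classes <- switch(stat,
        area_dead_space = "dead_space", area_shunt = "shunt",
        area_high_vq = "high_vq", area_low_vq = "low_vq",
        area_normal_vq = "normal", area_matched = matched_classes)
      n_lung <- sum(sel & mask)
      if (n_lung == 0) { feature_warn(name, "has empty scope"); return(0) }
      sum(in_class(classes)) / n_lung
    },
    mean_log10_vq_ratio = ,
    sd_log10_vq_ratio = ,
    median_log10_vq_ratio = ,
    iqr_log10_vq_ratio = ,
    high_side_fraction = {
      r <- vq$ratio[in_class(matched_classes)]
      r <- r[is.finite(r) & r > 0]
      if (length(r) == 0) { feature_warn(name, "has no matched pixels"); return(0) }
      lr <- log10(r)
      switch(stat,
        mean_log10_vq_ratio = mean(lr),
        sd_log10_vq_ratio = if (length(lr) > 1) stats::sd(lr) else 0,
        median_log10_vq_ratio = stats::median(lr),
        iqr_log10_vq_ratio = stats::IQR(lr),
        high_side_fraction = mean(lr > 0))
    },
    vq_correlation = {
      v <- vq$v_frac[sel & mask]; q <- vq$q_frac[sel & mask]
      if (length(v) < 3 || stats::sd(v) == 0 || stats::sd(q) == 0) {
        feature_warn(name, "is degenerate in scope"); return(0)
      }
      stats::cor(v, q)
    },
    stop("unknown vq_match stat: ", stat)
  )
}

vq_global_extra <- function(stat, vq, mask, name) {
  cls <- vq$unit_class
  roi <- roi_partition(nrow(mask))
  dorsal <- matrix(roi >= 3, nrow(mask), ncol(mask))
  vent_tot <- sum(vq$v_frac[cls %in% c("dead_space", "high_vq", "low_vq", "normal")])
  perf_tot <- sum(vq$q_frac[cls %in% c("shunt", "high_vq", "low_vq", "normal")])
  safe <- function(num, den) {
    if (den <= 0) { feature_warn(name, "has zero functional mass"); 0 }
    else num / den
  }
  switch(stat,
    dorsal_wasted_perfusion =
      safe(sum(vq$q_frac[dorsal & cls == "shunt"]), perf_tot),
    ventral_wasted_perfusion =
      safe(sum(vq$q_frac[!dorsal & cls == "shunt"]), perf_tot),
    dorsal_wasted_ventilation =
      safe(sum(vq$v_frac[dorsal & cls == "dead_space"]), vent_tot),
    ventral_wasted_ventilation =
      safe(sum(vq$v_frac[!dorsal & cls == "dead_space"]), vent_tot),
    total_wasted_fraction =
      (safe(sum(vq$v_frac[cls == "dead_space"]), vent_tot) +
         safe(sum(vq$q_frac[cls == "shunt"]), perf_tot)) / 2,
    vq_mismatch_index =
      1 - (safe(sum(vq$v_frac[cls == "normal"]), vent_tot) +
             safe(sum(vq$q_frac[cls == "normal"]), perf_tot)) / 2,
    stop("unknown global vq stat: ", stat)
  )
}

#' Compute one named feature from V'/Q maps
#'
#' Ventilation/perfusion ("allocation") fractions are expressed relative to
#' the total functional mass: ventilation fractions divide by the
#' ventilation on ventilated pixels, perfusion fractions by the perfusion
#' on perfused pixels, so dead space + high + low + normal ventilation
#' fractions always sum to 1 (and likewise for perfusion across
#' shunt/high/low/normal). Degenerate denominators yield 0 with a logged
#' note rather than a missing value, keeping feature tables complete.
#'
#' @param name registry feature name.
#' @param vq a [vq_maps()] object.
#' @param registry registry data.frame; defaults to
#'   [default_feature_registry()].
#' @return scalar feature value.
#' @export
compute_feature <- function(name, vq, registry = default_feature_registry()) {
  row <- registry[registry$name == name, ]
  if (nrow(row) != 1) stop("unknown feature: ", name)
  mask <- vq$mask
  sel <- scope_mask(row$scope, mask)
  if (row$family == "vent_perf") {
    m <- if (row$map == "v") vq$v_frac else vq$q_frac
    dist_stat(row$stat, m, sel, mask, name)
  } else if (row$scope == "global" &&
             row$stat %in% c("dorsal_wasted_perfusion",
                             "dorsal_wasted_ventilation",
                             "ventral_wasted_perfusion",
                             "ventral_wasted_ventilation",
                             "total_wasted_fraction", "vq_mismatch_index")) {
    vq_global_extra(row$stat, vq, mask, name)
  } else {
    vq_stat(row$stat, vq, sel, mask, name)
  }
}

#' Extract the full feature panel from component maps
#'
#' Normalises the maps, classifies V'/Q units and evaluates every registry
#' feature in registry order.
#'
#' @param maps a [component_maps()] object.
#' @param thresholds a [vq_thresholds()] list.
#' @param registry registry data.frame.
#' @return named numeric vector, one element per registry entry, with
#'   attributes `patient_id` and `peep`.
#' @export
extract_features <- function(maps, thresholds = vq_thresholds(),
                             registry = default_feature_registry()) {
  vq <- vq_maps(maps, thresholds)
  vals <- vapply(registry$name, compute_feature, numeric(1),
                 vq = vq, registry = registry)
  names(vals) <- registry$name
  attr(vals, "patient_id") <- maps$patient_id
  attr(vals, "peep") <- maps$peep
  vals
}

#' Extract per-step feature tables for a whole cohort
#'
#' Runs [component_maps()] and [extract_features()] on every recording.
#' Recordings whose pulsatility cannot be resolved are excluded with a
#' logged note.
#'
#' @param cohort an `eit_cohort` (or any list of patients with recordings).
#' @param thresholds,registry see [extract_features()].
#' @param resp_band,cardiac_band see [decompose()].
#' @param peep_subset optional subset of PEEP steps to featurise.
#' @return named list of data.frames, one per PEEP step: columns
#'   `patient_id`, `peep`, then the registry features.
#' @export
cohort_feature_tables <- function(cohort, thresholds = vq_thresholds(),
                                  registry = default_feature_registry(),
                                  resp_band = resp_band_default,
                                  cardiac_band = cardiac_band_default,
                                  peep_subset = NULL) {
  steps <- cohort$config$peep_steps
  if (!is.null(peep_subset)) steps <- intersect(steps, peep_subset)
  tables <- list()
  for (s in steps) {
    rows <- list()
    for (p in cohort$patients) {
      rec <- p$recordings[[as.character(s)]]
      fv <- tryCatch({
        maps <- component_maps(rec, resp_band, cardiac_band)
        extract_features(maps, thresholds, registry)
      }, eitomics_pulsatility_error = function(e) {
        eit_log(conditionMessage(e), " -- recording excluded")
        NULL
      })
      if (!is.null(fv)) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = p$patient_id, peep = s, t(fv),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    tables[[as.character(s)]] <- do.call(rbind, rows)
  }
  tables
}

#' Write / read a feature table as CSV
#' @param table feature table data.frame.
#' @param path file path.
#' @return `read_feature_table` returns the data.frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
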