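# Synthetic cohort generator: EIT recordings with planted sub-phenotype
# structure plus archetype-linked validation variables.

#' Cohort simulation settings
#'
#' Bundles every knob of the synthetic cohort generator. The defaults
#' emulate a 30-patient decremental PEEP trial from 18 to 4 cmH2O in steps
#' of 2 cmH2O, with respiratory and cardiac impedance components
#' superimposed per pixel on a 16 x 16 reconstruction grid.
#'
#' @param n_patients number of patients (>= number of archetypes).
#' @param mixture archetype mixing proportions; must sum to 1. Patient
#'   counts per archetype are fixed by deterministic largest-remainder
#'   rounding, so `mixture = c(0.5, 0.3, 0.2)` with 30 patients always
#'   yields 15/9/6.
#' @param seed master integer seed; every random draw in the generator is
#'   derived from it.
#' @param grid `c(rows, cols)` of the pixel grid; row 1 is ventral,
#'   increasing row index is dorsal.
#' @param fs sampling rate in Hz.
#' @param resp_rate respiratory rate, breaths/min.
#' @param cardiac_rate heart rate, beats/min. Its fundamental must clear the
#'   second harmonic of the respiratory rate, otherwise spectral separation
#'   of the two components is impossible and the configuration is rejected.
#' @param peep_steps PEEP values of the trial in cmH2O.
#' @param step_duration duration of each PEEP step in seconds (default 32 s:
#'   an integer number of breaths at the default respiratory rate, which
#'   keeps the tidal tones leakage-free on the Fourier grid). Must cover at
#'   least 10 cardiac periods and 10 seconds of signal.
#' @param noise_sd SD of the iid Gaussian pixel noise (impedance units;
#'   tidal amplitudes are O(1)).
#' @param separation archetype-separation multiplier: scales the
#'   archetype-specific map derangements (dead space/shunt extents, V'/Q
#'   dispersion, ventilation heterogeneity) away from a common neutral
#'   lung. 0 makes all archetypes identical; 1 is the study condition.
#' @param baseline end-expiratory impedance offset added on lung pixels.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 30,
                          mixture = c(0.5, 0.3, 0.2),
                          seed = 1L,
                          grid = c(16, 16),
                          fs = 10,
                          resp_rate = 15,
                          cardiac_rate = 80,
                          peep_steps = seq(18, 4, by = -2),
                          step_duration = 32,
                          noise_sd = 0.05,
                          separation = 1,
                          baseline = 10) {
  if (!is_count(n_patients)) stop("n_patients must be a positive integer")
  if (abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    stop("mixture must be non-negative and sum to 1")
  }
  stopifnot(length(grid) == 2, all(grid >= 4), fs > 0,
            resp_rate > 0, cardiac_rate > 0,
            length(peep_steps) >= 1, all(peep_steps > 0),
            step_duration > 0, noise_sd >= 0, separation >= 0)
  f_resp <- resp_rate / 60
  f_card <- cardiac_rate / 60
  # tidal profile carries power at f_resp and 2*f_resp; demand clearance
  if (f_card <= 2 * f_resp + 0.1) {
    stop("respiratory and cardiac spectral bands overlap (cardiac ",
         "fundamental must exceed the second respiratory harmonic); ",
         "component separation impossible")
  }
  if (fs <= 2 * f_card) stop("fs must exceed twice the cardiac frequency")
  if (step_duration < 10 / f_card) {
    stop("step_duration too short: fewer than 10 cardiac periods, ",
         "pulsatility cannot be resolved")
  }
  if (step_duration * fs < 10 * fs) {
    stop("recordings must span at least 10 s")
  }
  structure(
    list(n_patients = as.integer(n_patients), mixture = mixture,
         seed = as.integer(seed), grid = as.integer(grid), fs = fs,
         resp_rate = resp_rate, cardiac_rate = cardiac_rate,
         peep_steps = peep_steps, step_duration = step_duration,
         noise_sd = noise_sd, separation = separation, baseline = baseline),
    class = "cohort_config"
  )
}

#' Elliptical two-lung mask
#'
#' Boolean rows x cols matrix marking the lung region: two ellipses, one per
#' lung, on the reconstruction grid (row 1 ventral).
#'
#' @param rows,cols grid dimensions.
#' @return logical matrix.
#' @export
lung_mask <- function(rows, cols) {
  rf <- (matrix(seq_len(rows), rows, cols) - 0.5) / rows
  cf <- (matrix(seq_len(cols), rows, cols, byrow = TRUE) - 0.5) / cols
  inside <- function(r0, c0, ra, ca) ((rf - r0) / ra)^2 + ((cf - c0) / ca)^2 <= 1
  inside(0.52, 0.28, 0.40, 0.21) | inside(0.52, 0.72, 0.40, 0.21)
}

#' EIT recording container
#'
#' @param impedance numeric matrix, n_pixels x n_samples; pixel p maps to
#'   grid cell (row, col) by R's column-major order over a rows x cols
#'   matrix.
#' @param fs sampling rate (Hz).
#' @param mask logical rows x cols lung mask.
#' @param peep PEEP (cmH2O) at which the recording was taken.
#' @param patient_id identifier.
#' @param grid `c(rows, cols)`.
#' @return object of class `eit_recording`.
#' @export
eit_recording <- function(impedance, fs, mask, peep, patient_id, grid) {
  stopifnot(is.matrix(impedance), nrow(impedance) == prod(grid),
            is.logical(mask), all(dim(mask) == grid))
  if (ncol(impedance) < 10 * fs) {
    stop("recording too short: need at least 10 s of samples")
  }
  if (!any(mask)) stop("lung mask is empty")
  structure(
    list(impedance = impedance, fs = fs, mask = mask, peep = peep,
         patient_id = patient_id, grid = as.integer(grid)),
    class = "eit_recording"
  )
}

#' @export
print.eit_recording <- function(x, ...) {
  cat(sprintf(
    "<eit_recording> %s | PEEP %g cmH2O | %d x %d grid, %d samples @ %g Hz\n",
    x$patient_id, x$peep, x$grid[1], x$grid[2], ncol(x$impedance), x$fs))
  invisible(x)
}

# Patient-level random effects: global amplitudes, cardiac phase and the
# random phases of the spatial modulation fields. One draw per patient so
# the same lungs persist across PEEP steps.
draw_patient_params <- function(seed) {
  with_seed(seed, {
    list(
      amp_v = exp(rnorm(1, 0, 0.15)),
      amp_q = 0.25 * exp(rnorm(1, 0, 0.15)),
      card_phase = runif(1, 0, 2 * pi),
      extent_jitter = exp(rnorm(2, 0, 0.10)),
      disp_phase = runif(2, 0, 1),
      het_phase = runif(4, 0, 1)
    )
  })
}

# Archetype-specific per-pixel ventilation and pulsatility amplitude
# templates at one PEEP. Row 1 is ventral. Dead space: ventral region keeps
# ventilation but loses pulsatility; shunt: dorsal region keeps pulsatility
# but loses ventilation; V'/Q dispersion tilts v against q along a smooth
# field; ventilation heterogeneity multiplies v by a patchy field.
make_templates <- function(archetype, params, peep, config) {
  rows <- config$grid[1]; cols <- config$grid[2]
  mask <- lung_mask(rows, cols)
  rf <- (matrix(seq_len(rows), rows, cols) - 0.5) / rows
  cf <- (matrix(seq_len(cols), rows, cols, byrow = TRUE) - 0.5) / cols
  sev <- archetype$peep_response(peep) * config$separation

  v <- 1 + 0.3 * rf          # mildly dorsal-weighted healthy ventilation
  q <- 1 + 0.5 * rf          # gravity-dependent perfusion

  # smooth dispersion field in [-1, 1], patient-specific phase
  g <- sin(2 * pi * (1.5 * cf + params$disp_phase[1])) *
    cos(pi * (2 * rf + params$disp_phase[2]))
  disp <- archetype$vq_dispersion * sev
  v <- v * exp(+0.5 * disp * g)
  q <- q * exp(-0.5 * disp * g)

  # patchy heterogeneity field applied to ventilation only
  h <- 0.5 * (sin(2 * pi * (3 * cf + params$het_phase[1])) *
                sin(2 * pi * (3 * rf + params$het_phase[2])) +
              sin(2 * pi * (2 * cf + params$het_phase[3]) +
                    2 * pi * (2 * rf + params$het_phase[4])))
  het <- archetype$ventilation_heterogeneity * sev
  v <- v * exp(het * h)

  # unmatched regions: ventral dead space, dorsal shunt
  d_ext <- min(1, archetype$dead_space_level * sev * params$extent_jitter[1])
  s_ext <- min(1, archetype$shunt_level * sev * params$extent_jitter[2])
  dead <- rf < d_ext
  shunt <- rf > 1 - s_ext
  q[dead] <- q[dead] * 0.02
  v[shunt] <- v[shunt] * 0.02

  v <- v * params$amp_v
  q <- q * params$amp_q
  v[!mask] <- 0
  q[!mask] <- 0
  list(v = v, q = q, mask = mask)
}

#' Simulate one EIT recording at a given PEEP
#'
#' Each lung pixel carries `baseline + v_i * w_resp(t) + q_i * w_card(t) +
#' noise`, where `w_resp` is a raised-cosine tidal profile in \[0, 1\] at
#' the respiratory rate (so the end-inspiratory minus end-expiratory pixel
#' difference equals `v_i`), `w_card` is a unit sinusoid at the cardiac rate
#' with a patient-specific phase, and the spatial amplitude templates
#' `(v_i, q_i)` are drawn from the archetype at that PEEP. Pixels outside
#' the lung mask contain noise only.
#'
#' @param archetype a [phenotype_archetype()].
#' @param peep PEEP (cmH2O); must be one of `config$peep_steps`.
#' @param config a [cohort_config()].
#' @param seed integer seed; identical arguments and seed reproduce the
#'   recording bit for bit.
#' @param patient_id identifier stored in the recording.
#' @param params optional pre-drawn patient random effects (internal use,
#'   keeps one patient's lungs identical across PEEP steps).
#' @return an [eit_recording()]; the generating amplitude templates are
#'   attached as `attr(, "templates")` for validation purposes and are never
#'   read by the analysis stages.
#' @export
generate_recording <- function(archetype, peep, config, seed = config$seed,
                               patient_id = "P01", params = NULL) {
  stopifnot(inherits(archetype, "phenotype_archetype"),
            inherits(config, "cohort_config"))
  if (!peep %in% config$peep_steps) {
    stop("peep ", peep, " is not one of the configured trial steps")
  }
  if (is.null(params)) params <- draw_patient_params(derive_seed(seed, 0L))
  tpl <- make_templates(archetype, params, peep, config)

  n <- round(config$step_duration * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  w_resp <- ((1 - cos(2 * pi * (config$resp_rate / 60) * t)) / 2)^2
  w_card <- sin(2 * pi * (config$cardiac_rate / 60) * t + params$card_phase)

  v <- as.vector(tpl$v); q <- as.vector(tpl$q)
  base <- ifelse(as.vector(tpl$mask), config$baseline, 0)
  X <- outer(v, w_resp) + outer(q, w_card) + base
  if (config$noise_sd > 0) {
    X <- X + with_seed(derive_seed(seed, 1L),
                       matrix(rnorm(length(X), 0, config$noise_sd),
                              nrow(X), ncol(X)))
  }
  rec <- eit_recording(X, config$fs, tpl$mask, peep, patient_id, config$grid)
  attr(rec, "templates") <- list(v = tpl$v, q = tpl$q)
  rec
}

# Truncated-normal helper: redraws are avoided by reflecting at the floor.
pos_norm <- function(n, mean, sd, floor = 0.1) pmax(floor, rnorm(n, mean, sd))

draw_validation <- function(archetype, patient_id, seed) {
  with_seed(seed, {
    out <- list(patient_id = patient_id)
    for (lv in c("low", "intermediate", "high")) {
      row <- archetype$drive_profile[archetype$drive_profile$level == lv, ]
      out[[paste0("p01_", lv)]] <- pos_norm(1, row$p01_mean, row$p01_sd)
      out[[paste0("dpes_", lv)]] <- pos_norm(1, row$dpes_mean, row$dpes_sd)
      out[[paste0("dplung_", lv)]] <- pos_norm(1, row$dplung_mean, row$dplung_sd)
    }
    out$peepeit <- pos_norm(1, archetype$peepeit_mean, archetype$peepeit_sd,
                            floor = 4)
    sdlog <- 0.4
    out$icu_los <- max(1, round(rlnorm(1, log(archetype$los_mean) -
                                         sdlog^2 / 2, sdlog)))
    out$true_archetype <- archetype$name
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort with planted sub-phenotypes
#'
#' Simulates `config$n_patients` patients, each with one EIT recording per
#' PEEP step and one validation record (P0.1, esophageal and transpulmonary
#' pressure swings per PEEP level, personalised PEEP, ICU length of stay).
#' Archetype counts follow deterministic largest-remainder rounding of
#' `config$mixture`. Truth labels are returned separately from the
#' recordings so the clustering stages can stay blind to them.
#'
#' @param config a [cohort_config()].
#' @param archetypes list of [phenotype_archetype()]; defaults to
#'   [default_archetypes()].
#' @return object of class `eit_cohort`: list with elements
#'   `patients` (list of `list(patient_id, recordings)` with recordings
#'   named by PEEP), `validation` (data.frame, one row per patient) and
#'   `truth` (data.frame `patient_id`, `archetype`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            archetypes = default_archetypes()) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$mixture) != length(archetypes)) {
    stop("mixture length must match the number of archetypes")
  }
  if (config$n_patients < length(archetypes)) {
    stop("n_patients must be at least the number of archetypes")
  }
  counts <- round_mixture(config$n_patients, config$mixture)
  arch_idx <- rep(seq_along(archetypes), counts)
  ids <- sprintf("P%02d", seq_len(config$n_patients))

  patients <- vector("list", config$n_patients)
  validation <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    arch <- archetypes[[arch_idx[i]]]
    params <- draw_patient_params(derive_seed(config$seed, i, 0L))
    recs <- lapply(config$peep_steps, function(s) {
      generate_recording(arch, s, config,
                         seed = derive_seed(config$seed, i, round(10 * s)),
                         patient_id = ids[i], params = params)
    })
    names(recs) <- as.character(config$peep_steps)
    patients[[i]] <- list(patient_id = ids[i], recordings = recs)
    validation[[i]] <- draw_validation(arch, ids[i],
                                       derive_seed(config$seed, i, 999L))
  }
  structure(
    list(
      patients = patients,
      validation = do.call(rbind, validation),
      truth = data.frame(patient_id = ids,
                         archetype = vapply(archetypes[arch_idx],
                                            `[[`, "", "name"),
                         stringsAsFactors = FALSE),
      config = config
    ),
    class = "eit_cohort"
  )
}

#' @export
print.eit_cohort <- function(x, ...) {
  cat(sprintf("<eit_cohort> %d patients x %d PEEP steps (%s cmH2O), seed %d\n",
              length(x$patients), length(x$config$peep_steps),
              paste(x$config$peep_steps, collapse = ","), x$config$seed))
  print(table(x$truth$archetype))
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' One CSV per recording (pixels x samples), a cohort-level validation CSV,
#' a truth-label CSV and a JSON manifest recording the seed, the
#' configuration and every file written.
#'
#' @param cohort an `eit_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (p in cohort$patients) {
    for (rec in p$recordings) {
      f <- file.path(dir, sprintf("%s_peep%02d.csv", p$patient_id, rec$peep))
      utils::write.csv(rec$impedance, f, row.names = FALSE)
      files <- c(files, basename(f))
    }
  }
  utils::write.csv(cohort$validation, file.path(dir, "validation.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth_labels.csv"),
                   row.names = FALSE)
  mask <- lung_mask(cohort$config$grid[1], cohort$config$grid[2])
  utils::write.csv(mask * 1L, file.path(dir, "lung_mask.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = cohort$config$seed,
    config = cohort$config[setdiff(names(cohort$config), "mixture")],
    mixture = cohort$config$mixture,
    recordings = files,
    validation = "validation.csv",
    truth = "truth_labels.csv",
    mask = "lung_mask.csv"
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
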