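# Sub-phenotype archetypes driving the synthetic cohort generator.

#' Construct a sub-phenotype archetype
#'
#' An archetype bundles the regional-physiology parameters that shape a
#' synthetic patient's ventilation/perfusion maps together with the
#' respiratory drive, effort and outcome distributions used for external
#' validation. The three defaults (see [default_archetypes()]) emulate the
#' ARDS sub-phenotypes commonly described in functional EIT imaging:
#' unmatched V'/Q (frank dead space and shunt), mismatched V'/Q (wide
#' dispersion of regional V'/Q ratios without large unmatched regions) and
#' inhomogeneous ventilation (patchy ventilation with well-matched
#' perfusion).
#'
#' @param name archetype label; one of `"unmatched_vq"`, `"mismatched_vq"`,
#'   `"inhomogeneous_ventilation"` (other labels are allowed for custom
#'   archetypes).
#' @param dead_space_level fraction in \[0, 1\]: extent of the ventral
#'   ventilated-but-unperfused region at full severity.
#' @param shunt_level fraction in \[0, 1\]: extent of the dorsal
#'   perfused-but-unventilated region at full severity.
#' @param vq_dispersion non-negative spread (natural-log scale) of regional
#'   V'/Q ratios in matched lung.
#' @param ventilation_heterogeneity non-negative amplitude of the patchy
#'   multiplicative field applied to the ventilation template.
#' @param peep_response function mapping a PEEP value (cmH2O) to a severity
#'   multiplier in \[0, 1\] applied to the four parameters above. The default
#'   decreases linearly from 1 at PEEP 4 to 0.3 at PEEP 18, so derangements
#'   are most expressed at low PEEP and partially recruited away at high
#'   PEEP.
#' @param drive_profile data.frame with columns `level`
#'   (`"low"`, `"intermediate"`, `"high"`), `p01_mean`, `p01_sd`,
#'   `dpes_mean`, `dpes_sd`, `dplung_mean`, `dplung_sd` (all cmH2O):
#'   the per-PEEP-level distributions of respiratory drive (P0.1), effort
#'   (esophageal pressure swing) and dynamic lung stress (transpulmonary
#'   pressure swing).
#' @param peepeit_mean,peepeit_sd mean/SD (cmH2O) of the personalised PEEP
#'   selected for this archetype by an external overdistension/collapse
#'   balancing algorithm; emulated here as a validation variable only.
#' @param los_mean mean ICU length of stay in days (log-normal, >= 1 day).
#' @return an object of class `phenotype_archetype`.
#' @seealso [default_archetypes()], [generate_cohort()]
#' @export
phenotype_archetype <- function(name,
                                dead_space_level,
                                shunt_level,
                                vq_dispersion,
                                ventilation_heterogeneity,
                                peep_response = default_peep_response,
                                drive_profile,
                                peepeit_mean,
                                peepeit_sd = 2,
                                los_mean) {
  stopifnot(
    is.character(name), length(name) == 1L,
    dead_space_level >= 0, dead_space_level <= 1,
    shunt_level >= 0, shunt_level <= 1,
    vq_dispersion >= 0,
    ventilation_heterogeneity >= 0,
    is.function(peep_response),
    is.data.frame(drive_profile),
    peepeit_mean > 0, peepeit_sd >= 0, los_mean >= 1
  )
  need <- c("level", "p01_mean", "p01_sd", "dpes_mean", "dpes_sd",
            "dplung_mean", "dplung_sd")
  if (!all(need %in% names(drive_profile))) {
    stop("drive_profile must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(drive_profile$level, c("low", "intermediate", "high"))) {
    stop("drive_profile must cover levels low, intermediate, high")
  }
  sds <- unlist(drive_profile[, c("p01_sd", "dpes_sd", "dplung_sd")])
  if (any(sds < 0)) stop("drive_profile SDs must be >= 0")
  structure(
    list(
      name = name,
      dead_space_level = dead_space_level,
      shunt_level = shunt_level,
      vq_dispersion = vq_dispersion,
      ventilation_heterogeneity = ventilation_heterogeneity,
      peep_response = peep_response,
      drive_profile = drive_profile,
      peepeit_mean = peepeit_mean,
      peepeit_sd = peepeit_sd,
      los_mean = los_mean
    ),
    class = "phenotype_archetype"
  )
}

#' Default PEEP severity response
#'
#' Severity of the archetype-specific derangements as a function of PEEP:
#' 1 at 4 cmH2O, falling linearly to 0.3 at 18 cmH2O. Lung derangements are
#' therefore most expressed at low PEEP and partially, but never fully,
#' recruited away at high PEEP.
#'
#' @param peep PEEP in cmH2O.
#' @return severity multiplier in \[0.3, 1\].
#' @export
default_peep_response <- function(peep) {
  pmin(1, pmax(0.3, 0.3 + 0.7 * (18 - peep) / 14))
}

#' Map a PEEP value to its trial level
#'
#' Levels follow the decremental-trial convention: low = 4-8 cmH2O,
#' intermediate = 10-14 cmH2O, high = 16-18 cmH2O.
#'
#' @param peep PEEP value(s) in cmH2O.
#' @return character vector of `"low"`, `"intermediate"`, `"high"`.
#' @export
peep_level_of <- function(peep) {
  ifelse(peep <= 8, "low", ifelse(peep <= 14, "intermediate", "high"))
}

drive_df <- function(p01, dpes, dplung,
                     p01_sd = 0.7, dpes_sd = 2.0, dplung_sd = 2.5) {
  data.frame(
    level = c("low", "intermediate", "high"),
    p01_mean = p01, p01_sd = p01_sd,
    dpes_mean = dpes, dpes_sd = dpes_sd,
    dplung_mean = dplung, dplung_sd = dplung_sd,
    stringsAsFactors = FALSE
  )
}

#' The three default sub-phenotype archetypes
#'
#' Returns the archetype set planted by default in synthetic cohorts:
#'
#' * `unmatched_vq`: large dead space and shunt regions; highest
#'   respiratory drive (P0.1) and effort (esophageal swing) at low PEEP,
#'   converging toward the others at higher PEEP; a higher personalised
#'   PEEP and the longest ICU stay.
#' * `mismatched_vq`: wide dispersion of regional V'/Q ratios with only
#'   small unmatched regions; intermediate drive and effort at low PEEP.
#' * `inhomogeneous_ventilation`: patchy ventilation with well-matched
#'   perfusion; lowest drive and effort at low PEEP but the highest dynamic
#'   lung stress at high PEEP.
#'
#' At the low PEEP level the archetype means are ordered
#' unmatched > mismatched > inhomogeneous for both P0.1 and the esophageal
#' swing; the ordering dissolves at intermediate and high PEEP. The numeric
#' values are stylised generator defaults chosen to reproduce that
#' qualitative pattern; they are fully configurable via
#' [phenotype_archetype()].
#'
#' @return list of three `phenotype_archetype` objects.
#' @export
default_archetypes <- function() {
  list(
    phenotype_archetype(
      name = "unmatched_vq",
      dead_space_level = 0.35,
      shunt_level = 0.35,
      vq_dispersion = 0.25,
      ventilation_heterogeneity = 0.25,
      drive_profile = drive_df(p01 = c(3.5, 2.2, 1.6),
                               dpes = c(13.0, 9.0, 7.5),
                               dplung = c(16.0, 12.0, 10.0)),
      peepeit_mean = 14,
      los_mean = 18
    ),
    phenotype_archetype(
      name = "mismatched_vq",
      dead_space_level = 0.08,
      shunt_level = 0.08,
      vq_dispersion = 1.0,
      ventilation_heterogeneity = 0.30,
      drive_profile = drive_df(p01 = c(2.4, 2.0, 1.7),
                               dpes = c(10.5, 8.5, 7.5),
                               dplung = c(14.0, 11.5, 10.0)),
      peepeit_mean = 10,
      los_mean = 12
    ),
    phenotype_archetype(
      name = "inhomogeneous_ventilation",
      dead_space_level = 0.04,
      shunt_level = 0.04,
      vq_dispersion = 0.15,
      ventilation_heterogeneity = 1.0,
      drive_profile = drive_df(p01 = c(1.4, 1.7, 1.7),
                               dpes = c(6.5, 7.5, 7.5),
                               dplung = c(10.0, 10.5, 13.0)),
      peepeit_mean = 10,
      los_mean = 9
    )
  )
}

#' @export
print.phenotype_archetype <- function(x, ...) {
  cat("<phenotype_archetype>", x$name, "\n",
      sprintf("  dead space %.2f | shunt %.2f | V'/Q dispersion %.2f | vent. heterogeneity %.2f\n",
              x$dead_space_level, x$shunt_level, x$vq_dispersion,
              x$ventilation_heterogeneity),
      sprintf("  PEEPeit %.1f cmH2O | ICU LOS %.0f d\n",
              x$peepeit_mean, x$los_mean))
  invisible(x)
}
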