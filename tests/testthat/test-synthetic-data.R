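test_that("cohort_config rejects physically unseparable settings", {
  expect_error(cohort_config(resp_rate = 30, cardiac_rate = 60),
               "bands overlap")
  expect_error(cohort_config(step_duration = 5), "10 s|cardiac periods")
  expect_error(cohort_config(fs = 2), "twice the cardiac frequency")
  expect_error(cohort_config(mixture = c(0.5, 0.4)), "sum to 1")
  expect_error(cohort_config(n_patients = 0), "positive integer")
})

test_that("mixture rounding is deterministic largest-remainder (15/9/6 at n = 30)", {
  cohort <- quiet(generate_cohort(cohort_config(
    n_patients = 30, grid = c(8, 8), peep_steps = c(6, 4),
    step_duration = 16)))
  expect_equal(unname(table(cohort$truth$archetype)[
    c("unmatched_vq", "mismatched_vq", "inhomogeneous_ventilation")]),
    c(15, 9, 6), ignore_attr = TRUE)
})

test_that("recordings are reproducible from the seed and differ across seeds", {
  cfg <- tiny_config()
  arch <- default_archetypes()[[1]]
  r1 <- generate_recording(arch, 4, cfg, seed = 5L)
  r2 <- generate_recording(arch, 4, cfg, seed = 5L)
  r3 <- generate_recording(arch, 4, cfg, seed = 6L)
  expect_identical(r1$impedance, r2$impedance)
  expect_false(identical(r1$impedance, r3$impedance))
})

test_that("recording geometry and signal structure match the configuration", {
  cfg <- tiny_config(noise_sd = 0)
  rec <- generate_recording(default_archetypes()[[2]], 6, cfg, seed = 3L)
  expect_s3_class(rec, "eit_recording")
  expect_equal(dim(rec$impedance),
               c(prod(cfg$grid), cfg$step_duration * cfg$fs))
  # without noise, off-mask pixels carry no signal at all
  off <- rec$impedance[!as.vector(rec$mask), ]
  expect_equal(max(abs(off)), 0)
  # on-mask end-expiratory level sits at the configured baseline
  tpl <- attr(rec, "templates")
  on <- rec$impedance[as.vector(rec$mask), 1]
  expect_equal(min(on), cfg$baseline, tolerance = 0.3)
  expect_equal(dim(tpl$v), cfg$grid)
})

test_that("recording generation validates the requested PEEP", {
  expect_error(
    generate_recording(default_archetypes()[[1]], 5, tiny_config()),
    "not one of the configured trial steps")
})

test_that("patient lungs persist across PEEP steps while severity responds to PEEP", {
  cohort <- quiet(generate_cohort(tiny_config(noise_sd = 0)))
  recs <- cohort$patients[[1]]$recordings
  v_hi <- attr(recs[["10"]], "templates")$v
  v_lo <- attr(recs[["4"]], "templates")$v
  # same lung (strongly correlated templates), stronger derangement at low PEEP
  expect_gt(cor(as.vector(v_hi), as.vector(v_lo)), 0.5)
  expect_equal(default_peep_response(4), 1)
  expect_equal(default_peep_response(18), 0.3)
  expect_true(all(diff(default_peep_response(seq(4, 18, 2))) < 0))
})

test_that("validation table encodes the low-PEEP drive ordering of the archetypes", {
  arcs <- default_archetypes()
  low <- vapply(arcs, function(a) {
    a$drive_profile$p01_mean[a$drive_profile$level == "low"]
  }, numeric(1))
  names(low) <- vapply(arcs, `[[`, "", "name")
  expect_true(low["unmatched_vq"] > low["mismatched_vq"] &&
                low["mismatched_vq"] > low["inhomogeneous_ventilation"])

  cohort <- quiet(generate_cohort(tiny_config()))
  expect_equal(nrow(cohort$validation), 3)
  expect_true(all(c("p01_low", "dpes_intermediate", "dplung_high",
                    "peepeit", "icu_los") %in% names(cohort$validation)))
  expect_true(all(cohort$validation$icu_los >= 1))
})

test_that("truth labels are stored apart from the recordings", {
  cohort <- quiet(generate_cohort(tiny_config()))
  expect_named(cohort$patients[[1]], c("patient_id", "recordings"))
  expect_s3_class(cohort$truth, "data.frame")
  expect_setequal(names(cohort$truth), c("patient_id", "archetype"))
})

test_that("write_cohort produces a complete plain-text artifact set", {
  cohort <- quiet(generate_cohort(tiny_config()))
  dir <- file.path(tempdir(), "cohort_out")
  manifest_path <- write_cohort(cohort, dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  expect_equal(manifest$seed, 7)
  expect_length(manifest$recordings, 3 * 4)
  expect_true(all(file.exists(file.path(dir, manifest$recordings))))
  expect_true(file.exists(file.path(dir, manifest$validation)))
  expect_true(file.exists(file.path(dir, manifest$truth)))
  back <- as.matrix(utils::read.csv(file.path(dir, manifest$recordings[1])))
  rec <- cohort$patients[[1]]$recordings[[1]]
  expect_equal(unname(back), unname(rec$impedance), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
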