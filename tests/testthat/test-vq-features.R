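test_that("vq_thresholds validates its bounds", {
  expect_error(vq_thresholds(ventilated_cutoff = 1))
  expect_error(vq_thresholds(high_ratio = 0.4, low_ratio = 0.5))
  th <- vq_thresholds()
  expect_equal(th$high_ratio, 2)
  expect_equal(th$low_ratio, 0.5)
})

test_that("unit classification matches the definitions on a constructed lung", {
  mask <- matrix(TRUE, 4, 4)
  v <- matrix(0, 4, 4)
  q <- matrix(0, 4, 4)
  v[1, 1] <- 1; q[1, 1] <- 0          # ventilated only -> dead space
  v[2, 1] <- 0; q[2, 1] <- 1          # perfused only -> shunt
  v[3, 1] <- 1; q[3, 1] <- 1          # matched, ratio ~ 1 -> normal
  v[4, 1] <- 1; q[4, 1] <- 0.15       # matched, high ratio
  v[1, 2] <- 0.15; q[1, 2] <- 1       # matched, low ratio
  vq <- fake_vq(v, q, mask)
  expect_equal(vq$unit_class[1, 1], "dead_space")
  expect_equal(vq$unit_class[2, 1], "shunt")
  expect_equal(vq$unit_class[3, 1], "normal")
  expect_equal(vq$unit_class[4, 1], "high_vq")
  expect_equal(vq$unit_class[1, 2], "low_vq")
  expect_equal(vq$unit_class[4, 4], "background")
  # ratio is defined exactly on matched pixels
  expect_true(all(is.finite(vq$ratio[vq$unit_class %in%
                                       c("high_vq", "low_vq", "normal")])))
  expect_true(all(is.na(vq$ratio[vq$unit_class %in%
                                   c("dead_space", "shunt", "background")])))
})

test_that("all-left ventilation vs all-right perfusion gives total mismatch", {
  mask <- lung_mask(8, 8)
  v <- matrix(0, 8, 8); v[, 1:4] <- 1; v[!mask] <- 0
  q <- matrix(0, 8, 8); q[, 5:8] <- 1; q[!mask] <- 0
  vq <- quiet(fake_vq(v, q, mask))
  expect_equal(quiet(compute_feature("dead_space_fraction", vq)), 1)
  expect_equal(quiet(compute_feature("wasted_perfusion", vq)), 1)
  expect_equal(quiet(compute_feature("ventilation_to_matched", vq)), 0)
})

test_that("empty functional lung is an error", {
  mask <- lung_mask(8, 8)
  z <- matrix(0, 8, 8)
  expect_error(fake_vq(z, z, mask), "empty functional lung")
})

test_that("ventilation and perfusion allocations each sum to one", {
  cfg <- tiny_config()
  rec <- generate_recording(default_archetypes()[[1]], 4, cfg, seed = 21L)
  vq <- vq_maps(component_maps(rec))
  v_parts <- vapply(c("dead_space_fraction", "ventilation_to_high_vq",
                      "ventilation_to_low_vq", "ventilation_to_normal_vq"),
                    compute_feature, numeric(1), vq = vq)
  q_parts <- vapply(c("wasted_perfusion", "perfusion_to_high_vq",
                      "perfusion_to_low_vq", "perfusion_to_normal_vq"),
                    compute_feature, numeric(1), vq = vq)
  expect_equal(sum(v_parts), 1, tolerance = 1e-10)
  expect_equal(sum(q_parts), 1, tolerance = 1e-10)
  # and v_to_matched is the complement of dead space
  expect_equal(compute_feature("ventilation_to_matched", vq),
               1 - v_parts[["dead_space_fraction"]], tolerance = 1e-10)
})

test_that("roi_partition yields four contiguous ventral-to-dorsal layers", {
  roi <- roi_partition(16)
  expect_equal(unname(table(roi)), rep(4L, 4), ignore_attr = TRUE)
  expect_true(all(diff(roi) >= 0))
  expect_equal(roi_partition(6), c(1L, 2L, 2L, 3L, 4L, 4L))
  expect_error(roi_partition(3))
})

test_that("computed features agree with direct pixel-level recomputation", {
  cfg <- tiny_config()
  rec <- generate_recording(default_archetypes()[[2]], 6, cfg, seed = 13L)
  vq <- vq_maps(component_maps(rec))
  mask <- vq$mask
  cls <- vq$unit_class
  matched <- cls %in% c("high_vq", "low_vq", "normal")
  dim(matched) <- dim(cls)
  vent_tot <- sum(vq$v_frac[cls == "dead_space" | matched])

  # dead_space_fraction straight from its definition
  expect_equal(compute_feature("dead_space_fraction", vq),
               sum(vq$v_frac[cls == "dead_space"]) / vent_tot)

  # area_matched at roi2: matched pixels / lung pixels within the layer
  roi2 <- mask & matrix(roi_partition(nrow(mask)) == 2,
                        nrow(mask), ncol(mask))
  expect_equal(compute_feature("area_matched_roi2", vq),
               sum(matched & roi2) / sum(roi2))

  # v_roi_fraction_roi3: ventilation fraction carried by the third layer
  roi3 <- mask & matrix(roi_partition(nrow(mask)) == 3,
                        nrow(mask), ncol(mask))
  expect_equal(compute_feature("v_roi_fraction_roi3", vq),
               sum(vq$v_frac[roi3]))

  # sd of log10 V'/Q ratio over matched pixels
  expect_equal(compute_feature("sd_log10_vq_ratio", vq),
               sd(log10(vq$ratio[matched])))

  # dorsal fraction of perfusion: rows in ROI 3-4
  dorsal <- matrix(roi_partition(nrow(mask)) >= 3, nrow(mask), ncol(mask))
  expect_equal(compute_feature("q_dorsal_fraction", vq),
               sum(vq$q_frac[mask & dorsal]))
})

test_that("extract_features returns the full named 180-vector", {
  cfg <- tiny_config()
  rec <- generate_recording(default_archetypes()[[3]], 4, cfg, seed = 17L)
  fv <- extract_features(component_maps(rec))
  reg <- default_feature_registry()
  expect_length(fv, 180)
  expect_identical(names(fv), reg$name)
  expect_false(anyNA(fv))
  expect_equal(attr(fv, "peep"), 4)
})

test_that("cohort feature tables carry one row per patient and step", {
  cohort <- quiet(generate_cohort(tiny_config()))
  tabs <- quiet(cohort_feature_tables(cohort, peep_subset = c(6, 4)))
  expect_named(tabs, c("6", "4"))
  expect_equal(nrow(tabs[["4"]]), 3)
  expect_equal(ncol(tabs[["4"]]), 182)  # patient_id, peep, 180 features
  # round trip through CSV
  p <- tempfile(fileext = ".csv")
  write_feature_table(tabs[["4"]], p)
  back <- read_feature_table(p)
  expect_equal(back$dead_space_fraction, tabs[["4"]]$dead_space_fraction,
               tolerance = 1e-12)
  unlink(p)
})

test_that("registry round-trips through JSON", {
  reg <- default_feature_registry()
  p <- tempfile(fileext = ".json")
  write_registry(reg, p)
  back <- read_registry(p)
  expect_equal(back$name, reg$name)
  expect_equal(back$ratio_scaled, reg$ratio_scaled)
  unlink(p)
})
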