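test_that("scenario validation enforces fraction and sign constraints", {
  expect_error(synthetic_scenario(frac_shared = 1.2), "outside")
  expect_error(synthetic_scenario(frac_shared = -0.1), "outside")
  expect_error(
    synthetic_scenario(frac_shared = 0.5, frac_culture_only = 0.5,
                       frac_material_only = 0.5),
    "must not exceed 1"
  )
  expect_error(synthetic_scenario(voc_yield_slope = -1), "non-negative")
  expect_error(synthetic_scenario(ramp_duration_s = 0), "positive")
  layout <- default_sample_layout()
  layout$bacteria_truth[1] <- -5
  expect_error(synthetic_scenario(samples = layout), "non-negative")
})

test_that("chamber series has the requested grid and honours null sources", {
  sc <- synthetic_scenario(seed = 2)
  run <- gen_chamber_series(sc, "KC.1", duration_s = 900, hz = 1)
  counts <- dplyr::count(run$series, ion_label)
  expect_true(all(counts$n == 900))
  expect_equal(min(run$series$time_s), 0)

  # a blank with zero noise and zero offset is exactly flat at zero
  sc0 <- synthetic_scenario(seed = 2, noise_sd_fraction = 0,
                            blank_offset_ppb = 0)
  blank <- gen_chamber_series(sc0, "BLC.1.S1")
  expect_true(all(blank$series$conc_ppb == 0))
})

test_that("post-ramp mean sits near the steady level implied by the flux", {
  # choose biomass so one sampler's total flux gives a 10-ppb steady level
  # on the leading ion: solve for copies from the flux chain
  sc <- synthetic_scenario(seed = 5, noise_sd_fraction = 0.05,
                           blank_offset_ppb = 0)
  row <- sc$samples[sc$samples$sample_id == "KC.1", ]
  total_flux <- sc$voc_yield_slope *
    sum(row$bacteria_truth, row$fungi_truth, na.rm = TRUE) * 1e4 +
    sc$voc_background
  lead_flux <- total_flux * sc$ion_profile[1]
  ss_ugm3 <- lead_flux * 0.0025 / (0.25 * 0.06)
  ss_ppb <- ugm3_to_ppb(ss_ugm3, sc$ion_panel$neutral_mw[1])
  run <- gen_chamber_series(sc, "KC.1")
  lead <- dplyr::filter(run$series,
                        ion_label == sc$ion_panel$ion_label[1],
                        time_s >= 300)
  sd_expected <- 0.05 * ss_ppb
  expect_lt(abs(mean(lead$conc_ppb) - ss_ppb), 3 * sd_expected)
})

test_that("chamber generation is deterministic and rejects bad inputs", {
  sc <- synthetic_scenario(seed = 9)
  r1 <- gen_chamber_series(sc, "BT.1")
  r2 <- gen_chamber_series(sc, "BT.1")
  expect_identical(r1$series, r2$series)
  expect_error(gen_chamber_series(sc, "BT.1", duration_s = -1), "duration_s")
  expect_error(gen_chamber_series(sc, "BT.1", hz = 0), "hz")
  expect_error(gen_chamber_series(sc, "BT.1", flow_lpm = 0), "flow_lpm")
  expect_error(gen_chamber_series(sc, "nope"), "not found")
})

test_that("biomass table reproduces truth exactly at zero noise", {
  layout <- tibble::tibble(
    sample_id = paste0("S", 1:4),
    surface_type = "kitchen_coupon", location = "kitchen_front",
    period = "S1",
    bacteria_truth = c(1e6, 2e6, 5e5, 2.5e5),
    fungi_truth = c(1e6, 2e6, 5e5, 2.5e5) / 25
  )
  sc <- synthetic_scenario(seed = 3, samples = layout, noise_sd_fraction = 0)
  tbl <- gen_biomass_table(sc, layout = layout)
  expect_equal(tbl$bacteria_mean / tbl$fungi_mean, rep(25, 4))
  expect_equal(tbl$bacteria_mean, layout$bacteria_truth)
  expect_true(all(tbl$bacteria_sd == 0))
})

test_that("default biomass layout mirrors the household study structure", {
  sc <- synthetic_scenario(seed = 21)
  tbl <- gen_biomass_table(sc)
  expect_equal(nrow(tbl), 17)
  kitchen <- dplyr::filter(tbl, surface_type == "kitchen_coupon")
  bathroom <- dplyr::filter(tbl, surface_type == "bathroom_tile")
  expect_gt(mean(kitchen$bacteria_mean), mean(bathroom$bacteria_mean))
  expect_gt(mean(kitchen$bacteria_mean, na.rm = TRUE),
            mean(kitchen$fungi_mean, na.rm = TRUE))
  expect_equal(sum(tbl$fungi_below_detection), 1) # BT.5 fungal truth is BD
  expect_identical(tbl, gen_biomass_table(sc))
  expect_error(gen_biomass_table(sc, layout = tbl[0, ]), "at least one")
})

test_that("spectrum library composition follows the configured fractions", {
  sc <- synthetic_scenario(seed = 4, n_compounds = 100, frac_shared = 0.2,
                           frac_culture_only = 0.5, frac_material_only = 0.3,
                           intensity_jitter = 0)
  sp <- gen_spectra(sc)
  per_compound <- table(sp$compound_id)
  expect_equal(sum(per_compound == 2), 20) # shared compounds in both sources
  expect_equal(sum(sp$source == "culture"), 70)
  expect_equal(sum(sp$source == "material"), 50)

  # zero jitter: the two copies of a shared compound are identical spectra
  shared_id <- names(per_compound)[per_compound == 2][1]
  pair <- dplyr::filter(sp, compound_id == shared_id)
  sim <- modified_cosine(pair[1, ], pair[2, ])
  expect_equal(sim$score, 1, tolerance = 1e-9)
  expect_identical(gen_spectra(sc), sp)
})

test_that("fraction remainder becomes blank-only compounds", {
  sc <- synthetic_scenario(seed = 8, n_compounds = 50, frac_shared = 0.1,
                           frac_culture_only = 0.5, frac_material_only = 0.2)
  sp <- gen_spectra(sc)
  blank_only <- dplyr::filter(sp, source == "blank")
  expect_equal(dplyr::n_distinct(blank_only$compound_id), 10) # 0.2 * 50
})
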