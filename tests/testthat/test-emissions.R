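make_series <- function(conc, ion = "C4H8H+", hz = 1) {
  tibble::tibble(
    time_s = seq(0, by = 1 / hz, length.out = length(conc)),
    ion_label = ion, conc_ppb = conc
  )
}

test_that("steady-state mean rejects the transient and averages the rest", {
  # constant series: mean is the constant for any cutoff
  s <- make_series(rep(3.2, 900))
  expect_equal(steady_state_mean(s)$mean_ppb, 3.2)
  expect_equal(steady_state_mean(s, reject_initial_s = 10)$mean_ppb, 3.2)
  expect_equal(steady_state_mean(s)$n_points, 600L)

  # ramp + plateau: equals a hand-computed mean of the retained points
  conc <- c(seq(0, 10, length.out = 300), rep(10, 600)) +
    sin(seq_len(900)) * 0.5
  s2 <- make_series(conc)
  kept <- conc[seq_len(900) - 1 >= 300] # time starts at 0
  manual <- sum(kept) / length(kept)
  expect_equal(steady_state_mean(s2)$mean_ppb, manual)

  # prepending transient points before the cutoff does not change the mean
  early <- make_series(c(rep(99, 100), conc))
  early$time_s <- seq(-100, by = 1, length.out = nrow(early))
  expect_equal(steady_state_mean(early)$mean_ppb, manual)

  expect_error(steady_state_mean(make_series(rep(1, 100))), "no points")
})

test_that("abundance filter removes rare and excluded ions", {
  means <- tibble::tibble(
    ion_label = paste0("ion", 1:10),
    mean_ppb = c(0.0005, 0.0007, 0.0009, seq(0.002, 0.05, length.out = 7))
  )
  kept <- abundance_filter(means, threshold_ppt = 1)
  expect_equal(nrow(kept), 7)
  expect_equal(attr(kept, "removed_ions"), paste0("ion", 1:3))

  expect_identical(abundance_filter(means, threshold_ppt = 0)$ion_label,
                   means$ion_label)
  kept2 <- abundance_filter(means, threshold_ppt = 0, exclude = "ion10")
  expect_false("ion10" %in% kept2$ion_label)
  expect_error(abundance_filter(means, threshold_ppt = -1), "non-negative")
})

test_that("blank subtraction floors negatives and keeps the raw value", {
  sample <- tibble::tibble(ion_label = c("a", "b", "c"),
                           mean_ppb = c(10, 2, 1))
  blanks <- list(
    tibble::tibble(ion_label = c("a", "b", "c"), mean_ppb = c(2, 2, 2)),
    tibble::tibble(ion_label = c("a", "b", "c"), mean_ppb = c(2, 2, 2))
  )
  net <- blank_subtract(sample, blanks)
  expect_equal(net$net_conc_ppb, c(8, 0, 0))
  expect_equal(net$net_raw_ppb, c(8, 0, -1))
  expect_equal(net$floored, c(FALSE, FALSE, TRUE))

  # subtracting a zero blank is the identity; flooring never grows |net|
  zero <- tibble::tibble(ion_label = c("a", "b", "c"), mean_ppb = 0)
  net0 <- blank_subtract(sample, zero)
  expect_equal(net0$net_conc_ppb, sample$mean_ppb)
  expect_true(all(abs(net$net_conc_ppb) <= abs(net$net_raw_ppb) + 1e-15))
})

test_that("ppb to mass-concentration conversion is exact and invertible", {
  expect_equal(ppb_to_ugm3(0, 60), 0)
  expect_equal(ppb_to_ugm3(10, 60), 10 * 60 / 24.45)
  expect_equal(round(ppb_to_ugm3(10, 60), 2), 24.54)
  x <- c(0.1, 1, 17.3)
  expect_equal(ugm3_to_ppb(ppb_to_ugm3(x, 56.0626), 56.0626), x,
               tolerance = 1e-12)
  expect_error(ppb_to_ugm3(1, -5), "positive")
})

test_that("emission rate follows the concentration-times-flow chain", {
  panel <- ion_panel("C3H8O", neutral_mw = 60, protonated_mass = 61.00728)
  net <- tibble::tibble(ion_label = "C3H8OH+", net_conc_ppb = 10)
  est <- emission_rate(net, ion_panel = panel, sampler_area_m2 = 0.0025,
                       flow_lpm = 0.25)
  # 10 ppb x 60 g/mol / 24.45 = 24.54 ug/m3; x 0.015 m3/h = 0.368 ug/h;
  # / 0.0025 m2 = 147 ug/m2/h
  expect_equal(est$emission_ug_h, 10 * 60 / 24.45 * 0.015)
  expect_equal(round(est$emission_ug_h, 3), 0.368)
  expect_equal(round(est$flux_ug_m2_h), 147)
  expect_equal(est$rel_uncertainty, 0.30)

  est0 <- emission_rate(mutate(net, net_conc_ppb = 0), ion_panel = panel,
                        sampler_area_m2 = 0.0025, flow_lpm = 0.25)
  expect_equal(est0$flux_ug_m2_h, 0)
  expect_error(emission_rate(net, ion_panel = panel, sampler_area_m2 = 0,
                             flow_lpm = 0.25), "sampler_area")
  expect_error(
    emission_rate(tibble::tibble(ion_label = "X+", net_conc_ppb = 1),
                  ion_panel = panel, sampler_area_m2 = 1, flow_lpm = 1),
    "not in panel"
  )
})

test_that("sum of VOCs adds the selected subset and flags its share", {
  est <- tibble::tibble(
    ion_label = c("a", "b", "c"),
    flux_ug_m2_h = c(100, 200, 300)
  )
  expect_equal(sum_voc(est, ions = "c")$sumvoc_flux_ug_m2_h, 300)
  s <- sum_voc(est, ions = c("a", "b", "c"))
  expect_equal(s$sumvoc_flux_ug_m2_h, 600)
  expect_equal(s$rel_uncertainty, 0.15)
  expect_error(sum_voc(est, ions = "zz"), "unknown ion")

  # panel built so the top 19 of 25 ions carry >= 95% of the total
  est2 <- tibble::tibble(
    ion_label = sprintf("i%02d", 1:25),
    flux_ug_m2_h = c(rep(100, 19), rep(1, 6))
  )
  s2 <- sum_voc(est2, n_top = 19)
  expect_equal(s2$n_ions, 19L)
  expect_gte(s2$share_of_total, 0.95)
})

test_that("noise-free synthetic chambers return the generating flux", {
  sc <- noise_free_scenario()
  for (id in c("KC.2", "BT.1")) {
    run <- gen_chamber_series(sc, id)
    m <- steady_state_mean(run)
    zero_blank <- tibble::tibble(ion_label = m$ion_label, mean_ppb = 0)
    est <- emission_rate(blank_subtract(m, zero_blank), run,
                         ion_panel = sc$ion_panel)
    row <- sc$samples[sc$samples$sample_id == id, ]
    truth_total <- sc$voc_yield_slope *
      sum(row$bacteria_truth, row$fungi_truth, na.rm = TRUE) * 1e4 +
      sc$voc_background
    truth <- tibble::tibble(ion_label = sc$ion_panel$ion_label,
                            flux = truth_total * sc$ion_profile)
    joined <- dplyr::left_join(est, truth, by = "ion_label")
    expect_lt(max(abs(joined$flux_ug_m2_h - joined$flux) / joined$flux), 1e-6)
  }
})
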