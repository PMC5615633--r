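# deterministic per-output seed derived from the scenario seed and a key,
# kept below 2^31 so it is a valid R integer seed
run_seed <- function(seed, key, salt = 0) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 31 + salt) %% 2147483629) + 1L
}

#' Default sampler layout for synthetic studies
#'
#' Seventeen deployed samplers (kitchen coupons and bathroom tiles across
#' two seasonal periods, with the bundled qPCR densities as biomass truth)
#' plus, per period, two blank coupons, two blank tiles, and an empty-jar
#' blank. Blank samplers carry zero biomass; their chamber series contain
#' only the configured background offset.
#'
#' @return A tibble with columns `sample_id`, `surface_type`, `location`,
#'   `period`, `bacteria_truth`, `fungi_truth` (NA marks a fungal density
#'   below the assay detection limit).
#' @export
default_sample_layout <- function() {
  hh <- household_qpcr()
  deployed <- tibble(
    sample_id = hh$sample_id,
    surface_type = hh$surface_type,
    location = hh$location,
    period = hh$period,
    bacteria_truth = hh$bacteria_mean,
    fungi_truth = ifelse(hh$fungi_below_detection, NA_real_, hh$fungi_mean)
  )
  blanks <- tidyr::expand_grid(
    period = c("S1", "S2"),
    tibble(
      surface_type = c("blank_coupon", "blank_coupon",
                       "blank_tile", "blank_tile", "jar_blank"),
      idx = c(1L, 2L, 1L, 2L, 1L)
    )
  ) |>
    mutate(
      sample_id = paste0(
        c(blank_coupon = "BLC", blank_tile = "BLT",
          jar_blank = "JAR")[.data$surface_type],
        ".", .data$idx, ".", .data$period
      ),
      location = "control",
      bacteria_truth = 0, fungi_truth = 0
    ) |>
    select(-"idx") |>
    select(all_of(names(deployed)))
  bind_rows(deployed, blanks)
}

#' Describe a synthetic study scenario
#'
#' A scenario bundles everything the generators need: the ion panel and the
#' per-ion emission profile, the per-sample biomass truth, the true
#' biomass-to-emission yield (slope) and background flux, chamber noise and
#' transient parameters, and the compound-source composition of the
#' synthetic MS/MS library. The same scenario drives all three generators,
#' so downstream recovery of the generating parameters can be checked
#' end to end. Identical seeds give bit-identical outputs.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param ion_panel Ion panel tibble (see [ion_panel()]).
#' @param samples Sampler layout (see [default_sample_layout()]); truth
#'   columns must be non-negative (NA = below detection).
#' @param ion_profile Optional non-negative relative weights (one per panel
#'   ion) distributing a sample's total flux across ions; defaults to a
#'   geometric profile dominated by the leading ions.
#' @param voc_yield_slope True VOC yield, ug per gene copy per hour.
#' @param voc_background True background flux, ug/m2/h.
#' @param noise_sd_fraction Gaussian chamber noise, as a fraction of the
#'   steady-state level (concentrations are truncated at zero); also the
#'   lognormal sdlog of qPCR replicate noise.
#' @param ramp_duration_s Duration of the chamber concentration ramp, s.
#' @param blank_offset_ppb Chamber background offset added to every ion's
#'   series (blanks contain only this offset).
#' @param detection_limit Gene copies/cm2 below which a generated biomass
#'   mean is flagged below detection.
#' @param n_compounds Number of synthetic soluble compounds.
#' @param frac_shared,frac_culture_only,frac_material_only Source-composition
#'   fractions of the compound library; each in `[0, 1]` and summing to at
#'   most 1. Any remainder becomes compounds present only in blanks (removed
#'   by blank filtering downstream).
#' @param blank_contam_fraction Fraction of material-only compounds that
#'   also appear in a blank (and are therefore removed by the blank rule).
#' @param intensity_jitter Lognormal sdlog applied to peak intensities when
#'   a shared compound is emitted into both sources; keep small so
#'   self-similarity stays above the network threshold.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               ion_panel = default_ion_panel(),
                               samples = default_sample_layout(),
                               ion_profile = NULL,
                               voc_yield_slope = 8.4e-8,
                               voc_background = 1300,
                               noise_sd_fraction = 0.05,
                               ramp_duration_s = 300,
                               blank_offset_ppb = 0.2,
                               detection_limit = 50,
                               n_compounds = 200,
                               frac_shared = 0.05,
                               frac_culture_only = 0.75,
                               frac_material_only = 0.20,
                               blank_contam_fraction = 0,
                               intensity_jitter = 0.05) {
  ion_panel <- validate_ion_panel(ion_panel)
  samples <- as_tibble(samples)
  fracs <- c(frac_shared = frac_shared, frac_culture_only = frac_culture_only,
             frac_material_only = frac_material_only)
  if (any(fracs < 0 | fracs > 1)) {
    bad <- names(fracs)[fracs < 0 | fracs > 1]
    abort(paste0("fraction(s) outside [0, 1]: ", paste(bad, collapse = ", ")))
  }
  if (sum(fracs) > 1 + 1e-9) {
    abort("frac_shared + frac_culture_only + frac_material_only must not exceed 1")
  }
  for (field in c("voc_yield_slope", "voc_background", "noise_sd_fraction",
                  "blank_offset_ppb", "detection_limit",
                  "blank_contam_fraction", "intensity_jitter")) {
    if (get(field) < 0) abort(paste0(field, " must be non-negative"))
  }
  if (ramp_duration_s <= 0) abort("ramp_duration_s must be positive")
  if (n_compounds < 1) abort("n_compounds must be at least 1")
  if (any(c(samples$bacteria_truth, samples$fungi_truth) < 0, na.rm = TRUE)) {
    abort("biomass truth values must be non-negative")
  }
  profile <- ion_profile %||% 0.75^(seq_len(nrow(ion_panel)) - 1)
  if (length(profile) != nrow(ion_panel) || any(profile < 0) ||
      sum(profile) == 0) {
    abort("ion_profile must be non-negative weights, one per panel ion")
  }
  structure(
    list(
      seed = as.integer(seed), ion_panel = ion_panel, samples = samples,
      ion_profile = profile / sum(profile),
      voc_yield_slope = voc_yield_slope, voc_background = voc_background,
      noise_sd_fraction = noise_sd_fraction,
      ramp_duration_s = ramp_duration_s,
      blank_offset_ppb = blank_offset_ppb,
      detection_limit = detection_limit,
      n_compounds = as.integer(n_compounds),
      frac_shared = frac_shared, frac_culture_only = frac_culture_only,
      frac_material_only = frac_material_only,
      blank_contam_fraction = blank_contam_fraction,
      intensity_jitter = intensity_jitter
    ),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> seed", x$seed, "\n")
  cat("  ", nrow(x$samples), "samplers,", nrow(x$ion_panel), "ions,",
      x$n_compounds, "soluble compounds\n")
  cat("  yield", format(x$voc_yield_slope), "ug/copy/h, background",
      x$voc_background, "ug/m2/h, noise",
      paste0(100 * x$noise_sd_fraction, "%"), "\n")
  invisible(x)
}

sampler_area_for <- function(surface_type) {
  unname(c(kitchen_coupon = COUPON_AREA_M2, blank_coupon = COUPON_AREA_M2,
           jar_blank = COUPON_AREA_M2,
           bathroom_tile = TILE_AREA_M2, blank_tile = TILE_AREA_M2
  )[surface_type])
}

is_blank_surface <- function(surface_type) {
  surface_type %in% c("blank_coupon", "blank_tile", "jar_blank")
}

#' Generate a flux-chamber concentration time series
#'
#' Simulates what the mass spectrometer records while a sampler sits in a
#' flushed chamber: each ion's concentration rises from zero toward the
#' steady-state level implied by the sample's true emission flux, the
#' sampler area and the chamber flow rate (first-order approach with time
#' constant `ramp_duration_s / 3`, exactly at steady state after the ramp),
#' then fluctuates with Gaussian noise of standard deviation
#' `noise_sd_fraction` times the steady level, truncated at zero. A
#' constant background offset is added to every ion; blank samplers emit
#' nothing beyond that offset. The sample's total flux is
#' `voc_yield_slope x gene copies/m2 + voc_background`, distributed across
#' ions by the scenario's profile.
#'
#' @param scenario A [synthetic_scenario()].
#' @param sample_id A sampler id present in `scenario$samples`.
#' @param duration_s Run duration, s; must be positive and at least twice
#'   the ramp duration.
#' @param hz Scan rate, 1/s; must be positive.
#' @param flow_lpm Chamber flow rate, L/min; must be positive.
#' @return A `chamber_run`: sample metadata plus a tidy series tibble with
#'   columns `time_s`, `ion_label`, `conc_ppb` (`duration_s * hz` points
#'   per ion, starting at t = 0).
#' @export
gen_chamber_series <- function(scenario, sample_id, duration_s = 900,
                               hz = 1, flow_lpm = 0.25) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (duration_s <= 0) abort("duration_s must be positive")
  if (hz <= 0) abort("hz must be positive")
  if (flow_lpm <= 0) abort("flow_lpm must be positive")
  if (duration_s < 2 * scenario$ramp_duration_s) {
    abort("duration_s must be at least twice ramp_duration_s")
  }
  row <- scenario$samples[scenario$samples$sample_id == sample_id, ]
  if (nrow(row) != 1) {
    abort(paste0("sample_id '", sample_id, "' not found in scenario layout"))
  }
  area <- sampler_area_for(row$surface_type)
  copies_cm2 <- sum(c(row$bacteria_truth, row$fungi_truth), na.rm = TRUE)
  total_flux <- if (is_blank_surface(row$surface_type)) 0 else {
    scenario$voc_yield_slope * copies_cm2 * 1e4 + scenario$voc_background
  }
  flux <- total_flux * scenario$ion_profile # ug/m2/h per ion
  flow_m3h <- flow_lpm * 0.06
  ss_ugm3 <- flux * area / flow_m3h
  ss_ppb <- ugm3_to_ppb(ss_ugm3, scenario$ion_panel$neutral_mw) +
    scenario$blank_offset_ppb

  n_pts <- round(duration_s * hz)
  t <- seq(0, by = 1 / hz, length.out = n_pts)
  tau <- scenario$ramp_duration_s / 3
  set.seed(run_seed(scenario$seed, sample_id, salt = round(hz * 7)))
  series <- purrr::map2_dfr(
    scenario$ion_panel$ion_label, ss_ppb,
    function(lab, ss) {
      level <- ifelse(t < scenario$ramp_duration_s,
                      ss * (1 - exp(-t / tau)), ss)
      conc <- level
      if (scenario$noise_sd_fraction > 0 && ss > 0) {
        conc <- pmax(level + rnorm(n_pts, 0, scenario$noise_sd_fraction * ss), 0)
      }
      tibble(time_s = t, ion_label = lab, conc_ppb = conc)
    }
  )
  new_chamber_run(
    sample_id = sample_id, surface_type = row$surface_type,
    period = row$period, sampler_area_m2 = area, flow_lpm = flow_lpm,
    series = series
  )
}

new_chamber_run <- function(sample_id, surface_type, period,
                            sampler_area_m2, flow_lpm, series) {
  structure(
    list(sample_id = sample_id, surface_type = surface_type, period = period,
         sampler_area_m2 = sampler_area_m2, flow_lpm = flow_lpm,
         series = as_tibble(series)),
    class = "chamber_run"
  )
}

#' @export
print.chamber_run <- function(x, ...) {
  cat("<chamber_run>", x$sample_id, paste0("(", x$surface_type, ", ",
      x$period, ")"), "\n")
  cat("  ", dplyr::n_distinct(x$series$ion_label), "ions x",
      dplyr::n_distinct(x$series$time_s), "scans;",
      "area", x$sampler_area_m2, "m2, flow", x$flow_lpm, "L/min\n")
  invisible(x)
}

#' Generate a qPCR biomass table
#'
#' Lognormal replicate draws around each sampler's biomass truth, reported
#' as replicate mean and standard deviation per target. A truth of NA, or a
#' generated mean below the scenario detection limit, is flagged below
#' detection (the flag is explicit; the aggregation policy is applied
#' downstream, never here). With zero noise the table reproduces the truth
#' exactly.
#'
#' @param scenario A [synthetic_scenario()].
#' @param layout Sampler layout rows to generate for; defaults to the
#'   scenario's deployed (non-blank) samplers. Must be non-empty.
#' @param n_replicates Technical qPCR replicates per measurement.
#' @return A wide biomass tibble (`sample_id`, `surface_type`, `location`,
#'   `period`, `bacteria_mean`, `bacteria_sd`, `bacteria_below_detection`,
#'   `fungi_mean`, `fungi_sd`, `fungi_below_detection`).
#' @export
gen_biomass_table <- function(scenario, layout = NULL, n_replicates = 3) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  layout <- layout %||%
    scenario$samples[!is_blank_surface(scenario$samples$surface_type), ]
  if (nrow(layout) == 0) abort("layout must contain at least one sampler")
  set.seed(run_seed(scenario$seed, "biomass"))
  draw <- function(truth) {
    if (is.na(truth)) return(c(NA_real_, NA_real_, TRUE))
    if (scenario$noise_sd_fraction == 0) {
      return(c(truth, 0, truth < scenario$detection_limit))
    }
    reps <- truth * exp(rnorm(n_replicates, 0, scenario$noise_sd_fraction))
    m <- mean(reps)
    c(m, sd(reps), m < scenario$detection_limit)
  }
  bact <- t(vapply(layout$bacteria_truth, draw, numeric(3)))
  fung <- t(vapply(layout$fungi_truth, draw, numeric(3)))
  tibble(
    sample_id = layout$sample_id,
    surface_type = layout$surface_type,
    location = layout$location,
    period = layout$period,
    bacteria_mean = bact[, 1], bacteria_sd = bact[, 2],
    bacteria_below_detection = as.logical(bact[, 3]),
    fungi_mean = fung[, 1], fungi_sd = fung[, 2],
    fungi_below_detection = as.logical(fung[, 3])
  )
}

#' Generate a synthetic MS/MS spectrum library
#'
#' Draws `n_compounds` synthetic compounds, each with a precursor mass and
#' 6-20 fragment peaks, and emits spectra by source category: culture-only
#' and material-only compounds produce one spectrum each; shared compounds
#' produce a culture and a material spectrum whose intensities differ by a
#' small lognormal jitter (zero jitter gives identical copies with modified
#' cosine 1); any fraction remainder produces blank-only compounds, and a
#' configurable fraction of material compounds is additionally planted in a
#' blank so the blank-removal rule has something to remove.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A spectra tibble: `spectrum_id`, `compound_id` (generator
#'   truth), `source` (`culture`/`material`/`blank`), `precursor_mz`, and a
#'   `peaks` list-column of `(mz, intensity)` tibbles sorted by mz.
#' @export
gen_spectra <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_compounds
  n_shared <- round(scenario$frac_shared * n)
  n_culture <- round(scenario$frac_culture_only * n)
  n_material <- round(scenario$frac_material_only * n)
  n_blank <- n - n_shared - n_culture - n_material
  if (n_blank < 0) { # rounding overshoot when fractions sum to 1
    n_culture <- n_culture + n_blank
    n_blank <- 0
  }
  category <- rep(c("shared", "culture", "material", "blank"),
                  times = c(n_shared, n_culture, n_material, n_blank))
  set.seed(run_seed(scenario$seed, "spectra"))
  compounds <- tibble(
    compound_id = sprintf("CPD%04d", seq_len(n)),
    category = category,
    precursor_mz = runif(n, 120, 980)
  )
  make_peaks <- function(precursor) {
    k <- sample(6:20, 1)
    tibble(mz = sort(runif(k, 50, precursor - 1)),
           intensity = runif(k, 0.05, 1))
  }
  compounds$peaks <- purrr::map(compounds$precursor_mz, make_peaks)
  jitter_peaks <- function(p) {
    if (scenario$intensity_jitter == 0) return(p)
    mutate(p, intensity = .data$intensity *
             exp(rnorm(dplyr::n(), 0, scenario$intensity_jitter)))
  }
  emit <- function(row, source) {
    tibble(
      spectrum_id = paste(row$compound_id, source, sep = "."),
      compound_id = row$compound_id, source = source,
      precursor_mz = row$precursor_mz,
      peaks = list(jitter_peaks(row$peaks[[1]]))
    )
  }
  out <- purrr::map_dfr(seq_len(n), function(i) {
    row <- compounds[i, ]
    switch(row$category,
      culture = emit(row, "culture"),
      material = emit(row, "material"),
      blank = emit(row, "blank"),
      shared = bind_rows(emit(row, "culture"), emit(row, "material"))
    )
  })
  n_contam <- ceiling(scenario$blank_contam_fraction * n_material)
  if (n_contam > 0) {
    mat_ids <- compounds$compound_id[compounds$category == "material"]
    contam <- compounds[compounds$compound_id %in% mat_ids[seq_len(n_contam)], ]
    out <- bind_rows(out, purrr::map_dfr(seq_len(nrow(contam)),
                                         function(i) emit(contam[i, ], "blank")))
  }
  out
}
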