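# Per-ion relative uncertainty of PTR-MS concentrations quantified with an
# average proton-transfer rate constant; errors partially cancel in sums.
PER_ION_REL_UNCERTAINTY <- 0.30
SUM_REL_UNCERTAINTY <- 0.15

chamber_series_of <- function(run) {
  if (inherits(run, "chamber_run")) return(run$series)
  req <- c("time_s", "ion_label", "conc_ppb")
  if (is.data.frame(run) && all(req %in% names(run))) return(as_tibble(run))
  abort("run must be a chamber_run or a tibble with time_s, ion_label, conc_ppb")
}

chamber_id_of <- function(run) {
  if (inherits(run, "chamber_run")) return(run$sample_id)
  if (is.data.frame(run) && "sample_id" %in% names(run)) {
    return(paste(unique(run$sample_id), collapse = ","))
  }
  "chamber series"
}

#' Steady-state mean concentration per ion
#'
#' The chamber needs time to flush after a sample is enclosed, so the first
#' part of each run is a transient: points before `reject_initial_s` (5 min
#' by default) are discarded and the remaining, steady-state concentrations
#' are averaged per ion. A 15-min run at 1 Hz retains roughly 600 points.
#'
#' @param run A `chamber_run` or a tidy series tibble.
#' @param reject_initial_s Initial transient to reject, s.
#' @return A tibble with `ion_label`, `mean_ppb`, `n_points`.
#' @export
steady_state_mean <- function(run, reject_initial_s = 300) {
  series <- chamber_series_of(run)
  kept <- dplyr::filter(series, .data$time_s >= reject_initial_s)
  if (nrow(kept) == 0) {
    abort(paste0("no points at or after t = ", reject_initial_s,
                 " s in run '", chamber_id_of(run), "'"))
  }
  if (any(!is.finite(kept$conc_ppb))) {
    abort(paste0("non-finite concentrations in run '", chamber_id_of(run), "'"))
  }
  kept |>
    group_by(.data$ion_label) |>
    summarize(mean_ppb = mean(.data$conc_ppb), n_points = dplyr::n(),
              .groups = "drop")
}

#' Reject rare and unquantifiable ions
#'
#' Applies the abundance filter (1 ppt average by default) that removes
#' ions close to or below the detection limit, plus an explicit exclusion
#' list for internal ions (primary ions, water clusters) and ions that
#' cannot be quantified accurately. Removed labels are attached as the
#' `removed_ions` attribute.
#'
#' @param means A tibble from [steady_state_mean()].
#' @param threshold_ppt Abundance threshold in ppt (1 ppt = 0.001 ppb);
#'   must be non-negative.
#' @param exclude Character vector of ion labels to drop regardless of
#'   abundance.
#' @return The filtered tibble (possibly empty).
#' @export
abundance_filter <- function(means, threshold_ppt = 1, exclude = character()) {
  if (threshold_ppt < 0) abort("threshold_ppt must be non-negative")
  drop <- means$mean_ppb < threshold_ppt / 1000 | means$ion_label %in% exclude
  kept <- means[!drop, , drop = FALSE]
  attr(kept, "removed_ions") <- means$ion_label[drop]
  kept
}

#' Average several blank runs into one blank level per ion
#'
#' @param blank_means A single tibble from [steady_state_mean()] or a list
#'   of them (one per blank replicate).
#' @return A tibble with `ion_label`, `mean_ppb`.
#' @export
average_blanks <- function(blank_means) {
  if (is.data.frame(blank_means)) blank_means <- list(blank_means)
  if (length(blank_means) == 0) abort("no blank runs supplied")
  bind_rows(blank_means) |>
    group_by(.data$ion_label) |>
    summarize(mean_ppb = mean(.data$mean_ppb), .groups = "drop")
}

#' Subtract blank (control) concentrations
#'
#' Net concentration = sample mean minus the averaged blank level for the
#' matching material. The raw difference is retained for QC; the reported
#' net is floored at zero (a surface is treated as a source, not a sink)
#' and floored ions are flagged. Ions absent from the blank contribute a
#' blank level of zero.
#'
#' @param sample_means Tibble from [steady_state_mean()] (after filtering).
#' @param blank_means Averaged blank tibble, or a list of blank-run means
#'   (averaged via [average_blanks()]).
#' @return A tibble: `ion_label`, `mean_conc_ppb`, `blank_conc_ppb`,
#'   `net_raw_ppb`, `net_conc_ppb`, `floored`.
#' @export
blank_subtract <- function(sample_means, blank_means) {
  blanks <- average_blanks(blank_means)
  out <- sample_means |>
    select("ion_label", mean_conc_ppb = "mean_ppb") |>
    left_join(rename(blanks, blank_conc_ppb = "mean_ppb"), by = "ion_label") |>
    mutate(
      blank_conc_ppb = tidyr::replace_na(.data$blank_conc_ppb, 0),
      net_raw_ppb = .data$mean_conc_ppb - .data$blank_conc_ppb,
      net_conc_ppb = pmax(.data$net_raw_ppb, 0),
      floored = .data$net_raw_ppb < 0
    )
  out
}

#' Emission rate and area-normalised flux per ion
#'
#' Converts blank-corrected steady-state concentrations to emission rates:
#' the net mixing ratio becomes a mass concentration via the ion's neutral
#' molecular weight, the emission rate (ug/h) is that concentration times
#' the chamber flow rate, and the flux (ug/m2/h) divides by the sampler
#' area. Per-ion estimates carry a 30% relative uncertainty (average
#' rate-constant convention); sums over ions carry 15% (see [sum_voc()]).
#'
#' @param net Tibble from [blank_subtract()] (or any tibble with
#'   `ion_label` and `net_conc_ppb`).
#' @param run Optional `chamber_run` providing `sampler_area_m2` and
#'   `flow_lpm`.
#' @param ion_panel Ion panel with every label present in `net`.
#' @param sampler_area_m2,flow_lpm Override the run metadata; both must be
#'   positive.
#' @param molar_volume_l Molar volume for the ppb conversion, L/mol.
#' @return The input tibble extended with `conc_ugm3`, `emission_ug_h`,
#'   `flux_ug_m2_h`, `rel_uncertainty`.
#' @export
emission_rate <- function(net, run = NULL, ion_panel = default_ion_panel(),
                          sampler_area_m2 = NULL, flow_lpm = NULL,
                          molar_volume_l = MOLAR_VOLUME_L) {
  sampler_area_m2 <- sampler_area_m2 %||% run$sampler_area_m2
  flow_lpm <- flow_lpm %||% run$flow_lpm
  if (is.null(sampler_area_m2) || sampler_area_m2 <= 0) {
    abort("sampler_area_m2 must be positive")
  }
  if (is.null(flow_lpm) || flow_lpm <= 0) abort("flow_lpm must be positive")
  ion_panel <- validate_ion_panel(ion_panel)
  unknown <- setdiff(net$ion_label, ion_panel$ion_label)
  if (length(unknown) > 0) {
    abort(paste0("ion(s) not in panel: ", paste(unknown, collapse = ", ")))
  }
  flow_m3h <- flow_lpm * 0.06
  net |>
    left_join(select(ion_panel, "ion_label", "neutral_mw"), by = "ion_label") |>
    mutate(
      conc_ugm3 = ppb_to_ugm3(.data$net_conc_ppb, .data$neutral_mw,
                              molar_volume_l),
      emission_ug_h = .data$conc_ugm3 * flow_m3h,
      flux_ug_m2_h = .data$emission_ug_h / sampler_area_m2,
      rel_uncertainty = PER_ION_REL_UNCERTAINTY
    ) |>
    select(-"neutral_mw")
}

#' Sum of VOC fluxes over the most abundant ions
#'
#' The total flux over a selected ion subset, used as an estimate of the
#' sum of all VOCs. By default the 19 most abundant ions by flux are
#' selected (ties broken by ion label); in typical chamber panels these
#' carry over 95% of the observed total. The summed value carries a 15%
#' relative uncertainty because per-ion rate-constant errors partially
#' cancel.
#'
#' @param estimates Tibble from [emission_rate()].
#' @param ions Optional explicit ion subset (labels must exist).
#' @param n_top Number of top ions when `ions` is NULL.
#' @return A one-row tibble: `sumvoc_flux_ug_m2_h`, `n_ions`,
#'   `share_of_total`, `rel_uncertainty`.
#' @export
sum_voc <- function(estimates, ions = NULL, n_top = 19) {
  if (!is.null(ions)) {
    unknown <- setdiff(ions, estimates$ion_label)
    if (length(unknown) > 0) {
      abort(paste0("unknown ion label(s): ", paste(unknown, collapse = ", ")))
    }
    sel <- dplyr::filter(estimates, .data$ion_label %in% ions)
  } else {
    sel <- estimates |>
      arrange(desc(.data$flux_ug_m2_h), .data$ion_label) |>
      head(n_top)
  }
  if (nrow(sel) == 0) abort("ion subset is empty")
  total <- sum(estimates$flux_ug_m2_h)
  tibble(
    sumvoc_flux_ug_m2_h = sum(sel$flux_ug_m2_h),
    n_ions = nrow(sel),
    share_of_total = if (total > 0) sum(sel$flux_ug_m2_h) / total else NA_real_,
    rel_uncertainty = SUM_REL_UNCERTAINTY
  )
}
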