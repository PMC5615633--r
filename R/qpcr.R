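#' Bundled qPCR biomass example data
#'
#' Gene-copy densities (16S for bacteria, ITS for fungi; gene copies/cm2 of
#' surface, already control-subtracted and rounded to the precision at which
#' they were reported) for 17 samplers deployed on two periodically wet
#' household surfaces — stainless-steel kitchen-sink coupons and ceramic
#' shower-stall tiles — over two seasonal sampling periods (S1, S2). One
#' fungal measurement (BT.5) fell below the assay detection limit and is
#' carried as an explicit flag, not a zero or a missing value. The
#' front/side location split of the kitchen coupons is illustrative.
#'
#' @param format `"wide"` (one row per sample) or `"long"` (one row per
#'   sample x target, see [biomass_long()]).
#' @return A tibble of biomass measurements.
#' @examples
#' household_qpcr()
#' aggregate_biomass(household_qpcr("long"))
#' @export
household_qpcr <- function(format = c("wide", "long")) {
  format <- match.arg(format)
  wide <- tibble(
    sample_id = c("KC.1", "KC.2", "KC.3", "KC.4", "BT.1", "BT.2", "BT.3",
                  "KC.5", "KC.6", "KC.7", "KC.8", "KC.9", "KC.10",
                  "BT.4", "BT.5", "BT.6", "BT.7"),
    surface_type = rep(c("kitchen_coupon", "bathroom_tile",
                         "kitchen_coupon", "bathroom_tile"),
                       times = c(4, 3, 6, 4)),
    location = c("kitchen_front", "kitchen_front", "kitchen_side",
                 "kitchen_side", "bathroom", "bathroom", "bathroom",
                 "kitchen_front", "kitchen_front", "kitchen_front",
                 "kitchen_side", "kitchen_side", "kitchen_side",
                 "bathroom", "bathroom", "bathroom", "bathroom"),
    period = rep(c("S1", "S2"), times = c(7, 10)),
    bacteria_mean = c(2300000, 3800000, 229000, 1200000, 36000, 26700, 200,
                      574000, 887000, 2870000, 404000, 4620000, 378000,
                      780, 4900, 7800, 3700),
    bacteria_sd = c(900000, 200000, 65000, 140000, 2000, 200, 6,
                    46000, 25000, 1500000, 5000, 40000, 12000,
                    30, 200, 600, 100),
    bacteria_below_detection = FALSE,
    fungi_mean = c(251000, 122000, 17000, 226000, 8500, 10200, 800,
                   51300, 52200, 60900, 17900, 25700, 19900,
                   100, NA, 500, 2200),
    fungi_sd = c(94000, 5000, 5000, 23000, 4000, 3000, 500,
                 8000, 6000, 9000, 6000, 2000, 8000,
                 80, NA, 100, 22000),
    fungi_below_detection = c(rep(FALSE, 14), TRUE, FALSE, FALSE)
  )
  if (format == "wide") wide else biomass_long(wide)
}

#' Reshape a wide biomass table to one row per sample and target
#'
#' @param measurements A wide biomass tibble with `bacteria_mean`,
#'   `fungi_mean` (and optionally `*_sd`, `*_below_detection`) columns, as
#'   produced by [gen_biomass_table()] or [household_qpcr()]. Long-format
#'   input (already carrying a `target` column) is returned unchanged.
#' @return A tibble with columns `sample_id`, any metadata columns,
#'   `target` (`"bacteria"`/`"fungi"`), `gene_copies_per_cm2`, `sd`,
#'   `below_detection`.
#' @export
biomass_long <- function(measurements) {
  if ("target" %in% names(measurements)) return(as_tibble(measurements))
  for (tg in c("bacteria", "fungi")) {
    for (suffix in c("_sd", "_below_detection")) {
      col <- paste0(tg, suffix)
      if (!col %in% names(measurements)) {
        measurements[[col]] <- if (suffix == "_sd") NA_real_ else FALSE
      }
    }
  }
  long <- tidyr::pivot_longer(
    measurements,
    cols = tidyr::starts_with(c("bacteria", "fungi")),
    names_to = c("target", ".value"),
    names_pattern = "^(bacteria|fungi)_(.*)$"
  )
  long <- dplyr::rename(long, gene_copies_per_cm2 = "mean")
  long$below_detection <- long$below_detection | is.na(long$gene_copies_per_cm2)
  long
}

#' Subtract the qPCR negative-control signal
#'
#' Negative extraction/reagent controls carry a small bacterial background
#' (typically 1500-3000 gene copies; fungi are usually undetected in
#' controls). The control estimate is subtracted from each raw sample
#' estimate and the result floored at zero; floored values are flagged as
#' near the detection floor.
#'
#' @param measurements Either a numeric vector of raw gene-copy estimates,
#'   or a long-format biomass tibble (see [biomass_long()]).
#' @param control For a numeric vector, a single non-negative control
#'   estimate; for a tibble, a named vector of per-target controls, e.g.
#'   `c(bacteria = 2250, fungi = 0)`.
#' @return The corrected vector, or the tibble with `gene_copies_per_cm2`
#'   replaced by the corrected value plus a `near_detection` flag.
#' @examples
#' subtract_qpcr_control(c(36000, 2000, 2301500), control = c(0, 3000, 1500))
#' @export
subtract_qpcr_control <- function(measurements,
                                  control = c(bacteria = 0, fungi = 0)) {
  if (is.numeric(measurements)) {
    if (any(measurements < 0, na.rm = TRUE)) {
      abort("raw gene-copy estimates must be non-negative")
    }
    if (any(control < 0)) abort("control estimate must be non-negative")
    return(pmax(measurements - control, 0))
  }
  m <- biomass_long(measurements)
  if (any(m$gene_copies_per_cm2 < 0, na.rm = TRUE)) {
    abort("raw gene-copy estimates must be non-negative")
  }
  if (any(control < 0)) abort("control estimate must be non-negative")
  missing_targets <- setdiff(unique(m$target), names(control))
  if (length(missing_targets) > 0) {
    abort(paste0("no control estimate supplied for target(s): ",
                 paste(missing_targets, collapse = ", ")))
  }
  ctrl <- unname(control[m$target])
  raw <- m$gene_copies_per_cm2
  m$gene_copies_per_cm2 <- pmax(raw - ctrl, 0)
  m$near_detection <- !is.na(raw) & raw > 0 & (raw - ctrl) <= 0
  m
}

#' Aggregate biomass measurements into group averages
#'
#' Arithmetic group means of gene-copy densities with an explicit policy for
#' below-detection values: under `bd_policy = "zero"` they contribute zero
#' while still counting in the denominator (the convention that reproduces
#' the printed fungal average for the second-period bathroom tiles); under
#' `"exclude"` they are dropped from the group. Means are reported at full
#' precision alongside a three-significant-figure display value; downstream
#' computation should always use the unrounded column.
#'
#' @param measurements Biomass tibble, wide or long.
#' @param by Grouping columns; default `(surface_type, period, target)`.
#' @param bd_policy `"zero"` or `"exclude"`.
#' @return A tibble with the grouping columns plus `n`,
#'   `n_below_detection`, `mean_copies`, `mean_copies_3sf`.
#' @export
aggregate_biomass <- function(measurements,
                              by = c("surface_type", "period", "target"),
                              bd_policy = "zero") {
  if (!bd_policy %in% c("zero", "exclude")) {
    abort(paste0("unknown below-detection policy: '", bd_policy,
                 "' (use \"zero\" or \"exclude\")"))
  }
  m <- biomass_long(measurements)
  missing_cols <- setdiff(by, names(m))
  if (length(missing_cols) > 0) {
    abort(paste0("grouping column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (bd_policy == "zero") {
    m$value <- ifelse(m$below_detection, 0, m$gene_copies_per_cm2)
  } else {
    m <- dplyr::filter(m, !.data$below_detection)
    m$value <- m$gene_copies_per_cm2
  }
  if (nrow(m) == 0) abort("no measurements left to aggregate")
  m |>
    group_by(across(all_of(by))) |>
    summarize(
      n = dplyr::n(),
      n_below_detection = sum(.data$below_detection),
      mean_copies = mean(.data$value),
      .groups = "drop"
    ) |>
    mutate(mean_copies_3sf = signif(.data$mean_copies, 3))
}

#' Bacteria-to-fungi gene-copy ratio
#'
#' How many more marker-gene copies bacteria carry than fungi on the same
#' sampler. The default statistic is the arithmetic mean of per-sample
#' bacteria/fungi ratios over samples where fungi were detected (a
#' below-detection fungal value gives an undefined per-sample ratio and is
#' excluded). The alternative `"ratio_of_means"` divides the mean bacterial
#' density by the mean fungal density over the same valid pairs.
#'
#' @param measurements Biomass tibble, wide or long.
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return A one-row tibble: `method`, `ratio`, `n_pairs`.
#' @examples
#' bacteria_fungi_ratio(household_qpcr())
#' @export
bacteria_fungi_ratio <- function(measurements,
                                 method = c("mean_of_ratios",
                                            "ratio_of_means")) {
  method <- match.arg(method)
  m <- biomass_long(measurements)
  wide <- m |>
    select(any_of(c("sample_id", "target", "gene_copies_per_cm2",
                    "below_detection"))) |>
    tidyr::pivot_wider(
      names_from = "target",
      values_from = c("gene_copies_per_cm2", "below_detection")
    )
  valid <- wide |>
    dplyr::filter(
      !.data$below_detection_fungi, !.data$below_detection_bacteria,
      .data$gene_copies_per_cm2_fungi > 0
    )
  if (nrow(valid) == 0) abort("no valid bacteria/fungi pairs")
  ratio <- switch(method,
    mean_of_ratios = mean(valid$gene_copies_per_cm2_bacteria /
                            valid$gene_copies_per_cm2_fungi),
    ratio_of_means = mean(valid$gene_copies_per_cm2_bacteria) /
      mean(valid$gene_copies_per_cm2_fungi)
  )
  tibble(method = method, ratio = ratio, n_pairs = nrow(valid))
}
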