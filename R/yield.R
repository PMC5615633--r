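#' Average emission and biomass samples into regression points
#'
#' VOC emissions and qPCR biomass are measured on different physical
#' samplers, so they are linked at the level of location-period groups:
#' samplers in similar locations are averaged within each sampling period,
#' giving one point per group of mean total gene copies per m2 (bacteria +
#' fungi, converted from copies/cm2) against mean summed VOC flux.
#'
#' @param emissions Tibble with one row per sampler carrying the grouping
#'   columns and `sumvoc_flux_ug_m2_h` (see [sum_voc()]).
#' @param biomass Biomass tibble (wide or long); fungal below-detection
#'   values contribute zero to the per-sample total.
#' @param grouping Columns defining the groups, present in both inputs.
#' @return A tibble with the grouping columns, `copies_per_m2`,
#'   `sumvoc_flux_ug_m2_h`, `n_voc_samples`, `n_biomass_samples`.
#' @export
group_points <- function(emissions, biomass,
                         grouping = c("location", "period")) {
  for (nm in grouping) {
    if (!nm %in% names(emissions)) {
      abort(paste0("grouping column '", nm, "' missing from emissions"))
    }
  }
  b <- biomass_long(biomass)
  for (nm in grouping) {
    if (!nm %in% names(b)) {
      abort(paste0("grouping column '", nm, "' missing from biomass"))
    }
  }
  b_tot <- b |>
    mutate(value = ifelse(.data$below_detection, 0,
                          .data$gene_copies_per_cm2)) |>
    group_by(across(all_of(c("sample_id", grouping)))) |>
    summarize(total_copies_cm2 = sum(.data$value), .groups = "drop")
  b_grp <- b_tot |>
    group_by(across(all_of(grouping))) |>
    summarize(copies_per_m2 = mean(.data$total_copies_cm2) * 1e4,
              n_biomass_samples = dplyr::n(), .groups = "drop")
  e_grp <- emissions |>
    group_by(across(all_of(grouping))) |>
    summarize(sumvoc_flux_ug_m2_h = mean(.data$sumvoc_flux_ug_m2_h),
              n_voc_samples = dplyr::n(), .groups = "drop")
  joined <- full_join(e_grp, b_grp, by = grouping)
  orphan <- is.na(joined$sumvoc_flux_ug_m2_h) | is.na(joined$copies_per_m2)
  if (any(orphan)) {
    keys <- joined[orphan, grouping, drop = FALSE]
    abort(paste0("group(s) present in only one input: ",
                 paste(apply(keys, 1, paste, collapse = "/"),
                       collapse = ", ")))
  }
  select(joined, all_of(grouping), "copies_per_m2", "sumvoc_flux_ug_m2_h",
         "n_voc_samples", "n_biomass_samples")
}

#' Fit the biomass-to-emission yield regression
#'
#' Ordinary least squares of summed VOC flux (ug/m2/h) on total gene copies
#' per m2. The slope is the VOC production rate per gene copy (also
#' reported in fg/gene copy/h, 1 ug = 1e9 fg); the intercept is the
#' background flux from non-microbial sources. Periods should be fitted
#' separately, never pooled.
#'
#' @param points Tibble from [group_points()] (needs `copies_per_m2` and
#'   `sumvoc_flux_ug_m2_h`); at least two points with distinct abscissae.
#' @param period Optional period label to filter `points` by before
#'   fitting.
#' @return A `voc_yield_fit` with components `model` (the underlying lm),
#'   `slope`, `intercept`, `slope_fg`, `r_squared`, `n`, `period`,
#'   `points`. Supports [tidy()], [glance()], `confint()` via `$model`,
#'   and `autoplot()`.
#' @examples
#' pts <- tibble::tibble(copies_per_m2 = c(0, 1e10),
#'                       sumvoc_flux_ug_m2_h = c(630, 840))
#' fit_yield(pts) # slope 2.1e-8 ug/copy/h, intercept 630
#' @export
fit_yield <- function(points, period = NULL) {
  if (!is.null(period) && "period" %in% names(points)) {
    points <- dplyr::filter(points, .data$period == !!period)
  }
  if (nrow(points) < 2) abort("need at least 2 points to fit")
  if (dplyr::n_distinct(points$copies_per_m2) < 2) {
    abort("degenerate abscissae: points need at least 2 distinct gene-copy values")
  }
  m <- lm(sumvoc_flux_ug_m2_h ~ copies_per_m2, data = points)
  s <- suppressWarnings(summary(m)) # n = 2 reconstructions fit exactly
  structure(
    list(
      model = m,
      slope = unname(coef(m)[2]),
      intercept = unname(coef(m)[1]),
      slope_fg = unname(coef(m)[2]) * 1e9,
      r_squared = s$r.squared,
      n = nrow(points),
      period = period %||%
        (if ("period" %in% names(points)) {
          paste(unique(points$period), collapse = "+")
        } else NA_character_),
      points = as_tibble(points)
    ),
    class = "voc_yield_fit"
  )
}

#' @export
print.voc_yield_fit <- function(x, ...) {
  cat("<voc_yield_fit>",
      if (!is.na(x$period)) paste0("period ", x$period) else "", "\n")
  cat(sprintf("  sumVOC (ug/m2/h) = %.3g (ug/gene copy/h) x gene copies/m2 + %.3g\n",
              x$slope, x$intercept))
  cat(sprintf("  yield %.3g fg/gene copy/h, R2 = %.3f, n = %d\n",
              x$slope_fg, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_yield
#' @param x A `voc_yield_fit`.
#' @param ... Unused.
#' @export
tidy.voc_yield_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = c("intercept_ug_m2_h", "slope_ug_per_copy_h"),
    estimate = unname(co[, 1]), std.error = unname(co[, 2]),
    statistic = unname(co[, 3]), p.value = unname(co[, 4])
  )
}

#' @rdname fit_yield
#' @export
glance.voc_yield_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, nobs = x$n,
    slope_fg_per_copy_h = x$slope_fg, intercept_ug_m2_h = x$intercept
  )
}

#' @rdname fit_yield
#' @param object A `voc_yield_fit`.
#' @export
autoplot.voc_yield_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$copies_per_m2,
                               .data$sumvoc_flux_ug_m2_h)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = "gene copies / m2 (bacteria + fungi)",
      y = "sum of VOC flux (ug/m2/h)",
      title = sprintf("VOC yield: %.3g fg/gene copy/h (R2 = %.2f)",
                      object$slope_fg, object$r_squared)
    )
}

#' Range of VOC yields across fitted periods
#'
#' Minimum and maximum slope in fg per gene copy per hour across one or
#' more fits, with a one-significant-figure display string of the form
#' `"~20-80 fg/gene copy/h"`. The underlying values are kept at full
#' precision.
#'
#' @param fits A `voc_yield_fit` or a list of them.
#' @return A one-row tibble: `min_fg`, `max_fg`, `display`.
#' @export
yield_range <- function(fits) {
  if (inherits(fits, "voc_yield_fit")) fits <- list(fits)
  if (length(fits) == 0) abort("need at least one fit")
  slopes <- purrr::map_dbl(fits, "slope_fg")
  tibble(
    min_fg = min(slopes), max_fg = max(slopes),
    display = sprintf("~%g-%g fg/gene copy/h",
                      signif(min(slopes), 1), signif(max(slopes), 1))
  )
}

#' Seeded recovery simulation for the yield regression
#'
#' Repeatedly simulates location-period points at the study's scale —
#' ordinates from the given slope and intercept with multiplicative
#' Gaussian noise — refits the regression, and records whether the
#' two-sided confidence interval covers the true slope. Used to
#' characterise how reliably the yield can be recovered from a handful of
#' averaged points.
#'
#' @param slope,intercept True coefficients (ug/gene copy/h, ug/m2/h).
#' @param copies_per_m2 Abscissae of the simulated points; defaults to the
#'   three location-group means implied by the bundled biomass data for
#'   the first sampling period.
#' @param noise_fraction Gaussian noise sd as a fraction of the ordinate.
#' @param n_reps Number of replicates.
#' @param level Confidence level.
#' @param seed Seed for the simulation stream.
#' @return A tibble with one row per replicate (`slope_hat`, `ci_lo`,
#'   `ci_hi`, `covered`); the `coverage` attribute holds the empirical
#'   coverage fraction.
#' @export
yield_recovery_sim <- function(slope = 8.4e-8, intercept = 1300,
                               copies_per_m2 = c(3.24e10, 8.36e9, 2.75e8),
                               noise_fraction = 0.05, n_reps = 200,
                               level = 0.95, seed = 1) {
  set.seed(run_seed(seed, "yield-recovery"))
  y_true <- slope * copies_per_m2 + intercept
  res <- purrr::map_dfr(seq_len(n_reps), function(i) {
    y <- y_true * (1 + rnorm(length(y_true), 0, noise_fraction))
    fit <- fit_yield(tibble(copies_per_m2 = copies_per_m2,
                            sumvoc_flux_ug_m2_h = y))
    ci <- confint(fit$model, "copies_per_m2", level = level)
    tibble(slope_hat = fit$slope, ci_lo = ci[1], ci_hi = ci[2],
           covered = ci[1] <= slope && slope <= ci[2])
  })
  attr(res, "coverage") <- mean(res$covered)
  res
}
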