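default_config <- function() {
  list(
    seed = 1L,
    scenario = list(
      n_compounds = 80, frac_shared = 0.05, frac_culture_only = 0.75,
      frac_material_only = 0.20, blank_contam_fraction = 0.05,
      noise_sd_fraction = 0.05, ramp_duration_s = 300,
      voc_yield_slope = 8.4e-8, voc_background = 1300,
      blank_offset_ppb = 0.2, intensity_jitter = 0.02,
      detection_limit = 50
    ),
    chamber = list(
      flow_lpm = 0.25, duration_s = 900, hz = 1, reject_initial_s = 300,
      abundance_threshold_ppt = 1, molar_volume_l = MOLAR_VOLUME_L,
      n_top_voc = 19, exclude_ions = character(0)
    ),
    qpcr = list(
      control_bacteria = 0, control_fungi = 0,
      bd_policy = "zero", ratio_method = "mean_of_ratios"
    ),
    regression = list(grouping = c("location", "period")),
    box_model = list(
      a_summer = 1.13, a_winter = 0.61, volume_m3 = 160, n_top_ions = 15
    ),
    network = list(
      precursor_tol = 2, fragment_tol = 0.5, min_cosine = 0.75,
      min_matched = 6, library_min_cosine = 0.70, library_min_peaks = 6
    )
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Starts from the package defaults and merges the supplied overrides.
#' Unknown keys are rejected, and physical parameters are checked for
#' validity (positive flow, durations, air exchange rates, volumes;
#' fractions in range). The configuration round-trips unchanged through
#' [write_config_json()] / [read_config_json()].
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param scenario,chamber,qpcr,regression,box_model,network Named lists
#'   of overrides for the corresponding stage blocks.
#' @return A validated `surfvoc_config` list.
#' @export
pipeline_config <- function(seed = 1, scenario = list(), chamber = list(),
                            qpcr = list(), regression = list(),
                            box_model = list(), network = list()) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  for (block in c("scenario", "chamber", "qpcr", "regression",
                  "box_model", "network")) {
    override <- get(block)
    unknown <- setdiff(names(override), names(cfg[[block]]))
    if (length(unknown) > 0) {
      abort(paste0("unknown key(s) in config block '", block, "': ",
                   paste(unknown, collapse = ", ")))
    }
    cfg[[block]] <- modifyList(cfg[[block]], override)
  }
  validate_config(cfg)
}

validate_config <- function(config) {
  template <- default_config()
  unknown <- setdiff(names(config), names(template))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (block in setdiff(names(template), "seed")) {
    unknown <- setdiff(names(config[[block]]), names(template[[block]]))
    if (length(unknown) > 0) {
      abort(paste0("unknown key(s) in config block '", block, "': ",
                   paste(unknown, collapse = ", ")))
    }
  }
  positive <- list(
    flow_lpm = config$chamber$flow_lpm,
    duration_s = config$chamber$duration_s,
    hz = config$chamber$hz,
    a_summer = config$box_model$a_summer,
    a_winter = config$box_model$a_winter,
    volume_m3 = config$box_model$volume_m3,
    molar_volume_l = config$chamber$molar_volume_l
  )
  for (nm in names(positive)) {
    if (positive[[nm]] <= 0) abort(paste0(nm, " must be positive"))
  }
  if (config$chamber$abundance_threshold_ppt < 0) {
    abort("abundance_threshold_ppt must be non-negative")
  }
  do.call(network_params, config$network) # thresholds must be positive
  structure(config, class = "surfvoc_config")
}

#' @rdname pipeline_config
#' @param config A `surfvoc_config`.
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- modifyList(default_config(), x)
  # empty JSON arrays deserialise as lists; these fields are character
  cfg$chamber$exclude_ions <- as.character(unlist(cfg$chamber$exclude_ions))
  cfg$regression$grouping <- as.character(unlist(cfg$regression$grouping))
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
}

scenario_from_config <- function(config) {
  do.call(synthetic_scenario, c(list(seed = config$seed), config$scenario))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

# choose the averaged blank for a sample's material, falling back to the
# empty-jar blank; errors when neither exists
select_blank <- function(surface_type, period, blank_means) {
  wanted <- switch(surface_type,
    kitchen_coupon = "blank_coupon", bathroom_tile = "blank_tile",
    abort(paste0("no blank policy for surface type '", surface_type, "'"))
  )
  pool <- blank_means[blank_means$surface_type == wanted &
                        blank_means$period == period, ]
  if (nrow(pool) == 0) {
    pool <- blank_means[blank_means$surface_type == "jar_blank" &
                          blank_means$period == period, ]
  }
  if (nrow(pool) == 0) {
    abort(paste0("no blank run available for ", wanted, " in ", period))
  }
  average_blanks(split(pool, pool$sample_id) |>
                   purrr::map(~ select(.x, "ion_label", "mean_ppb")))
}

#' Run the full surface-chemistry pipeline
#'
#' Executes every stage on synthetic or on-disk data: chamber series to
#' blank-corrected emission estimates and summed VOC fluxes; biomass
#' aggregation and the bacteria:fungi ratio; the per-period yield
#' regression; box-model projection of kitchen-sink and shower-stall
#' contributions to indoor air; and the molecular network with its source
#' partition. Writes tabular outputs and a Markdown report when `outdir`
#' is given. A failure in any stage aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if needed).
#' @param input_dir Optional directory of on-disk inputs as written by
#'   [make_demo()] (`chamber/*.tsv`, `biomass.csv`, `spectra.mgf`); when
#'   NULL the scenario generators are used in memory.
#' @return A `surfvoc_results` list: `emissions`, `flux_by_ion`,
#'   `biomass`, `biomass_aggregates`, `ratio`, `points`, `fits`,
#'   `yield_range`, `contributions`, `contribution_totals`, `network`,
#'   `partition`, `report` (character lines).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         input_dir = NULL) {
  config <- validate_config(config)
  scenario <- scenario_from_config(config)
  ch <- config$chamber

  runs <- run_stage("ingest", {
    if (is.null(input_dir)) {
      purrr::map(scenario$samples$sample_id,
                 ~ gen_chamber_series(scenario, .x,
                                      duration_s = ch$duration_s,
                                      hz = ch$hz, flow_lpm = ch$flow_lpm))
    } else {
      files <- sort(list.files(file.path(input_dir, "chamber"),
                               pattern = "\\.tsv$", full.names = TRUE))
      if (length(files) == 0) abort("no chamber TSV files found")
      purrr::map(files, read_chamber_tsv)
    }
  })

  emissions_out <- run_stage("emissions", {
    means <- purrr::map(runs, function(r) {
      steady_state_mean(r, reject_initial_s = ch$reject_initial_s) |>
        mutate(sample_id = r$sample_id, surface_type = r$surface_type,
               period = r$period)
    })
    all_means <- bind_rows(means)
    blank_means <- dplyr::filter(all_means,
                                 is_blank_surface(.data$surface_type))
    run_meta <- purrr::map_dfr(runs, ~ tibble(
      sample_id = .x$sample_id, surface_type = .x$surface_type,
      period = .x$period, sampler_area_m2 = .x$sampler_area_m2,
      flow_lpm = .x$flow_lpm
    ))
    deployed <- dplyr::filter(run_meta,
                              !is_blank_surface(.data$surface_type))
    per_sample <- purrr::map(seq_len(nrow(deployed)), function(i) {
      m <- deployed[i, ]
      sm <- dplyr::filter(all_means, .data$sample_id == m$sample_id) |>
        abundance_filter(threshold_ppt = ch$abundance_threshold_ppt,
                         exclude = ch$exclude_ions)
      blk <- select_blank(m$surface_type, m$period, blank_means)
      est <- blank_subtract(sm, blk) |>
        emission_rate(ion_panel = scenario$ion_panel,
                      sampler_area_m2 = m$sampler_area_m2,
                      flow_lpm = m$flow_lpm,
                      molar_volume_l = ch$molar_volume_l)
      list(meta = m, estimates = est,
           sumvoc = sum_voc(est, n_top = ch$n_top_voc))
    })
    emissions_tbl <- purrr::map_dfr(per_sample, function(x) {
      bind_cols(x$meta, x$sumvoc)
    })
    flux_by_ion <- purrr::map_dfr(per_sample, function(x) {
      mutate(x$estimates, sample_id = x$meta$sample_id,
             surface_type = x$meta$surface_type, period = x$meta$period)
    })
    list(emissions = emissions_tbl, flux_by_ion = flux_by_ion)
  })

  biomass_out <- run_stage("biomass", {
    biomass <- if (is.null(input_dir)) {
      gen_biomass_table(scenario)
    } else {
      read_biomass_csv(file.path(input_dir, "biomass.csv"))
    }
    long <- biomass_long(biomass)
    if (config$qpcr$control_bacteria > 0 || config$qpcr$control_fungi > 0) {
      long <- subtract_qpcr_control(
        long, control = c(bacteria = config$qpcr$control_bacteria,
                          fungi = config$qpcr$control_fungi)
      )
    }
    list(
      biomass = biomass,
      aggregates = aggregate_biomass(long, bd_policy = config$qpcr$bd_policy),
      ratio = bacteria_fungi_ratio(long, method = config$qpcr$ratio_method)
    )
  })

  regression_out <- run_stage("regression", {
    grouping <- config$regression$grouping
    emissions_loc <- emissions_out$emissions |>
      left_join(select(scenario$samples, "sample_id", "location"),
                by = "sample_id")
    points <- group_points(emissions_loc, biomass_out$biomass,
                           grouping = grouping)
    periods <- if ("period" %in% grouping) {
      sort(unique(points$period))
    } else {
      NA_character_
    }
    fits <- purrr::map(periods, ~ fit_yield(points, period = .x))
    names(fits) <- periods
    list(points = points, fits = fits, range = yield_range(fits))
  })

  boxmodel_out <- run_stage("box_model", {
    bm <- config$box_model
    a_for <- c(S1 = bm$a_summer, S2 = bm$a_winter)
    geometry_for <- list(
      kitchen_coupon = fixture_geometry("double_bowl_sink"),
      bathroom_tile = fixture_geometry("shower_stall")
    )
    combos <- emissions_out$flux_by_ion |>
      distinct(.data$surface_type, .data$period)
    contributions <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
      st <- combos$surface_type[i]; pd <- combos$period[i]
      if (!pd %in% names(a_for)) {
        abort(paste0("no air exchange rate configured for period ", pd))
      }
      a <- a_for[[pd]]
      flux <- emissions_out$flux_by_ion |>
        dplyr::filter(.data$surface_type == st, .data$period == pd) |>
        group_by(.data$ion_label) |>
        summarize(flux_ug_m2_h = mean(.data$flux_ug_m2_h),
                  .groups = "drop")
      scale_and_project(flux, geometry_for[[st]], air_exchange_h = a,
                        volume_m3 = bm$volume_m3,
                        ion_panel = scenario$ion_panel,
                        n_top = bm$n_top_ions,
                        molar_volume_l = ch$molar_volume_l) |>
        mutate(source = ifelse(st == "kitchen_coupon", "kitchen_sink",
                               "shower_stall"),
               period = pd)
    })
    totals <- contributions |>
      group_by(.data$source, .data$period) |>
      summarize(C_ugm3 = sum(.data$C_ugm3), C_ppb = sum(.data$C_ppb),
                .groups = "drop")
    list(contributions = contributions, totals = totals)
  })

  network_out <- run_stage("network", {
    spectra <- if (is.null(input_dir)) {
      gen_spectra(scenario)
    } else {
      read_mgf(file.path(input_dir, "spectra.mgf"))
    }
    params <- do.call(network_params, config$network)
    nodes <- cluster_to_compounds(spectra, params)
    net <- build_network(nodes, params) |> remove_blank_nodes()
    list(network = net, partition = partition_summary(net))
  })

  results <- structure(
    list(
      config = config,
      emissions = emissions_out$emissions,
      flux_by_ion = emissions_out$flux_by_ion,
      biomass = biomass_out$biomass,
      biomass_aggregates = biomass_out$aggregates,
      ratio = biomass_out$ratio,
      points = regression_out$points,
      fits = regression_out$fits,
      yield_range = regression_out$range,
      contributions = boxmodel_out$contributions,
      contribution_totals = boxmodel_out$totals,
      network = network_out$network,
      partition = network_out$partition
    ),
    class = "surfvoc_results"
  )
  results$report <- render_report(results)

  if (!is.null(outdir)) {
    run_stage("write_outputs", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(results$emissions, file.path(outdir, "emissions.csv"))
      readr::write_csv(results$biomass_aggregates,
                       file.path(outdir, "biomass_aggregates.csv"))
      readr::write_csv(results$points, file.path(outdir, "points.csv"))
      readr::write_csv(results$contributions,
                       file.path(outdir, "contributions.csv"))
      readr::write_csv(results$partition, file.path(outdir, "partition.csv"))
      write_network(results$network, file.path(outdir, "network_edges.tsv"),
                    node_path = file.path(outdir, "network_nodes.csv"))
      fits_json <- purrr::map(results$fits, function(f) {
        list(period = f$period, slope = f$slope, intercept = f$intercept,
             slope_fg = f$slope_fg, r_squared = f$r_squared, n = f$n)
      })
      jsonlite::write_json(fits_json, file.path(outdir, "fits.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      readr::write_lines(results$report, file.path(outdir, "report.md"))
    })
  }
  results
}

fmt_tbl <- function(df, digits = 4) {
  df <- mutate(df, across(where(is.numeric), ~ signif(.x, digits)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(header, sep, rows)
}

render_report <- function(results) {
  fits_lines <- purrr::imap(results$fits, function(f, nm) {
    sprintf("- %s: sumVOC (ug/m2/h) = %.3g x gene copies/m2 + %.4g (R2 = %.3f, n = %d)",
            nm, f$slope, f$intercept, f$r_squared, f$n)
  })
  c(
    "# Surface microbiome chemistry report",
    "",
    sprintf("Seed: %d", results$config$seed),
    "",
    "## Biomass (gene copies/cm2, group averages)",
    "",
    fmt_tbl(results$biomass_aggregates),
    "",
    sprintf("Bacteria:fungi ratio (%s): %.1f over %d pairs",
            results$ratio$method, results$ratio$ratio,
            results$ratio$n_pairs),
    "",
    "## VOC yield regression",
    "",
    unlist(fits_lines),
    "",
    sprintf("Yield range: %s", results$yield_range$display),
    "",
    "## Modelled indoor contributions (steady state)",
    "",
    fmt_tbl(results$contribution_totals),
    "",
    "## Soluble-compound source partition",
    "",
    fmt_tbl(results$partition),
    ""
  )
}

#' @export
print.surfvoc_results <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Write a complete demo study to disk
#'
#' Emits a small synthetic study — chamber TSV series for every sampler
#' and blank, a biomass CSV, an MGF spectrum library, and the pipeline
#' configuration — sized to run end to end in well under a minute via
#' `run_pipeline(config, input_dir = outdir)`.
#'
#' @param outdir Output directory; created if needed, must be writable.
#' @param seed Scenario seed.
#' @param config Optional pre-built configuration.
#' @return Invisibly, a list with the written `paths` and the `config`.
#' @export
make_demo <- function(outdir, seed = 1,
                      config = pipeline_config(
                        seed = seed, scenario = list(n_compounds = 60)
                      )) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    abort(paste0("cannot create output directory: ", outdir))
  }
  if (file.access(outdir, mode = 2) != 0) {
    abort(paste0("output directory is not writable: ", outdir))
  }
  scenario <- scenario_from_config(config)
  chamber_dir <- file.path(outdir, "chamber")
  dir.create(chamber_dir, showWarnings = FALSE)
  ch <- config$chamber
  chamber_paths <- purrr::map_chr(scenario$samples$sample_id, function(id) {
    run <- gen_chamber_series(scenario, id, duration_s = ch$duration_s,
                              hz = ch$hz, flow_lpm = ch$flow_lpm)
    p <- file.path(chamber_dir, paste0(id, ".tsv"))
    write_chamber_tsv(run, p)
    p
  })
  biomass_path <- file.path(outdir, "biomass.csv")
  write_biomass_csv(gen_biomass_table(scenario), biomass_path)
  mgf_path <- file.path(outdir, "spectra.mgf")
  write_mgf(gen_spectra(scenario), mgf_path)
  config_path <- file.path(outdir, "config.json")
  write_config_json(config, config_path)
  invisible(list(
    paths = list(chamber = chamber_paths, biomass = biomass_path,
                 spectra = mgf_path, config = config_path),
    config = config
  ))
}
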