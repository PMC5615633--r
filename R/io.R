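#' Read and write chamber series as tidy TSV
#'
#' The on-disk schema is one row per scan and ion (`time_s`, `ion_label`,
#' `conc_ppb`, `sample_id`, `surface_type`) with the run metadata
#' (`period`, `sampler_area_m2`, `flow_lpm`) in `# key: value` comment
#' lines above the header, so a file round-trips to an identical run.
#'
#' @param run A `chamber_run`.
#' @param path File path.
#' @return `write_chamber_tsv()` returns `path` invisibly;
#'   `read_chamber_tsv()` returns a `chamber_run`.
#' @export
write_chamber_tsv <- function(run, path) {
  stopifnot(inherits(run, "chamber_run"))
  meta <- c(
    paste0("# sample_id: ", run$sample_id),
    paste0("# surface_type: ", run$surface_type),
    paste0("# period: ", run$period),
    paste0("# sampler_area_m2: ", format(run$sampler_area_m2, digits = 15)),
    paste0("# flow_lpm: ", format(run$flow_lpm, digits = 15))
  )
  readr::write_lines(meta, path)
  out <- run$series |>
    mutate(sample_id = run$sample_id, surface_type = run$surface_type)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_chamber_tsv
#' @export
read_chamber_tsv <- function(path) {
  header <- readr::read_lines(path, n_max = 20)
  header <- header[startsWith(header, "# ")]
  kv <- strsplit(sub("^# ", "", header), ": ")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  series <- readr::read_tsv(path, comment = "#",
                            col_types = readr::cols(
                              time_s = "d", ion_label = "c", conc_ppb = "d",
                              sample_id = "c", surface_type = "c"
                            ))
  new_chamber_run(
    sample_id = unname(meta[["sample_id"]]),
    surface_type = unname(meta[["surface_type"]]),
    period = unname(meta[["period"]]),
    sampler_area_m2 = as.numeric(meta[["sampler_area_m2"]]),
    flow_lpm = as.numeric(meta[["flow_lpm"]]),
    series = select(series, "time_s", "ion_label", "conc_ppb")
  )
}

#' Read and write biomass tables as CSV
#'
#' Wide schema: one row per sample with per-target mean, replicate sd and
#' below-detection flag columns.
#'
#' @param measurements A wide biomass tibble.
#' @param path File path.
#' @export
write_biomass_csv <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' @rdname write_biomass_csv
#' @export
read_biomass_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", surface_type = "c", location = "c", period = "c",
    .default = "d",
    bacteria_below_detection = "l", fungi_below_detection = "l"
  ))
}

#' Read and write MS/MS spectra as MGF
#'
#' Mascot generic format with `BEGIN IONS`/`END IONS` blocks, `PEPMASS`,
#' `CHARGE`, and `mz intensity` peak lines. Source labels and generator
#' compound ids travel in `SOURCE=` and `COMPOUND=` key-value lines (a
#' common key-value extension of the dialect).
#'
#' @param spectra A spectra tibble (see [gen_spectra()]).
#' @param path File path.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::map(seq_len(nrow(spectra)), function(i) {
    p <- spectra$peaks[[i]]
    c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[i]),
      paste0("PEPMASS=", sprintf("%.9g", spectra$precursor_mz[i])),
      "CHARGE=1+",
      paste0("SOURCE=", spectra$source[i]),
      if (!is.null(spectra$compound_id)) {
        paste0("COMPOUND=", spectra$compound_id[i])
      },
      sprintf("%.9g %.9g", p$mz, p$intensity),
      "END IONS", ""
    )
  })
  readr::write_lines(unlist(blocks), path)
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- readr::read_lines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) abort("malformed MGF: unbalanced blocks")
  purrr::map_dfr(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    pm <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
    tibble(
      spectrum_id = if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else {
        paste0("spectrum_", k)
      },
      compound_id = if ("COMPOUND" %in% keys) {
        vals[keys == "COMPOUND"][1]
      } else {
        NA_character_
      },
      source = if ("SOURCE" %in% keys) vals[keys == "SOURCE"][1] else {
        "unknown"
      },
      precursor_mz = as.numeric(strsplit(vals[keys == "PEPMASS"][1],
                                         " ")[[1]][1]),
      peaks = list(tibble(mz = as.numeric(pm[, 1]),
                          intensity = as.numeric(pm[, 2])))
    )
  })
}

#' Write a study scenario as JSON
#'
#' @param scenario A [synthetic_scenario()].
#' @param path File path.
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  synthetic_scenario(
    seed = x$seed,
    ion_panel = as_tibble(x$ion_panel),
    samples = as_tibble(x$samples),
    ion_profile = x$ion_profile,
    voc_yield_slope = x$voc_yield_slope,
    voc_background = x$voc_background,
    noise_sd_fraction = x$noise_sd_fraction,
    ramp_duration_s = x$ramp_duration_s,
    blank_offset_ppb = x$blank_offset_ppb,
    detection_limit = x$detection_limit,
    n_compounds = x$n_compounds,
    frac_shared = x$frac_shared,
    frac_culture_only = x$frac_culture_only,
    frac_material_only = x$frac_material_only,
    blank_contam_fraction = x$blank_contam_fraction,
    intensity_jitter = x$intensity_jitter
  )
}

#' Write a spectral network as edge list, node table, and GraphML
#'
#' @param network A `spectral_network`.
#' @param edge_path TSV path for the edge list (`node_a`, `node_b`,
#'   `cosine`, `n_matched`).
#' @param node_path Optional CSV path for the node table (`node_id`,
#'   `parent_mass`, `presence`, `component`, `n_spectra`).
#' @param graphml_path Optional GraphML path.
#' @export
write_network <- function(network, edge_path, node_path = NULL,
                          graphml_path = NULL) {
  stopifnot(inherits(network, "spectral_network"))
  readr::write_tsv(network$edges, edge_path)
  if (!is.null(node_path)) {
    nodes <- network$nodes |>
      mutate(presence = purrr::map_chr(.data$sources, paste,
                                       collapse = ";")) |>
      select("node_id", "parent_mass", "presence", "component", "n_spectra")
    readr::write_csv(nodes, node_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = data.frame(
        name = network$nodes$node_id,
        parent_mass = network$nodes$parent_mass,
        presence = purrr::map_chr(network$nodes$sources, paste,
                                  collapse = ";")
      )
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
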