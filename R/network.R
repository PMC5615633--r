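#' Molecular-networking parameters
#'
#' Thresholds for spectral clustering, network edges, and reference-library
#' identification: precursor tolerance 2 Da, fragment tolerance 0.5 Da,
#' minimum pair cosine 0.75 with at least 6 matched fragment ions for an
#' edge, and cosine 0.70 with 6 matched peaks for a library hit.
#'
#' @param precursor_tol,fragment_tol Mass tolerances, Da.
#' @param min_cosine,min_matched Edge thresholds.
#' @param library_min_cosine,library_min_peaks Identification thresholds.
#' @return A `network_params` list; all values must be positive.
#' @export
network_params <- function(precursor_tol = 2, fragment_tol = 0.5,
                           min_cosine = 0.75, min_matched = 6,
                           library_min_cosine = 0.70, library_min_peaks = 6) {
  vals <- c(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
            min_cosine = min_cosine, min_matched = min_matched,
            library_min_cosine = library_min_cosine,
            library_min_peaks = library_min_peaks)
  if (any(vals <= 0)) {
    abort(paste0("network parameter(s) must be positive: ",
                 paste(names(vals)[vals <= 0], collapse = ", ")))
  }
  structure(as.list(vals), class = "network_params")
}

# normalize a peak table: sqrt intensities, unit L2 norm
spectrum_parts <- function(spec) {
  if (is.data.frame(spec) && "peaks" %in% names(spec)) {
    if (nrow(spec) != 1) abort("expected a single spectrum row")
    peaks <- spec$peaks[[1]]
  } else if (is.list(spec) && !is.null(spec$peaks)) {
    peaks <- spec$peaks
    if (is.list(peaks) && !is.data.frame(peaks)) peaks <- peaks[[1]]
  } else {
    abort("spectrum must carry $peaks and a precursor (or parent) mass")
  }
  precursor <- spec[["precursor_mz"]] %||% spec[["parent_mass"]]
  if (is.null(precursor) || length(precursor) != 1 || !is.finite(precursor)) {
    abort("spectrum must carry a finite precursor_mz or parent_mass")
  }
  if (is.null(peaks) || nrow(peaks) == 0) abort("spectrum has no peaks")
  if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
    abort("peak intensities must be finite and non-negative")
  }
  w <- sqrt(peaks$intensity)
  nrm <- sqrt(sum(w^2))
  list(mz = peaks$mz, w = if (nrm > 0) w / nrm else w,
       precursor = precursor)
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Spectral similarity that tolerates a systematic mass shift between
#' structurally related compounds: intensities are square-root transformed
#' and L2-normalised, and fragment peaks may pair either directly (mass
#' difference within `fragment_tol`) or shifted by the precursor mass
#' difference. Among all candidate pairs a one-to-one assignment maximising
#' the summed intensity products is selected — exactly, via maximum-weight
#' bipartite matching (`method = "exact"`, the default), or with the
#' common greedy heuristic (`method = "greedy"`). The score is the summed
#' product of the chosen pairs, in `[0, 1]`; with equal precursor masses it
#' reduces to the plain cosine.
#'
#' @param spec_a,spec_b One-row spectra tibbles (with `peaks` list-column
#'   and `precursor_mz`) or lists with `$peaks` and `$precursor_mz`.
#' @param fragment_tol Fragment mass tolerance, Da (non-negative).
#' @param method Peak-assignment strategy.
#' @return A list: `score`, `n_matched`.
#' @examples
#' s <- list(precursor_mz = 200,
#'           peaks = tibble::tibble(mz = c(55, 70, 90), intensity = c(1, 2, 1)))
#' modified_cosine(s, s) # score 1, n_matched 3
#' @export
modified_cosine <- function(spec_a, spec_b, fragment_tol = 0.5,
                            method = c("exact", "greedy")) {
  method <- match.arg(method)
  if (fragment_tol < 0) abort("fragment_tol must be non-negative")
  a <- spectrum_parts(spec_a)
  b <- spectrum_parts(spec_b)
  delta <- a$precursor - b$precursor
  d <- outer(a$mz, b$mz, "-")
  cand <- abs(d) <= fragment_tol | abs(d - delta) <= fragment_tol
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(score = 0, n_matched = 0L))
  w <- a$w[idx[, 1]] * b$w[idx[, 2]]
  pos <- w > 0
  idx <- idx[pos, , drop = FALSE]
  w <- w[pos]
  if (length(w) == 0) return(list(score = 0, n_matched = 0L))
  if (!anyDuplicated(idx[, 1]) && !anyDuplicated(idx[, 2])) {
    return(list(score = min(sum(w), 1), n_matched = nrow(idx)))
  }
  if (method == "greedy") {
    ord <- order(-w)
    used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
    score <- 0; n <- 0L
    for (k in ord) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        score <- score + w[k]; n <- n + 1L
      }
    }
    return(list(score = min(score, 1), n_matched = n))
  }
  na <- length(a$mz)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, length(b$mz))),
    edges = as.vector(t(cbind(idx[, 1], na + idx[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = w, eps = 1e-12)
  list(score = min(m$matching_weight, 1), n_matched = m$matching_size)
}

# merge peak lists of clustered spectra: bin by mz gap > tol, consensus mz
# intensity-weighted, intensity averaged over members
merge_peaks <- function(peaks, fragment_tol, n_members) {
  p <- arrange(peaks, .data$mz)
  grp <- cumsum(c(TRUE, diff(p$mz) > fragment_tol))
  p |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarize(mz2 = weighted.mean(.data$mz, pmax(.data$intensity, 1e-12)),
              intensity = sum(.data$intensity) / n_members,
              .groups = "drop") |>
    transmute(mz = .data$mz2, intensity = .data$intensity)
}

#' Collapse replicate spectra into consensus compound nodes
#'
#' Spectra whose precursor masses agree within `precursor_tol` and whose
#' modified cosine reaches `min_cosine` are considered the same compound
#' and merged (single linkage) into one node. A node's source-presence set
#' is the union of its members' sources; its consensus spectrum merges the
#' member peaks (intensity-weighted m/z, averaged intensity).
#'
#' @param spectra A spectra tibble (see [gen_spectra()] / [read_mgf()]).
#' @param params A [network_params()].
#' @return A nodes tibble: `node_id`, `parent_mass`, `n_spectra`,
#'   `sources` and `peaks` list-columns, `member_ids`.
#' @export
cluster_to_compounds <- function(spectra, params = network_params()) {
  n <- nrow(spectra)
  if (n == 0) abort("no spectra to cluster")
  ord <- order(spectra$precursor_mz)
  pm <- spectra$precursor_mz[ord]
  edges <- integer(0)
  for (ii in seq_len(n - 1)) {
    jj <- ii + 1
    while (jj <= n && pm[jj] - pm[ii] <= params$precursor_tol) {
      sim <- modified_cosine(spectra[ord[ii], ], spectra[ord[jj], ],
                             fragment_tol = params$fragment_tol)
      if (sim$score >= params$min_cosine) {
        edges <- c(edges, ord[ii], ord[jj])
      }
      jj <- jj + 1
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  purrr::map_dfr(seq_len(max(comp)), function(k) {
    members <- spectra[comp == k, ]
    tibble(
      parent_mass = mean(members$precursor_mz),
      n_spectra = nrow(members),
      sources = list(sort(unique(members$source))),
      peaks = list(merge_peaks(bind_rows(members$peaks),
                               params$fragment_tol, nrow(members))),
      member_ids = list(members$spectrum_id)
    )
  }) |>
    arrange(.data$parent_mass) |>
    mutate(node_id = sprintf("N%04d", dplyr::row_number()),
           .before = 1)
}

#' Build the thresholded molecular similarity network
#'
#' Computes the modified cosine between every pair of consensus nodes and
#' keeps an edge where the score reaches `min_cosine` and at least
#' `min_matched` fragment pairs are used. Connected components are
#' labelled on the nodes; singletons are retained as size-1 components.
#'
#' @param nodes Nodes tibble from [cluster_to_compounds()].
#' @param params A [network_params()].
#' @return A `spectral_network`: list with `nodes` (plus `component`
#'   column), `edges` (`node_a`, `node_b`, `cosine`, `n_matched`), and
#'   `params`.
#' @export
build_network <- function(nodes, params = network_params()) {
  n <- nrow(nodes)
  if (n == 0) abort("need at least one node")
  pairs <- if (n > 1) utils::combn(n, 2) else matrix(numeric(0), nrow = 2)
  edge_rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sim <- modified_cosine(nodes[i, ], nodes[j, ],
                           fragment_tol = params$fragment_tol)
    if (sim$score >= params$min_cosine &&
        sim$n_matched >= params$min_matched) {
      tibble(node_a = nodes$node_id[i], node_b = nodes$node_id[j],
             cosine = sim$score, n_matched = as.integer(sim$n_matched))
    } else {
      NULL
    }
  })
  if (nrow(edge_rows) == 0) {
    edge_rows <- tibble(node_a = character(), node_b = character(),
                        cosine = numeric(), n_matched = integer())
  }
  new_spectral_network(nodes, edge_rows, params)
}

new_spectral_network <- function(nodes, edges, params) {
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = data.frame(name = nodes$node_id)
  )
  nodes$component <- unname(igraph::components(g)$membership[nodes$node_id])
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "spectral_network")
}

#' @export
print.spectral_network <- function(x, ...) {
  cat("<spectral_network>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges,", dplyr::n_distinct(x$nodes$component), "components\n")
  invisible(x)
}

#' Remove nodes detected in blanks
#'
#' Any node whose source-presence set intersects the blank sources
#' (unexposed tiles/coupons, culture media, solvent) is deleted together
#' with its edges, regardless of whether it was also seen in a real
#' source: presence in a blank marks the compound as background. The
#' operation is idempotent; the number of removed nodes is stored in the
#' returned network's `n_blank_removed`.
#'
#' @param network A `spectral_network`.
#' @param blank_sources Source labels treated as blanks.
#' @return The filtered `spectral_network` (components recomputed).
#' @export
remove_blank_nodes <- function(network,
                               blank_sources = c("blank", "solvent")) {
  stopifnot(inherits(network, "spectral_network"))
  keep <- !purrr::map_lgl(network$nodes$sources,
                          ~ any(.x %in% blank_sources))
  nodes <- network$nodes[keep, , drop = FALSE]
  kept_ids <- nodes$node_id
  edges <- dplyr::filter(network$edges, .data$node_a %in% kept_ids &
                           .data$node_b %in% kept_ids)
  if (nrow(nodes) == 0) {
    out <- structure(list(nodes = nodes, edges = edges,
                          params = network$params),
                     class = "spectral_network")
  } else {
    out <- new_spectral_network(nodes, edges, network$params)
  }
  out$n_blank_removed <- sum(!keep) + (network$n_blank_removed %||% 0L)
  out
}

#' Source partition of a blank-filtered network
#'
#' Counts nodes by source presence — culture only, material only, or shared
#' (both) — and reports percentages of the total at one decimal, plus the
#' shared compounds' share of everything detected on material samples,
#' `n_shared / (n_shared + n_material_only)`. Apply [remove_blank_nodes()]
#' first.
#'
#' @param network A `spectral_network`.
#' @return A one-row tibble (see [partition_percentages()]).
#' @export
partition_summary <- function(network) {
  stopifnot(inherits(network, "spectral_network"))
  if (nrow(network$nodes) == 0) abort("network is empty")
  has_c <- purrr::map_lgl(network$nodes$sources, ~ "culture" %in% .x)
  has_m <- purrr::map_lgl(network$nodes$sources, ~ "material" %in% .x)
  partition_percentages(
    n_culture_only = sum(has_c & !has_m),
    n_material_only = sum(has_m & !has_c),
    n_shared = sum(has_c & has_m),
    n_total = nrow(network$nodes)
  )
}

#' Partition percentages from source counts
#'
#' The arithmetic of the partition summary, exposed so that published
#' count tables can be re-analysed directly. `n_total` defaults to the sum
#' of the three counts but may be given explicitly when the network
#' contains additional unclassified nodes.
#'
#' @param n_culture_only,n_material_only,n_shared Node counts.
#' @param n_total Total node count (denominator of the percentages).
#' @return A one-row tibble: counts, `pct_culture_only`,
#'   `pct_material_only`, `pct_shared` (1 decimal, percentages of
#'   `n_total`), and `shared_share_of_material_pct`.
#' @examples
#' partition_percentages(2045, 199, 81, n_total = 2369)
#' @export
partition_percentages <- function(n_culture_only, n_material_only, n_shared,
                                  n_total = NULL) {
  n_total <- n_total %||% (n_culture_only + n_material_only + n_shared)
  if (n_total <= 0) abort("n_total must be positive")
  tibble(
    n_total = n_total,
    n_culture_only = n_culture_only,
    n_material_only = n_material_only,
    n_shared = n_shared,
    pct_culture_only = round(100 * n_culture_only / n_total, 1),
    pct_material_only = round(100 * n_material_only / n_total, 1),
    pct_shared = round(100 * n_shared / n_total, 1),
    shared_share_of_material_pct =
      if (n_shared + n_material_only > 0) {
        round(100 * n_shared / (n_shared + n_material_only), 1)
      } else {
        NA_real_
      }
  )
}

#' Identify nodes against a reference spectral library
#'
#' Scores every node against every named reference spectrum with the
#' modified cosine and reports the best hit passing the identification
#' thresholds (cosine >= `library_min_cosine`, matched peaks >=
#' `library_min_peaks`). Ties are broken by higher matched count, then by
#' reference name. No hit is a valid outcome (NA row).
#'
#' @param nodes Nodes tibble (consensus spectra).
#' @param reference Tibble with `name`, `precursor_mz`, `peaks`.
#' @param params A [network_params()].
#' @return A tibble: `node_id`, `match_name`, `score`, `n_matched`.
#' @export
library_match <- function(nodes, reference, params = network_params()) {
  if (!all(c("name", "precursor_mz", "peaks") %in% names(reference))) {
    abort("reference library needs columns name, precursor_mz, peaks")
  }
  purrr::map_dfr(seq_len(nrow(nodes)), function(i) {
    hits <- purrr::map_dfr(seq_len(nrow(reference)), function(j) {
      sim <- modified_cosine(nodes[i, ], reference[j, ],
                             fragment_tol = params$fragment_tol)
      tibble(name = reference$name[j], score = sim$score,
             n_matched = as.integer(sim$n_matched))
    }) |>
      dplyr::filter(.data$score >= params$library_min_cosine,
                    .data$n_matched >= params$library_min_peaks) |>
      arrange(desc(.data$score), desc(.data$n_matched), .data$name)
    if (nrow(hits) == 0) {
      tibble(node_id = nodes$node_id[i], match_name = NA_character_,
             score = NA_real_, n_matched = NA_integer_)
    } else {
      tibble(node_id = nodes$node_id[i], match_name = hits$name[1],
             score = hits$score[1], n_matched = hits$n_matched[1])
    }
  })
}

#' @rdname build_network
#' @param object A `spectral_network`.
#' @param ... Unused.
#' @export
autoplot.spectral_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = object$nodes$node_id)
  )
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  has_c <- purrr::map_lgl(object$nodes$sources, ~ "culture" %in% .x)
  has_m <- purrr::map_lgl(object$nodes$sources, ~ "material" %in% .x)
  nodes <- tibble(
    node_id = object$nodes$node_id, x = xy[, 1], y = xy[, 2],
    presence = dplyr::case_when(
      has_c & has_m ~ "shared",
      has_c ~ "culture only",
      has_m ~ "material only",
      TRUE ~ "other"
    )
  )
  seg <- object$edges |>
    left_join(rename(nodes, node_a = "node_id", xa = "x", ya = "y"),
              by = "node_a") |>
    left_join(rename(nodes, node_b = "node_id", xb = "x", yb = "y"),
              by = "node_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya,
                   xend = .data$xb, yend = .data$yb),
      color = "grey70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, color = .data$presence), size = 2
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "source presence")
}
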