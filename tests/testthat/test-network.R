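toy_spec <- function(mz, intensity, precursor = 300) {
  list(precursor_mz = precursor,
       peaks = tibble::tibble(mz = mz, intensity = intensity))
}

test_that("modified cosine is a self-normalised bounded similarity", {
  s <- toy_spec(c(55.2, 70.1, 91.8, 120.4), c(1, 3, 2, 0.5))
  self <- modified_cosine(s, s)
  expect_equal(self$score, 1, tolerance = 1e-9)
  expect_equal(self$n_matched, 4L)

  disjoint <- modified_cosine(
    toy_spec(c(50, 60), c(1, 1), precursor = 200),
    toy_spec(c(80, 90), c(1, 1), precursor = 200)
  )
  expect_equal(disjoint$score, 0)
  expect_equal(disjoint$n_matched, 0L)

  a <- toy_spec(c(55, 70, 90), c(1, 2, 3), precursor = 210)
  b <- toy_spec(c(55.1, 70.2, 95), c(2, 1, 1), precursor = 250)
  ab <- modified_cosine(a, b)
  ba <- modified_cosine(b, a)
  expect_equal(ab$score, ba$score, tolerance = 1e-12)
  expect_equal(ab$n_matched, ba$n_matched)
  expect_true(ab$score >= 0 && ab$score <= 1)
  expect_error(modified_cosine(a, b, fragment_tol = -1), "non-negative")
})

test_that("zero precursor shift reduces to the plain cosine", {
  mz <- c(60, 75, 102, 133)
  ia <- c(4, 1, 2, 1)
  ib <- c(1, 3, 1, 2)
  got <- modified_cosine(toy_spec(mz, ia), toy_spec(mz, ib))
  wa <- sqrt(ia) / sqrt(sum(ia))
  wb <- sqrt(ib) / sqrt(sum(ib))
  expect_equal(got$score, sum(wa * wb), tolerance = 1e-12)
  expect_equal(got$n_matched, 4L)
})

test_that("a shifted peak is matched through the precursor difference", {
  # b is a + 14 Da on the precursor and on one fragment: the shifted pair
  # can only be found through the delta-shifted candidate rule
  a <- toy_spec(c(55, 70, 90, 110), c(1, 1, 1, 1), precursor = 200)
  b <- toy_spec(c(55, 70, 90, 124), c(1, 1, 1, 1), precursor = 214)
  got <- modified_cosine(a, b)
  expect_equal(got$score, 1, tolerance = 1e-9)
  expect_equal(got$n_matched, 4L)
})

test_that("exact assignment equals the exhaustive oracle on toy cases", {
  # ambiguous case: two peaks of A compete for one peak of B directly and
  # via the shift; exact matching must find the best disjoint assignment
  a <- toy_spec(c(100, 100.3, 150, 180), c(3, 1, 2, 1), precursor = 300)
  b <- toy_spec(c(100.1, 150.2, 180.4, 210), c(1, 2, 1, 3), precursor = 310)
  got <- modified_cosine(a, b)
  oracle <- bf_modified_cosine(a, b)
  expect_equal(got$score, oracle$score, tolerance = 1e-12)
  expect_equal(got$n_matched, oracle$n)
  # greedy can never beat the exact assignment
  greedy <- modified_cosine(a, b, method = "greedy")
  expect_lte(greedy$score, got$score + 1e-12)
})

test_that("clustering merges replicate spectra and separates compounds", {
  p <- tibble::tibble(mz = c(80, 120, 160, 200, 240, 260),
                      intensity = c(1, 2, 3, 2, 1, 1))
  spectra <- tibble::tibble(
    spectrum_id = c("c1", "m1", "far1"),
    source = c("culture", "material", "culture"),
    precursor_mz = c(400, 400.5, 410),
    peaks = list(p, p, dplyr::mutate(p, mz = mz + 37.7))
  )
  nodes <- cluster_to_compounds(spectra)
  expect_equal(nrow(nodes), 2)
  merged <- nodes[purrr::map_int(nodes$member_ids, length) == 2, ]
  expect_equal(merged$sources[[1]], c("culture", "material"))
  expect_equal(merged$n_spectra, 2)

  # a synthetic library clusters back to one node per generated compound
  sc <- synthetic_scenario(seed = 13, n_compounds = 40, frac_shared = 0.25,
                           frac_culture_only = 0.5,
                           frac_material_only = 0.25,
                           intensity_jitter = 0.02)
  sp <- gen_spectra(sc)
  lib_nodes <- cluster_to_compounds(sp)
  expect_equal(nrow(lib_nodes), 40)
})

test_that("network edges respect both thresholds and components form", {
  p <- tibble::tibble(mz = seq(60, 200, by = 20),
                      intensity = c(1, 2, 3, 4, 3, 2, 1, 1))
  nodes <- tibble::tibble(
    node_id = c("N1", "N2", "N3"),
    parent_mass = c(300, 314, 600),
    n_spectra = 1L,
    sources = list("culture", "material", "culture"),
    peaks = list(p, dplyr::mutate(p, intensity = intensity * 1.1),
                 tibble::tibble(mz = c(61, 83, 99, 104, 151, 202),
                                intensity = rep(1, 6)))
  )
  net <- build_network(nodes)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$node_a, net$edges$node_b)), c("N1", "N2"))
  expect_true(net$edges$cosine >= 0.75 && net$edges$n_matched >= 6)
  expect_equal(dplyr::n_distinct(net$nodes$component), 2)

  # high cosine with too few matched fragments is rejected
  small <- tibble::tibble(mz = c(60, 80, 100), intensity = c(1, 2, 1))
  pair <- tibble::tibble(
    node_id = c("A", "B"), parent_mass = c(250, 250), n_spectra = 1L,
    sources = list("culture", "material"),
    peaks = list(small, small)
  )
  net2 <- build_network(pair)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(modified_cosine(pair[1, ], pair[2, ])$score, 1,
               tolerance = 1e-9)
})

test_that("every emitted edge re-verifies above the thresholds", {
  sc <- synthetic_scenario(seed = 31, n_compounds = 50, frac_shared = 0.2,
                           frac_culture_only = 0.5, frac_material_only = 0.3,
                           intensity_jitter = 0.05)
  nodes <- cluster_to_compounds(gen_spectra(sc))
  # plant structural analogs (+14 Da on precursor and every fragment) so
  # the network is guaranteed to contain edges to audit
  analogs <- nodes[1:3, ] |>
    dplyr::mutate(
      node_id = paste0(node_id, "a"),
      parent_mass = parent_mass + 14,
      peaks = purrr::map(peaks, ~ dplyr::mutate(.x, mz = mz + 14))
    )
  nodes <- dplyr::bind_rows(nodes, analogs)
  net <- build_network(nodes)
  expect_gte(nrow(net$edges), 3)
  params <- net$params
  for (k in seq_len(nrow(net$edges))) {
    i <- match(net$edges$node_a[k], net$nodes$node_id)
    j <- match(net$edges$node_b[k], net$nodes$node_id)
    sim <- modified_cosine(net$nodes[i, ], net$nodes[j, ],
                           fragment_tol = params$fragment_tol)
    expect_gte(sim$score, params$min_cosine)
    expect_gte(sim$n_matched, params$min_matched)
  }
})

test_that("blank-derived nodes are removed by presence, idempotently", {
  p <- tibble::tibble(mz = c(60, 90, 120), intensity = c(1, 1, 1))
  nodes <- tibble::tibble(
    node_id = paste0("N", 1:4),
    parent_mass = c(200, 300, 400, 500), n_spectra = 1L,
    sources = list("blank", c("blank", "culture"), "culture", "material"),
    peaks = list(p, p, p, p)
  )
  net <- build_network(nodes)
  cleaned <- remove_blank_nodes(net)
  expect_equal(sort(cleaned$nodes$node_id), c("N3", "N4"))
  expect_equal(cleaned$n_blank_removed, 2)
  again <- remove_blank_nodes(cleaned)
  expect_equal(again$nodes, cleaned$nodes)

  free <- build_network(nodes[3:4, ])
  expect_equal(remove_blank_nodes(free)$nodes$node_id, free$nodes$node_id)
})

test_that("partition arithmetic matches counts and handles edge cases", {
  got <- partition_percentages(2045, 199, 81, n_total = 2369)
  expect_equal(got$pct_culture_only, 86.3)
  expect_equal(got$pct_material_only, 8.4)
  expect_equal(got$pct_shared, 3.4)
  expect_equal(got$shared_share_of_material_pct, 28.9)

  p <- tibble::tibble(mz = c(60, 90, 120), intensity = c(1, 1, 1))
  all_shared <- build_network(tibble::tibble(
    node_id = paste0("N", 1:3), parent_mass = c(200, 300, 400),
    n_spectra = 2L, sources = list(c("culture", "material"),
                                   c("culture", "material"),
                                   c("culture", "material")),
    peaks = list(p, p, p)
  ))
  deg <- partition_summary(all_shared)
  expect_equal(deg$n_shared, 3)
  expect_equal(deg$pct_shared, 100)
  expect_equal(deg$shared_share_of_material_pct, 100)

  empty <- remove_blank_nodes(build_network(tibble::tibble(
    node_id = "N1", parent_mass = 100, n_spectra = 1L,
    sources = list("blank"), peaks = list(p)
  )))
  expect_error(partition_summary(empty), "empty")

  # counts always sum to the total; percentages to 100 within rounding
  sc <- synthetic_scenario(seed = 17, n_compounds = 60, frac_shared = 0.15,
                           frac_culture_only = 0.55,
                           frac_material_only = 0.30)
  net <- remove_blank_nodes(build_network(
    cluster_to_compounds(gen_spectra(sc))
  ))
  summ <- partition_summary(net)
  expect_equal(summ$n_culture_only + summ$n_material_only + summ$n_shared,
               summ$n_total)
  expect_lt(abs(summ$pct_culture_only + summ$pct_material_only +
                  summ$pct_shared - 100), 0.16)
})

test_that("library matching identifies planted references only", {
  sc <- synthetic_scenario(seed = 23, n_compounds = 50, frac_shared = 0,
                           frac_culture_only = 1, frac_material_only = 0,
                           intensity_jitter = 0)
  sp <- gen_spectra(sc)
  nodes <- cluster_to_compounds(sp)
  # plant 4% of the compounds as named references
  planted <- nodes[c(10, 35), ]
  reference <- tibble::tibble(
    name = c("ref_a", "ref_b"),
    precursor_mz = planted$parent_mass,
    peaks = planted$peaks
  )
  hits <- library_match(nodes, reference)
  expect_equal(sum(!is.na(hits$match_name)), 2)
  expect_equal(mean(!is.na(hits$match_name)), 0.04)
  matched <- hits[!is.na(hits$match_name), ]
  expect_equal(matched$score, c(1, 1), tolerance = 1e-9)
  expect_equal(matched$node_id, planted$node_id)

  # a best score below the threshold yields no identification
  weak_ref <- tibble::tibble(
    name = "weak",
    precursor_mz = nodes$parent_mass[1],
    peaks = list(dplyr::mutate(nodes$peaks[[1]],
                               mz = mz + 0.45, intensity = rev(intensity)))
  )
  weak_hit <- library_match(nodes[1, ], weak_ref,
                            params = network_params(library_min_cosine = 0.999))
  expect_true(is.na(weak_hit$match_name))
})

test_that("networks render and export", {
  sc <- synthetic_scenario(seed = 29, n_compounds = 20, frac_shared = 0.3,
                           frac_culture_only = 0.4, frac_material_only = 0.3)
  net <- build_network(cluster_to_compounds(gen_spectra(sc)))
  p <- ggplot2::autoplot(net)
  expect_s3_class(p, "ggplot")
  tmp <- withr::local_tempdir()
  write_network(net, file.path(tmp, "edges.tsv"),
                node_path = file.path(tmp, "nodes.csv"),
                graphml_path = file.path(tmp, "net.graphml"))
  expect_true(file.exists(file.path(tmp, "edges.tsv")))
  expect_true(file.exists(file.path(tmp, "nodes.csv")))
  expect_true(file.exists(file.path(tmp, "net.graphml")))
})
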