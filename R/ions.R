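.element_masses <- c(
  C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
  S = 31.972071, P = 30.973762
)

# monoisotopic mass of a neutral elemental formula such as "C4H8O2"
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (length(parts) == 0 || paste(parts, collapse = "") != f) {
      abort(paste0("cannot parse elemental formula: '", f, "'"))
    }
    el <- gsub("[0-9]", "", parts)
    n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", parts)))
    n[is.na(n)] <- 1L
    unknown <- setdiff(el, names(.element_masses))
    if (length(unknown) > 0) {
      abort(paste0("unknown element(s) in formula '", f, "': ",
                   paste(unknown, collapse = ", ")))
    }
    sum(.element_masses[el] * n)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Define a PTR-MS ion panel
#'
#' Builds a table of protonated ion species from neutral elemental formulas.
#' Proton-transfer ionisation yields `MH+` ions, so each panel entry carries
#' the protonated exact mass and the neutral molecular weight used for
#' ppb-to-mass conversion. Formula-derived masses are monoisotopic.
#'
#' @param formula Character vector of neutral formulas, e.g. `"C4H8"`.
#' @param label Ion labels; default appends `"H+"` to the formula. Labels
#'   must be unique within a panel.
#' @param name Optional putative compound name(s).
#' @param protonated_mass Optional protonated exact masses (Da); computed
#'   from the formula when omitted, and checked for consistency with
#'   `neutral_mw` (within 0.01 Da of `protonated_mass - 1.00728`).
#' @param neutral_mw Optional neutral molecular weights (g/mol).
#' @return A tibble with columns `ion_label`, `formula`, `name`,
#'   `protonated_mass`, `neutral_mw`.
#' @examples
#' ion_panel("C4H8O2", name = "butanoic acid")
#' @export
ion_panel <- function(formula, label = paste0(formula, "H+"),
                      name = NA_character_,
                      protonated_mass = NULL, neutral_mw = NULL) {
  neutral <- neutral_mw %||% formula_mass(formula)
  proton <- protonated_mass %||% (neutral + PROTON_MASS_DA)
  panel <- tibble(
    ion_label = label, formula = formula, name = name,
    protonated_mass = proton, neutral_mw = neutral
  )
  validate_ion_panel(panel)
}

#' @rdname ion_panel
#' @param panel An ion panel tibble to validate.
#' @export
validate_ion_panel <- function(panel) {
  req <- c("ion_label", "protonated_mass", "neutral_mw")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("ion panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(panel$ion_label)) {
    dup <- unique(panel$ion_label[duplicated(panel$ion_label)])
    abort(paste0("duplicated ion label(s): ", paste(dup, collapse = ", ")))
  }
  if (any(panel$neutral_mw <= 0)) abort("neutral_mw must be positive")
  dev <- abs(panel$neutral_mw - (panel$protonated_mass - PROTON_MASS_DA))
  if (any(dev > 0.01)) {
    bad <- panel$ion_label[dev > 0.01]
    abort(paste0("neutral_mw inconsistent with protonated_mass for: ",
                 paste(bad, collapse = ", ")))
  }
  as_tibble(panel)
}

#' Default panel of abundant surface-emitted VOC ions
#'
#' A 20-ion panel representative of flux-chamber measurements over wetted
#' kitchen and bathroom surfaces: alkyl/alkenyl fragments of larger volatile
#' fatty acids, short- and medium-chain fatty acids and their oxidation
#' products, sulfur- and nitrogen-bearing species. Identifications are
#' putative (soft ionisation is structurally nonspecific; isomers share a
#' formula and hence a molecular weight).
#'
#' @return An ion panel tibble (see [ion_panel()]).
#' @export
default_ion_panel <- function() {
  ion_panel(
    formula = c(
      "C4H8", "C5H10", "C6H12", "C8H16", "C10H20", "C8H14",
      "C8H8O2", "C4H8OS", "C2H4O2", "C4H8O2", "C3H6O", "CH4O",
      "C2H6O", "C2H6S", "C5H5N", "C7H5NS", "C2H4O", "C3H4O2",
      "C2H5NO", "C5H8"
    ),
    name = c(
      "butene / alkyl fragment", "pentene / alkyl fragment",
      "hexene / alkyl fragment", "octene / alkyl fragment",
      "decene / alkyl fragment", "octadiene / alkadienyl fragment",
      "phenylacetic acid / methyl benzoate", "methional / S-methyl thioester",
      "acetic acid", "butanoic acid", "acetone", "methanol",
      "ethanol", "dimethyl sulfide / ethanethiol", "pyridine",
      "benzothiazole", "acetaldehyde", "pyruvaldehyde / acrylic acid",
      "acetamide", "isoprene"
    )
  )
}

#' Convert between ppb and mass concentration
#'
#' `ppb_to_ugm3()` converts a gas-phase mixing ratio to mass concentration
#' using the species' neutral molecular weight and the molar volume of air
#' (24.45 L/mol at 25 degC, 1 atm by default). `ugm3_to_ppb()` is the exact
#' inverse.
#'
#' @param conc_ppb,conc_ugm3 Numeric concentration vectors.
#' @param neutral_mw Neutral molecular weight(s), g/mol; must be positive.
#' @param molar_volume_l Molar volume of air, L/mol.
#' @return Numeric vector in the target unit.
#' @examples
#' ppb_to_ugm3(10, 60) # 24.54 ug/m3
#' @export
ppb_to_ugm3 <- function(conc_ppb, neutral_mw, molar_volume_l = MOLAR_VOLUME_L) {
  if (any(neutral_mw <= 0)) abort("neutral_mw must be positive")
  if (molar_volume_l <= 0) abort("molar_volume_l must be positive")
  conc_ppb * neutral_mw / molar_volume_l
}

#' @rdname ppb_to_ugm3
#' @export
ugm3_to_ppb <- function(conc_ugm3, neutral_mw, molar_volume_l = MOLAR_VOLUME_L) {
  if (any(neutral_mw <= 0)) abort("neutral_mw must be positive")
  if (molar_volume_l <= 0) abort("molar_volume_l must be positive")
  conc_ugm3 * molar_volume_l / neutral_mw
}
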