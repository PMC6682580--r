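#' Element property table
#'
#' Frozen per-element constants used throughout the descriptor machinery:
#' atomic mass, van der Waals radius (Bondi), Sanderson electronegativity,
#' static polarizability and van der Waals volume (sphere volume at the Bondi
#' radius). The table is shipped in code, not looked up from an external
#' source at run time, so descriptor values are reproducible across
#' environments. Weighting schemes for 3D-MoRSE descriptors normalise mass,
#' volume, electronegativity and polarizability by the carbon value
#' (Dragon/Mordred convention), so the carbon row doubles as the
#' normalisation reference.
#'
#' Coverage is the organic subset relevant to drug-like ligands:
#' H, C, N, O, F, P, S, Cl, Br, I.
#'
#' @return A tibble with columns `element`, `mass` (amu), `vdw_radius`
#'   (Angstrom), `sanderson_en`, `polarizability` (Angstrom^3) and
#'   `vdw_volume` (Angstrom^3).
#' @examples
#' element_table()
#' @export
element_table <- function() {
  tibble::tribble(
    ~element, ~mass,    ~vdw_radius, ~sanderson_en, ~polarizability,
    "H",       1.008,   1.20,        2.592,         0.667,
    "C",      12.011,   1.70,        2.746,         1.760,
    "N",      14.007,   1.55,        3.194,         1.100,
    "O",      15.999,   1.52,        3.654,         0.802,
    "F",      18.998,   1.47,        4.000,         0.557,
    "P",      30.974,   1.80,        2.515,         3.630,
    "S",      32.060,   1.80,        2.957,         2.900,
    "Cl",     35.450,   1.75,        3.475,         2.180,
    "Br",     79.904,   1.85,        3.219,         3.050,
    "I",     126.904,   1.98,        2.778,         5.350
  ) |>
    dplyr::mutate(vdw_volume = 4 / 3 * pi * .data$vdw_radius^3)
}

# Fast lookup of one element column; errors on unknown symbols, naming them.
element_property <- function(elements, property) {
  tab <- element_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(unique(elements[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  tab[[property]][idx]
}

#' Atomic weights for 3D-MoRSE weighting schemes
#'
#' Resolves one of the six weighting schemes to a per-atom numeric vector.
#' Schemes `m` (mass), `v` (van der Waals volume), `e` (Sanderson
#' electronegativity) and `p` (polarizability) are normalised by the carbon
#' value, so a carbon atom always carries weight 1. Scheme `u` is unweighted
#' (all ones) and `c` uses signed partial charges as-is.
#'
#' @param elements Character vector of element symbols.
#' @param scheme One of `"u"`, `"m"`, `"v"`, `"e"`, `"p"`, `"c"`.
#' @param charges Per-atom partial charges; required for scheme `"c"`.
#' @return Numeric vector of per-atom weights, or `NULL` when charges are
#'   requested but unavailable (the caller flags the descriptor undefined).
#' @export
atomic_weights <- function(elements, scheme, charges = NULL) {
  scheme <- match.arg(scheme, c("u", "m", "v", "e", "p", "c"))
  if (scheme == "u") return(rep(1, length(elements)))
  if (scheme == "c") {
    if (is.null(charges) || anyNA(charges)) return(NULL)
    return(charges)
  }
  prop <- c(m = "mass", v = "vdw_volume", e = "sanderson_en", p = "polarizability")[[scheme]]
  tab <- element_table()
  ref <- tab[[prop]][tab$element == "C"]
  element_property(elements, prop) / ref
}
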