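#' 3D-MoRSE descriptors
#'
#' Molecule Representation of Structures based on Electron diffraction:
#' weighted double sums of the scattered-intensity kernel over atom pairs,
#' `Mor_w(s_index) = sum_{i<j} w_i w_j * sin(s r_ij) / (s r_ij)`, with
#' `sinc(0) = 1` and scattering parameter `s = s_index - 1` (inverse
#' Angstrom, `s_index` in 1..32, the Dragon/Mordred convention). At
#' `s_index = 1` the kernel is identically 1 and the descriptor collapses to
#' `sum_{i<j} w_i w_j`, which depends only on composition — for the
#' unweighted scheme simply `N(N-1)/2` — and is therefore constant across
#' all conformers of a molecule. That invariance is what pins the
#' `s = s_index - 1` mapping.
#'
#' @param coords n x 3 coordinates (Angstrom), n >= 2.
#' @param elements Element symbols.
#' @param s_index Scattering index, 1..32 (scalar or vector).
#' @param scheme Weighting scheme code, see [atomic_weights()].
#' @param charges Per-atom charges (needed for scheme `"c"`).
#' @return Numeric vector, one value per `s_index`; `NA` when charge
#'   weighting is requested without charges.
#' @export
morse <- function(coords, elements, s_index, scheme = "u", charges = NULL) {
  stopifnot(all(s_index >= 1 & s_index <= 32))
  w <- atomic_weights(elements, scheme, charges)
  if (is.null(w)) return(rep(NA_real_, length(s_index)))
  dm <- geometric_distance_matrix(coords)
  pair <- which(upper.tri(dm), arr.ind = TRUE)
  r <- dm[pair]
  wprod <- w[pair[, 1]] * w[pair[, 2]]
  vapply(s_index, function(si) {
    s <- si - 1
    kern <- if (s == 0) rep(1, length(r)) else {
      x <- s * r
      ifelse(x < 1e-12, 1, sin(x) / x)
    }
    sum(wprod * kern)
  }, numeric(1))
}

#' Gravitational indexes
#'
#' Mass-weighted inverse-square pair sums: `G = sum m_i m_j / r_ij^2` over
#' all atom pairs (`grav_all`) and over bonded pairs only (`grav_bonded`),
#' with square- and cube-root transforms of each.
#'
#' @inheritParams morse
#' @param bonds Bond tibble with columns `i`, `j` (for the bonded variant).
#' @return Named vector: `grav_all`, `grav_all_sqrt`, `grav_all_cbrt`,
#'   `grav_bonded`, `grav_bonded_sqrt`, `grav_bonded_cbrt` (amu^2/Angstrom^2
#'   and its roots). Bonded forms are `NA` for a molecule without bonds.
#' @export
gravitational_indexes <- function(coords, elements, bonds = NULL) {
  dm <- geometric_distance_matrix(coords)
  if (any(dm[upper.tri(dm)] < 1e-6)) {
    stop("coincident atoms: gravitational index undefined", call. = FALSE)
  }
  m <- element_property(elements, "mass")
  pair <- which(upper.tri(dm), arr.ind = TRUE)
  g_all <- sum(m[pair[, 1]] * m[pair[, 2]] / dm[pair]^2)
  g_bond <- NA_real_
  if (!is.null(bonds) && nrow(bonds) > 0) {
    r_b <- dm[cbind(bonds$i, bonds$j)]
    g_bond <- sum(m[bonds$i] * m[bonds$j] / r_b^2)
  }
  c(grav_all = g_all, grav_all_sqrt = sqrt(g_all), grav_all_cbrt = g_all^(1 / 3),
    grav_bonded = g_bond, grav_bonded_sqrt = sqrt(g_bond),
    grav_bonded_cbrt = g_bond^(1 / 3))
}

#' Principal moments of inertia
#'
#' Eigenvalues of the inertia tensor about the centre of mass, sorted
#' ascending, plus the three pairwise ratios. Ratios with a denominator
#' below 1e-10 amu Angstrom^2 (e.g. a linear molecule's smallest moment)
#' are flagged `NA` rather than returned as huge numbers.
#'
#' @inheritParams morse
#' @return Named vector `inertia_1..3` (amu Angstrom^2) and
#'   `inertia_ratio_12`, `inertia_ratio_13`, `inertia_ratio_23`.
#' @export
inertia_moments <- function(coords, elements) {
  stopifnot_finite_coords(coords)
  if (nrow(coords) < 2) stop("need at least 2 atoms", call. = FALSE)
  m <- element_property(elements, "mass")
  com <- colSums(coords * m) / sum(m)
  rel <- sweep(coords, 2, com)
  r2 <- rowSums(rel^2)
  tensor <- diag(3) * sum(m * r2) - t(rel) %*% (rel * m)
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)  # clamp numerical negatives at -1e-13 scale
  ratio <- function(a, b) if (b < 1e-10) NA_real_ else a / b
  c(inertia_1 = ev[1], inertia_2 = ev[2], inertia_3 = ev[3],
    inertia_ratio_12 = ratio(ev[1], ev[2]),
    inertia_ratio_13 = ratio(ev[1], ev[3]),
    inertia_ratio_23 = ratio(ev[2], ev[3]))
}

#' Geometric (distance-matrix) shape indexes
#'
#' From the geometric distance matrix: per-atom eccentricity
#' `e_i = max_j r_ij`, geometric radius `R = min e_i`, geometric diameter
#' `D = max e_i`, and the 3D Petitjean index `(D - R) / R`. The "geometric
#' shape index" ships in two selectable variants because conventions differ
#' between toolkits: `"petitjean"` (default) is `(D - R) / R` again computed
#' on the geometric matrix; `"ratio"` is `D / R`.
#'
#' @inheritParams morse
#' @param shape_variant `"petitjean"` or `"ratio"`.
#' @return Named vector `geom_radius`, `geom_diameter` (Angstrom),
#'   `petitjean_3d`, `shape_index_3d` (dimensionless; `NA` when all atoms
#'   coincide).
#' @export
geometric_indexes <- function(coords, shape_variant = c("petitjean", "ratio")) {
  shape_variant <- match.arg(shape_variant)
  dm <- geometric_distance_matrix(coords)
  ecc <- apply(dm, 1, max)
  R <- min(ecc); D <- max(ecc)
  if (R < 1e-6) {
    return(c(geom_radius = R, geom_diameter = D,
             petitjean_3d = NA_real_, shape_index_3d = NA_real_))
  }
  shape <- if (shape_variant == "petitjean") (D - R) / R else D / R
  c(geom_radius = R, geom_diameter = D,
    petitjean_3d = (D - R) / R, shape_index_3d = shape)
}

#' Charged partial surface area (CPSA) descriptors
#'
#' The Stanton-Jurs set combining per-atom solvent-accessible surface areas
#' with partial charges: partial positive/negative surface areas (PPSA/PNSA,
#' three weightings each), their differences (DPSA), fractional (FPSA/FNSA)
#' and surface-weighted (WPSA/WNSA) forms, relative charge (RPCG/RNCG) and
#' relative charged surface (RPCS/RNCS), plus the atomic-charge-threshold
#' split TASA / TCSA (areas of atoms with |q| < 0.2 vs >= 0.2) and their
#' fractions RASA / RPSA.
#'
#' When no atom carries positive (or negative) charge, that half of the
#' family is flagged `NA` rather than zeroed — the difference matters when
#' averaging descriptor variability downstream.
#'
#' @param atom_area Per-atom accessible areas, Angstrom^2.
#' @param charges Per-atom partial charges, elementary-charge units.
#' @return Named vector of 30 CPSA descriptors (all prefixed `cpsa_`).
#' @export
cpsa <- function(atom_area, charges) {
  stopifnot(length(atom_area) == length(charges))
  if (anyNA(charges) || anyNA(atom_area)) {
    nm <- names(cpsa(c(1, 1), c(0.1, -0.1)))
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  tsa <- sum(atom_area)
  pos <- charges > 0
  neg <- charges < 0
  ppsa1 <- if (any(pos)) sum(atom_area[pos]) else NA_real_
  pnsa1 <- if (any(neg)) sum(atom_area[neg]) else NA_real_
  qpos <- sum(charges[pos]); qneg <- sum(charges[neg])
  ppsa2 <- qpos * ppsa1
  pnsa2 <- qneg * pnsa1
  ppsa3 <- if (any(pos)) sum(charges[pos] * atom_area[pos]) else NA_real_
  pnsa3 <- if (any(neg)) sum(charges[neg] * atom_area[neg]) else NA_real_
  rpcg <- if (any(pos)) max(charges[pos]) / qpos else NA_real_
  rncg <- if (any(neg)) min(charges[neg]) / qneg else NA_real_
  rpcs <- if (any(pos)) atom_area[pos][which.max(charges[pos])] * rpcg else NA_real_
  rncs <- if (any(neg)) atom_area[neg][which.min(charges[neg])] * rncg else NA_real_
  tasa <- sum(atom_area[abs(charges) < 0.2])
  tcsa <- sum(atom_area[abs(charges) >= 0.2])
  out <- c(
    tsa = tsa,
    ppsa1 = ppsa1, ppsa2 = ppsa2, ppsa3 = ppsa3,
    pnsa1 = pnsa1, pnsa2 = pnsa2, pnsa3 = pnsa3,
    dpsa1 = ppsa1 - pnsa1, dpsa2 = ppsa2 - pnsa2, dpsa3 = ppsa3 - pnsa3,
    fpsa1 = ppsa1 / tsa, fpsa2 = ppsa2 / tsa, fpsa3 = ppsa3 / tsa,
    fnsa1 = pnsa1 / tsa, fnsa2 = pnsa2 / tsa, fnsa3 = pnsa3 / tsa,
    wpsa1 = ppsa1 * tsa / 1000, wpsa2 = ppsa2 * tsa / 1000, wpsa3 = ppsa3 * tsa / 1000,
    wnsa1 = pnsa1 * tsa / 1000, wnsa2 = pnsa2 * tsa / 1000, wnsa3 = pnsa3 * tsa / 1000,
    rpcg = rpcg, rncg = rncg, rpcs = rpcs, rncs = rncs,
    tasa = tasa, tcsa = tcsa, rasa = tasa / tsa, rpsa = tcsa / tsa
  )
  stats::setNames(out, paste0("cpsa_", names(out)))
}

# Stable, documented descriptor ordering: CPSA block, geometric block,
# gravitational block, inertia block, then the 192 MoRSE values (schemes
# u, m, v, e, p, c; within each scheme s_index 1..32).
morse_names <- function() {
  schemes <- c("u", "m", "v", "e", "p", "c")
  as.vector(t(outer(schemes, 1:32, function(w, s) sprintf("morse_%s_%d", w, s))))
}

#' Names of the full descriptor inventory, in output order
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function() {
  c(names(cpsa(c(1, 1), c(0.1, -0.1))),
    c("geom_radius", "geom_diameter", "petitjean_3d", "shape_index_3d"),
    c("grav_all", "grav_all_sqrt", "grav_all_cbrt",
      "grav_bonded", "grav_bonded_sqrt", "grav_bonded_cbrt"),
    c("inertia_1", "inertia_2", "inertia_3",
      "inertia_ratio_12", "inertia_ratio_13", "inertia_ratio_23"),
    morse_names())
}

#' Compute the full 3D-descriptor vector for one conformer
#'
#' Concatenates the five descriptor families — CPSA, geometric indexes,
#' gravitational indexes, moments of inertia and 3D-MoRSE (32 scattering
#' indexes x 6 weighting schemes) — into one named vector with the stable
#' ordering of [descriptor_names()]. Values that are undefined for the given
#' input (e.g. charge-weighted MoRSE without charges) come back as `NA`,
#' never as a silent zero.
#'
#' @param mol A [molecule()] (topology, elements, optional charges).
#' @param coords Conformer coordinates; defaults to the molecule's own.
#' @param charges Per-atom charges; defaults to [resolve_charges()] output.
#' @param probe_radius,sasa_points Surface parameters, see
#'   [shrake_rupley_sasa()].
#' @param shape_variant See [geometric_indexes()].
#' @param charge_source See [resolve_charges()]; `"none"` skips charges, so
#'   CPSA and charge-weighted MoRSE are flagged `NA`.
#' @return Named numeric vector over [descriptor_names()].
#' @export
compute_descriptor_vector <- function(mol, coords = NULL, charges = NULL,
                                      probe_radius = 1.4, sasa_points = 960,
                                      shape_variant = "petitjean",
                                      charge_source = "auto") {
  if (is.null(coords)) coords <- coords_matrix(mol)
  el <- mol$atoms$element
  if (is.null(charges)) {
    charges <- if (identical(charge_source, "none")) {
      rep(NA_real_, length(el))
    } else {
      resolve_charges(mol, charge_source)
    }
  }
  sasa <- shrake_rupley_sasa(coords, el, probe_radius, sasa_points)
  mor <- unlist(lapply(c("u", "m", "v", "e", "p", "c"), function(w) {
    morse(coords, el, 1:32, scheme = w, charges = charges)
  }))
  names(mor) <- morse_names()
  out <- c(cpsa(sasa$atom_area, charges),
           geometric_indexes(coords, shape_variant),
           gravitational_indexes(coords, el, mol$bonds),
           inertia_moments(coords, el),
           mor)
  out[descriptor_names()]
}

#' Compute descriptor tables for a set of pose ensembles
#'
#' The tidy entry point of the descriptor stage: one row per (compound,
#' pose), metadata columns first, then every descriptor of
#' [descriptor_names()] in stable order. Partial charges are resolved once
#' per compound (they depend on topology, not geometry); surface areas are
#' recomputed per pose.
#'
#' @param ensembles List of [pose_ensemble()] objects (e.g. from
#'   [read_sdf_ensembles()] or [make_benchmark_dataset()]).
#' @inheritParams compute_descriptor_vector
#' @return Tibble with columns `compound_id`, `pose_rank` (file order),
#'   `docking_score`, then the descriptors.
#' @export
compute_descriptors <- function(ensembles, probe_radius = 1.4,
                                sasa_points = 960,
                                shape_variant = "petitjean",
                                charge_source = "auto") {
  rows <- purrr::map(ensembles, function(ens) {
    mol <- ens$molecule
    charges <- if (identical(charge_source, "none")) {
      rep(NA_real_, nrow(mol$atoms))
    } else {
      resolve_charges(mol, charge_source)
    }
    vals <- purrr::map(seq_along(ens$poses), function(p) {
      v <- compute_descriptor_vector(
        mol, ens$poses[[p]], charges = charges,
        probe_radius = probe_radius, sasa_points = sasa_points,
        shape_variant = shape_variant
      )
      tibble::as_tibble_row(c(list(compound_id = mol$id, pose_rank = p,
                                   docking_score = ens$scores[[p]]),
                              as.list(v)))
    })
    dplyr::bind_rows(vals)
  })
  dplyr::bind_rows(rows)
}

#' Write a descriptor table to CSV
#'
#' One row per (compound, pose); column order is stable across runs.
#'
#' @param desc Tibble from [compute_descriptors()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(desc, path) {
  readr::write_csv(desc, path)
  invisible(path)
}
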