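#' Synthetic benchmark specification
#'
#' Parameters of the seeded generator that stands in for a docking campaign:
#' per-compound ensembles of up to ten scored poses whose geometric spread
#' grows with rotatable-bond count and differs between an "active" and an
#' "inactive" population. Defaults define the package's reference benchmark
#' conditions; see the methods vignette for the rationale behind each value.
#'
#' Pose variability is injected in torsion space (each rotatable bond
#' perturbed independently), so a compound's spread scales with its
#' rotatable-bond count by construction — the causal structure the
#' downstream correlation analysis is meant to recover. The active class is
#' generated with larger torsional noise than the inactive class, planting a
#' class difference of the kind the group comparison measures.
#'
#' @param n_compounds Number of compounds (default 200).
#' @param rotbond_range Inclusive integer range of rotatable-bond counts,
#'   cycled uniformly over compounds (default 1..10).
#' @param n_poses Poses per compound, at most 10 (default 10).
#' @param torsion_noise_sd Named numeric, radians: per-class torsional noise
#'   (default active 0.35, inactive 0.20).
#' @param coordinate_jitter_sd Isotropic Cartesian jitter per atom, Angstrom
#'   (default 0.15).
#' @param score_noise_sd Noise on docking scores (default 0.5).
#' @param ambiguous_frac Fraction of compounds given an affinity between the
#'   activity thresholds, exercising the ambiguous-label path (default 0.1).
#' @param seed Master seed; every compound derives its own stream from
#'   `(seed, compound index)`, so the dataset is stable under changes of
#'   `n_compounds`.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 200, rotbond_range = c(1, 10),
                           n_poses = 10,
                           torsion_noise_sd = c(active = 0.35, inactive = 0.20),
                           coordinate_jitter_sd = 0.15, score_noise_sd = 0.5,
                           ambiguous_frac = 0.1, seed = 1) {
  stopifnot(n_poses >= 1, n_poses <= 10,
            all(torsion_noise_sd >= 0), coordinate_jitter_sd >= 0,
            score_noise_sd >= 0, length(rotbond_range) == 2,
            rotbond_range[1] >= 0, rotbond_range[2] >= rotbond_range[1])
  stopifnot(all(c("active", "inactive") %in% names(torsion_noise_sd)))
  structure(list(
    n_compounds = as.integer(n_compounds),
    rotbond_range = as.integer(rotbond_range),
    n_poses = as.integer(n_poses),
    torsion_noise_sd = torsion_noise_sd,
    coordinate_jitter_sd = coordinate_jitter_sd,
    score_noise_sd = score_noise_sd,
    ambiguous_frac = ambiguous_frac,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Build a branched-chain test molecule
#'
#' Deterministic heavy-atom skeleton with an exact number of rotatable
#' bonds: a zig-zag backbone of `n_rot + 3` atoms (ideal 1.5 Angstrom bonds,
#' tetrahedral angles) contributes exactly `n_rot` acyclic single bonds with
#' non-terminal ends; any remaining atoms are attached as terminal
#' decorations on interior backbone atoms, which leaves the rotatable count
#' unchanged. Elements cycle through C/N/O so that mass, electronegativity,
#' polarizability and charge weightings are all non-trivial.
#'
#' A path graph maximises internal edges, so `n_rot + 3` heavy atoms is the
#' minimum feasible size for `n_rot >= 1`.
#'
#' @param n_heavy Total heavy atoms (`>= n_rot + 3` when `n_rot >= 1`,
#'   `>= 2` otherwise).
#' @param n_rot Desired rotatable-bond count.
#' @param id Compound id.
#' @return A [molecule()].
#' @export
make_chain_molecule <- function(n_heavy, n_rot, id = "synthetic") {
  n_heavy <- as.integer(n_heavy); n_rot <- as.integer(n_rot)
  backbone <- if (n_rot > 0) n_rot + 3L else min(n_heavy, 3L)
  if (n_heavy < max(backbone, 2L)) {
    stop("infeasible: ", n_rot, " rotatable bonds need at least ",
         max(backbone, 2L), " heavy atoms", call. = FALSE)
  }
  # trans zig-zag backbone in the xy-plane
  theta <- (pi - acos(-1 / 3)) / 2           # half the tetrahedral supplement
  step <- 1.5
  xy <- matrix(0, backbone, 3)
  for (a in seq_len(backbone)[-1]) {
    dir <- c(cos(theta * ifelse(a %% 2 == 0, 1, -1)),
             sin(theta * ifelse(a %% 2 == 0, 1, -1)), 0)
    xy[a, ] <- xy[a - 1, ] + step * dir
  }
  coords <- xy
  bonds_i <- seq_len(backbone - 1L)
  bonds_j <- bonds_i + 1L
  # terminal decorations on interior backbone atoms (round-robin)
  n_extra <- n_heavy - backbone
  interior <- if (backbone > 2) 2:(backbone - 1L) else 1L
  golden <- pi * (3 - sqrt(5))
  for (e in seq_len(n_extra)) {
    host <- interior[(e - 1L) %% length(interior) + 1L]
    lap <- (e - 1L) %/% length(interior)
    dir <- c(0.45 * cos(golden * e), 0.45 * sin(golden * e),
             ifelse(lap %% 2 == 0, 1, -1))
    dir <- dir / sqrt(sum(dir^2))
    coords <- rbind(coords, coords[host, ] + step * dir)
    bonds_i <- c(bonds_i, host)
    bonds_j <- c(bonds_j, backbone + e)
  }
  elements <- rep(c("C", "C", "N", "C", "O", "C"), length.out = backbone)
  if (n_extra > 0) {
    elements <- c(elements, rep(c("O", "N", "C"), length.out = n_extra))
  }
  molecule(
    atoms = tibble::tibble(element = elements, x = coords[, 1],
                           y = coords[, 2], z = coords[, 3]),
    bonds = tibble::tibble(i = bonds_i, j = bonds_j, order = 1),
    id = id
  )
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Sample a synthetic pose ensemble for one molecule
#'
#' Each pose starts from the molecule's base conformer; every rotatable
#' torsion is perturbed by `N(0, torsion_noise_sd[label]^2)`, isotropic
#' Cartesian jitter and a random rigid motion (rotation + translation) are
#' added, and a docking score is assigned as a base value plus the pose's
#' torsional perturbation magnitude plus noise — so better-scored poses are,
#' on average, closer to the base geometry and top-k selection is
#' well-defined.
#'
#' Uses the current RNG state; seed it (or go through
#' [make_benchmark_dataset()]) for reproducibility.
#'
#' @param mol A [molecule()].
#' @param spec A [synthetic_spec()].
#' @param label `"active"` or `"inactive"` (selects the torsional noise
#'   scale).
#' @return A [pose_ensemble()].
#' @export
sample_pose_ensemble <- function(mol, spec, label = "active") {
  stopifnot(inherits(spec, "synthetic_spec"))
  noise_key <- if (label %in% names(spec$torsion_noise_sd)) label else "inactive"
  sd_t <- spec$torsion_noise_sd[[noise_key]]
  base <- coords_matrix(mol)
  b <- mol$bonds
  el <- mol$atoms$element
  heavy <- el != "H"
  deg <- tabulate(c(b$i[heavy[b$j]], b$j[heavy[b$i]]), nbins = nrow(base))
  rot_idx <- which(b$order == 1 & !b$in_ring & heavy[b$i] & heavy[b$j] &
                     deg[b$i] >= 2 & deg[b$j] >= 2)
  poses <- vector("list", spec$n_poses)
  scores <- numeric(spec$n_poses)
  for (p in seq_len(spec$n_poses)) {
    xyz <- base
    quality <- 0
    for (r in rot_idx) {
      dtheta <- stats::rnorm(1, 0, sd_t)
      quality <- quality + dtheta^2
      xyz <- rotate_torsion(xyz, b, b$i[r], b$j[r], dtheta)
    }
    if (spec$coordinate_jitter_sd > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$coordinate_jitter_sd),
                          nrow(xyz), 3)
    }
    xyz <- xyz %*% t(random_rotation()) +
      rep(stats::runif(3, -10, 10), each = nrow(xyz))
    poses[[p]] <- xyz
    scores[p] <- -8 + 2 * sqrt(quality) + stats::rnorm(1, 0, spec$score_noise_sd)
  }
  pose_ensemble(mol, poses, scores)
}

#' Generate the synthetic benchmark dataset
#'
#' Compounds span `rotbond_range` uniformly (cycled); activity classes
#' alternate 50/50 and carry class-specific torsional noise; affinities are
#' sampled log-uniformly inside the class's own range — below 100 nM for
#' actives, above 1000 nM for inactives — so labels round-trip through
#' [label_activity()], except for an `ambiguous_frac` slice whose affinity
#' falls between the thresholds. A third of compounds report IC50 instead of
#' Ki (at twice the Ki value), exercising the IC50/2 rule. Every compound
#' draws its own RNG stream from `(seed, index)`.
#'
#' With `dir` given, the dataset is also written as the SDF/CSV dialect
#' [read_sdf_ensembles()] and [read_activity_csv()] consume, plus a
#' `manifest.txt` of `key=value` generator parameters; regenerating from an
#' identical spec yields byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @return List of class `pose_benchmark`: `ensembles` (named list),
#'   `activity` (tibble `compound_id`, `ki_nm`, `ic50_nm`, `label`,
#'   `noise_class`), `manifest` (named list), and `files` when written.
#' @export
make_benchmark_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rb <- seq(spec$rotbond_range[1], spec$rotbond_range[2])
  ensembles <- list()
  act_rows <- list()
  for (i in seq_len(spec$n_compounds)) {
    set.seed(derive_seed(spec$seed, i))
    id <- sprintf("synt_%04d", i)
    n_rot <- rb[(i - 1) %% length(rb) + 1]
    # alternate classes, phase-shifted each rotbond cycle so that class and
    # rotatable-bond count stay unconfounded
    parity <- ((i - 1) + (i - 1) %/% length(rb)) %% 2
    noise_class <- if (parity == 0) "active" else "inactive"
    mol <- make_chain_molecule(n_heavy = max(n_rot + 3, 3) + 2, n_rot = n_rot,
                               id = id)
    ensembles[[id]] <- sample_pose_ensemble(mol, spec, noise_class)
    ambiguous <- stats::runif(1) < spec$ambiguous_frac
    ki <- if (ambiguous) {
      10^stats::runif(1, log10(100), log10(1000))
    } else if (noise_class == "active") {
      10^stats::runif(1, 0, log10(99))
    } else {
      10^stats::runif(1, log10(1001), 5)
    }
    as_ic50 <- i %% 3 == 0
    act_rows[[i]] <- tibble::tibble(
      compound_id = id,
      ki_nm = if (as_ic50) NA_real_ else ki,
      ic50_nm = if (as_ic50) 2 * ki else NA_real_,
      noise_class = noise_class
    )
  }
  activity <- dplyr::bind_rows(act_rows)
  activity$label <- label_activity(activity$ki_nm, activity$ic50_nm)
  manifest <- list(
    generator = "posestab_synthetic_benchmark",
    n_compounds = spec$n_compounds,
    rotbond_min = spec$rotbond_range[1], rotbond_max = spec$rotbond_range[2],
    n_poses = spec$n_poses,
    torsion_noise_sd_active = spec$torsion_noise_sd[["active"]],
    torsion_noise_sd_inactive = spec$torsion_noise_sd[["inactive"]],
    coordinate_jitter_sd = spec$coordinate_jitter_sd,
    score_noise_sd = spec$score_noise_sd,
    ambiguous_frac = spec$ambiguous_frac,
    seed = spec$seed
  )
  out <- structure(list(ensembles = ensembles, activity = activity,
                        manifest = manifest), class = "pose_benchmark")
  if (!is.null(dir)) out$files <- write_benchmark(out, dir)
  out
}

#' Write a benchmark dataset to disk
#'
#' @param bench A `pose_benchmark` from [make_benchmark_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named character vector `sdf`, `activity`, `manifest`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sdf = file.path(dir, "poses.sdf"),
             activity = file.path(dir, "activity.csv"),
             manifest = file.path(dir, "manifest.txt"))
  write_sdf_ensembles(bench$ensembles, paths[["sdf"]])
  readr::write_csv(bench$activity[, c("compound_id", "ki_nm", "ic50_nm")],
                   paths[["activity"]])
  writeLines(paste0(names(bench$manifest), "=",
                    vapply(bench$manifest, format, character(1))),
             paths[["manifest"]])
  invisible(paths)
}

#' Rebuild a benchmark from its manifest
#'
#' Reads `manifest.txt` and regenerates the identical dataset (the manifest
#' records every generator parameter including the seed).
#'
#' @param path Path to a manifest file.
#' @return A `pose_benchmark`, as from [make_benchmark_dataset()].
#' @export
replay_manifest <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  spec <- synthetic_spec(
    n_compounds = as.integer(vals[["n_compounds"]]),
    rotbond_range = c(as.integer(vals[["rotbond_min"]]),
                      as.integer(vals[["rotbond_max"]])),
    n_poses = as.integer(vals[["n_poses"]]),
    torsion_noise_sd = c(active = as.numeric(vals[["torsion_noise_sd_active"]]),
                         inactive = as.numeric(vals[["torsion_noise_sd_inactive"]])),
    coordinate_jitter_sd = as.numeric(vals[["coordinate_jitter_sd"]]),
    score_noise_sd = as.numeric(vals[["score_noise_sd"]]),
    ambiguous_frac = as.numeric(vals[["ambiguous_frac"]]),
    seed = as.integer(vals[["seed"]])
  )
  make_benchmark_dataset(spec)
}
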