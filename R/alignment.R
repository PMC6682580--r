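#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of one coordinate set onto
#' another with known atom correspondence, via SVD of the covariance matrix.
#' A reflection, if the SVD proposes one, is corrected by flipping the sign
#' of the smallest singular direction, so the returned rotation is always
#' proper (`det = +1`). Only atoms selected by `mask` drive the fit (and the
#' reported RMSD); by default all atoms do.
#'
#' @param moving n x 3 coordinates to be superposed.
#' @param reference n x 3 target coordinates.
#' @param mask Logical or integer atom selection; at least 3 non-collinear
#'   atoms are required for a unique rotation.
#' @return List of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom, over masked atoms). Apply as
#'   `coords %*% t(rotation) + translation` (rowwise).
#' @export
kabsch <- function(moving, reference, mask = NULL) {
  stopifnot_finite_coords(moving)
  stopifnot_finite_coords(reference)
  if (nrow(moving) != nrow(reference)) stop("atom counts differ", call. = FALSE)
  if (is.null(mask)) mask <- seq_len(nrow(moving))
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) < 3) stop("need >= 3 masked atoms for superposition", call. = FALSE)
  A <- moving[mask, , drop = FALSE]
  B <- reference[mask, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity guard: rank of the masked point cloud must be >= 2
  if (sum(svd(A0)$d > 1e-8 * max(1, max(abs(A0)))) < 2) {
    stop("masked atoms are collinear: rotation not unique", call. = FALSE)
  }
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cb - as.vector(R %*% ca)
  aligned <- A %*% t(R) + rep(translation, each = nrow(A))
  rmsd <- sqrt(mean(rowSums((aligned - B)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sup) {
  coords %*% t(sup$rotation) + rep(sup$translation, each = nrow(coords))
}

#' Atom-position variability across the top-k poses of one ensemble
#'
#' The positional counterpart of descriptor variability: the selected poses
#' are superposed onto the best-scoring pose (heavy atoms drive the fit,
#' since docking programs place hydrogens erratically), and each atom's
#' root-mean-square fluctuation about its mean aligned position is computed:
#' `rmsf_a = sqrt(mean_p ||x_pa - mu_a||^2)` (population divisor by default;
#' `ddof = 1` switches to the sample form). The compound-level value is the
#' mean RMSF over heavy atoms.
#'
#' @param ens A [pose_ensemble()].
#' @param k Poses to use (top-k by docking score). `NULL` uses all poses.
#' @param ddof 0 (population, default) or 1 (sample divisor).
#' @return List: `rmsf` (per atom, Angstrom; hydrogens included in the
#'   vector but not the mean), `mean_rmsf`, `n_poses_used`. `NULL` with a
#'   warning when fewer than 2 poses survive selection (compound skipped).
#' @export
ensemble_atom_std <- function(ens, k = NULL, ddof = 0) {
  sel <- if (is.null(k)) ens else select_top_k(ens, k)
  if (isTRUE(attr(sel, "skip")) || length(sel$poses) < 2) {
    warning("compound '", ens$molecule$id, "' skipped: fewer than 2 poses",
            call. = FALSE)
    return(NULL)
  }
  heavy <- sel$molecule$atoms$element != "H"
  ref_idx <- which.min(sel$scores)
  ref <- sel$poses[[ref_idx]]
  aligned <- lapply(sel$poses, function(p) {
    apply_superposition(p, kabsch(p, ref, mask = heavy))
  })
  n_pose <- length(aligned)
  n_atom <- nrow(ref)
  mu <- Reduce(`+`, aligned) / n_pose
  dev2 <- Reduce(`+`, lapply(aligned, function(p) rowSums((p - mu)^2)))
  rmsf <- sqrt(dev2 / (n_pose - ddof))
  list(rmsf = rmsf, mean_rmsf = mean(rmsf[heavy]), n_poses_used = n_pose)
}

#' Atom variability table for many ensembles
#'
#' Tidy wrapper over [ensemble_atom_std()]: one row per compound per `k`.
#' Compounds with fewer than 2 usable poses appear in the `skipped`
#' attribute, never silently vanish.
#'
#' @param ensembles List of [pose_ensemble()] objects.
#' @param k Integer vector of ensemble depths (default `c(3, 5, 10)`).
#' @inheritParams ensemble_atom_std
#' @return Tibble `compound_id`, `k`, `n_poses_used`, `atom_std` (Angstrom),
#'   with attribute `skipped` (tibble of compound_id, k, reason).
#' @export
atom_variability <- function(ensembles, k = c(3, 5, 10), ddof = 0) {
  grid <- tidyr::expand_grid(id = names(ensembles), k = as.integer(k))
  skipped <- list()
  rows <- purrr::pmap(grid, function(id, k) {
    res <- withCallingHandlers(
      ensemble_atom_std(ensembles[[id]], k = k, ddof = ddof),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(res)) {
      skipped[[length(skipped) + 1]] <<- tibble::tibble(
        compound_id = id, k = k, reason = "fewer than 2 poses")
      return(NULL)
    }
    tibble::tibble(compound_id = id, k = k,
                   n_poses_used = res$n_poses_used, atom_std = res$mean_rmsf)
  })
  empty_skip <- tibble::tibble(compound_id = character(), k = integer(),
                               reason = character())
  out <- dplyr::bind_rows(c(list(tibble::tibble(
    compound_id = character(), k = integer(),
    n_poses_used = integer(), atom_std = numeric())), rows))
  attr(out, "skipped") <- dplyr::bind_rows(c(list(empty_skip), skipped))
  out
}
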