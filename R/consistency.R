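#' Fit a descriptor standardization model
#'
#' Per-descriptor z-scaling parameters (mean, standard deviation) computed
#' over every (compound, pose) row of a descriptor table. Raw descriptor
#' scales differ by orders of magnitude (a gravitational index in the
#' thousands vs a Petitjean index below 1), so averaging raw standard
#' deviations "over all descriptors" would be dominated by the largest-scale
#' family; standardization makes the average scale-free. Descriptors with
#' (near-)zero variance (sd < 1e-12) or more than 50% undefined entries are
#' dropped and recorded.
#'
#' @param desc Descriptor tibble from [compute_descriptors()] (>= 2 rows).
#' @return Object of class `standardization`: list with `center`, `scale`
#'   (named vectors over retained descriptors) and `dropped` (tibble of
#'   descriptor, reason).
#' @export
fit_standardization <- function(desc) {
  if (nrow(desc) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  cols <- descriptor_columns(desc)
  center <- scale_ <- stats::setNames(numeric(length(cols)), cols)
  dropped <- list()
  for (cn in cols) {
    x <- desc[[cn]]
    na_frac <- mean(is.na(x))
    if (na_frac > 0.5) {
      dropped[[cn]] <- "majority undefined"
      next
    }
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12) {
      dropped[[cn]] <- "zero variance"
      next
    }
    center[[cn]] <- mean(x, na.rm = TRUE)
    scale_[[cn]] <- s
  }
  keep <- setdiff(cols, names(dropped))
  structure(list(
    center = center[keep], scale = scale_[keep],
    dropped = tibble::tibble(descriptor = names(dropped),
                             reason = unlist(dropped, use.names = FALSE))
  ), class = "standardization")
}

#' @export
print.standardization <- function(x, ...) {
  cat(sprintf("<standardization> %d descriptors retained, %d dropped\n",
              length(x$center), nrow(x$dropped)))
  invisible(x)
}

#' Apply (or invert) a standardization model
#'
#' @param object A [fit_standardization()] model.
#' @param new_data Descriptor tibble.
#' @param inverse Undo the scaling instead of applying it.
#' @param ... Unused.
#' @return Tibble with metadata columns unchanged, retained descriptors
#'   z-scaled (or restored), dropped descriptors removed.
#' @export
predict.standardization <- function(object, new_data, inverse = FALSE, ...) {
  keep <- names(object$center)
  meta <- intersect(names(new_data), c("compound_id", "pose_rank", "docking_score"))
  out <- new_data[, c(meta, keep)]
  for (cn in keep) {
    out[[cn]] <- if (inverse) {
      new_data[[cn]] * object$scale[[cn]] + object$center[[cn]]
    } else {
      (new_data[[cn]] - object$center[[cn]]) / object$scale[[cn]]
    }
  }
  out
}

#' Per-compound descriptor variability over poses
#'
#' The pose-consistency score of one compound: for each retained descriptor,
#' the standard deviation of its (standardized) value across that compound's
#' selected poses; the compound's score is the mean of those standard
#' deviations over descriptors. Undefined entries are excluded per
#' descriptor; a compound whose descriptors are all undefined is reported as
#' `NA` (callers skip it with a reason).
#'
#' @param rows Standardized descriptor rows of one compound's top-k poses
#'   (>= 2 rows).
#' @param ddof 0 (population, default) or 1 (sample divisor).
#' @return Non-negative scalar, or `NA` if nothing is defined.
#' @export
compound_descriptor_std <- function(rows, ddof = 0) {
  if (nrow(rows) < 2) stop("need >= 2 poses", call. = FALSE)
  cols <- descriptor_columns(rows)
  stds <- vapply(cols, function(cn) std_dev(rows[[cn]], ddof = ddof), numeric(1))
  if (all(is.na(stds))) return(NA_real_)
  mean(stds, na.rm = TRUE)
}

#' Full pose-consistency analysis of a set of ensembles
#'
#' The pipeline's main entry point. For each requested ensemble depth `k`,
#' poses are restricted to the top-k by docking score, descriptors are
#' z-standardized over all retained (compound, pose) rows at that depth, and
#' each compound receives a descriptor-variability score
#' ([compound_descriptor_std()]) and an atom-position variability score
#' ([ensemble_atom_std()]), alongside its rotatable-bond count and activity
#' label.
#'
#' @param ensembles Named list of [pose_ensemble()] objects.
#' @param activity Optional tibble with `compound_id` and `label` (e.g. from
#'   [read_activity_csv()]); compounds without a record get label
#'   `"unknown"`.
#' @param k Integer vector of depths; the workflow's standard choices are 3,
#'   5 and 10.
#' @param desc Optional precomputed [compute_descriptors()] table (saves the
#'   dominant cost when analysing several `k`).
#' @param standardize Z-scale descriptors before the per-compound std
#'   (default `TRUE`); the raw-scale mode is mainly useful together with
#'   [per_descriptor_std_summary()].
#' @param ddof Std divisor, see [compound_descriptor_std()].
#' @param ... Passed to [compute_descriptors()] when `desc` is missing.
#' @return Tibble of class `pose_consistency`: `compound_id`, `k`,
#'   `n_poses_used`, `descriptor_std`, `atom_std`, `n_rot`, `label`; skipped
#'   compounds in the `skipped` attribute, dropped descriptors per depth in
#'   the `dropped` attribute.
#' @export
pose_consistency <- function(ensembles, activity = NULL, k = c(3, 5, 10),
                             desc = NULL, standardize = TRUE, ddof = 0, ...) {
  stopifnot(length(ensembles) > 0)
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles)))) {
    names(ensembles) <- vapply(ensembles, function(e) e$molecule$id, character(1))
  }
  if (is.null(desc)) desc <- compute_descriptors(ensembles, ...)
  n_rot <- vapply(ensembles, function(e) count_rotatable_bonds(e$molecule), integer(1))
  atom_tbl <- atom_variability(ensembles, k = k, ddof = ddof)
  skipped <- attr(atom_tbl, "skipped")
  dropped <- list()

  per_k <- purrr::map(as.integer(k), function(kk) {
    # rows entering the depth-kk analysis: top-kk poses of each compound
    sel <- desc |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::arrange(.data$docking_score, .data$pose_rank, .by_group = TRUE) |>
      dplyr::slice_head(n = kk) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::ungroup()
    if (nrow(sel) == 0) return(NULL)
    z <- if (standardize) {
      model <- fit_standardization(sel)
      dropped[[as.character(kk)]] <<- model$dropped
      predict(model, sel)
    } else {
      sel
    }
    z |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::group_modify(function(rows, key) {
        tibble::tibble(
          descriptor_std = compound_descriptor_std(rows, ddof = ddof),
          n_poses_used = nrow(rows))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(k = kk)
  })

  out <- dplyr::bind_rows(per_k) |>
    dplyr::left_join(atom_tbl[, c("compound_id", "k", "atom_std")],
                     by = c("compound_id", "k")) |>
    dplyr::mutate(n_rot = unname(n_rot[.data$compound_id]))
  lab <- if (!is.null(activity)) {
    stats::setNames(activity$label, activity$compound_id)
  } else {
    character()
  }
  out$label <- dplyr::coalesce(unname(lab[out$compound_id]), "unknown")
  out <- out[, c("compound_id", "k", "n_poses_used", "descriptor_std",
                 "atom_std", "n_rot", "label")]
  out <- tibble::new_tibble(out, class = "pose_consistency")
  attr(out, "skipped") <- skipped
  attr(out, "dropped") <- dropped
  out
}

#' Group summary of variability by activity class
#'
#' The actives-vs-inactives comparison: per ensemble depth `k`, the mean
#' descriptor variability and mean atom-position variability of the active
#' and the inactive population, with an indicator for whether actives came
#' out higher (the analog of bolding in a comparison table). Ambiguous and
#' unlabeled compounds are excluded; an empty class yields `NA` cells (a
#' missing group is not a zero).
#'
#' @param records A [pose_consistency()] tibble.
#' @return Tibble per `k`: `n_active`, `n_inactive`,
#'   `descriptor_std_active`, `descriptor_std_inactive`, `atom_std_active`,
#'   `atom_std_inactive`, `descriptor_actives_higher`, `atom_actives_higher`.
#' @export
summarize_groups <- function(records) {
  records |>
    dplyr::filter(.data$label %in% c("active", "inactive")) |>
    dplyr::group_by(.data$k, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      descriptor_std = mean(.data$descriptor_std, na.rm = TRUE),
      atom_std = mean(.data$atom_std, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "label",
                       values_from = c("n", "descriptor_std", "atom_std")) |>
    (\(tb) {
      for (cn in c("n_active", "n_inactive", "descriptor_std_active",
                   "descriptor_std_inactive", "atom_std_active",
                   "atom_std_inactive")) {
        if (!cn %in% names(tb)) tb[[cn]] <- NA_real_
      }
      tb
    })() |>
    dplyr::mutate(
      descriptor_actives_higher = .data$descriptor_std_active > .data$descriptor_std_inactive,
      atom_actives_higher = .data$atom_std_active > .data$atom_std_inactive
    ) |>
    dplyr::select("k", "n_active", "n_inactive",
                  "descriptor_std_active", "descriptor_std_inactive",
                  "atom_std_active", "atom_std_inactive",
                  "descriptor_actives_higher", "atom_actives_higher")
}

#' Correlation of descriptor variability with rotatable-bond count
#'
#' Pearson product-moment correlation between a compound's rotatable-bond
#' count and its mean descriptor std, per ensemble depth `k`. All labeled
#' and unlabeled compounds contribute (the flexibility-variability relation
#' is not an activity comparison). Zero variance in either variable flags
#' the coefficient `NA`.
#'
#' @param records A [pose_consistency()] tibble.
#' @return Tibble `k`, `r`, `n`.
#' @export
rotbond_correlation <- function(records) {
  records |>
    dplyr::filter(is.finite(.data$descriptor_std), is.finite(.data$n_rot)) |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      r = if (dplyr::n() >= 3 &&
              stats::sd(.data$n_rot) > 0 && stats::sd(.data$descriptor_std) > 0) {
        stats::cor(.data$n_rot, .data$descriptor_std)
      } else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-descriptor variability summary
#'
#' Which descriptors are stable across poses and which are not: for every
#' descriptor, the std across each compound's selected poses, averaged over
#' compounds — reported on the standardized scale (`mean_std`) and on the
#' raw scale (`mean_std_raw`) — sorted ascending by the standardized value.
#' Conformation-independent descriptors (the first 3D-MoRSE scattering
#' index) sit at the bottom of this ranking; distance-matrix shape indexes
#' tend to sit at the top.
#'
#' @param desc Descriptor tibble from [compute_descriptors()].
#' @param k Optional depth: restrict each compound to its top-k poses first.
#' @param ddof Std divisor.
#' @return Tibble `descriptor`, `mean_std`, `mean_std_raw`, `n_compounds`.
#' @export
per_descriptor_std_summary <- function(desc, k = NULL, ddof = 0) {
  if (!is.null(k)) {
    desc <- desc |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::arrange(.data$docking_score, .data$pose_rank, .by_group = TRUE) |>
      dplyr::slice_head(n = as.integer(k)) |>
      dplyr::ungroup()
  }
  desc <- desc |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
  model <- fit_standardization(desc)
  cols <- descriptor_columns(desc)
  per_cpd_std <- function(tbl, cn) {
    tbl |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::summarise(s = std_dev(.data[[cn]], ddof = ddof), .groups = "drop")
  }
  z <- predict(model, desc)
  rows <- purrr::map(cols, function(cn) {
    raw <- per_cpd_std(desc, cn)
    standardized <- if (cn %in% names(model$center)) {
      mean(per_cpd_std(z, cn)$s, na.rm = TRUE)
    } else {
      # dropped from the z-model (constant or majority-undefined): its raw
      # per-compound stds are still reported; standardized mean shown as raw/1
      mean(raw$s, na.rm = TRUE)
    }
    tibble::tibble(descriptor = cn,
                   mean_std = standardized,
                   mean_std_raw = mean(raw$s, na.rm = TRUE),
                   n_compounds = sum(is.finite(raw$s)))
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$mean_std)
}

#' Write the four consistency result tables
#'
#' `consistency.csv` (one row per compound x k), `groups.csv` (activity-class
#' summary), `correlations.csv` (rotatable-bond correlations) and
#' `per_descriptor.csv` (per-descriptor variability ranking), plus
#' `skipped.csv` when any compound was dropped. Byte-stable for identical
#' inputs.
#'
#' @param records A [pose_consistency()] result.
#' @param desc The descriptor table the records were computed from.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_consistency_outputs <- function(records, desc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    consistency = file.path(dir, "consistency.csv"),
    groups = file.path(dir, "groups.csv"),
    correlations = file.path(dir, "correlations.csv"),
    per_descriptor = file.path(dir, "per_descriptor.csv")
  )
  readr::write_csv(records, paths[["consistency"]])
  readr::write_csv(summarize_groups(records), paths[["groups"]])
  readr::write_csv(rotbond_correlation(records), paths[["correlations"]])
  readr::write_csv(per_descriptor_std_summary(desc), paths[["per_descriptor"]])
  skipped <- attr(records, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0) {
    paths <- c(paths, skipped = file.path(dir, "skipped.csv"))
    readr::write_csv(skipped, paths[["skipped"]])
  }
  invisible(paths)
}
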