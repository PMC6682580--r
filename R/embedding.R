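#' Per-compound descriptor variability vectors
#'
#' The feature matrix behind the 2D map: for each compound, the std of every
#' retained (standardized) descriptor across its top-k poses — one column
#' per descriptor, rather than the single averaged score of
#' [pose_consistency()].
#'
#' @param desc Descriptor tibble from [compute_descriptors()].
#' @param k Optional depth (top-k poses per compound).
#' @param ddof Std divisor.
#' @return Tibble: `compound_id` plus one `std_`-prefixed column per
#'   retained descriptor.
#' @export
descriptor_std_vectors <- function(desc, k = NULL, ddof = 0) {
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
  z <- predict(fit_standardization(desc), desc)
  cols <- descriptor_columns(z)
  z |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols),
                                   \(x) std_dev(x, ddof = ddof)),
                     .groups = "drop") |>
    dplyr::rename_with(\(nm) paste0("std_", nm), dplyr::all_of(cols))
}

#' Embed variability vectors into 2D
#'
#' Deterministic 2D projection of per-compound vectors for visual
#' inspection: `"pca"` projects onto the top two principal axes; `"mds"`
#' runs classical metric scaling on Euclidean distances. Both are exact
#' linear-algebra methods with no random state, so repeated runs are
#' identical (a plug-in point for stochastic neighbour embeddings is the
#' `method` argument of downstream code, not this function). Feature
#' columns are z-scaled first; constant columns are ignored.
#'
#' @param vectors Tibble with `compound_id`, optional `label`, and numeric
#'   feature columns (e.g. [descriptor_std_vectors()] output, optionally
#'   joined with labels). At least 3 rows.
#' @param method `"pca"` or `"mds"`.
#' @return Object of class `pose_embedding`: list with `points` (tibble
#'   `compound_id`, `x`, `y`, `label`), `method`, `params`.
#' @export
embed_vectors <- function(vectors, method = c("pca", "mds")) {
  method <- match.arg(method)
  stopifnot(nrow(vectors) >= 3, "compound_id" %in% names(vectors))
  label <- if ("label" %in% names(vectors)) vectors$label else
    rep("unknown", nrow(vectors))
  feat <- as.matrix(vectors[, vapply(vectors, is.numeric, logical(1)), drop = FALSE])
  feat[!is.finite(feat)] <- 0
  sds <- apply(feat, 2, stats::sd)
  keep <- is.finite(sds) & sds > 1e-12
  if (!any(keep)) {
    warning("all feature columns constant: every point placed at the origin",
            call. = FALSE)
    xy <- matrix(0, nrow(vectors), 2)
  } else {
    feat <- scale(feat[, keep, drop = FALSE])
    xy <- if (method == "pca") {
      pc <- stats::prcomp(feat, center = FALSE, scale. = FALSE)
      sc <- pc$x
      if (ncol(sc) < 2) sc <- cbind(sc, 0)
      sc[, 1:2]
    } else {
      stats::cmdscale(stats::dist(feat), k = 2)
    }
  }
  structure(list(
    points = tibble::tibble(compound_id = vectors$compound_id,
                            x = xy[, 1], y = xy[, 2],
                            label = dplyr::coalesce(label, "unknown")),
    method = method,
    params = list(n_features = sum(keep))
  ), class = "pose_embedding")
}

#' @export
print.pose_embedding <- function(x, ...) {
  cat(sprintf("<pose_embedding> %s, %d points, %d features\n",
              x$method, nrow(x$points), x$params$n_features))
  invisible(x)
}

#' Export an embedding for interactive inspection
#'
#' One machine-readable table mapping each plotted point to its compound:
#' coordinates, activity label, the red/black colour convention (actives
#' red, inactives black, anything else grey), the consistency scores and an
#' optional structure line notation. Written as CSV or JSON-lines; a round
#' trip through the CSV reader reproduces the table exactly.
#'
#' @param embedding A [embed_vectors()] result.
#' @param records A [pose_consistency()] tibble (one `k`; supplies
#'   `descriptor_std`, `atom_std`, `n_rot`). Every embedded compound must
#'   appear here.
#' @param smiles Optional named character vector of structure strings,
#'   indexed by compound id.
#' @param path Optional output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return The export tibble (invisibly when `path` is given).
#' @export
export_viz <- function(embedding, records, smiles = NULL, path = NULL,
                       format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(embedding, "pose_embedding"))
  pts <- embedding$points
  orphans <- setdiff(pts$compound_id, records$compound_id)
  if (length(orphans)) {
    stop("compound id(s) missing from records: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  rec <- records[, c("compound_id", "descriptor_std", "atom_std", "n_rot")]
  out <- pts |>
    dplyr::left_join(rec, by = "compound_id") |>
    dplyr::mutate(
      label = dplyr::if_else(is.na(.data$label) | .data$label == "",
                             "unknown", .data$label),
      color = dplyr::case_when(
        .data$label == "active" ~ "red",
        .data$label == "inactive" ~ "black",
        .default = "gray"
      ),
      smiles = if (is.null(smiles)) NA_character_ else
        unname(smiles[.data$compound_id])
    ) |>
    dplyr::select("compound_id", "x", "y", "label", "color",
                  "descriptor_std", "atom_std", "n_rot", "smiles")
  if (!is.null(path)) {
    if (format == "csv") {
      readr::write_csv(out, path)
    } else {
      con <- file(path, open = "w")
      on.exit(close(con))
      for (r in seq_len(nrow(out))) {
        writeLines(jsonlite::toJSON(as.list(out[r, ]), auto_unbox = TRUE,
                                    digits = NA, na = "null"), con)
      }
    }
    return(invisible(out))
  }
  out
}
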