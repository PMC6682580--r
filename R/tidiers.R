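#' Tidy a standardization model
#'
#' @param x A [fit_standardization()] model.
#' @param ... Unused.
#' @return Tibble `descriptor`, `center`, `scale`, `dropped`, `reason`.
#' @method tidy standardization
#' @export
tidy.standardization <- function(x, ...) {
  kept <- tibble::tibble(descriptor = names(x$center),
                         center = unname(x$center),
                         scale = unname(x$scale),
                         dropped = FALSE, reason = NA_character_)
  if (nrow(x$dropped) > 0) {
    kept <- dplyr::bind_rows(kept, dplyr::mutate(x$dropped, center = NA_real_,
                                                 scale = NA_real_,
                                                 dropped = TRUE))
  }
  kept[, c("descriptor", "center", "scale", "dropped", "reason")]
}

#' @rdname tidy.standardization
#' @method glance standardization
#' @export
glance.standardization <- function(x, ...) {
  tibble::tibble(n_retained = length(x$center), n_dropped = nrow(x$dropped))
}

#' Tidy an embedding
#'
#' @param x A [embed_vectors()] result.
#' @param ... Unused.
#' @return The points tibble (`compound_id`, `x`, `y`, `label`).
#' @method tidy pose_embedding
#' @export
tidy.pose_embedding <- function(x, ...) x$points

#' @rdname tidy.pose_embedding
#' @method glance pose_embedding
#' @export
glance.pose_embedding <- function(x, ...) {
  tibble::tibble(method = x$method, n_points = nrow(x$points),
                 n_features = x$params$n_features)
}

#' One-row summary of a pose-consistency analysis
#'
#' @param x A [pose_consistency()] tibble.
#' @param ... Unused.
#' @return Tibble with compound counts and the correlation at the deepest
#'   `k`.
#' @method glance pose_consistency
#' @export
glance.pose_consistency <- function(x, ...) {
  ct <- rotbond_correlation(x)
  deepest <- ct[which.max(ct$k), ]
  tibble::tibble(
    n_compounds = length(unique(x$compound_id)),
    n_k = length(unique(x$k)),
    n_active = sum(x$label == "active" & x$k == max(x$k)),
    n_inactive = sum(x$label == "inactive" & x$k == max(x$k)),
    r_rotbond_deepest_k = deepest$r
  )
}
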