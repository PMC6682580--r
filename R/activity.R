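#' Label compound activity from Ki / IC50
#'
#' Applies the affinity thresholds this analysis uses to split compounds into
#' populations: a compound is *active* when its effective Ki is below 100 nM
#' and *inactive* when above 1000 nM; everything in between — including the
#' boundary values themselves, since the cuts are strict — is *ambiguous* and
#' excluded from group statistics. When only an IC50 is known the effective
#' Ki is taken as IC50 / 2; when both are given, Ki wins.
#'
#' @param ki_nm Ki in nM (vector; `NA` where unknown).
#' @param ic50_nm IC50 in nM (vector; `NA` where unknown).
#' @return Character vector in `{"active", "inactive", "ambiguous"}`.
#' @examples
#' label_activity(ki_nm = c(50, 500, 2000))
#' label_activity(ic50_nm = 150)  # effective Ki 75 -> active
#' @export
label_activity <- function(ki_nm = NULL, ic50_nm = NULL) {
  n <- max(length(ki_nm), length(ic50_nm))
  if (n == 0) stop("provide ki_nm and/or ic50_nm", call. = FALSE)
  ki <- rep_len(if (is.null(ki_nm)) NA_real_ else as.numeric(ki_nm), n)
  ic <- rep_len(if (is.null(ic50_nm)) NA_real_ else as.numeric(ic50_nm), n)
  if (any(is.na(ki) & is.na(ic))) {
    stop("at least one of ki_nm, ic50_nm must be given per compound", call. = FALSE)
  }
  if (any(ki <= 0, na.rm = TRUE) || any(ic <= 0, na.rm = TRUE)) {
    stop("affinity values must be positive", call. = FALSE)
  }
  eff <- ifelse(is.na(ki), ic / 2, ki)
  dplyr::case_when(
    eff < 100 ~ "active",
    eff > 1000 ~ "inactive",
    .default = "ambiguous"
  )
}

#' Read an activity side table
#'
#' CSV with columns `compound_id`, `ki_nm`, `ic50_nm` (either affinity column
#' may be empty per row, not both). A `label` column is derived via
#' [label_activity()].
#'
#' @param path CSV file path.
#' @return Tibble with `compound_id`, `ki_nm`, `ic50_nm`, `label`.
#' @export
read_activity_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    ki_nm = readr::col_double(),
    ic50_nm = readr::col_double()
  ))
  tbl$label <- label_activity(tbl$ki_nm, tbl$ic50_nm)
  tbl
}
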