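# Internal helpers shared across modules.

# Derive a per-item RNG seed from a master seed so that item i's stream does
# not depend on how many items precede it. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1009) %% 2147483647)
}

stopifnot_finite_coords <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) != 3) {
    stop("coordinates must be an n x 3 matrix", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  invisible(coords)
}

# Population (ddof = 0) or sample (ddof = 1) standard deviation.
std_dev <- function(x, ddof = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / (n - ddof))
}

# Columns of a descriptor table that hold descriptor values (not metadata).
descriptor_columns <- function(tbl) {
  setdiff(names(tbl), c("compound_id", "pose_rank", "docking_score", "label"))
}
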