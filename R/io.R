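#' Read pose ensembles from a multi-conformer SDF file
#'
#' Parses a V2000 SDF (via ChemmineR) in which each record is one docking
#' pose. Records are grouped into per-compound ensembles by a compound-id SD
#' tag; the per-record docking score is read from a score SD tag and
#' per-atom partial charges, when present, from a comma-separated charge tag.
#' Pose order within a compound follows file order.
#'
#' Malformed records are skipped with a warning (count retrievable from the
#' `skipped_records` attribute); a record with no score raises an error; a
#' compound whose records disagree on atom count or element sequence is
#' rejected wholesale and listed in the `rejected_compounds` attribute.
#'
#' @param path SDF file.
#' @param score_tag SD tag holding the docking score (default the Glide
#'   export name `"r_i_docking_score"`).
#' @param id_tag SD tag holding the compound id.
#' @param charge_tag SD tag holding comma-separated per-atom partial charges.
#' @return Named list of [pose_ensemble()] objects (empty for an empty file),
#'   with attributes `skipped_records` (integer) and `rejected_compounds`
#'   (character).
#' @export
read_sdf_ensembles <- function(path, score_tag = "r_i_docking_score",
                               id_tag = "compound_id",
                               charge_tag = "atom.dprop.PartialCharge") {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    out <- list()
    attr(out, "skipped_records") <- 0L
    attr(out, "rejected_compounds") <- character()
    return(out)
  }
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdf)
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    warning(n_skip, " malformed SDF record(s) skipped", call. = FALSE)
    sdf <- sdf[ok]
  }

  records <- lapply(seq_along(ChemmineR::cid(sdf)), function(r) {
    one <- sdf[[r]]
    ab <- ChemmineR::atomblock(one)
    bb <- ChemmineR::bondblock(one)
    dat <- ChemmineR::datablock(one)
    id <- if (id_tag %in% names(dat)) dat[[id_tag]] else ChemmineR::header(one)[["Molecule_Name"]]
    if (!score_tag %in% names(dat) || !nzchar(dat[[score_tag]])) {
      stop("SDF record ", r, " (", id, ") lacks the '", score_tag,
           "' docking-score tag", call. = FALSE)
    }
    score <- suppressWarnings(as.numeric(dat[[score_tag]]))
    if (is.na(score)) stop("non-numeric docking score in record ", r, call. = FALSE)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    charges <- NULL
    if (charge_tag %in% names(dat) && nzchar(dat[[charge_tag]])) {
      charges <- as.numeric(strsplit(dat[[charge_tag]], ",", fixed = TRUE)[[1]])
      if (length(charges) != length(elements)) charges <- NULL
    }
    bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
      tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                     order = as.numeric(bb[, 3]))
    } else {
      tibble::tibble(i = integer(), j = integer(), order = numeric())
    }
    list(id = id, elements = elements, coords = coords, bonds = bonds,
         score = score, charges = charges)
  })

  ids <- vapply(records, `[[`, character(1), "id")
  rejected <- character()
  ensembles <- list()
  for (id in unique(ids)) {
    grp <- records[ids == id]
    first <- grp[[1]]
    same <- vapply(grp, function(g) {
      length(g$elements) == length(first$elements) &&
        all(g$elements == first$elements)
    }, logical(1))
    if (!all(same)) {
      rejected <- c(rejected, id)
      next
    }
    atoms <- tibble::tibble(
      element = first$elements,
      x = first$coords[, 1], y = first$coords[, 2], z = first$coords[, 3],
      charge = if (is.null(first$charges)) NA_real_ else first$charges
    )
    mol <- molecule(atoms, first$bonds, id = id)
    ensembles[[id]] <- pose_ensemble(
      mol,
      poses = lapply(grp, `[[`, "coords"),
      scores = vapply(grp, `[[`, numeric(1), "score")
    )
  }
  if (length(rejected)) {
    warning("rejected compound(s) with inconsistent atoms: ",
            paste(rejected, collapse = ", "), call. = FALSE)
  }
  attr(ensembles, "skipped_records") <- n_skip
  attr(ensembles, "rejected_compounds") <- rejected
  ensembles
}

#' Write pose ensembles to a multi-conformer SDF file
#'
#' Emits one V2000 record per pose with the compound id, docking score and
#' (when present on the molecule) per-atom partial charges as SD tags, in the
#' same dialect [read_sdf_ensembles()] consumes. Formatting is fixed-width
#' and fully deterministic, so identical ensembles always produce
#' byte-identical files.
#'
#' @param ensembles List of [pose_ensemble()] objects.
#' @param path Output file.
#' @inheritParams read_sdf_ensembles
#' @return `path`, invisibly.
#' @export
write_sdf_ensembles <- function(ensembles, path, score_tag = "r_i_docking_score",
                                id_tag = "compound_id",
                                charge_tag = "atom.dprop.PartialCharge") {
  out <- character()
  for (ens in ensembles) {
    mol <- ens$molecule
    n_atom <- nrow(mol$atoms)
    bonds <- mol$bonds
    for (p in seq_along(ens$poses)) {
      xyz <- ens$poses[[p]]
      block <- c(
        mol$id,
        "  posestab",
        "",
        sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atom, nrow(bonds)),
        sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element),
        if (nrow(bonds) > 0)
          sprintf("%3d%3d%3d  0", bonds$i, bonds$j, as.integer(bonds$order)),
        "M  END",
        sprintf(">  <%s>", id_tag), mol$id, "",
        sprintf(">  <%s>", score_tag), sprintf("%.6f", ens$scores[[p]]), ""
      )
      if (!anyNA(mol$atoms$charge)) {
        block <- c(block,
                   sprintf(">  <%s>", charge_tag),
                   paste(sprintf("%.6f", mol$atoms$charge), collapse = ","), "")
      }
      out <- c(out, block, "$$$$")
    }
  }
  writeLines(out, path)
  invisible(path)
}
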