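#' Construct a molecule
#'
#' The molecular data model every later stage consumes: an ordered atom table
#' (the atom order is the identity that links docking poses of one compound)
#' plus a bond graph. Ring membership of each bond is derived at construction
#' time: a bond lies in a ring exactly when it is not a bridge of the bond
#' graph.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (elementary-charge units; `NA` until computed or read
#'   from input).
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for aromatic).
#' @param id Compound identifier.
#' @return An object of class `molecule`: a list with tibbles `atoms` (gains
#'   no columns) and `bonds` (gains logical `in_ring`), and the `id`.
#' @examples
#' mol <- molecule(
#'   atoms = data.frame(element = c("C", "C", "O"),
#'                      x = c(0, 1.5, 2.2), y = c(0, 0, 1.2), z = 0),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1),
#'   id = "demo"
#' )
#' count_rotatable_bonds(mol)
#' @export
molecule <- function(atoms, bonds, id = "mol") {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  n <- nrow(atoms)
  element_property(atoms$element, "mass") # errors on unknown elements
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (nrow(bonds) > 0) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    if (any(bonds$i == bonds$j)) stop("self-loop bond", call. = FALSE)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      stop("bond index out of range", call. = FALSE)
    }
    if (!all(bonds$order %in% c(1, 2, 3, 4))) {
      stop("bond order must be 1, 2, 3 or 4 (aromatic)", call. = FALSE)
    }
    bonds$in_ring <- ring_bonds(n, bonds)
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(),
                            order = numeric(), in_ring = logical())
  }
  structure(list(atoms = atoms, bonds = bonds, id = id), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds, %d rotatable\n",
              x$id, nrow(x$atoms), nrow(x$bonds), count_rotatable_bonds(x)))
  invisible(x)
}

# A bond is part of a ring iff it is not a bridge of the bond graph.
ring_bonds <- function(n_atoms, bonds) {
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_atoms - igraph::vcount(g)))
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(bonds))
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Count rotatable bonds
#'
#' A bond counts as rotatable when it is a single, non-ring bond between two
#' heavy (non-hydrogen) atoms, each of which is bonded to at least one other
#' heavy atom — i.e. an acyclic single bond between two non-terminal heavy
#' atoms. The count depends only on the bond graph, never on coordinates or
#' atom order. Amide C-N bonds can optionally be excluded (off by default),
#' which eases cross-checks against toolkits that apply that convention.
#'
#' @param mol A [molecule()].
#' @param exclude_amide Exclude C-N single bonds where the carbon carries a
#'   double-bonded oxygen.
#' @return Non-negative integer.
#' @export
count_rotatable_bonds <- function(mol, exclude_amide = FALSE) {
  bonds <- mol$bonds
  if (nrow(bonds) == 0) return(0L)
  el <- mol$atoms$element
  heavy <- el != "H"
  # per-atom count of bonded heavy neighbours
  deg <- integer(length(el))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    if (heavy[j]) deg[i] <- deg[i] + 1L
    if (heavy[i]) deg[j] <- deg[j] + 1L
  }
  rot <- bonds$order == 1 & !bonds$in_ring &
    heavy[bonds$i] & heavy[bonds$j] &
    deg[bonds$i] >= 2L & deg[bonds$j] >= 2L
  if (exclude_amide && any(rot)) {
    carbonyl_c <- unique(c(
      bonds$i[bonds$order == 2 & el[bonds$j] == "O" & el[bonds$i] == "C"],
      bonds$j[bonds$order == 2 & el[bonds$i] == "O" & el[bonds$j] == "C"]
    ))
    amide <- (el[bonds$i] == "C" & el[bonds$j] == "N" & bonds$i %in% carbonyl_c) |
             (el[bonds$j] == "C" & el[bonds$i] == "N" & bonds$j %in% carbonyl_c)
    rot <- rot & !amide
  }
  sum(rot)
}

#' Pairwise geometric distance matrix
#'
#' @param coords n x 3 coordinate matrix in Angstrom.
#' @return Symmetric n x n matrix of Euclidean distances with zero diagonal.
#' @export
geometric_distance_matrix <- function(coords) {
  stopifnot_finite_coords(coords)
  if (nrow(coords) < 2) stop("need at least 2 atoms", call. = FALSE)
  as.matrix(stats::dist(coords))
}

#' Construct a pose ensemble
#'
#' Groups the docking poses of one compound: a shared topology (the
#' [molecule()], whose coordinates serve as reference geometry) plus one
#' coordinate set and one docking score per pose. Glide convention: lower
#' score is better. At most ten poses are accepted, matching the cap docking
#' runs in this workflow impose per ligand.
#'
#' @param mol A [molecule()].
#' @param poses List of n x 3 coordinate matrices, same atom count and order
#'   as `mol`.
#' @param scores Numeric docking scores, one per pose.
#' @return Object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(mol, poses, scores) {
  stopifnot(inherits(mol, "molecule"))
  n_pose <- length(poses)
  if (n_pose < 1 || n_pose > 10) {
    stop("a pose ensemble holds between 1 and 10 poses", call. = FALSE)
  }
  if (length(scores) != n_pose) stop("one score per pose required", call. = FALSE)
  if (anyNA(scores)) stop("missing docking score", call. = FALSE)
  n_atom <- nrow(mol$atoms)
  for (p in poses) {
    stopifnot_finite_coords(p)
    if (nrow(p) != n_atom) {
      stop("pose atom count differs from molecule", call. = FALSE)
    }
  }
  structure(list(molecule = mol, poses = poses, scores = as.numeric(scores)),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("<pose_ensemble> %s: %d atoms, %d poses, best score %.3f\n",
              x$molecule$id, nrow(x$molecule$atoms), length(x$poses),
              min(x$scores)))
  invisible(x)
}

#' Keep the top-k poses of an ensemble by docking score
#'
#' Poses are sorted ascending by score (lower is better; ties keep file
#' order) and the first `min(k, available)` are retained. Downstream
#' variability statistics need at least two poses; ensembles left with fewer
#' carry a `skip` attribute so callers can report rather than silently drop
#' them.
#'
#' @param ens A [pose_ensemble()].
#' @param k Number of poses to retain (`k >= 2`).
#' @return A `pose_ensemble` with attributes `partial` (fewer than `k` poses
#'   were available) and `skip` (fewer than 2 poses retained).
#' @export
select_top_k <- function(ens, k) {
  stopifnot(inherits(ens, "pose_ensemble"), k >= 2)
  ord <- order(ens$scores)      # stable: ties broken by file order
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- pose_ensemble(ens$molecule, ens$poses[keep], ens$scores[keep])
  attr(out, "partial") <- length(keep) < k
  attr(out, "skip") <- length(keep) < 2
  out
}

# Rotate the j-side subtree about the i->j bond axis by theta (radians).
# Used by the synthetic conformer generator; bonds must form a tree across
# the (i, j) cut, otherwise the rotation is ill-defined and an error thrown.
rotate_torsion <- function(coords, bonds, i, j, theta) {
  n <- nrow(coords)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds$i[r]; b <- bonds$j[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # BFS from j with the i-j edge removed
  side <- logical(n)
  side[j] <- TRUE
  queue <- j
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!side[w] && !(v == j && w == i)) {
        side[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  if (side[i]) stop("bond (", i, ",", j, ") lies on a cycle; torsion undefined",
                    call. = FALSE)
  axis <- coords[j, ] - coords[i, ]
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_about_axis(axis, theta)
  moving <- which(side & seq_len(n) != j)
  if (length(moving)) {
    rel <- sweep(coords[moving, , drop = FALSE], 2, coords[j, ])
    coords[moving, ] <- rel %*% t(R) + rep(coords[j, ], each = length(moving))
  }
  coords
}

# Rodrigues rotation matrix about a unit axis.
rotation_about_axis <- function(axis, theta) {
  u <- axis
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
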