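# Small molecules and geometry helpers built in code for the tests.

# n-butane heavy-atom skeleton: C-C-C-C zig-zag, one rotatable bond
butane_mol <- function() {
  molecule(
    atoms = data.frame(element = "C",
                       x = c(0, 1.5, 2.4, 3.9),
                       y = c(0, 0, 1.2, 1.2),
                       z = 0),
    bonds = data.frame(i = 1:3, j = 2:4, order = 1),
    id = "butane"
  )
}

ethane_mol <- function() {
  molecule(
    atoms = data.frame(element = "C", x = c(0, 1.5), y = 0, z = 0),
    bonds = data.frame(i = 1, j = 2, order = 1),
    id = "ethane"
  )
}

# benzene with explicit hydrogens: 6 aromatic ring bonds + 6 C-H bonds
benzene_mol <- function() {
  ang <- 2 * pi * (0:5) / 6
  molecule(
    atoms = data.frame(
      element = rep(c("C", "H"), each = 6),
      x = c(1.39 * cos(ang), 2.48 * cos(ang)),
      y = c(1.39 * sin(ang), 2.48 * sin(ang)),
      z = 0
    ),
    bonds = data.frame(i = c(1:6, 1:6),
                       j = c(2:6, 1, 7:12),
                       order = c(rep(4, 6), rep(1, 6))),
    id = "benzene"
  )
}

hf_mol <- function() {
  molecule(
    atoms = data.frame(element = c("H", "F"), x = c(0, 0.92), y = 0, z = 0),
    bonds = data.frame(i = 1, j = 2, order = 1),
    id = "hf"
  )
}

random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = runif(3, -5, 5))
}

apply_rigid <- function(coords, rig) {
  coords %*% t(rig$R) + rep(rig$t, each = nrow(coords))
}

# a generic small test cluster with varied elements
random_cluster <- function(n_atoms = 8) {
  matrix(rnorm(n_atoms * 3, sd = 2), n_atoms, 3)
}

cluster_elements <- function(n_atoms = 8) {
  rep(c("C", "N", "O", "S"), length.out = n_atoms)
}

# base coordinates of mol with every rotatable torsion perturbed (seeded);
# uses package internals, visible because the test env's parent is the
# package namespace
coords_via_torsions <- function(mol, seed, sd = 0.4) {
  set.seed(seed)
  b <- mol$bonds
  heavy <- mol$atoms$element != "H"
  deg <- integer(nrow(mol$atoms))
  for (r in seq_len(nrow(b))) {
    if (heavy[b$j[r]]) deg[b$i[r]] <- deg[b$i[r]] + 1L
    if (heavy[b$i[r]]) deg[b$j[r]] <- deg[b$j[r]] + 1L
  }
  rot <- which(b$order == 1 & !b$in_ring & heavy[b$i] & heavy[b$j] &
                 deg[b$i] >= 2 & deg[b$j] >= 2)
  xyz <- coords_matrix(mol)
  for (r in rot) {
    xyz <- rotate_torsion(xyz, b, b$i[r], b$j[r], rnorm(1, 0, sd))
  }
  xyz
}
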