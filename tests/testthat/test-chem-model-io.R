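test_that("molecule construction enforces its invariants", {
  expect_error(molecule(data.frame(element = "Xx", x = 0, y = 0, z = 0),
                        data.frame(i = integer(), j = integer(), order = numeric())),
               "unknown element")
  expect_error(molecule(data.frame(element = "C", x = c(0, Inf), y = 0, z = 0),
                        data.frame(i = 1, j = 2, order = 1)),
               "finite")
  expect_error(molecule(data.frame(element = "C", x = c(0, 1), y = 0, z = 0),
                        data.frame(i = 1, j = 1, order = 1)),
               "self-loop")
  expect_error(molecule(data.frame(element = "C", x = c(0, 1), y = 0, z = 0),
                        data.frame(i = 1, j = 3, order = 1)),
               "out of range")
})

test_that("ring membership comes from cycle detection", {
  expect_true(all(benzene_mol()$bonds$in_ring[1:6]))
  expect_false(any(benzene_mol()$bonds$in_ring[7:12]))
  expect_false(any(butane_mol()$bonds$in_ring))
})

test_that("rotatable-bond counting follows the non-terminal heavy-atom rule", {
  expect_identical(count_rotatable_bonds(butane_mol()), 1L)
  expect_identical(count_rotatable_bonds(benzene_mol()), 0L)
  expect_identical(count_rotatable_bonds(ethane_mol()), 0L)
})

test_that("rotatable-bond count ignores coordinates and atom order", {
  mol <- butane_mol()
  # permute atoms 1<->4, 2<->3 and relabel bonds accordingly
  perm <- c(4, 3, 2, 1)
  atoms2 <- mol$atoms[perm, ]
  atoms2$x <- atoms2$x + 100 # and move it
  inv <- order(perm)
  bonds2 <- data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j], order = 1)
  mol2 <- molecule(atoms2, bonds2, id = "butane-permuted")
  expect_identical(count_rotatable_bonds(mol2), count_rotatable_bonds(mol))
})

test_that("amide exclusion flag removes C-N rotatables next to a carbonyl", {
  # H3C-C(=O)-N(-C)-C fragment, heavy atoms only: C1-C2(=O3)-N4(-C5)(-C6)
  amide <- molecule(
    atoms = data.frame(element = c("C", "C", "O", "N", "C", "C"),
                       x = c(0, 1.5, 2.2, 2.2, 3.7, 1.5),
                       y = c(0, 0, 1.2, -1.2, -1.2, -2.4), z = 0),
    bonds = data.frame(i = c(1, 2, 2, 4, 4), j = c(2, 3, 4, 5, 6),
                       order = c(1, 2, 1, 1, 1)),
    id = "amide"
  )
  # only the C2-N4 bond has two non-terminal heavy ends
  expect_identical(count_rotatable_bonds(amide), 1L)
  expect_identical(count_rotatable_bonds(amide, exclude_amide = TRUE), 0L)
})

test_that("activity labeling applies the strict 100/1000 nM thresholds", {
  expect_identical(label_activity(ki_nm = 50), "active")
  expect_identical(label_activity(ic50_nm = 150), "active") # effective Ki 75
  expect_identical(label_activity(ki_nm = 500), "ambiguous")
  expect_identical(label_activity(ki_nm = 2000), "inactive")
  # boundaries are excluded ("below"/"above" are strict)
  expect_identical(label_activity(ki_nm = 100), "ambiguous")
  expect_identical(label_activity(ki_nm = 1000), "ambiguous")
  # Ki wins when both are present
  expect_identical(label_activity(ki_nm = 50, ic50_nm = 1e5), "active")
  expect_error(label_activity(), "provide")
  expect_error(label_activity(ki_nm = NA_real_), "at least one")
  expect_error(label_activity(ki_nm = -5), "positive")
})

test_that("labeling partitions the positive axis into three intervals", {
  ki <- 10^seq(-1, 6, length.out = 200)
  lab <- label_activity(ki_nm = ki)
  expect_setequal(unique(lab), c("active", "ambiguous", "inactive"))
  # monotone: once inactive, never active again
  expect_true(all(diff(match(lab, c("active", "ambiguous", "inactive"))) >= 0))
})

test_that("geometric distance matrix is Euclidean, symmetric, isometry-invariant", {
  two <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(geometric_distance_matrix(two)[1, 2], 5)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  dm <- geometric_distance_matrix(tri)
  expect_equal(unname(dm[upper.tri(dm)]), rep(1, 3))
  expect_identical(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 3))
  set.seed(41)
  coords <- random_cluster(6)
  moved <- apply_rigid(coords, random_rigid())
  expect_equal(geometric_distance_matrix(moved),
               geometric_distance_matrix(coords), tolerance = 1e-10)
  expect_error(geometric_distance_matrix(rbind(c(0, 0, 0), c(NA, 0, 0))),
               "finite")
})

test_that("SDF round trip preserves ensembles and ids", {
  spec <- synthetic_spec(n_compounds = 4, n_poses = 3, seed = 5)
  bench <- make_benchmark_dataset(spec)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_ensembles(bench$ensembles, path)
  back <- read_sdf_ensembles(path)
  expect_identical(names(back), names(bench$ensembles))
  for (id in names(back)) {
    a <- bench$ensembles[[id]]; b <- back[[id]]
    expect_identical(b$molecule$atoms$element, a$molecule$atoms$element)
    expect_equal(length(b$poses), length(a$poses))
    # coordinates to the printed precision (4 decimals)
    for (p in seq_along(a$poses)) {
      expect_equal(b$poses[[p]], a$poses[[p]], tolerance = 1e-4)
    }
    expect_equal(b$scores, a$scores, tolerance = 1e-6)
  }
})

test_that("SDF reader groups poses by compound id", {
  spec <- synthetic_spec(n_compounds = 1, n_poses = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_ensembles(make_benchmark_dataset(spec)$ensembles, path)
  ens <- read_sdf_ensembles(path)
  expect_length(ens, 1)
  expect_length(ens[[1]]$poses, 3)
})

test_that("SDF reader rejects compounds with inconsistent atom counts", {
  s1 <- make_benchmark_dataset(synthetic_spec(n_compounds = 1, n_poses = 1,
                                              rotbond_range = c(2, 2), seed = 1))
  s2 <- make_benchmark_dataset(synthetic_spec(n_compounds = 1, n_poses = 1,
                                              rotbond_range = c(5, 5), seed = 1))
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_ensembles(s1$ensembles, p1)
  write_sdf_ensembles(s2$ensembles, p2)
  merged <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(readLines(p1), readLines(p2)), merged)
  expect_warning(ens <- read_sdf_ensembles(merged), "inconsistent")
  expect_length(ens, 0)
  expect_identical(attr(ens, "rejected_compounds"), "synt_0001")
})

test_that("empty SDF yields an empty list without error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(), path)
  ens <- read_sdf_ensembles(path)
  expect_length(ens, 0)
  expect_identical(attr(ens, "skipped_records"), 0L)
})

test_that("a record without a docking score raises an error", {
  spec <- synthetic_spec(n_compounds = 1, n_poses = 1, seed = 9)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_ensembles(make_benchmark_dataset(spec)$ensembles, path)
  lines <- readLines(path)
  lines <- lines[!grepl("r_i_docking_score", lines, fixed = TRUE)]
  writeLines(lines, path)
  expect_error(read_sdf_ensembles(path), "docking-score")
})

test_that("activity CSV reader derives labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,ki_nm,ic50_nm", "a,50,", "b,,150", "c,2000,"), path)
  tbl <- read_activity_csv(path)
  expect_identical(tbl$label, c("active", "active", "inactive"))
})
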