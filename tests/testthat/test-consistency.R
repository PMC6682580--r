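make_desc_tbl <- function(values, ids = NULL) {
  # minimal descriptor table: metadata + given descriptor columns
  n <- nrow(values)
  tibble::tibble(
    compound_id = if (is.null(ids)) rep("c1", n) else ids,
    pose_rank = seq_len(n),
    docking_score = seq_len(n) * -1,
    !!!as.data.frame(values)
  )
}

test_that("top-k selection sorts by score and flags short ensembles", {
  mol <- make_chain_molecule(6, 1)
  poses <- lapply(1:10, function(p) coords_matrix(mol) + p)
  scores <- c(3, -1, 2, -5, 0, 4, -2, 1, -4, 5)
  ens <- pose_ensemble(mol, poses, scores)
  top3 <- select_top_k(ens, 3)
  expect_equal(top3$scores, c(-5, -4, -2))
  expect_false(attr(top3, "partial"))
  short <- pose_ensemble(mol, poses[1:2], scores[1:2])
  sel <- select_top_k(short, 5)
  expect_length(sel$poses, 2)
  expect_true(attr(sel, "partial"))
  expect_false(attr(sel, "skip"))
  single <- pose_ensemble(mol, poses[1], scores[1])
  expect_true(attr(select_top_k(single, 3), "skip"))
})

test_that("ties in docking score keep file order", {
  mol <- make_chain_molecule(6, 1)
  poses <- lapply(1:4, function(p) coords_matrix(mol) + p)
  ens <- pose_ensemble(mol, poses, scores = c(-1, -1, -2, -1))
  top <- select_top_k(ens, 3)
  expect_equal(top$poses[[1]], poses[[3]])
  expect_equal(top$poses[[2]], poses[[1]])
  expect_equal(top$poses[[3]], poses[[2]])
})

test_that("standardization drops constants, scales to unit variance, inverts", {
  set.seed(3)
  vals <- cbind(a = rnorm(10, 5, 2), b = rep(7, 10), c = runif(10))
  tbl <- make_desc_tbl(vals, ids = rep(c("x", "y"), each = 5))
  model <- fit_standardization(tbl)
  expect_setequal(model$dropped$descriptor, "b")
  z <- predict(model, tbl)
  expect_false("b" %in% names(z))
  expect_equal(mean(z$a), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$a), 1, tolerance = 1e-12)
  # inverse recovers raw values
  back <- predict(model, z, inverse = TRUE)
  expect_equal(back$a, tbl$a, tolerance = 1e-10)
  expect_equal(back$c, tbl$c, tolerance = 1e-10)
  # re-fit on standardized output is the identity scaling
  model2 <- fit_standardization(z)
  expect_equal(unname(model2$center), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(model2$scale), c(1, 1), tolerance = 1e-12)
  # majority-undefined descriptors are dropped with a reason
  vals_na <- cbind(a = rnorm(10), d = c(rnorm(3), rep(NA, 7)))
  m3 <- fit_standardization(make_desc_tbl(vals_na))
  expect_identical(m3$dropped$reason, "majority undefined")
  expect_error(fit_standardization(tbl[0, ]), "2 rows")
})

test_that("compound descriptor std averages per-descriptor stds", {
  # identical rows -> 0
  rows <- make_desc_tbl(cbind(a = c(1, 1), b = c(2, 2)))
  expect_equal(compound_descriptor_std(rows), 0)
  # one descriptor varying as (-1, +1), D = 4 retained -> 1/D
  D <- 4
  vals <- matrix(5, nrow = 2, ncol = D,
                 dimnames = list(NULL, paste0("d", 1:D)))
  vals[, 1] <- c(-1, 1)
  expect_equal(compound_descriptor_std(make_desc_tbl(vals)), 1 / D)
  # sample divisor scales by sqrt(2) for two poses
  expect_equal(compound_descriptor_std(make_desc_tbl(vals), ddof = 1),
               sqrt(2) / D)
  # undefined entries are excluded per descriptor, not imputed
  vals_na <- cbind(a = c(0, 2), b = c(NA, NA))
  expect_equal(compound_descriptor_std(make_desc_tbl(vals_na)), 1)
  expect_true(is.na(compound_descriptor_std(make_desc_tbl(cbind(b = c(NA, NA))))))
})

test_that("scaling a raw descriptor column leaves the standardized std unchanged", {
  set.seed(11)
  bench <- make_benchmark_dataset(synthetic_spec(n_compounds = 4, n_poses = 4,
                                                 seed = 13))
  desc <- compute_descriptors(bench$ensembles, sasa_points = 96)
  rec1 <- pose_consistency(bench$ensembles, k = 3, desc = desc)
  desc2 <- dplyr::mutate(desc, grav_all = .data$grav_all * 1234.5)
  rec2 <- pose_consistency(bench$ensembles, k = 3, desc = desc2)
  expect_equal(rec2$descriptor_std, rec1$descriptor_std, tolerance = 1e-10)
})

test_that("group summary separates classes and flags the higher one", {
  rec <- tibble::tibble(
    compound_id = sprintf("c%d", 1:6),
    k = 3L, n_poses_used = 3L,
    descriptor_std = c(0.5, 0.6, 0.7, 0.2, 0.3, 0.4),
    atom_std = c(1.0, 1.1, 1.2, 0.4, 0.5, 0.6),
    n_rot = 1:6,
    label = c("active", "active", "active", "inactive", "inactive", "ambiguous")
  )
  g <- summarize_groups(rec)
  expect_equal(g$n_active, 3)
  expect_equal(g$n_inactive, 2) # ambiguous excluded
  expect_equal(g$descriptor_std_active, 0.6)
  expect_equal(g$descriptor_std_inactive, 0.25)
  expect_true(g$descriptor_actives_higher)
  expect_true(g$atom_actives_higher)
  # single-class input: other column missing, not zero
  g1 <- summarize_groups(dplyr::filter(rec, label == "active"))
  expect_true(is.na(g1$descriptor_std_inactive))
  expect_equal(g1$descriptor_std_active, 0.6)
})

test_that("rotatable-bond correlation matches cor() and flags degeneracy", {
  rec <- tibble::tibble(
    compound_id = sprintf("c%d", 1:8), k = 10L, n_poses_used = 10L,
    descriptor_std = 0.1 * (1:8), atom_std = 0.2, n_rot = 1:8,
    label = "unknown"
  )
  expect_equal(rotbond_correlation(rec)$r, 1.0)
  rec$n_rot <- rep(3L, 8)
  expect_true(is.na(rotbond_correlation(rec)$r))
})

test_that("permuted rotbond counts give correlations inside the null band", {
  set.seed(99)
  n <- 60
  base <- tibble::tibble(
    compound_id = sprintf("c%d", 1:n), k = 10L, n_poses_used = 10L,
    descriptor_std = rnorm(n, 0.5, 0.1), atom_std = 0.2,
    n_rot = sample(1:10, n, replace = TRUE), label = "unknown"
  )
  r_obs <- abs(rotbond_correlation(base)$r)
  # permutation null: 97.5% quantile of |r| under independence
  null_r <- replicate(400, {
    b <- base
    b$n_rot <- sample(b$n_rot)
    abs(rotbond_correlation(b)$r)
  })
  expect_lt(r_obs, stats::quantile(null_r, 0.995))
})

test_that("per-descriptor summary ranks the constant MoRSE index at the floor", {
  bench <- make_benchmark_dataset(synthetic_spec(n_compounds = 8, seed = 21))
  desc <- compute_descriptors(bench$ensembles, sasa_points = 96)
  pds <- per_descriptor_std_summary(desc, k = 10)
  m1 <- pds[pds$descriptor == "morse_u_1", ]
  expect_lte(m1$mean_std_raw, 2e-18)
  expect_equal(m1$mean_std_raw, min(pds$mean_std_raw))
  # distance-matrix shape indexes top the dimensionless descriptors
  dimless <- c("petitjean_3d", "shape_index_3d",
               "inertia_ratio_12", "inertia_ratio_13", "inertia_ratio_23",
               grep("fpsa|fnsa|rasa|rpsa|rpcg|rncg", pds$descriptor, value = TRUE))
  sub <- pds[pds$descriptor %in% dimless, ]
  top2 <- sub$descriptor[order(-sub$mean_std_raw)][1:2]
  expect_setequal(top2, c("petitjean_3d", "shape_index_3d"))
})

test_that("all-identical poses give zero everywhere in the summary", {
  mol <- make_chain_molecule(7, 2)
  poses <- lapply(1:3, function(p) coords_matrix(mol))
  ens <- list(m = pose_ensemble(mol, poses, scores = c(-3, -2, -1)))
  desc <- compute_descriptors(ens, sasa_points = 96)
  pds <- per_descriptor_std_summary(desc)
  expect_lt(max(pds$mean_std_raw, na.rm = TRUE), 1e-12)
})

test_that("the consistency pipeline reports skips and respects labels", {
  spec <- synthetic_spec(n_compounds = 5, n_poses = 4, seed = 8)
  bench <- make_benchmark_dataset(spec)
  # cripple one compound to a single pose
  one <- bench$ensembles[[3]]
  bench$ensembles[[3]] <- pose_ensemble(one$molecule, one$poses[1], one$scores[1])
  desc <- compute_descriptors(bench$ensembles, sasa_points = 96)
  rec <- suppressWarnings(
    pose_consistency(bench$ensembles, bench$activity, k = c(3, 4), desc = desc))
  expect_s3_class(rec, "pose_consistency")
  skipped <- attr(rec, "skipped")
  expect_true(names(bench$ensembles)[3] %in% skipped$compound_id)
  expect_setequal(unique(rec$k), c(3L, 4L))
  # every compound is either analysed or skipped, per k
  for (kk in c(3L, 4L)) {
    ids <- c(rec$compound_id[rec$k == kk], skipped$compound_id[skipped$k == kk])
    expect_setequal(ids, names(bench$ensembles))
  }
  expect_true(all(rec$label %in% c("active", "inactive", "ambiguous")))
  expect_true(all(rec$descriptor_std >= 0))
})

test_that("consistency CSV outputs are byte-identical across runs", {
  spec <- synthetic_spec(n_compounds = 4, n_poses = 4, seed = 6)
  bench <- make_benchmark_dataset(spec)
  desc <- compute_descriptors(bench$ensembles, sasa_points = 96)
  rec <- pose_consistency(bench$ensembles, bench$activity, k = 3, desc = desc)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_consistency_outputs(rec, desc, d1)
  write_consistency_outputs(rec, desc, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
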