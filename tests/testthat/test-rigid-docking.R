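toy <- shared_toy()

test_that("random poses are reproducible, separated and uniformly oriented", {
  p1 <- randomize_pose(toy$receptor, toy$glycan, seed = 5)
  p2 <- randomize_pose(toy$receptor, toy$glycan, seed = 5)
  expect_identical(p1, p2)
  posed <- pose_ligand(toy$glycan, p1)
  d2 <- glycodock:::cross_dist2(glycodock:::str_coords(toy$receptor),
                                glycodock:::str_coords(posed))
  expect_gt(sqrt(min(d2)), 2)
  # orientation uniformity: the mean rotation matrix over many draws is
  # near zero (3-sigma Monte-Carlo bound, each entry has sd ~ 1/sqrt(3n))
  n <- 2000
  acc <- matrix(0, 3, 3)
  set.seed(1)
  for (i in 1:n) acc <- acc + glycodock:::quat_to_mat(glycodock:::random_quat())
  expect_true(all(abs(acc / n) < 3 / sqrt(3 * n) + 0.02))
})

test_that("rigid transforms preserve internal geometry", {
  p <- randomize_pose(toy$receptor, toy$glycan, seed = 9)
  posed <- pose_ligand(toy$glycan, p)
  d0 <- dist(glycodock:::str_coords(toy$glycan))
  d1 <- dist(glycodock:::str_coords(posed))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
})

test_that("minimization is stationary at a minimum and never worsens its objective", {
  rs <- build_airs(toy$receptor, toy$glycan, "ti-aa", calibrate_bounds = TRUE)
  w <- scoring_weights("rigid-vdw")
  id <- list(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0))
  m <- rigid_minimize(toy$receptor, toy$glycan, id, rs, w, max_iter = 150)
  expect_lt(sqrt(sum(m$pose$translation^2)), 0.1)
  expect_lt(il_rmsd(m, toy), 0.1)
  # from a random start the exit objective cannot exceed the start
  p <- randomize_pose(toy$receptor, toy$glycan, seed = 21)
  ctx_start <- lennard_jones(toy$receptor, pose_ligand(toy$glycan, p)) +
    coulomb(toy$receptor, pose_ligand(toy$glycan, p)) +
    total_air_energy(toy$receptor, pose_ligand(toy$glycan, p), rs)
  m2 <- rigid_minimize(toy$receptor, toy$glycan, p, rs, w, max_iter = 150)
  ctx_end <- lennard_jones(toy$receptor, m2$ligand) +
    coulomb(toy$receptor, m2$ligand) +
    total_air_energy(toy$receptor, m2$ligand, rs)
  expect_lte(ctx_end, ctx_start + 1e-6)
})

test_that("a single tight restraint is satisfied after minimization", {
  sel <- select_interface(toy$receptor, toy$glycan, 3.9)
  rs <- build_airs(toy$receptor, toy$glycan, "ti-aa",
                   active = list(receptor = sel$receptor[1],
                                 ligand = sel$ligand[1]),
                   calibrate_bounds = TRUE)
  w <- scoring_weights("rigid-vdw")
  p <- randomize_pose(toy$receptor, toy$glycan, seed = 3)
  m <- rigid_minimize(toy$receptor, toy$glycan, p, rs, w, max_iter = 300)
  air <- rs$airs[[1]]
  rh <- toy$receptor$atoms[!toy$receptor$atoms$is_h, ]
  lh <- m$ligand$atoms[!m$ligand$atoms$is_h, ]
  d <- effective_distance(
    as.matrix(rh[rh$reskey == air$anchor, c("x", "y", "z")]),
    as.matrix(lh[lh$reskey %in% air$targets, c("x", "y", "z")]))
  expect_lte(d, air$upper_bound + 0.5)
})

test_that("model generation counts, sorts and reproduces deterministically", {
  rs <- build_airs(toy$receptor, toy$glycan, "ti-aa", calibrate_bounds = TRUE)
  w <- scoring_weights("rigid-vdw")
  cfg <- sampling_config(n_models = 6, seed = 2, max_iter = 40,
                         surface_n_points = 100)
  run <- generate_models(toy$receptor, toy$glycan, rs, cfg, w)
  expect_length(run$models, 6)
  sc <- vapply(run$models, function(m) m$score, numeric(1))
  expect_false(is.unsorted(sc))
  expect_identical(sort(vapply(run$models, function(m) m$model_id, 1L)), 1:6)
  run2 <- generate_models(toy$receptor, toy$glycan, rs, cfg, w)
  expect_identical(sc, vapply(run2$models, function(m) m$score, numeric(1)))
  # ensemble sampling: n_models_per_conformer per member
  ens <- list(toy$glycan,
              glycodock:::set_coords(toy$glycan,
                                     glycodock:::str_coords(toy$glycan)))
  cfg2 <- sampling_config(n_models_per_conformer = 3, seed = 2, max_iter = 20,
                          surface_n_points = 100)
  run3 <- generate_models(toy$receptor, ens, rs, cfg2, w)
  expect_length(run3$models, 6)
  expect_setequal(vapply(run3$models, function(m) m$source_conformer, 1L),
                  c(1L, 2L))
})

test_that("each model records its own independently discarded restraint draw", {
  rs <- build_airs(toy$receptor, toy$glycan, "ti-aa", calibrate_bounds = TRUE)
  seeds <- vapply(1:5, function(i) glycodock:::derive_seed(2, i), numeric(1))
  subs <- lapply(seeds, function(s) random_discard(rs, 0.5, seed = s))
  keys <- vapply(subs, function(x)
    paste(vapply(x$airs, function(a) a$anchor, ""), collapse = "+"), "")
  expect_gt(length(unique(keys)), 1)
  expect_true(all(vapply(subs, function(x) length(x$airs), 1L) ==
                  ceiling(0.5 * length(rs$airs))))
})

test_that("score tables serialize deterministically", {
  rs <- build_airs(toy$receptor, toy$glycan, "ti-aa", calibrate_bounds = TRUE)
  w <- scoring_weights("rigid-vdw")
  cfg <- sampling_config(n_models = 3, seed = 8, max_iter = 20,
                         surface_n_points = 100)
  run <- generate_models(toy$receptor, toy$glycan, rs, cfg, w)
  f1 <- tempfile(); f2 <- tempfile()
  write_score_table(run, f1)
  write_score_table(run, f2)
  expect_identical(readLines(f1), readLines(f2))
  df <- read.delim(f1)
  expect_named(df, c("model_id", "E_vdW", "E_elec", "E_desolv", "E_BSA",
                     "E_air", "score", "seed", "source_conformer", "stage"))
})
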