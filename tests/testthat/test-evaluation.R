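toy <- shared_toy()

test_that("Kabsch superposition recovers exact matches and pure rotations", {
  set.seed(3)
  X <- matrix(rnorm(30), 10)
  f <- kabsch_superpose(X, X)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  expect_equal(f$R, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  Y <- X %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(X, Y)$rmsd, 0, tolerance = 1e-9)
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("fitted RMSD beats thousands of random rotations", {
  set.seed(11)
  for (i in 1:5) {
    X <- matrix(rnorm(30, sd = 3), 10)
    Y <- matrix(rnorm(30, sd = 3), 10)
    best <- kabsch_superpose(X, Y)$rmsd
    rots <- replicate(2000, random_rotation(), simplify = FALSE)
    expect_lte(best, min(rotation_rmsds(X, Y, rots)) + 1e-9)
  }
})

test_that("IL-RMSD measures glycan displacement in the interface frame", {
  expect_equal(il_rmsd(toy, toy), 0, tolerance = 1e-9)
  # rigid 2 A glycan shift with the protein fixed reads exactly 2 A
  shifted <- list(receptor = toy$receptor,
                  ligand = glycodock:::set_coords(
                    toy$glycan, glycodock:::str_coords(toy$glycan) +
                      matrix(c(2, 0, 0), nrow(toy$glycan$atoms), 3,
                             byrow = TRUE)))
  expect_equal(il_rmsd(shifted, toy), 2, tolerance = 1e-9)
  # a joint rigid transform of the whole complex is invisible
  R <- random_rotation()
  joint <- list(
    receptor = glycodock:::set_coords(
      toy$receptor, glycodock:::str_coords(toy$receptor) %*% t(R) + 5),
    ligand = glycodock:::set_coords(
      toy$glycan, glycodock:::str_coords(toy$glycan) %*% t(R) + 5))
  expect_equal(il_rmsd(joint, toy), 0, tolerance = 1e-9)
})

test_that("quality tiers use inclusive cutoffs at 1, 2, 3 and 4 Angstrom", {
  expect_equal(as.character(classify_quality(c(0.52, 2.22, 4.42))),
               c("high", "acceptable", "none"))
  expect_equal(as.character(classify_quality(c(1, 2, 3, 4))),
               c("high", "medium", "acceptable", "near-acceptable"))
  expect_equal(as.character(classify_quality(c(1.0001, 4.0001))),
               c("medium", "none"))
})

test_that("single-model success rates count cumulative tiers by rank", {
  rec <- function(il) data.frame(model_id = seq_along(il),
                                 score = seq_along(il),
                                 rank_by_score = seq_along(il),
                                 il_rmsd = il,
                                 quality = classify_quality(il))
  # one complex, high model at rank 1: all tiers 100% from T1 on
  sr <- success_rate(list(rec(c(0.5, 5, 5))), tops = c(1, 5))
  expect_true(all(sr[, -1] == 1))
  # two complexes, one with an acceptable model only at rank 3
  sr2 <- success_rate(list(rec(c(9, 9, 2.6, 9, 9)), rec(rep(9, 5))),
                      tops = c(1, 5))
  expect_equal(sr2$acceptable, c(0, 0.5))
  expect_equal(sr2$high, c(0, 0))
  expect_error(success_rate(list()), "empty")
})

test_that("success rates are monotone in depth and tier leniency", {
  set.seed(14)
  recs <- lapply(1:12, function(i) {
    il <- runif(20, 0, 8)
    data.frame(model_id = 1:20, score = sort(runif(20)),
               rank_by_score = 1:20, il_rmsd = il,
               quality = classify_quality(il))
  })
  sr <- success_rate(recs, tops = c(1, 5, 10, 20))
  for (tier in c("high", "medium", "acceptable", "near-acceptable"))
    expect_false(is.unsorted(sr[[tier]]))
  expect_true(all(sr$high <= sr$medium & sr$medium <= sr$acceptable &
                    sr$acceptable <= sr[["near-acceptable"]]))
})

test_that("cluster quality comes from the top members only", {
  mkrec <- function(il) data.frame(model_id = seq_along(il),
                                   score = seq_along(il),
                                   rank_by_score = seq_along(il),
                                   il_rmsd = il,
                                   quality = classify_quality(il))
  # high model inside the top 4 makes the cluster high
  cl1 <- list(mkrec(c(9, 9, 0.8, 9)))
  sr <- cluster_success_rate(list(cl1), top_members = 4, tops = 1)
  expect_equal(sr$high, 1)
  # acceptable only at member rank 5 does not count under the top-4 rule
  cl2 <- list(mkrec(c(9, 9, 9, 9, 2.5)))
  sr2 <- cluster_success_rate(list(cl2), top_members = 4, tops = 1)
  expect_equal(sr2$acceptable, 0)
  sr2b <- cluster_success_rate(list(cl2), top_members = 5, tops = 1)
  expect_equal(sr2b$acceptable, 1)
})

test_that("a synthetic multi-cluster fixture reproduces hand-enumerated rates", {
  mkrec <- function(il) data.frame(model_id = seq_along(il),
                                   score = seq_along(il),
                                   rank_by_score = seq_along(il),
                                   il_rmsd = il,
                                   quality = classify_quality(il))
  # complex A: clusters ranked with qualities none, medium, high
  ca <- list(mkrec(rep(9, 4)), mkrec(c(9, 1.8, 9, 9)), mkrec(c(0.5, 9, 9, 9)))
  # complex B: acceptable in the first cluster, nothing after
  cb <- list(mkrec(c(2.9, 9, 9, 9)), mkrec(rep(9, 4)))
  sr <- cluster_success_rate(list(ca, cb), top_members = 4, tops = 1:3)
  expect_equal(sr$high, c(0, 0, 0.5))
  # only complex A ever reaches medium (via its rank-2 cluster)
  expect_equal(sr$medium, c(0, 0.5, 0.5))
  expect_equal(sr$acceptable, c(0.5, 1, 1))
})

test_that("the success-rate bar chart renders without error", {
  sr <- success_rate(list(data.frame(model_id = 1, score = 1,
                                     rank_by_score = 1, il_rmsd = 0.5,
                                     quality = classify_quality(0.5))),
                     tops = c(1, 5))
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot_success_rates(sr))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
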