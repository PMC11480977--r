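toy <- shared_toy()

decoy_models <- function(reqs, seed = 2, scores = NULL) {
  make_decoys(toy, reqs, seed = seed, scores = scores)$models
}

test_that("RMSD matrix basics: duplicates, rigid invariance, oracle pairs", {
  ms <- decoy_models(c(1.5, 1.5, 4), seed = 3)
  ms[[2]] <- ms[[1]]; ms[[2]]$model_id <- 2
  m <- rmsd_matrix(ms, toy, "tip-ap")
  D <- as.matrix(glycodock:::as_dist(m))
  expect_equal(D[1, 2], 0, tolerance = 1e-9)
  # a globally translated copy superposes to zero distance
  shifted <- ms[[3]]
  shifted$ligand <- glycodock:::set_coords(
    shifted$ligand, glycodock:::str_coords(shifted$ligand) + 1)
  shifted$receptor <- glycodock:::set_coords(
    shifted$receptor, glycodock:::str_coords(shifted$receptor) + 1)
  m2 <- rmsd_matrix(list(ms[[3]], shifted), toy, "tip-ap")
  expect_equal(m2$distances[1], 0, tolerance = 1e-9)
  # oracle: per-pair fitted RMSD via bio3d on the same selection
  ms5 <- decoy_models(c(0.5, 1.5, 2.5, 4, 6), seed = 9)
  mm <- rmsd_matrix(ms5, toy, "tip-ap")
  sel <- glycodock:::rmsd_selection(toy, "tip-ap")
  coords <- lapply(ms5, function(x)
    rbind(glycodock:::str_coords(x$receptor)[sel$receptor, ],
          glycodock:::str_coords(x$ligand)[sel$ligand, ]))
  Dref <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    Dref[i, j] <- Dref[j, i] <- bio3d::rmsd(as.vector(t(coords[[i]])),
                                            as.vector(t(coords[[j]])),
                                            fit = TRUE)
  }
  expect_equal(as.matrix(glycodock:::as_dist(mm)), Dref, tolerance = 1e-3,
               ignore_attr = TRUE)
})

# models that are exact rigid translates of the bound pose
translate_model <- function(toy, shift, id) {
  structure(list(receptor = toy$receptor,
                 ligand = glycodock:::set_coords(
                   toy$glycan, sweep(glycodock:::str_coords(toy$glycan), 2,
                                     -shift)),
                 score = id, model_id = id, seed = 1,
                 source_conformer = 1L, energies = NULL, stage = "decoy"),
            class = "docking_model")
}

test_that("distance-cut clustering separates planted groups", {
  # two tight groups of poses ~10 A apart in RMSD space
  shifts <- c(0, 0.1, 0.2, 0.3)
  ms <- c(lapply(1:4, function(i) translate_model(toy, c(shifts[i], 0, 0), i)),
          lapply(1:4, function(i) translate_model(toy, c(shifts[i], 10, 3),
                                                  i + 4)))
  m <- rmsd_matrix(ms, toy, "tip-ap")
  cl <- cluster_hier(m, cut = list(distance = 2.5), min_size = 4)
  expect_length(cl$clusters, 2)
  expect_setequal(lengths(cl$clusters), c(4, 4))
  expect_setequal(cl$clusters[[1]], 1:4)
  # all-close case: a single cluster keeps everyone
  ms2 <- lapply(1:8, function(i) translate_model(toy, c(0.05 * i, 0, 0), i))
  cl2 <- cluster_hier(rmsd_matrix(ms2, toy, "tip-ap"),
                      cut = list(distance = 2.5), min_size = 4)
  expect_length(cl2$clusters, 1)
  expect_length(cl2$clusters[[1]], 8)
  expect_error(cluster_hier(m, cut = list(n_clusters = 99)), "configuration")
})

test_that("flat cuts match exhaustive average-linkage enumeration (n <= 8)", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(4:8, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 10)
    D <- D + t(D)
    m <- structure(list(n_models = n, distances = as.vector(as.dist(D)),
                        model_ids = seq_len(n), mode = "ti-aa"),
                   class = "rmsd_matrix")
    k <- sample(2:(n - 1), 1)
    cl <- cluster_hier(m, cut = list(n_clusters = k), min_size = 1)
    memb <- integer(n)
    for (i in seq_along(cl$clusters)) memb[cl$clusters[[i]]] <- i
    expect_true(same_partition(memb, naive_average_linkage(D, k)))
    h <- runif(1, 1, 8)
    clh <- cluster_hier(m, cut = list(distance = h), min_size = 1)
    membh <- integer(n)
    for (i in seq_along(clh$clusters)) membh[clh$clusters[[i]]] <- i
    expect_true(same_partition(membh, naive_average_linkage_h(D, h)))
  }
})

test_that("clustering is invariant to model input order", {
  ms <- decoy_models(c(0.2, 0.3, 3, 3.1, 6, 6.1, 6.2, 0.25), seed = 8)
  m <- rmsd_matrix(ms, toy, "tip-ap")
  cl <- cluster_hier(m, cut = list(distance = 2.5), min_size = 2)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  mperm <- rmsd_matrix(ms[perm], toy, "tip-ap")
  clperm <- cluster_hier(mperm, cut = list(distance = 2.5), min_size = 2)
  canon <- function(cs) {
    s <- lapply(cs$clusters, sort)
    s[order(vapply(s, min, numeric(1)))]
  }
  expect_identical(canon(cl), canon(clperm))
})

test_that("distance-cut partitions nest as the cut grows", {
  ms <- decoy_models(seq(0.3, 6, length.out = 8), seed = 10)
  m <- rmsd_matrix(ms, toy, "tip-ap")
  cuts <- c(0.5, 1.5, 3, 6, 12)
  membs <- lapply(cuts, function(h) {
    cl <- cluster_hier(m, cut = list(distance = h), min_size = 1)
    memb <- integer(m$n_models)
    for (i in seq_along(cl$clusters)) memb[cl$clusters[[i]]] <- i
    memb
  })
  for (i in seq_len(length(cuts) - 1)) {
    a <- membs[[i]]; b <- membs[[i + 1]]
    # every cluster at the smaller cut stays together at the larger cut
    expect_true(all(tapply(b, a, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster ranking averages the best members and breaks ties stably", {
  cl <- structure(list(clusters = list(c(1, 2, 3, 4, 5), c(6, 7, 8, 9)),
                       unclustered = integer(0), cut = list(distance = 2.5),
                       min_size = 4, rank_scores = NULL),
                  class = "cluster_set")
  scores <- setNames(c(-10, -8, -6, -4, -2, -30, 0, 0, 0), 1:9)
  r <- rank_clusters(cl, scores, top_k = 4)
  expect_equal(r$rank_scores, c(mean(c(-30, 0, 0, 0)), -7))
  expect_equal(r$clusters[[1]][1], 6)
  # tie in rank score: cluster with the smaller leading id first
  scores2 <- setNames(c(rep(-4, 5), rep(-4, 4)), 1:9)
  r2 <- rank_clusters(cl, scores2, top_k = 4)
  expect_equal(min(r2$clusters[[1]]), 1)
})

test_that("top-cluster selection concatenates the best of each cluster", {
  cl <- structure(list(clusters = list(1:6, 7:11, 12:15),
                       unclustered = integer(0), cut = list(n_clusters = 3),
                       min_size = 4, rank_scores = c(-5, -4, -3)),
                  class = "cluster_set")
  sel <- select_top_clusters(cl, models_per_cluster = 5)
  expect_length(sel, 5 + 5 + 4)
  expect_equal(sel[1:5], 1:5)
  empty <- structure(list(clusters = list(), unclustered = 1:3,
                          cut = list(distance = 2.5), min_size = 4,
                          rank_scores = NULL), class = "cluster_set")
  expect_warning(sel0 <- select_top_clusters(empty), "empty")
  expect_length(sel0, 0)
})
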