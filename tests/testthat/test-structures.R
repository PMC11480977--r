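test_that("PDB round trip preserves coordinates, chains and residue ids", {
  toy <- shared_toy()
  f <- tempfile(fileext = ".pdb")
  write_pdb(toy$glycan, f)
  back <- read_pdb(f, "ligand")
  expect_s3_class(back, "pg_structure")
  expect_equal(glycodock:::str_coords(back),
               glycodock:::str_coords(toy$glycan), tolerance = 1e-3)
  expect_identical(back$atoms$chain, toy$glycan$atoms$chain)
  expect_identical(back$atoms$resid, toy$glycan$atoms$resid)
  expect_identical(back$atoms$atname, toy$glycan$atoms$atname)
})

test_that("single-record files and multi-MODEL ensembles parse", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f, "receptor")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(length(glycodock:::res_keys(s)), 1)
  expect_equal(unname(glycodock:::str_coords(s)[1, ]), c(11, 22, 33))

  toy <- shared_toy()
  ens_file <- tempfile(fileext = ".pdb")
  members <- list(toy$glycan,
                  glycodock:::set_coords(toy$glycan,
                                         glycodock:::str_coords(toy$glycan) + 1),
                  toy$glycan)
  write_pdb(members, ens_file)
  txt <- readLines(ens_file)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  ens <- read_pdb(ens_file, "ligand")
  expect_s3_class(ens, "pg_ensemble")
  expect_length(ens, 3)
  expect_equal(glycodock:::str_coords(ens[[2]]),
               glycodock:::str_coords(members[[2]]), tolerance = 1e-3)
})

test_that("malformed and out-of-range input is rejected informatively", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  twenty  33.00  1.00  0.00          C",
    "END"), f)
  expect_error(read_pdb(f, "receptor"), "line 1")
  expect_error(read_pdb(tempfile(), "receptor"), "not found")
  toy <- shared_toy()
  far <- glycodock:::set_coords(toy$glycan,
                                glycodock:::str_coords(toy$glycan) + 1e5)
  expect_error(write_pdb(far, tempfile(fileext = ".pdb")), "overflow")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CB  ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f, "receptor")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$atname == "CA"], 2.0)
})

test_that("glycan topology detection counts linkages and finds branches", {
  di <- make_toy_complex(2, FALSE, seed = 1)
  expect_equal(di$topology$n_units, 2)
  expect_equal(nrow(di$topology$linkage_edges), 1)
  expect_true(di$topology$is_linear)

  hepta <- glycodock:::build_toy_glycan(7, FALSE)
  topo7 <- build_glycan_topology(hepta)
  expect_equal(topo7$n_units, 7)
  expect_equal(nrow(topo7$linkage_edges), 6)
  expect_true(topo7$is_linear)

  br <- make_toy_complex(5, TRUE, seed = 2)
  expect_false(br$topology$is_linear)
  deg <- igraph::degree(br$topology$graph)
  expect_equal(max(deg), 3)

  # disconnected: shift one residue far away
  g <- di$glycan
  xyz <- glycodock:::str_coords(g)
  second <- g$atoms$reskey == glycodock:::res_keys(g)[2]
  xyz[second, ] <- xyz[second, ] + 100
  expect_error(build_glycan_topology(glycodock:::set_coords(g, xyz)),
               "disconnected")
})

test_that("size classification is total over unit count and branching", {
  mk <- function(n, lin) structure(list(n_units = n, is_linear = lin),
                                   class = "glycan_topology")
  expect_equal(classify_glycan(mk(3, TRUE)), "SL")
  expect_equal(classify_glycan(mk(3, FALSE)), "SB")
  expect_equal(classify_glycan(mk(4, TRUE)), "LL")
  expect_equal(classify_glycan(mk(4, FALSE)), "LB")
  expect_equal(classify_glycan(mk(1, TRUE)), "SL")
  expect_equal(classify_glycan(make_toy_complex(5, TRUE, seed = 2)$topology),
               "LB")
})

test_that("interface selection matches a brute-force all-pairs oracle and is symmetric", {
  a <- mk_structure("C", matrix(c(0, 0, 0), 1), resid = "1")
  b <- mk_structure("C", matrix(c(3.8, 0, 0), 1), resid = "1",
                    role = "receptor")
  sel <- select_interface(a, b, 3.9)
  expect_length(sel$receptor, 1)
  expect_length(sel$ligand, 1)
  b4 <- mk_structure("C", matrix(c(4.0, 0, 0), 1), resid = "1")
  expect_warning(sel2 <- select_interface(a, b4, 3.9), "empty")
  expect_length(sel2$receptor, 0)

  toy <- shared_toy()
  sel <- select_interface(toy$receptor, toy$glycan, 3.9)
  # oracle: residue in iff min heavy-atom cross distance <= cutoff
  ra <- toy$receptor$atoms[!toy$receptor$atoms$is_h, ]
  la <- toy$glycan$atoms[!toy$glycan$atoms$is_h, ]
  expected_r <- character(0)
  for (k in unique(ra$reskey)) {
    d2 <- glycodock:::cross_dist2(as.matrix(ra[ra$reskey == k, c("x", "y", "z")]),
                                  as.matrix(la[, c("x", "y", "z")]))
    if (min(d2) <= 3.9^2) expected_r <- c(expected_r, k)
  }
  expect_setequal(sel$receptor, expected_r)
  # symmetry: glycan-side selection from the transposed comparison
  expected_l <- character(0)
  for (k in unique(la$reskey)) {
    d2 <- glycodock:::cross_dist2(as.matrix(la[la$reskey == k, c("x", "y", "z")]),
                                  as.matrix(ra[, c("x", "y", "z")]))
    if (min(d2) <= 3.9^2) expected_l <- c(expected_l, k)
  }
  expect_setequal(sel$ligand, expected_l)
})
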