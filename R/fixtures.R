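# Synthetic fixtures: toy protein-glycan complexes with a planted bound
# pose, and decoy sets with planted interface-ligand RMSDs. Pseudo-atom
# chemistry (generic C/O classes): the fixtures exercise the mechanics of
# restraints, energies, RMSDs and clustering, not force-field realism.

# idealized pyranose stand-in: hexagonal ring (5 C + ring O) with four
# exocyclic oxygens; C1 is the anomeric carbon, O4 the linkage acceptor,
# O6 the branch acceptor. All atoms heavy. Local frame: ring in the xy
# plane, C1 on +x, O4 on -x.
ring_template <- function() {
  r <- 1.5
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(r * cos(ang), r * sin(ang), 0)
  rownames(ring) <- c("C1", "C2", "C3", "C4", "C5", "O5")
  sub <- function(k, tilt, len = 1.43) {
    v <- ring[k, ]
    u <- v / sqrt(sum(v^2))
    dir <- u * cos(tilt) + c(0, 0, 1) * sin(tilt)
    v + len * dir
  }
  xyz <- rbind(ring,
               O2 = sub("C2", 0.9), O3 = sub("C3", -0.9),
               O4 = sub("C4", 0), O6 = sub("C5", 0.9))
  xyz
}

# N-acetyl-like arm grafted onto C2 (replacing O2), as on
# N-acetylglucosamine: marks the reducing-end unit and makes the chain
# sterically asymmetric
arm_template <- function() {
  tmpl <- ring_template()
  c2 <- tmpl["C2", ]
  u <- c2 / sqrt(sum(c2^2))
  n2 <- c2 + 1.45 * (u * cos(-0.6) + c(0, 0, 1) * sin(-0.6))
  un <- (n2 - c2) / sqrt(sum((n2 - c2)^2))
  c7 <- n2 + 1.45 * (un * cos(0.9) + c(0, 0, -1) * sin(0.9))
  o7 <- c7 + 1.23 * u
  tmpl <- tmpl[setdiff(rownames(tmpl), "O2"), ]
  rbind(tmpl, N2 = n2, C7 = c7, O7 = o7)
}

# intra-residue covalent bonds of the template (by atom name)
ring_bonds <- function() {
  rbind(c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
        c("C5", "O5"), c("O5", "C1"), c("C2", "O2"), c("C3", "O3"),
        c("C4", "O4"), c("C5", "O6"))
}

glycan_atoms_df <- function(xyz, resid, serial0, resname = "BGC") {
  data.frame(serial = serial0 + seq_len(nrow(xyz)),
             atname = rownames(xyz), resname = resname, chain = "G",
             resid = as.character(resid),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
             elem = substr(rownames(xyz), 1, 1), stringsAsFactors = FALSE)
}

# Place a template copy so that its C1 sits at `c1_pos` with its local +x
# axis along -`dir` (the chain extension direction) after rotation R_extra.
place_ring <- function(tmpl, c1_pos, R) {
  xyz <- tmpl %*% t(R)
  shift <- c1_pos - xyz["C1", ]
  sweep(xyz, 2, shift, "+")
}

build_toy_glycan <- function(n_units, branched) {
  tmpl <- ring_template()
  n_main <- if (branched) n_units - 1 else n_units
  # the reducing-end (last main-chain) unit carries the acetamido arm,
  # making the chain sterically asymmetric end to end
  tmpl_of <- function(i) if (i == n_main) arm_template() else tmpl
  rings <- list(tmpl_of(1))
  parent_O <- "O4"
  for (i in seq_len(n_main)[-1]) {
    prev <- rings[[i - 1]]
    o <- prev[parent_O, ]
    c4 <- prev["C4", ]
    dir <- (o - c4) / sqrt(sum((o - c4)^2))
    # incommensurate twist about the chain axis: successive units are never
    # related by a screw symmetry, so the chain has a distinguishable
    # orientation (C1 and O4 both sit on the local x axis, so the twist
    # leaves the linkage geometry intact)
    R <- rotmat_axis_angle(c(1, 0, 0), (i - 1) * 100 * pi / 180)
    rings[[i]] <- place_ring(tmpl_of(i), o + 1.43 * dir, R)
  }
  if (branched) {
    # branch off O6 of the second (interior) unit, giving it degree 3;
    # orient the branch ring to extend outward along the C5-O6 direction
    host <- rings[[2]]
    o <- host["O6", ]
    c5 <- host["C5", ]
    dir <- (o - c5) / sqrt(sum((o - c5)^2))
    ex <- c(1, 0, 0)
    ax <- pracma_cross(ex, -dir)
    ang <- acos(max(-1, min(1, sum(ex * -dir))))
    Rb <- if (sum(ax^2) < 1e-12) diag(3) else rotmat_axis_angle(ax, ang)
    rings[[n_units]] <- place_ring(tmpl %*% t(Rb), o + 1.43 * dir, diag(3))
  }
  # roll the whole chain about its axis so the acetamido arm points to
  # negative z: the pocket wall (built below and beside the glycan) then
  # wraps around the arm, which keys the orientation of the chain
  armring <- rings[[n_main]]
  rad <- armring["C2", ] - colMeans(armring[c("C1", "C2", "C3", "C4", "C5", "O5"), ])
  alpha <- atan2(rad[2], rad[3]) - pi
  Rroll <- rotmat_axis_angle(c(1, 0, 0), -alpha)
  rings <- lapply(rings, function(x) x %*% t(Rroll))
  dfs <- lapply(seq_along(rings), function(i)
    glycan_atoms_df(rings[[i]], i, 0L,
                    resname = if (nrow(rings[[i]]) > 10) "NAG" else "BGC"))
  atoms <- do.call(rbind, dfs)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, role = "ligand")
}

# pseudo amino-acid residue: CA at the centre, backbone N/C/O plus a
# two-atom side chain; CB points along +x with CG bent off-axis, the
# carbonyl O along roughly -y
residue_template <- function() {
  rbind(N = c(-0.69, 1.29, 0), CA = c(0, 0, 0), C = c(-0.71, -1.34, 0),
        O = c(-0.27, -2.48, 0), CB = c(1.53, 0, 0),
        CG = c(2.14, 1.37, 0))
}

#' Generate a toy protein-glycan complex with a known bound pose
#'
#' Builds an idealized glycan of \code{n_units} hexagonal pseudo-pyranoses
#' (linear chain, or with one unit branched off the first ring) and a
#' concave receptor pocket of pseudo amino-acid residues cradling it from
#' below and from the sides, leaving the top open. The construction is the
#' reference (bound) pose: at least 3 receptor residues lie within 3.9 A of
#' the glycan and no heavy-atom pair is closer than 2.2 A.
#'
#' @param n_units number of monosaccharide units, 2..7.
#' @param branched logical; one branch point on the first unit.
#' @param seed integer; jitters the pocket deterministically.
#' @return object of class \code{toy_complex}: \code{$receptor},
#'   \code{$glycan} (bound pose), \code{$topology}, \code{$seed}.
#' @export
make_toy_complex <- function(n_units = 2, branched = FALSE, seed = 1L) {
  stopifnot(n_units >= 2, n_units <= 7)
  if (branched && n_units < 4)
    stop("a branch point (degree-3 unit) needs at least 4 units")
  glycan <- build_toy_glycan(n_units, branched)
  gxyz <- str_coords(glycan)
  gres <- glycan$atoms$reskey
  res_ctr <- do.call(rbind, lapply(res_keys(glycan), function(k)
    colMeans(gxyz[gres == k, , drop = FALSE])))
  rownames(res_ctr) <- res_keys(glycan)
  tmpl <- residue_template()
  gpar <- resolve_params(glycan)
  with_seed(seed, {
    dfs <- list()
    kept <- 0L
    placed <- matrix(numeric(0), 0, 3)
    # One pocket-wall candidate per exocyclic/ring glycan atom, placed
    # along the outward normal from its ring centre; the top (+z) is left
    # open so the bound pose sits in a concave cup. Each wall residue
    # presents a charge-complementary partner atom to the glycan atom it
    # faces (carbonyl O toward sugar carbons, CB toward sugar oxygens), at
    # a near-optimal van der Waals contact. A second, backing layer 3.5 A
    # behind the wall provides receptor bulk so the binding site is only
    # reachable from the open face. The receptor is rigid, so wall
    # residues may pack tightly.
    for (layer in 1L) {
      for (j in seq_len(nrow(gxyz))) {
        nvec <- gxyz[j, ] - res_ctr[gres[j], ]
        if (sqrt(sum(nvec^2)) < 1.0) next
        nvec <- nvec / sqrt(sum(nvec^2))
        if (nvec[3] > 0.3) next
        partner <- if (glycan$atoms$elem[j] == "O") "CB" else "O"
        plocal <- tmpl[partner, ]
        plen <- sqrt(sum(plocal^2))
        dist <- 3.6 + plen
        ctr <- gxyz[j, ] + dist * nvec + stats::rnorm(3, sd = 0.12)
        # rotate so the partner atom points back toward the glycan atom;
        # the spin about that axis is then chosen to minimize the
        # residue's interaction energy with the bound glycan, so the
        # reference pose is the engineered optimum of the pocket
        u <- plocal / plen
        ax <- pracma_cross(u, -nvec)
        ang <- acos(max(-1, min(1, sum(u * -nvec))))
        R0 <- if (sum(ax^2) < 1e-12) diag(3) else rotmat_axis_angle(ax, ang)
        best <- NULL; ebest <- Inf
        for (spin in seq(0, 330, by = 30) * pi / 180) {
          Rs <- rotmat_axis_angle(nvec, spin) %*% R0
          cand <- sweep(tmpl %*% t(Rs), 2, ctr, "+")
          e <- residue_glycan_energy(cand, rownames(tmpl), gxyz, gpar)
          if (e < ebest) { ebest <- e; best <- cand }
        }
        xyz <- best
        if (min(cross_dist2(xyz, gxyz)) < 3.2^2) next
        if (nrow(placed) && min(cross_dist2(xyz, placed)) < 1.6^2) next
        kept <- kept + 1L
        placed <- rbind(placed, xyz)
        dfs[[kept]] <- data.frame(
          serial = (kept - 1L) * 6L + seq_len(nrow(tmpl)),
          atname = rownames(tmpl),
          resname = "ALA", chain = "R", resid = as.character(kept),
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
          elem = substr(rownames(tmpl), 1, 1), stringsAsFactors = FALSE)
      }
    }
    # solid interior: single-atom pseudo-residues on a coarse grid fill the
    # body of the receptor under and around the cup, so that no binding
    # surface exists on the far side of the pocket wall
    gmin <- apply(gxyz, 2, min); gmax <- apply(gxyz, 2, max)
    grid <- as.matrix(expand.grid(seq(gmin[1] - 9, gmax[1] + 9, by = 2.6),
                                  seq(gmin[2] - 9, gmax[2] + 9, by = 2.6),
                                  seq(gmin[3] - 11, gmax[3] + 2, by = 2.6)))
    d2g <- cross_dist2(grid, gxyz)
    nearest <- apply(d2g, 1, which.min)
    dmin <- sqrt(d2g[cbind(seq_len(nrow(grid)), nearest)])
    dirz <- (grid[, 3] - gxyz[nearest, 3]) / pmax(dmin, 1e-9)
    okg <- dmin >= 4.8 & dmin <= 9 & dirz <= 0.3
    for (gi in which(okg)) {
      p <- grid[gi, , drop = FALSE]
      if (nrow(placed) && min(cross_dist2(p, placed)) < 1.8^2) next
      kept <- kept + 1L
      placed <- rbind(placed, p)
      dfs[[kept]] <- data.frame(
        serial = (kept - 1L) * 5L + 1L, atname = "CW",
        resname = "ALA", chain = "R", resid = as.character(kept),
        x = p[1], y = p[2], z = p[3], occ = 1,
        elem = "C", stringsAsFactors = FALSE)
    }
    ratoms <- do.call(rbind, dfs)
    ratoms$serial <- seq_len(nrow(ratoms))
    receptor <- new_structure(ratoms, role = "receptor")
  })
  # relax the constructed pose rigidly (no restraints) so the reference
  # bound pose is a genuine optimum of the package's own energy model, as
  # for a minimized experimental complex
  relax <- rigid_minimize(receptor, glycan,
                          list(quaternion = c(1, 0, 0, 0),
                               translation = c(0, 0, 0)),
                          empty_restraints(), scoring_weights("rigid-vdw"),
                          max_iter = 200, surface_n_points = 120)
  glycan <- relax$ligand
  topo <- build_glycan_topology(glycan)
  iface <- select_interface(receptor, glycan, 3.9)
  stopifnot(length(iface$receptor) >= 3)
  structure(list(receptor = receptor, glycan = glycan, topology = topo,
                 seed = as.integer(seed)),
            class = "toy_complex")
}

empty_restraints <- function() {
  structure(list(airs = list(), scenario = "ti-aa", active = list(),
                 upper_bound = 2, lower_bound = 0, force_constant = 50,
                 switch_violation = 1),
            class = "restraint_set")
}

# unswitched LJ + Coulomb of one pseudo-residue against the glycan, used
# to pick wall-residue spins during pocket construction
residue_glycan_energy <- function(xyz, atnames, gxyz, gpar) {
  cls <- ifelse(atnames == "C", "CC", ifelse(atnames == "O", "OC",
                ifelse(atnames == "N", "N", "C")))
  tab <- nonbonded_params()
  i <- match(cls, tab$class)
  d2 <- cross_dist2(xyz, gxyz)
  d2[d2 < 1] <- 1
  r <- sqrt(d2)
  sig <- outer(tab$sigma[i], gpar$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(tab$eps[i], gpar$eps))
  qq <- COULOMB_CONST * outer(tab$charge[i], gpar$charge) / 10
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6 * sr6 - sr6) + qq / r)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("<toy_complex> %s glycan of %d units; receptor of %d residues (seed %d)\n",
              classify_glycan(x$topology), x$topology$n_units,
              length(res_keys(x$receptor)), x$seed))
  invisible(x)
}

#' Build a decoy set with planted interface-ligand RMSDs
#'
#' Each decoy applies a screw motion (coupled rotation about and translation
#' along a seeded random axis through the glycan centroid) to the bound
#' glycan, with the screw amplitude bisected until the realized IL-RMSD
#' matches the request within 0.1 A. Scores are plantable to impose any
#' ranking; by default decoys are scored by their requested RMSD (so the
#' ranking follows quality).
#'
#' @param toy a \code{\link{make_toy_complex}} result.
#' @param il_rmsds numeric vector of requested IL-RMSD values, Angstrom.
#' @param seed integer.
#' @param scores optional numeric vector of planted scores (same length).
#' @param plant_clash if TRUE, each decoy's receptor additionally gets one
#'   interface side-chain (CB) atom displaced to 2.3 A from the nearest
#'   glycan heavy atom, creating a steric clash that side-chain-flexible
#'   refinement can resolve.
#' @return object of class \code{decoy_set}: \code{$models} (list of
#'   \code{docking_model}-like objects), \code{$il_rmsd} realized values,
#'   \code{$quality} tiers.
#' @export
make_decoys <- function(toy, il_rmsds, seed = 1L, scores = NULL,
                        plant_clash = FALSE) {
  stopifnot(all(il_rmsds >= 0))
  if (is.null(scores)) scores <- il_rmsds
  gxyz <- str_coords(toy$glycan)
  ctr <- colMeans(gxyz)
  models <- vector("list", length(il_rmsds))
  realized <- numeric(length(il_rmsds))
  for (i in seq_along(il_rmsds)) {
    axis <- with_seed(derive_seed(seed, i), {
      a <- stats::rnorm(3); a / sqrt(sum(a^2))
    })
    target <- il_rmsds[i]
    screw <- function(s) {
      R <- rotmat_axis_angle(axis, s * 0.25)
      xyz <- rotate_about(gxyz, R, ctr, shift = axis * s * 0.8)
      set_coords(toy$glycan, xyz)
    }
    if (target == 0) {
      lig <- toy$glycan
      realized[i] <- 0
    } else {
      # bracket then bisect the screw amplitude
      hi <- 1
      f <- function(s) il_rmsd(list(receptor = toy$receptor, ligand = screw(s)),
                               toy) - target
      while (f(hi) < 0 && hi < 64) hi <- hi * 2
      if (f(hi) < 0) {
        warning(sprintf("requested IL-RMSD %.2f A unreachable; best effort", target))
        s <- hi
      } else {
        s <- stats::uniroot(f, c(0, hi), tol = 1e-4)$root
      }
      lig <- screw(s)
      realized[i] <- f(s) + target
    }
    receptor <- toy$receptor
    if (plant_clash) {
      # swing the side-chain tip (CG) of the closest wall residue onto the
      # line from its CB to the nearest glycan atom, 2.3 A short of it:
      # a genuine clash reachable with intact covalent geometry
      ra <- receptor$atoms
      cb <- which(ra$atname == "CB")
      lx <- str_coords(lig)[heavy_idx(lig), , drop = FALSE]
      d2 <- cross_dist2(as.matrix(ra[cb, c("x", "y", "z")]), lx)
      hit <- arrayInd(which.min(d2), dim(d2))
      a <- cb[hit[1]]
      target <- lx[hit[2], ]
      p <- c(ra$x[a], ra$y[a], ra$z[a])
      dcb <- sqrt(sum((target - p)^2))
      u <- (target - p) / dcb
      # stay within covalent reach of CB while getting as close to 2.3 A
      # from the glycan atom as that allows
      pnew <- p + min(1.7, dcb - 2.3) * u
      cg <- which(ra$atname == "CG" & ra$reskey == ra$reskey[a])
      receptor$atoms$x[cg] <- pnew[1]
      receptor$atoms$y[cg] <- pnew[2]
      receptor$atoms$z[cg] <- pnew[3]
    }
    models[[i]] <- structure(
      list(receptor = receptor, ligand = lig, score = scores[i],
           model_id = i, seed = seed, source_conformer = 1L,
           energies = NULL, pose = NULL, stage = "decoy"),
      class = "docking_model")
  }
  structure(list(models = models, il_rmsd = realized,
                 quality = classify_quality(realized), seed = seed),
            class = "decoy_set")
}
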