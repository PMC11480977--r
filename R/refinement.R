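# Simplified semi-flexible interface refinement: two-stage restrained
# Cartesian minimization (side chains + glycan first, then also interface
# backbone) with harmonic geometry restraints replacing full torsion-angle
# simulated annealing. Heavy atoms only.

# Covalent bond detection by distance over heavy atoms: intra-residue
# pairs and inter-residue carbon-oxygen / peptide pairs within the cutoff.
covalent_bonds <- function(s, cutoff = 1.8) {
  a <- s$atoms[!s$atoms$is_h, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- cross_dist2(xyz, xyz)
  hit <- which(d2 <= cutoff^2 & upper.tri(d2), arr.ind = TRUE)
  keep <- a$reskey[hit[, 1]] == a$reskey[hit[, 2]] |
    (a$elem[hit[, 1]] == "C" & a$elem[hit[, 2]] == "O") |
    (a$elem[hit[, 1]] == "O" & a$elem[hit[, 2]] == "C") |
    (a$elem[hit[, 1]] == "N" & a$elem[hit[, 2]] == "C") |
    (a$elem[hit[, 1]] == "C" & a$elem[hit[, 2]] == "N")
  hit[keep, , drop = FALSE]
}

# 1-3 pairs (atoms bonded to a common neighbour); their distances stand in
# for angle restraints
one_three_pairs <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    out[[length(out) + 1L]] <- t(cmb)
  }
  p <- unique(do.call(rbind, out))
  bondkey <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  p[!(paste(p[, 1], p[, 2]) %in% bondkey), , drop = FALSE]
}

# harmonic pair restraints: E = k (d - d0)^2 summed over pairs
harm_pairs_energy_grad <- function(X, pairs, d0, k) {
  if (!nrow(pairs)) return(list(E = 0, g = matrix(0, nrow(X), 3)))
  diff <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  d <- sqrt(rowSums(diff^2))
  dev <- d - d0
  g <- matrix(0, nrow(X), 3)
  f <- diff * (2 * k * dev / pmax(d, 1e-9))
  m1 <- rowsum(f, pairs[, 1]); i1 <- as.integer(rownames(m1))
  g[i1, ] <- g[i1, ] + m1
  m2 <- rowsum(f, pairs[, 2]); i2 <- as.integer(rownames(m2))
  g[i2, ] <- g[i2, ] - m2
  list(E = sum(k * dev^2), g = g)
}

# AIR energy and Cartesian gradient over resolved atom-index lists
air_energy_grad <- function(idx, rxyz, lxyz, rs) {
  gR <- matrix(0, nrow(rxyz), 3)
  gL <- matrix(0, nrow(lxyz), 3)
  E <- 0
  for (ai in idx) {
    if (ai$anchor_side == "receptor") {
      A <- rxyz[ai$anchor, , drop = FALSE]; B <- lxyz[ai$targets, , drop = FALSE]
    } else {
      A <- lxyz[ai$anchor, , drop = FALSE]; B <- rxyz[ai$targets, , drop = FALSE]
    }
    d2 <- cross_dist2(A, B)
    if (any(d2 < 1e-12)) stop("singularity in AIR evaluation")
    S <- sum(d2^(-3))
    d_eff <- S^(-1 / 6)
    ub <- if (is.null(ai$ub)) rs$upper_bound else ai$ub
    up <- d_eff > ub
    lo <- d_eff < rs$lower_bound
    if (!up && !lo) next
    v <- if (up) d_eff - ub else rs$lower_bound - d_eff
    E <- E + flat_bottom_energy(v, rs$force_constant, rs$switch_violation)
    dEdd <- flat_bottom_dEdv(v, rs$force_constant, rs$switch_violation) *
      (if (up) 1 else -1)
    # d(d_eff)/dx through S = sum d2^-3
    coeff <- dEdd * (-1 / 6) * S^(-7 / 6) * (-6) * d2^(-4)  # per pair
    for (r in seq_len(nrow(A))) {
      diff <- matrix(A[r, ], nrow(B), 3, byrow = TRUE) - B
      contrib <- diff * coeff[r, ]
      gaA <- colSums(contrib)
      if (ai$anchor_side == "receptor") {
        gR[ai$anchor[r], ] <- gR[ai$anchor[r], ] + gaA
        gL[ai$targets, ] <- gL[ai$targets, ] - contrib
      } else {
        gL[ai$anchor[r], ] <- gL[ai$anchor[r], ] + gaA
        gR[ai$targets, ] <- gR[ai$targets, ] - contrib
      }
    }
  }
  list(E = E, gR = gR, gL = gL)
}

# Greedy adaptive-step gradient descent on the flexible rows of X.
# energy_grad_fn(X) must return list(E=, g=) with g over all rows.
# The evaluation budget counts calls to energy_grad_fn.
cartesian_min <- function(X, flex, energy_grad_fn, max_evals = 500,
                          max_step = 0.25) {
  cur <- energy_grad_fn(X)
  evals <- 1
  alpha <- 1e-3
  while (evals < max_evals) {
    step <- -alpha * cur$g[flex, , drop = FALSE]
    mx <- max(abs(step))
    if (mx > max_step) step <- step * (max_step / mx)
    Xn <- X
    Xn[flex, ] <- Xn[flex, ] + step
    nxt <- energy_grad_fn(Xn)
    evals <- evals + 1
    if (is.finite(nxt$E) && nxt$E < cur$E) {
      X <- Xn; cur <- nxt; alpha <- alpha * 1.3
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-9) break
    }
  }
  list(X = X, E = cur$E, evals = evals)
}

#' Semi-flexible refinement of a docking model
#'
#' Two-stage restrained Cartesian minimization standing in for
#' torsion-angle simulated annealing: stage 1 lets receptor interface side
#' chains and all glycan atoms move; stage 2 additionally frees the
#' interface backbone. The objective is the refinement-stage pairwise
#' score terms (vdW, electrostatics, restraint energy) plus stiff harmonic
#' restraints on covalent bond lengths and 1-3 distances of the flexible
#' region, which preserves covalent geometry (ring closure included). Any
#' bond stretching beyond 0.5 A rejects the refinement and returns the
#' input model flagged. Non-flexible atoms never move.
#'
#' @param model a \code{docking_model} (carries receptor and posed ligand).
#' @param restraints \code{restraint_set} used for E_air.
#' @param n_stages 1 or 2 (default 2).
#' @param steps_per_stage objective evaluations per stage (default 500).
#' @param flex_cutoff receptor residues within this distance of the glycan
#'   are flexible, Angstrom (default 5.0).
#' @param weights scoring weights (default flexref preset).
#' @param params nonbonded table.
#' @param bond_k,angle_k restraint constants, kcal/(mol A^2).
#' @param surface_n_points sphere points for the final surface terms.
#' @return a re-scored \code{docking_model} with \code{$stage = "flexref"}
#'   and \code{$flagged = TRUE} if the refinement was rejected.
#' @export
flex_refine <- function(model, restraints, n_stages = 2, steps_per_stage = 500,
                        flex_cutoff = 5.0, weights = scoring_weights("flexref"),
                        params = nonbonded_params(), bond_k = 300, angle_k = 60,
                        surface_n_points = 240) {
  receptor <- model$receptor
  ligand <- model$ligand
  rh <- heavy_idx(receptor); lh <- heavy_idx(ligand)
  nR <- length(rh); nL <- length(lh)
  ra <- receptor$atoms[rh, , drop = FALSE]
  la <- ligand$atoms[lh, , drop = FALSE]
  X0 <- rbind(as.matrix(ra[, c("x", "y", "z")]),
              as.matrix(la[, c("x", "y", "z")]))
  # an empty selection (model far from contact) is fine here: the glycan
  # alone is refined
  iface <- suppressWarnings(select_interface(receptor, ligand, flex_cutoff))
  sidechain <- which(ra$reskey %in% iface$receptor & !ra$is_backbone)
  backbone <- which(ra$reskey %in% iface$receptor & ra$is_backbone)
  flex_stages <- list(c(sidechain, nR + seq_len(nL)))
  if (n_stages >= 2)
    flex_stages[[2]] <- c(sidechain, backbone, nR + seq_len(nL))
  # geometry restraints over the whole complex (receptor bonds + glycan
  # bonds; no spurious receptor-ligand bonds expected at a docked pose)
  bondsR <- covalent_bonds(receptor)
  bondsL <- covalent_bonds(ligand) + nR
  bonds <- rbind(bondsR, bondsL)
  d0_b <- sqrt(rowSums((X0[bonds[, 1], ] - X0[bonds[, 2], ])^2))
  if (any(d0_b > 2.0))
    stop("invalid input geometry: stretched bond in the flexible region")
  # a heavy atom of a multi-atom residue with no covalent partner at all
  # marks torn (over-stretched) geometry the distance detection cannot see
  keys <- c(ra$reskey, la$reskey)
  bonded <- tabulate(c(bonds), nR + nL) > 0
  multi <- keys %in% names(which(table(keys) > 1))
  if (any(!bonded & multi))
    stop("invalid input geometry: atom(s) detached from their residue")
  ot <- one_three_pairs(bonds, nR + nL)
  d0_a <- sqrt(rowSums((X0[ot[, 1], , drop = FALSE] -
                        X0[ot[, 2], , drop = FALSE])^2))
  pr <- resolve_params(receptor, params); pl <- resolve_params(ligand, params)
  pm <- pair_param_matrices(pr, pl)
  air_idx <- air_indices(restraints, receptor, ligand)
  rs <- restraints
  energy_grad <- function(X) {
    Rx <- X[seq_len(nR), , drop = FALSE]
    Lx <- X[nR + seq_len(nL), , drop = FALSE]
    pe <- pair_energies(Rx, Lx, pm$EPS, pm$SIG, pm$QQ, cutoff = 8.5,
                        grad = TRUE, wlj = weights$w_vdW, wel = weights$w_elec)
    ag <- air_energy_grad(air_idx, Rx, Lx, rs)
    hb <- harm_pairs_energy_grad(X, bonds, d0_b, bond_k)
    ha <- harm_pairs_energy_grad(X, ot, d0_a, angle_k)
    E <- weights$w_vdW * pe$E_vdW + weights$w_elec * pe$E_elec +
      weights$w_air * ag$E + hb$E + ha$E
    g <- hb$g + ha$g
    g[seq_len(nR), ] <- g[seq_len(nR), ] + pe$gA + weights$w_air * ag$gR
    g[nR + seq_len(nL), ] <- g[nR + seq_len(nL), ] + pe$gB +
      weights$w_air * ag$gL
    list(E = E, g = g)
  }
  X <- X0
  if (steps_per_stage > 0) {
    for (st in seq_len(min(n_stages, length(flex_stages)))) {
      res <- cartesian_min(X, flex_stages[[st]], energy_grad,
                           max_evals = steps_per_stage)
      X <- res$X
    }
  }
  dev <- abs(sqrt(rowSums((X[bonds[, 1], ] - X[bonds[, 2], ])^2)) - d0_b)
  flagged <- FALSE
  if (max(dev) > 0.5) {
    X <- X0
    flagged <- TRUE
  }
  rxyz <- str_coords(receptor); rxyz[rh, ] <- X[seq_len(nR), ]
  lxyz <- str_coords(ligand); lxyz[lh, ] <- X[nR + seq_len(nL), ]
  receptor2 <- set_coords(receptor, rxyz)
  ligand2 <- set_coords(ligand, lxyz)
  pe <- pair_energies(X[seq_len(nR), ], X[nR + seq_len(nL), ],
                      pm$EPS, pm$SIG, pm$QQ, cutoff = 8.5)
  ea <- sum(air_energies_from_coords(air_idx, X[seq_len(nR), ],
                                     X[nR + seq_len(nL), ], rs))
  stt <- surface_terms(receptor2, ligand2, params, n_points = surface_n_points)
  rep_ <- energy_report(E_vdW = pe$E_vdW, E_elec = pe$E_elec,
                        E_desolv = stt$E_desolv, E_BSA = stt$E_BSA, E_air = ea)
  out <- model
  out$receptor <- receptor2
  out$ligand <- ligand2
  out$energies <- rep_
  out$score <- haddock_score(rep_, weights)
  out$stage <- "flexref"
  out$flagged <- flagged
  out
}
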