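# Glycan conformer presampling: glycosidic-torsion perturbation with rigid
# rings, clash-relaxing restrained minimization, reduction of the ensemble
# to cluster centers, RMSD-to-reference bookkeeping.

# Describe the rotatable glycosidic linkages of a glycan: for each linkage
# edge, the anomeric-carbon/oxygen bond atoms, the oxygen's own ring
# carbon (second axis), and the downstream atom set rooted away from the
# first residue.
linkage_axes <- function(glycan, topology) {
  a <- glycan$atoms
  hv <- which(!a$is_h)
  ah <- a[hv, , drop = FALSE]
  xyz <- as.matrix(ah[, c("x", "y", "z")])
  keys <- topology$residues
  root <- keys[1]
  g <- topology$graph
  # BFS orientation away from the root residue
  bfs <- igraph::bfs(g, root = which(keys == root), father = TRUE)
  father <- as.integer(bfs$father)
  axes <- list()
  for (e in seq_len(nrow(topology$linkage_edges))) {
    pair <- topology$linkage_edges[e, ]
    i1 <- which(keys == pair[1]); i2 <- which(keys == pair[2])
    child <- if (!is.na(father[i2]) && keys[father[i2]] == pair[1]) i2 else i1
    parent <- if (child == i2) i1 else i2
    # bonded C-O pair across the two residues
    ci <- which(ah$elem == "C" & ah$reskey %in% keys[c(parent, child)])
    oi <- which(ah$elem == "O" & ah$reskey %in% keys[c(parent, child)])
    d2 <- cross_dist2(xyz[ci, , drop = FALSE], xyz[oi, , drop = FALSE])
    hit <- which(d2 <= 1.8^2 & outer(ah$reskey[ci], ah$reskey[oi], "!=") ,
                 arr.ind = TRUE)
    if (!nrow(hit)) next
    cat_i <- ci[hit[1, 1]]; oat_i <- oi[hit[1, 2]]
    # the oxygen's attachment carbon within its own residue
    own <- which(ah$elem == "C" & ah$reskey == ah$reskey[oat_i])
    d2o <- cross_dist2(xyz[oat_i, , drop = FALSE], xyz[own, , drop = FALSE])
    oc_i <- own[which.min(d2o)]
    # downstream residues: component containing the child after edge removal
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(pair[1], pair[2])))
    comp <- igraph::components(g2)$membership
    downstream <- keys[comp == comp[child]]
    axes[[length(axes) + 1L]] <- list(
      phi_axis = c(cat_i, oat_i), psi_axis = c(oat_i, oc_i),
      downstream = hv[which(ah$reskey %in% downstream)])
  }
  axes
}

# heavy-atom pairs with covalent-graph distance >= 3 and different
# residues: the set checked for steric clashes
nonbonded_intra_pairs <- function(glycan) {
  hv <- which(!glycan$atoms$is_h)
  bonds <- covalent_bonds(glycan)
  n <- length(hv)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, t(bonds))
  topo_d <- igraph::distances(g)
  ah <- glycan$atoms[hv, , drop = FALSE]
  cand <- which(upper.tri(topo_d) & topo_d >= 3 &
                outer(ah$reskey, ah$reskey, "!="), arr.ind = TRUE)
  cand
}

apply_linkage_perturbation <- function(xyz, axes, dphi, dpsi) {
  for (k in seq_along(axes)) {
    ax <- axes[[k]]
    for (turn in 1:2) {
      idx <- if (turn == 1) ax$phi_axis else ax$psi_axis
      ang <- if (turn == 1) dphi[k] else dpsi[k]
      p1 <- xyz[idx[1], ]; p2 <- xyz[idx[2], ]
      v <- p2 - p1
      if (sum(v^2) < 1e-12) next
      R <- rotmat_axis_angle(v, ang)
      rows <- ax$downstream
      xyz[rows, ] <- rotate_about(xyz[rows, , drop = FALSE], R, p1)
    }
  }
  xyz
}

#' Sample a glycan conformer ensemble
#'
#' Each member perturbs every glycosidic linkage's two torsions by Gaussian
#' deviates of width \code{sigma_deg * sqrt(effort)} degrees, keeping rings
#' internally rigid. Members with residual heavy-atom clashes (non-bonded
#' intra-glycan pairs under \code{clash_cutoff}) after a short restrained
#' relaxation are resampled, up to a retry cap. Deterministic per seed.
#'
#' @param glycan ligand \code{pg_structure}.
#' @param topology its \code{\link{build_glycan_topology}} result.
#' @param n_models ensemble size (the heavier presampling preset uses 400).
#' @param effort sampling-length multiplier (the preset analogous to a 16x
#'   longer refinement is \code{effort = 16}).
#' @param seed integer.
#' @param sigma_deg base torsion step, degrees (default 20).
#' @param clash_cutoff Angstrom (default 2.2).
#' @param max_retry resamples per member.
#' @return object of class \code{conformer_ensemble}: \code{members} (list
#'   of structures, \code{model_id} set), \code{provenance}.
#' @export
sample_conformers <- function(glycan, topology, n_models, effort = 1,
                              seed = 1L, sigma_deg = 20, clash_cutoff = 2.2,
                              max_retry = 25) {
  stopifnot(n_models >= 1)
  axes <- linkage_axes(glycan, topology)
  pairs <- nonbonded_intra_pairs(glycan)
  hv <- which(!glycan$atoms$is_h)
  # per-pair clash thresholds: never stricter than the input geometry, so
  # pre-existing tight contacts (e.g. around a branch point) do not
  # deadlock the resampling loop
  x0 <- str_coords(glycan)
  d0 <- sqrt(rowSums((x0[hv[pairs[, 1]], , drop = FALSE] -
                      x0[hv[pairs[, 2]], , drop = FALSE])^2))
  thr <- pmin(clash_cutoff, d0 - 0.05)
  sigma <- sigma_deg * sqrt(effort) * pi / 180
  members <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    done <- FALSE
    for (attempt in 0:max_retry) {
      xyz <- with_seed(derive_seed(seed, m, attempt), {
        dphi <- stats::rnorm(length(axes), sd = sigma)
        dpsi <- stats::rnorm(length(axes), sd = sigma)
        if (m == 1 && effort == 0) { dphi[] <- 0; dpsi[] <- 0 }
        apply_linkage_perturbation(str_coords(glycan), axes, dphi, dpsi)
      })
      if (clash_free(xyz, hv, pairs, thr)) { done <- TRUE; break }
      xyz <- relax_glycan(glycan, xyz, thr)
      if (clash_free(xyz, hv, pairs, thr)) { done <- TRUE; break }
    }
    if (!done)
      stop("unresolvable clash while sampling conformer ", m)
    s <- set_coords(glycan, xyz)
    s$model_id <- m
    members[[m]] <- s
  }
  structure(list(members = members,
                 provenance = list(n_models = n_models, effort = effort,
                                   seed = as.integer(seed),
                                   sigma_deg = sigma_deg),
                 rmsd_to_reference = NULL),
            class = "conformer_ensemble")
}

clash_free <- function(xyz, hv, pairs, cutoff) {
  if (!nrow(pairs)) return(TRUE)
  d2 <- rowSums((xyz[hv[pairs[, 1]], , drop = FALSE] -
                 xyz[hv[pairs[, 2]], , drop = FALSE])^2)
  all(d2 >= cutoff^2)
}

# short clash-relaxing restrained minimization: soft repulsion on clashing
# non-bonded pairs plus bond/1-3 restraints to the perturbed geometry
relax_glycan <- function(glycan, xyz, thr, max_evals = 60) {
  hv <- which(!glycan$atoms$is_h)
  bonds <- covalent_bonds(glycan)
  d0_b <- sqrt(rowSums((xyz[hv[bonds[, 1]], , drop = FALSE] -
                        xyz[hv[bonds[, 2]], , drop = FALSE])^2))
  ot <- one_three_pairs(bonds, length(hv))
  d0_a <- sqrt(rowSums((xyz[hv[ot[, 1]], , drop = FALSE] -
                        xyz[hv[ot[, 2]], , drop = FALSE])^2))
  pairs <- nonbonded_intra_pairs(glycan)
  X <- xyz[hv, , drop = FALSE]
  eg <- function(X) {
    hb <- harm_pairs_energy_grad(X, bonds, d0_b, 300)
    ha <- harm_pairs_energy_grad(X, ot, d0_a, 60)
    # one-sided repulsion below the clash cutoff
    diff <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums(diff^2))
    pen <- pmax(thr + 0.1 - d, 0)
    E <- hb$E + ha$E + sum(50 * pen^2)
    g <- hb$g + ha$g
    f <- diff * (-100 * pen / pmax(d, 1e-9))
    m1 <- rowsum(f, pairs[, 1]); i1 <- as.integer(rownames(m1))
    g[i1, ] <- g[i1, ] + m1
    m2 <- rowsum(f, pairs[, 2]); i2 <- as.integer(rownames(m2))
    g[i2, ] <- g[i2, ] - m2
    list(E = E, g = g)
  }
  res <- cartesian_min(X, seq_len(nrow(X)), eg, max_evals = max_evals)
  xyz[hv, ] <- res$X
  xyz
}

#' Heavy-atom RMSD of each ensemble member to a reference conformation
#'
#' @param ensemble a \code{conformer_ensemble}.
#' @param reference glycan \code{pg_structure} with matching atoms.
#' @return the ensemble with \code{$rmsd_to_reference} filled (Angstrom).
#' @export
rmsd_to_reference <- function(ensemble, reference) {
  ra <- reference$atoms[!reference$atoms$is_h, , drop = FALSE]
  rid <- atom_ids(ra)
  vals <- vapply(ensemble$members, function(m) {
    ma <- m$atoms
    mi <- match(rid, atom_ids(ma))
    if (anyNA(mi)) stop("correspondence error with reference glycan")
    kabsch_superpose(as.matrix(ma[mi, c("x", "y", "z")]),
                     as.matrix(ra[, c("x", "y", "z")]))$rmsd
  }, numeric(1))
  ensemble$rmsd_to_reference <- vals
  ensemble
}

#' Reduce an ensemble to cluster-center representatives
#'
#' Average-linkage clustering of the member-by-member heavy-atom RMSD
#' matrix into \code{n_clusters} flat clusters; each cluster contributes
#' the member minimizing the mean RMSD to its co-members. Requesting 20
#' clusters from a 400-member ensemble is the default docking preset.
#'
#' @param ensemble a \code{conformer_ensemble}.
#' @param n_clusters requested number of centers (default 20).
#' @return a \code{conformer_ensemble} of the centers (a subset of the
#'   input members, in cluster order).
#' @export
reduce_to_centers <- function(ensemble, n_clusters = 20) {
  n <- length(ensemble$members)
  stopifnot(n >= n_clusters)
  models <- lapply(ensemble$members, function(m)
    list(receptor = NULL, ligand = m, model_id = m$model_id))
  xyz <- lapply(ensemble$members, function(m)
    str_coords(m)[heavy_idx(m), , drop = FALSE])
  d <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (j in seq_len(n - 1)) for (i in (j + 1):n) {
    k <- k + 1L
    d[k] <- kabsch_superpose(xyz[[i]], xyz[[j]])$rmsd
  }
  if (max(d) < 1e-9) {
    warning("degenerate ensemble (all members identical): single center")
    out <- ensemble
    out$members <- ensemble$members[1]
    return(out)
  }
  dd <- structure(d, Size = n, class = "dist", Diag = FALSE, Upper = FALSE)
  memb <- stats::cutree(stats::hclust(dd, method = "average"), k = n_clusters)
  full <- as.matrix(dd)
  centers <- vapply(sort(unique(memb)), function(cl) {
    rows <- which(memb == cl)
    if (length(rows) == 1) return(rows)
    rows[which.min(rowMeans(full[rows, rows, drop = FALSE]))]
  }, integer(1))
  out <- ensemble
  out$members <- ensemble$members[sort(centers)]
  out$provenance$reduced_from <- n
  out$provenance$n_clusters <- n_clusters
  if (!is.null(ensemble$rmsd_to_reference))
    out$rmsd_to_reference <- ensemble$rmsd_to_reference[sort(centers)]
  out
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d members (effort %gx, seed %d)\n",
              length(x$members), x$provenance$effort, x$provenance$seed))
  if (!is.null(x$rmsd_to_reference))
    cat(sprintf("  RMSD to reference: min %.2f / median %.2f / max %.2f A\n",
                min(x$rmsd_to_reference), stats::median(x$rmsd_to_reference),
                max(x$rmsd_to_reference)))
  invisible(x)
}
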