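# Independent oracles and small fixture builders used across the suite.

# a bare structure from an atom table; helper around the package internals
mk_structure <- function(elem, xyz, resname = "ALA", chain = "A",
                         resid = NULL, atname = NULL,
                         role = "receptor") {
  n <- length(elem)
  if (is.null(resid)) resid <- as.character(seq_len(n))
  if (is.null(atname)) atname <- ifelse(elem == "C", "CB", elem)
  atoms <- data.frame(serial = seq_len(n), atname = atname,
                      resname = resname, chain = chain,
                      resid = as.character(resid),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, elem = elem, stringsAsFactors = FALSE)
  glycodock:::new_structure(atoms, role = role)
}

# random heavy-atom cloud as a structure (one residue per atom)
random_structure <- function(n, seed, spread = 6, shift = c(0, 0, 0),
                             elems = c("C", "N", "O", "S")) {
  set.seed(seed)
  xyz <- sweep(matrix(runif(3 * n, -spread, spread), n, 3), 2, shift, "+")
  mk_structure(sample(elems, n, replace = TRUE), xyz)
}

# Brute-force double-loop Lennard-Jones + Coulomb with the same physical
# definitions (Lorentz-Berthelot, cubic switch) written independently of
# the vectorized implementation.
brute_energies <- function(receptor, ligand, params = nonbonded_params(),
                           cutoff = 8.5, eps_r = 10, switch_width = 1.5) {
  pr <- glycodock:::resolve_params(receptor, params)
  pl <- glycodock:::resolve_params(ligand, params)
  A <- glycodock:::str_coords(receptor)[glycodock:::heavy_idx(receptor), , drop = FALSE]
  B <- glycodock:::str_coords(ligand)[glycodock:::heavy_idx(ligand), , drop = FALSE]
  r_on <- cutoff - switch_width
  elj <- 0; eel <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      r <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (r >= cutoff) next
      s <- if (r <= r_on) 1 else {
        t <- (r - r_on) / (cutoff - r_on)
        1 - t^2 * (3 - 2 * t)
      }
      eps <- sqrt(pr$eps[i] * pl$eps[j])
      sig <- (pr$sigma[i] + pl$sigma[j]) / 2
      elj <- elj + 4 * eps * ((sig / r)^12 - (sig / r)^6) * s
      eel <- eel + 332.0636 * pr$charge[i] * pl$charge[j] / (eps_r * r) * s
    }
  }
  list(E_vdW = elj, E_elec = eel)
}

# Exhaustive average-linkage agglomeration on a full distance matrix:
# repeatedly merge the pair of clusters with the smallest mean
# inter-cluster distance. Returns the flat partition with k clusters, as a
# membership vector.
naive_average_linkage <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  memb
}

# same, cutting when no inter-cluster mean distance is below h
naive_average_linkage_h <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  memb
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# RMSD between centred point sets under an explicit rotation matrix, via
# the trace identity: closed-form evaluation used to probe many random
# rotations cheaply
rotation_rmsds <- function(X, Y, rotations) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  Sx <- sum(Xc^2); Sy <- sum(Yc^2)
  A <- t(Xc) %*% Yc   # tr(R A) = sum_i y_i . (R x_i)
  vapply(rotations, function(R) {
    sqrt(max(Sx + Sy - 2 * sum(diag(R %*% A)), 0) / nrow(X))
  }, numeric(1))
}

random_rotation <- function() glycodock:::quat_to_mat(glycodock:::quat_normalize(rnorm(4)))

# shared toy fixture (built once per test file load)
shared_toy <- local({
  toy <- NULL
  function() {
    if (is.null(toy)) toy <<- make_toy_complex(3, FALSE, seed = 7)
    toy
  }
})
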