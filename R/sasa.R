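# Solvent-accessible surface area by Shrake-Rupley sphere sampling, plus
# the buried-surface and empirical desolvation terms derived from it.

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(elem) {
  r <- .VDW_RADII[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples points on each heavy atom's solvent-expanded sphere (van der
#' Waals radius + probe) on a deterministic golden-spiral lattice and counts
#' the fraction not buried inside any neighbouring sphere. Hydrogens get
#' zero area and do not occlude.
#'
#' @param structure a \code{pg_structure} (or anything with an atoms table).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return numeric vector of per-atom areas in A^2, aligned with the atom
#'   table (zeros for hydrogens).
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  stopifnot(probe > 0, n_points >= 100)
  a <- structure$atoms
  out <- numeric(nrow(a))
  hv <- which(!a$is_h)
  if (!length(hv)) return(out)
  xyz <- as.matrix(a[hv, c("x", "y", "z")])
  rad <- vdw_radius(a$elem[hv]) + probe
  pts <- sphere_points(n_points)
  n <- length(hv)
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nbr)) {
      out[hv[i]] <- 4 * pi * rad[i]^2
      next
    }
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    # a point is buried if it falls inside any neighbouring sphere
    dj <- cross_dist2(p, xyz[nbr, , drop = FALSE])
    buried <- rowSums(dj < matrix(rad[nbr]^2, n_points, length(nbr),
                                  byrow = TRUE)) > 0
    out[hv[i]] <- 4 * pi * rad[i]^2 * mean(!buried)
  }
  out
}

# merge two partners into one structure for complex-state surface areas
combine_structures <- function(receptor, ligand) {
  atoms <- rbind(receptor$atoms, ligand$atoms)
  structure(list(atoms = atoms, role = "receptor", model_id = 1L),
            class = "pg_structure")
}

#' Buried surface area of a posed complex
#'
#' \code{SASA(receptor) + SASA(ligand) - SASA(complex)}; non-negative up to
#' sampling noise.
#'
#' @inheritParams sasa
#' @param receptor,ligand posed partners.
#' @return buried surface area, A^2.
#' @export
bsa <- function(receptor, ligand, probe = 1.4, n_points = 960) {
  st <- surface_terms(receptor, ligand, probe = probe, n_points = n_points)
  st$E_BSA
}

#' Empirical desolvation energy
#'
#' Per-atom solvation parameter times the surface area each atom loses on
#' complex formation, summed over both partners:
#' \eqn{\sum \sigma_{solv} (SASA_{free} - SASA_{complex})}.
#'
#' @inheritParams bsa
#' @param params nonbonded parameter table carrying the \code{solv} column.
#' @return E_desolv, kcal/mol.
#' @export
desolvation <- function(receptor, ligand, params = nonbonded_params(),
                        probe = 1.4, n_points = 960) {
  st <- surface_terms(receptor, ligand, params, probe, n_points)
  st$E_desolv
}

# Shared computation of BSA and desolvation from three SASA evaluations.
# receptor_sasa allows the (pose-independent) free-receptor areas to be
# precomputed once per docking run.
surface_terms <- function(receptor, ligand, params = nonbonded_params(),
                          probe = 1.4, n_points = 960, receptor_sasa = NULL) {
  sr <- if (is.null(receptor_sasa)) sasa(receptor, probe, n_points)
        else receptor_sasa
  sl <- sasa(ligand, probe, n_points)
  sc <- sasa(combine_structures(receptor, ligand), probe, n_points)
  free <- c(sr, sl)
  buried <- free - sc
  sig <- numeric(length(free))
  hr <- !receptor$atoms$is_h
  hl <- !ligand$atoms$is_h
  sig[which(hr)] <- resolve_params(receptor, params)$solv
  sig[nrow(receptor$atoms) + which(hl)] <- resolve_params(ligand, params)$solv
  list(E_BSA = max(sum(buried), 0), E_desolv = sum(sig * buried))
}
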