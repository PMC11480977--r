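# Intermolecular energetics: nonbonded parameter table, Lennard-Jones,
# Coulomb, score assembly. Heavy atoms only; hydrogens carry no nonbonded
# parameters here.

COULOMB_CONST <- 332.0636  # kcal mol^-1 A e^-2

#' Default nonbonded parameter table
#'
#' A compact, self-contained table of Lennard-Jones well depths/diameters,
#' partial charges and atomic solvation parameters per atom class, with an
#' element-level fallback. Classes: \code{C} aliphatic carbon, \code{CC}
#' carbonyl carbon, \code{O} hydroxyl/ether oxygen, \code{OC} carbonyl
#' oxygen, \code{N} nitrogen, \code{S} sulfur. Values are in the OPLS range
#' but deliberately generic; every number can be overridden by passing an
#' edited copy to the energy functions.
#'
#' @return data.frame with columns \code{class}, \code{eps} (kcal/mol),
#'   \code{sigma} (Angstrom), \code{charge} (e), \code{solv}
#'   (kcal/(mol A^2)).
#' @export
nonbonded_params <- function() {
  # sugar carbons (CS) carry a compensating positive charge so that a
  # heavy-atom-only monosaccharide is net neutral (the hydroxyl protons
  # that would balance the ring are not represented)
  # CW is an uncharged coarse "bulk" carbon with an inflated radius,
  # representing close-packed interior protein in coarse fixtures
  data.frame(
    class = c("C",    "CC",   "CS",   "O",    "OC",   "OS",   "N",    "S",   "CW"),
    eps   = c(0.066,  0.105,  0.066,  0.170,  0.210,  0.170,  0.170,  0.250, 0.02),
    sigma = c(3.50,   3.75,   3.50,   3.07,   2.96,   3.07,   3.25,   3.55,  4.60),
    charge = c(0.10,  0.45,   0.30,  -0.40,  -0.45,  -0.30,  -0.35,  -0.15, 0.00),
    solv  = c(0.012,  0.012,  0.008, -0.006, -0.006, -0.006, -0.006,  0.006, 0.00),
    stringsAsFactors = FALSE
  )
}

# simple atom-class typer; element-level fallback is the class of the bare
# element symbol where present, else an error
atom_class <- function(elem, atname, kind) {
  cls <- elem
  cls[elem == "C" & atname == "C" & kind == "amino-acid"] <- "CC"
  cls[elem == "O" & atname == "O" & kind == "amino-acid"] <- "OC"
  cls[elem == "C" & kind == "monosaccharide"] <- "CS"
  cls[elem == "O" & kind == "monosaccharide"] <- "OS"
  cls[atname == "CW"] <- "CW"
  cls
}

resolve_params <- function(s, params = nonbonded_params()) {
  a <- s$atoms[!s$atoms$is_h, , drop = FALSE]
  cls <- atom_class(a$elem, a$atname, a$kind)
  i <- match(cls, params$class)
  fb <- is.na(i)
  i[fb] <- match(a$elem[fb], params$class)
  if (anyNA(i))
    stop("parameter error: no nonbonded parameters for atom class(es) ",
         paste(unique(cls[is.na(i)]), collapse = ", "))
  list(eps = params$eps[i], sigma = params$sigma[i],
       charge = params$charge[i], solv = params$solv[i])
}

# cubic smoothstep switching from 1 at r_on down to 0 at r_off
switch_fn <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  s[r >= r_off] <- 0
  mid <- r > r_on & r < r_off
  t <- (r[mid] - r_on) / (r_off - r_on)
  s[mid] <- 1 - t * t * (3 - 2 * t)
  s
}

switch_dfn <- function(r, r_on, r_off) {
  ds <- rep(0, length(r))
  mid <- r > r_on & r < r_off
  t <- (r[mid] - r_on) / (r_off - r_on)
  ds[mid] <- -6 * t * (1 - t) / (r_off - r_on)
  ds
}

# Pairwise intermolecular energies (and optionally Cartesian gradients)
# between two coordinate blocks, given precomputed pair parameter matrices.
pair_energies <- function(A, B, EPS, SIG, QQ, cutoff, switch_width = 1.5,
                          grad = FALSE, wlj = 1, wel = 1) {
  # wlj/wel weight the two terms inside the returned gradient only; the
  # energies are always reported unweighted
  d2 <- cross_dist2(A, B)
  within <- which(d2 < cutoff^2 & d2 > 1e-12)
  out <- list(E_vdW = 0, E_elec = 0)
  if (grad) { out$gA <- matrix(0, nrow(A), 3); out$gB <- matrix(0, nrow(B), 3) }
  if (!length(within)) return(out)
  if (any(d2 <= 1e-12)) stop("singularity: coincident intermolecular atoms")
  r <- sqrt(d2[within])
  r_on <- cutoff - switch_width
  s <- switch_fn(r, r_on, cutoff)
  eps <- EPS[within]; sig <- SIG[within]; qq <- QQ[within]
  sr6 <- (sig / r)^6
  elj <- 4 * eps * (sr6 * sr6 - sr6)
  eel <- qq / r
  out$E_vdW <- sum(elj * s)
  out$E_elec <- sum(eel * s)
  if (grad) {
    ds <- switch_dfn(r, r_on, cutoff)
    dlj <- 4 * eps * (-12 * sr6 * sr6 + 6 * sr6) / r
    del <- -qq / (r * r)
    dEdr <- (wlj * dlj + wel * del) * s + (wlj * elj + wel * eel) * ds
    ij <- arrayInd(within, dim(d2))
    diff <- A[ij[, 1], , drop = FALSE] - B[ij[, 2], , drop = FALSE]
    f <- diff * (dEdr / r)
    mA <- rowsum(f, ij[, 1])
    iA <- as.integer(rownames(mA))
    out$gA[iA, ] <- out$gA[iA, ] + mA
    mB <- rowsum(f, ij[, 2])
    iB <- as.integer(rownames(mB))
    out$gB[iB, ] <- out$gB[iB, ] - mB
  }
  out
}

pair_param_matrices <- function(pr, pl, eps_r = 10) {
  list(
    EPS = sqrt(outer(pr$eps, pl$eps)),
    SIG = outer(pr$sigma, pl$sigma, function(a, b) (a + b) / 2),
    QQ = COULOMB_CONST * outer(pr$charge, pl$charge) / eps_r
  )
}

#' Intermolecular Lennard-Jones energy
#'
#' Sum over receptor-ligand heavy-atom pairs of the 12-6 potential with
#' Lorentz-Berthelot combination, smoothly switched to zero over the last
#' \code{switch_width} Angstrom before the cutoff.
#'
#' @param receptor,ligand posed partners.
#' @param params nonbonded table (see \code{\link{nonbonded_params}}).
#' @param cutoff pair cutoff, Angstrom (default 8.5).
#' @param switch_width width of the switching region, Angstrom.
#' @return E_vdW in kcal/mol.
#' @export
lennard_jones <- function(receptor, ligand, params = nonbonded_params(),
                          cutoff = 8.5, switch_width = 1.5) {
  stopifnot(cutoff > 0)
  pr <- resolve_params(receptor, params); pl <- resolve_params(ligand, params)
  pm <- pair_param_matrices(pr, pl)
  A <- str_coords(receptor)[heavy_idx(receptor), , drop = FALSE]
  B <- str_coords(ligand)[heavy_idx(ligand), , drop = FALSE]
  pair_energies(A, B, pm$EPS, pm$SIG, pm$QQ, cutoff, switch_width)$E_vdW
}

#' Intermolecular Coulomb energy
#'
#' \eqn{332.0636\, q_i q_j / (\epsilon_r r_{ij})} summed over intermolecular
#' heavy-atom pairs within the cutoff, with the same cubic switching as the
#' Lennard-Jones term. The relative permittivity defaults to 10.
#'
#' @inheritParams lennard_jones
#' @param eps_r relative permittivity.
#' @return E_elec in kcal/mol.
#' @export
coulomb <- function(receptor, ligand, params = nonbonded_params(),
                    cutoff = 8.5, eps_r = 10, switch_width = 1.5) {
  stopifnot(cutoff > 0)
  pr <- resolve_params(receptor, params); pl <- resolve_params(ligand, params)
  pm <- pair_param_matrices(pr, pl, eps_r)
  A <- str_coords(receptor)[heavy_idx(receptor), , drop = FALSE]
  B <- str_coords(ligand)[heavy_idx(ligand), , drop = FALSE]
  pair_energies(A, B, pm$EPS, pm$SIG, pm$QQ, cutoff, switch_width)$E_elec
}

#' Stage-specific scoring weights
#'
#' Weight vectors for the linear score. \code{"rigid-default"} uses
#' w_vdW = 0.01, the historical rigid-body weighting; \code{"rigid-vdw"}
#' raises w_vdW to 1.0, the weighting recommended for small ligands such as
#' glycans; \code{"flexref"} is the refinement-stage weighting. Buried
#' surface enters with a negative weight (burial is rewarded).
#'
#' @param stage one of \code{"rigid-default"}, \code{"rigid-vdw"},
#'   \code{"flexref"}, or \code{"custom"} (then supply every weight).
#' @param w_vdW,w_elec,w_desolv,w_BSA,w_air optional overrides.
#' @return named list of weights with class \code{scoring_weights}.
#' @export
scoring_weights <- function(stage = c("rigid-default", "rigid-vdw", "flexref",
                                      "custom"),
                            w_vdW = NULL, w_elec = NULL, w_desolv = NULL,
                            w_BSA = NULL, w_air = NULL) {
  stage <- match.arg(stage)
  w <- switch(stage,
    "rigid-default" = list(w_vdW = 0.01, w_elec = 1.0, w_desolv = 1.0,
                           w_BSA = -0.01, w_air = 0.01),
    "rigid-vdw" = list(w_vdW = 1.0, w_elec = 1.0, w_desolv = 1.0,
                       w_BSA = -0.01, w_air = 0.01),
    "flexref" = list(w_vdW = 1.0, w_elec = 1.0, w_desolv = 1.0,
                     w_BSA = 0.0, w_air = 0.1),
    "custom" = list(w_vdW = 1.0, w_elec = 1.0, w_desolv = 1.0,
                    w_BSA = 0.0, w_air = 1.0)
  )
  for (nm in names(w)) {
    ov <- get(nm)
    if (!is.null(ov)) w[[nm]] <- ov
  }
  stopifnot(all(vapply(w, is.finite, TRUE)))
  structure(c(w, list(stage = stage)), class = "scoring_weights")
}

#' Assemble an energy report
#' @param E_vdW,E_elec,E_desolv,E_air kcal/mol; \code{E_BSA} in A^2.
#' @return named list of class \code{energy_report}.
#' @export
energy_report <- function(E_vdW = 0, E_elec = 0, E_desolv = 0, E_BSA = 0,
                          E_air = 0) {
  r <- list(E_vdW = E_vdW, E_elec = E_elec, E_desolv = E_desolv,
            E_BSA = E_BSA, E_air = E_air)
  stopifnot(all(vapply(r, is.finite, TRUE)))
  structure(r, class = "energy_report")
}

#' Weighted docking score
#'
#' The linear combination \eqn{w_{vdW} E_{vdW} + w_{elec} E_{elec} +
#' w_{desolv} E_{desolv} + w_{BSA} E_{BSA} + w_{air} E_{air}}; lower is
#' better.
#'
#' @param report an \code{\link{energy_report}}.
#' @param weights a \code{\link{scoring_weights}} object.
#' @return dimensionless score.
#' @export
haddock_score <- function(report, weights) {
  weights$w_vdW * report$E_vdW + weights$w_elec * report$E_elec +
    weights$w_desolv * report$E_desolv + weights$w_BSA * report$E_BSA +
    weights$w_air * report$E_air
}
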