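# Ambiguous interaction restraints (AIRs): construction, effective distance,
# flat-bottom harmonic-to-linear energy, random discard.

#' Build ambiguous interaction restraints from interface information
#'
#' Two scenarios are supported. In the true-interface scenario
#' (\code{"ti-aa"}) the interface residues of both partners (residues with a
#' heavy atom within \code{interface_cutoff} of the partner in the reference
#' complex) are active, and each active residue anchors one AIR whose
#' targets are the partner's active set. In the protein-active / glycan-
#' passive scenario (\code{"tip-ap"}) only the protein interface residues
#' are active and every glycan residue is a passive target; glycan residues
#' anchor no restraint and hence generate no energy of their own.
#'
#' @param receptor,ligand the docking partners (\code{pg_structure}).
#' @param scenario \code{"ti-aa"} or \code{"tip-ap"}.
#' @param interface_cutoff heavy-atom contact cutoff defining the true
#'   interface, Angstrom (default 3.9).
#' @param reference optional list(receptor=, ligand=) bound complex defining
#'   the true interface; defaults to the input pair itself.
#' @param active optional list(receptor=, ligand=) of residue keys supplied
#'   directly, bypassing interface detection.
#' @param upper_bound,lower_bound AIR distance bounds, Angstrom.
#' @param force_constant harmonic constant, kcal/(mol A^2).
#' @param switch_violation violation at which the harmonic branch hands over
#'   to the linear one, Angstrom.
#' @param calibrate_bounds if TRUE (and a reference is available), each
#'   AIR's upper bound is widened to its effective distance at the
#'   reference pose (plus a 0.1 A margin) whenever the nominal bound is
#'   tighter: a true-interface restraint must be satisfiable at the truth
#'   it was derived from. The conventional 2.0 A bound presumes all-atom
#'   residues; for sparse atom sets the calibrated bound keeps the
#'   restraint minimum at the reference geometry.
#' @return object of class \code{restraint_set}.
#' @export
build_airs <- function(receptor, ligand, scenario = c("ti-aa", "tip-ap"),
                       interface_cutoff = 3.9, reference = NULL, active = NULL,
                       upper_bound = 2.0, lower_bound = 0.0,
                       force_constant = 50, switch_violation = 1.0,
                       calibrate_bounds = FALSE) {
  scenario <- match.arg(scenario)
  ref <- if (is.null(reference)) list(receptor = receptor, ligand = ligand) else reference
  if (is.null(active)) {
    active <- select_interface(ref$receptor, ref$ligand, interface_cutoff)
  }
  if (!length(active$receptor))
    stop("configuration error: empty active set on the protein")
  airs <- list()
  if (scenario == "ti-aa") {
    if (!length(active$ligand))
      stop("configuration error: ti-aa needs active residues on the glycan")
    for (r in active$receptor)
      airs[[length(airs) + 1L]] <- list(side = "receptor", anchor = r,
                                        targets = active$ligand)
    for (l in active$ligand)
      airs[[length(airs) + 1L]] <- list(side = "ligand", anchor = l,
                                        targets = active$receptor)
  } else {
    passive <- res_keys(ligand)
    for (r in active$receptor)
      airs[[length(airs) + 1L]] <- list(side = "receptor", anchor = r,
                                        targets = passive)
  }
  rs <- structure(list(airs = airs, scenario = scenario,
                       active = active,
                       upper_bound = upper_bound, lower_bound = lower_bound,
                       force_constant = force_constant,
                       switch_violation = switch_violation),
                  class = "restraint_set")
  if (calibrate_bounds) {
    idx <- air_indices(rs, ref$receptor, ref$ligand)
    rxyz <- str_coords(ref$receptor)[heavy_idx(ref$receptor), , drop = FALSE]
    lxyz <- str_coords(ref$ligand)[heavy_idx(ref$ligand), , drop = FALSE]
    for (k in seq_along(rs$airs)) {
      ai <- idx[[k]]
      d <- if (ai$anchor_side == "receptor")
        effective_distance(rxyz[ai$anchor, , drop = FALSE],
                           lxyz[ai$targets, , drop = FALSE])
      else
        effective_distance(lxyz[ai$anchor, , drop = FALSE],
                           rxyz[ai$targets, , drop = FALSE])
      rs$airs[[k]]$upper_bound <- max(upper_bound, d + 0.1)
    }
  }
  rs
}

# per-AIR upper bound (calibrated) falling back to the set default
air_upper_bound <- function(air, rs) {
  if (!is.null(air$upper_bound)) air$upper_bound else rs$upper_bound
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %s: %d AIRs (k=%g, bounds [%g, %g] A, switch %g A)\n",
              x$scenario, length(x$airs), x$force_constant,
              x$lower_bound, x$upper_bound, x$switch_violation))
  invisible(x)
}

#' Effective distance between two heavy-atom sets
#'
#' The ambiguous-restraint distance: \eqn{d_{eff} = (\sum_{ij}
#' d_{ij}^{-6})^{-1/6}} over all anchor-target atom pairs. Dominated by the
#' shortest pair, and never larger than it.
#'
#' @param anchor_atoms,target_atoms n x 3 coordinate matrices.
#' @return effective distance, Angstrom.
#' @export
effective_distance <- function(anchor_atoms, target_atoms) {
  if (!nrow(anchor_atoms) || !nrow(target_atoms)) stop("empty atom set")
  d2 <- cross_dist2(anchor_atoms, target_atoms)
  if (any(d2 < 1e-12)) stop("coincident atoms in effective distance")
  sum(d2^(-3))^(-1 / 6)
}

#' Flat-bottom restraint energy
#'
#' Zero inside \code{[lower_bound, upper_bound]}; harmonic \eqn{k v^2} for
#' violations up to \code{switch_violation}; beyond that, linear with the
#' slope and value matched at the switch (so the force stays bounded).
#' Violations below the lower bound are treated symmetrically.
#'
#' @param d_eff effective distance, Angstrom.
#' @param restraints a \code{restraint_set} supplying k, bounds and switch.
#' @return energy in kcal/mol.
#' @export
air_energy <- function(d_eff, restraints) {
  v <- pmax(d_eff - restraints$upper_bound, restraints$lower_bound - d_eff, 0)
  flat_bottom_energy(v, restraints$force_constant, restraints$switch_violation)
}

flat_bottom_energy <- function(v, k, sv) {
  ifelse(v <= sv, k * v^2, k * sv^2 + 2 * k * sv * (v - sv))
}

# dE/dv of the flat-bottom form (used by the refinement gradients)
flat_bottom_dEdv <- function(v, k, sv) {
  ifelse(v <= sv, 2 * k * v, 2 * k * sv)
}

#' Total restraint energy of a posed complex
#'
#' Sums \code{\link{air_energy}} over every AIR in the set, resolving each
#' anchor and target residue to its heavy atoms in the supplied pose.
#'
#' @param receptor,ligand posed partners.
#' @param restraints a \code{restraint_set} (possibly after
#'   \code{\link{random_discard}}).
#' @return total E_air, kcal/mol (non-negative).
#' @export
total_air_energy <- function(receptor, ligand, restraints) {
  idx <- air_indices(restraints, receptor, ligand)
  rxyz <- str_coords(receptor)[heavy_idx(receptor), , drop = FALSE]
  lxyz <- str_coords(ligand)[heavy_idx(ligand), , drop = FALSE]
  sum(air_energies_from_coords(idx, rxyz, lxyz, restraints))
}

# Resolve AIR residues to row indices into the heavy-atom coordinate blocks
# of each partner; fails loudly if a restrained residue is absent.
air_indices <- function(restraints, receptor, ligand) {
  rh <- receptor$atoms[!receptor$atoms$is_h, , drop = FALSE]
  lh <- ligand$atoms[!ligand$atoms$is_h, , drop = FALSE]
  lookup <- function(keys, tab, what) {
    out <- lapply(keys, function(k) which(tab$reskey == k))
    miss <- keys[!vapply(out, length, 1L) > 0]
    if (length(miss))
      stop("restraint resolution error: residue(s) not in ", what, ": ",
           paste(miss, collapse = ", "))
    out
  }
  lapply(restraints$airs, function(air) {
    if (air$side == "receptor") {
      list(anchor_side = "receptor",
           anchor = unlist(lookup(air$anchor, rh, "receptor")),
           targets = unlist(lookup(air$targets, lh, "ligand")),
           ub = air_upper_bound(air, restraints))
    } else {
      list(anchor_side = "ligand",
           anchor = unlist(lookup(air$anchor, lh, "ligand")),
           targets = unlist(lookup(air$targets, rh, "receptor")),
           ub = air_upper_bound(air, restraints))
    }
  })
}

air_energies_from_coords <- function(idx, rxyz, lxyz, restraints) {
  vapply(idx, function(ai) {
    if (ai$anchor_side == "receptor") {
      d <- effective_distance(rxyz[ai$anchor, , drop = FALSE],
                              lxyz[ai$targets, , drop = FALSE])
    } else {
      d <- effective_distance(lxyz[ai$anchor, , drop = FALSE],
                              rxyz[ai$targets, , drop = FALSE])
    }
    v <- max(d - ai$ub, restraints$lower_bound - d, 0)
    flat_bottom_energy(v, restraints$force_constant,
                       restraints$switch_violation)
  }, numeric(1))
}

#' Randomly discard a fraction of the AIRs
#'
#' Each docking model draws its own independently discarded restraint
#' subset (by default half of them), a hedge against false-positive
#' interface information. Deterministic for a given seed.
#'
#' @param restraints a \code{restraint_set}.
#' @param fraction proportion to discard, in [0, 1).
#' @param seed integer seed for the draw.
#' @return a \code{restraint_set} retaining \code{ceiling((1-fraction)*n)}
#'   AIRs.
#' @export
random_discard <- function(restraints, fraction = 0.5, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(restraints$airs)
  keep_n <- ceiling((1 - fraction) * n)
  if (keep_n == n) return(restraints)
  keep <- with_seed(seed, sort(sample.int(n, keep_n)))
  restraints$airs <- restraints$airs[keep]
  restraints
}

#' Read an active/passive residue table
#'
#' Plain-text restraint definitions: a whitespace- or tab-separated table
#' with columns \code{chain}, \code{resid}, \code{role} (\code{active} or
#' \code{passive}) and \code{partner} (\code{receptor} or \code{ligand}).
#' Lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @return list with \code{active} and \code{passive}, each holding
#'   \code{receptor}/\code{ligand} residue-key vectors, suitable for the
#'   \code{active} argument of \code{\link{build_airs}}.
#' @export
read_restraint_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chain", "resid", "role", "partner")
  if (!all(need %in% names(df)))
    stop("restraint table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$role %in% c("active", "passive")))
    stop("role must be 'active' or 'passive'")
  if (!all(df$partner %in% c("receptor", "ligand")))
    stop("partner must be 'receptor' or 'ligand'")
  key <- paste(df$chain, df$resid, sep = ":")
  pick <- function(role, partner) key[df$role == role & df$partner == partner]
  list(active = list(receptor = pick("active", "receptor"),
                     ligand = pick("active", "ligand")),
       passive = list(receptor = pick("passive", "receptor"),
                      ligand = pick("passive", "ligand")))
}

#' Export the derived AIR list for audit
#'
#' One row per ambiguous restraint: anchor side and residue, target
#' residues, and the (possibly calibrated) upper bound.
#'
#' @param restraints a \code{restraint_set}.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_restraint_table <- function(restraints, path) {
  df <- do.call(rbind, lapply(restraints$airs, function(a)
    data.frame(side = a$side, anchor = a$anchor,
               targets = paste(a$targets, collapse = ","),
               upper_bound = air_upper_bound(a, restraints),
               lower_bound = restraints$lower_bound)))
  df$upper_bound <- sprintf("%.3f", df$upper_bound)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
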