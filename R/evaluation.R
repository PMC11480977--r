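# CAPRI-style model quality assessment: interface-ligand RMSD, quality
# tiers, single-model and cluster-based success rates.

# small synonym map for glycan atom-naming dialects
.ATOM_SYNONYMS <- c("O5'" = "O5", "C1'" = "C1", "C2'" = "C2", "C3'" = "C3",
                    "C4'" = "C4", "C5'" = "C5", "C6'" = "C6")

canonical_atname <- function(atname) {
  hit <- match(atname, names(.ATOM_SYNONYMS))
  atname[!is.na(hit)] <- .ATOM_SYNONYMS[hit[!is.na(hit)]]
  atname
}

atom_ids <- function(atoms) {
  paste(atoms$chain, atoms$resid, canonical_atname(atoms$atname))
}

# pull a model/reference into a list(receptor=, ligand=) pair
as_complex_pair <- function(x) {
  if (inherits(x, "toy_complex")) return(list(receptor = x$receptor, ligand = x$glycan))
  if (inherits(x, "docking_model")) return(list(receptor = x$receptor, ligand = x$ligand))
  stopifnot(!is.null(x$receptor), !is.null(x$ligand) || !is.null(x$glycan))
  list(receptor = x$receptor, ligand = if (is.null(x$ligand)) x$glycan else x$ligand)
}

#' Interface-ligand RMSD
#'
#' The model is superposed onto the reference using the backbone atoms of
#' the reference's protein interface residues (heavy-atom contacts within
#' \code{interface_cutoff} of the glycan); the RMSD is then measured over
#' the heavy atoms of the glycan without re-fitting. This keeps the metric
#' sensitive to the ligand placement rather than the (much larger) protein
#' interface.
#'
#' @param model a posed complex: \code{docking_model}, \code{toy_complex},
#'   or list(receptor=, ligand=).
#' @param reference the reference complex, same forms accepted.
#' @param interface_cutoff heavy-atom cutoff defining the reference
#'   interface, Angstrom (default 3.9).
#' @return IL-RMSD in Angstrom.
#' @export
il_rmsd <- function(model, reference, interface_cutoff = 3.9) {
  m <- as_complex_pair(model); r <- as_complex_pair(reference)
  iface <- select_interface(r$receptor, r$ligand, interface_cutoff)
  rra <- r$receptor$atoms
  fit_ref <- rra$is_backbone & rra$reskey %in% iface$receptor
  if (sum(fit_ref) < 3)
    stop("fewer than 3 backbone atoms in the reference protein interface")
  mra <- m$receptor$atoms
  ref_ids <- atom_ids(rra)[fit_ref]
  mi <- match(ref_ids, atom_ids(mra))
  if (anyNA(mi))
    stop("correspondence error: interface backbone atoms missing in model: ",
         paste(ref_ids[is.na(mi)], collapse = ", "))
  fit <- kabsch_superpose(as.matrix(mra[mi, c("x", "y", "z")]),
                          as.matrix(rra[fit_ref, c("x", "y", "z")]))
  # measure on glycan heavy atoms, transform from the interface fit
  rla <- r$ligand$atoms[!r$ligand$atoms$is_h, , drop = FALSE]
  mla <- m$ligand$atoms
  li <- match(atom_ids(rla), atom_ids(mla))
  if (anyNA(li))
    stop("correspondence error: glycan heavy atoms missing in model: ",
         paste(atom_ids(rla)[is.na(li)], collapse = ", "))
  mob <- as.matrix(mla[li, c("x", "y", "z")]) %*% t(fit$R)
  mob <- sweep(mob, 2, fit$t, "+")
  coord_rmsd(mob, as.matrix(rla[, c("x", "y", "z")]))
}

#' Quality tier from IL-RMSD
#'
#' Inclusive cutoffs: high \eqn{\le} 1.0 A, medium \eqn{\le} 2.0 A,
#' acceptable \eqn{\le} 3.0 A, near-acceptable \eqn{\le} 4.0 A, else none.
#' The 4 A tier is meaningful mainly for long glycans.
#'
#' @param il_rmsd numeric vector of IL-RMSD values, Angstrom.
#' @return factor with levels high, medium, acceptable, near-acceptable,
#'   none.
#' @export
classify_quality <- function(il_rmsd) {
  stopifnot(all(il_rmsd >= 0))
  cut(il_rmsd, breaks = c(-Inf, 1, 2, 3, 4, Inf),
      labels = c("high", "medium", "acceptable", "near-acceptable", "none"))
}

.TIER_CUTOFFS <- c(high = 1, medium = 2, acceptable = 3, "near-acceptable" = 4)

#' Evaluate a set of docking models against a reference
#'
#' @param models list of \code{docking_model}s (scored).
#' @param reference reference complex.
#' @param interface_cutoff Angstrom.
#' @return data.frame (one row per model, ranked by score): model_id,
#'   score, rank_by_score, il_rmsd, quality.
#' @export
eval_records <- function(models, reference, interface_cutoff = 3.9) {
  sc <- vapply(models, function(m) m$score, numeric(1))
  id <- vapply(models, function(m) m$model_id, numeric(1))
  ord <- order(sc, id)
  ilr <- vapply(models[ord], il_rmsd, numeric(1), reference = reference,
                interface_cutoff = interface_cutoff)
  data.frame(model_id = id[ord], score = sc[ord],
             rank_by_score = seq_along(ord), il_rmsd = ilr,
             quality = classify_quality(ilr))
}

#' Single-model success-rate table
#'
#' For each top-N ranking depth and each quality tier, the fraction of
#' complexes with at least one model of that tier or better among the top N
#' by score. Tiers count cumulatively (a high model also satisfies medium,
#' acceptable and near-acceptable).
#'
#' @param records list of per-complex evaluation tables (from
#'   \code{\link{eval_records}}), each ranked by score.
#' @param tops integer vector of ranking depths.
#' @return data.frame: top_n plus one fraction column per tier.
#' @export
success_rate <- function(records, tops = c(1, 5, 10, 50, 100, 200)) {
  if (!length(records)) stop("empty complex list")
  out <- data.frame(top_n = tops)
  for (tier in names(.TIER_CUTOFFS)) {
    thr <- .TIER_CUTOFFS[tier]
    best_rank <- vapply(records, function(r) {
      hit <- which(r$il_rmsd <= thr)
      if (length(hit)) r$rank_by_score[hit[1]] else Inf
    }, numeric(1))
    out[[tier]] <- vapply(tops, function(N) mean(best_rank <= N), numeric(1))
  }
  out
}

#' Cluster-based success-rate table
#'
#' A cluster inherits the best tier among its top \code{top_members}
#' scoring members (4 after refinement; the rigid stage uses 5). The SR at
#' depth N is the fraction of complexes whose top-N ranked clusters include
#' one of the required tier or better.
#'
#' @param cluster_records list (one element per complex) of lists of
#'   per-cluster evaluation tables in cluster-rank order, each table ranked
#'   by member score.
#' @param top_members members considered per cluster (default 4).
#' @param tops cluster ranking depths (default 1..10).
#' @return data.frame as in \code{\link{success_rate}}.
#' @export
cluster_success_rate <- function(cluster_records, top_members = 4,
                                 tops = 1:10) {
  if (!length(cluster_records)) stop("empty complex list")
  out <- data.frame(top_n = tops)
  for (tier in names(.TIER_CUTOFFS)) {
    thr <- .TIER_CUTOFFS[tier]
    best_rank <- vapply(cluster_records, function(clusters) {
      ok <- vapply(clusters, function(r)
        any(utils::head(r$il_rmsd, top_members) <= thr), logical(1))
      if (any(ok)) which(ok)[1] else Inf
    }, numeric(1))
    out[[tier]] <- vapply(tops, function(N) mean(best_rank <= N), numeric(1))
  }
  out
}

#' Bar chart of a success-rate table
#'
#' Grouped bars (one group per ranking depth, one bar per quality tier),
#' in the style of benchmark success-rate figures.
#'
#' @param sr a table from \code{\link{success_rate}} or
#'   \code{\link{cluster_success_rate}}.
#' @param main plot title.
#' @return invisibly, the bar midpoints.
#' @export
plot_success_rates <- function(sr, main = "Success rate") {
  tiers <- setdiff(names(sr), "top_n")
  m <- t(as.matrix(sr[, tiers])) * 100
  colnames(m) <- paste0("T", sr$top_n)
  mid <- graphics::barplot(m, beside = TRUE, ylim = c(0, 100),
                           ylab = "Success rate (%)", main = main,
                           legend.text = tiers,
                           col = grDevices::hcl.colors(length(tiers), "Blues 3"))
  invisible(mid)
}
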