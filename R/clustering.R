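# Pairwise RMSD matrices over docking models, average-linkage hierarchical
# clustering, cluster ranking and cluster-based model selection.

# Selection atom indices for the RMSD matrix, defined on the reference
# complex: ti-aa uses heavy atoms of all interface residues on both
# partners; tip-ap uses the protein interface residues plus the whole
# glycan.
rmsd_selection <- function(reference, mode = c("ti-aa", "tip-ap"),
                           interface_cutoff = 3.9) {
  mode <- match.arg(mode)
  ref <- as_complex_pair(reference)
  iface <- select_interface(ref$receptor, ref$ligand, interface_cutoff)
  ra <- ref$receptor$atoms
  la <- ref$ligand$atoms
  ridx <- which(!ra$is_h & ra$reskey %in% iface$receptor)
  lidx <- if (mode == "ti-aa") which(!la$is_h & la$reskey %in% iface$ligand)
          else which(!la$is_h)
  list(receptor = ridx, ligand = lidx, mode = mode)
}

#' Pairwise RMSD matrix between docking models
#'
#' Heavy-atom RMSD over the restraint scenario's selection (interface
#' residues of both partners for ti-aa; protein interface plus whole
#' glycan for tip-ap), after optimal pairwise superposition of each model
#' pair on that same selection.
#'
#' @param models list of \code{docking_model}s sharing atom ordering.
#' @param reference reference complex defining the interface.
#' @param mode \code{"ti-aa"} or \code{"tip-ap"}.
#' @param interface_cutoff Angstrom (default 3.9).
#' @param superpose if FALSE, models are assumed to share a frame (e.g. a
#'   fixed receptor after rigid docking) and no fitting is done.
#' @return object of class \code{rmsd_matrix}: \code{n_models}, condensed
#'   \code{distances} (lower triangle, \code{\link[stats]{dist}} order),
#'   \code{model_ids}, \code{mode}.
#' @export
rmsd_matrix <- function(models, reference, mode = c("ti-aa", "tip-ap"),
                        interface_cutoff = 3.9, superpose = TRUE) {
  mode <- match.arg(mode)
  n <- length(models)
  if (n < 2) stop("need at least 2 models for an RMSD matrix")
  sel <- rmsd_selection(reference, mode, interface_cutoff)
  coords <- lapply(models, function(m) {
    p <- as_complex_pair(m)
    if (nrow(p$receptor$atoms) < max(sel$receptor) ||
        nrow(p$ligand$atoms) < max(sel$ligand))
      stop("alignment error: model atom count mismatch with reference")
    rbind(str_coords(p$receptor)[sel$receptor, , drop = FALSE],
          str_coords(p$ligand)[sel$ligand, , drop = FALSE])
  })
  nat <- vapply(coords, nrow, 1L)
  if (length(unique(nat)) != 1)
    stop("alignment error: models differ in selection atom count")
  d <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (j in seq_len(n - 1)) {
    for (i in (j + 1):n) {
      k <- k + 1L
      d[k] <- if (superpose) kabsch_superpose(coords[[i]], coords[[j]])$rmsd
              else coord_rmsd(coords[[i]], coords[[j]])
    }
  }
  structure(list(n_models = n, distances = d,
                 model_ids = vapply(models, function(m) m$model_id, numeric(1)),
                 mode = mode),
            class = "rmsd_matrix")
}

as_dist <- function(m) {
  structure(m$distances, Size = m$n_models, class = "dist",
            Diag = FALSE, Upper = FALSE, method = "rmsd",
            Labels = as.character(m$model_ids))
}

#' Agglomerative hierarchical clustering of an RMSD matrix
#'
#' Average-linkage clustering with a flat cut either at a distance
#' threshold (2.5 A default) or into a requested number of clusters.
#' Clusters below \code{min_size} are dropped from reporting but their
#' members are retained in an unclustered pool, so cutting to N clusters
#' may report fewer than N.
#'
#' @param matrix an \code{\link{rmsd_matrix}}.
#' @param cut list with either \code{distance} (Angstrom) or
#'   \code{n_clusters}; default \code{list(distance = 2.5)}.
#' @param min_size minimum reported cluster size (default 4).
#' @return object of class \code{cluster_set}: \code{clusters} (list of
#'   model-id vectors), \code{unclustered}, \code{cut}, \code{min_size}.
#' @export
cluster_hier <- function(matrix, cut = list(distance = 2.5), min_size = 4) {
  n <- matrix$n_models
  h <- stats::hclust(as_dist(matrix), method = "average")
  if (!is.null(cut$n_clusters)) {
    if (cut$n_clusters > n)
      stop("configuration error: more clusters requested than models")
    memb <- stats::cutree(h, k = cut$n_clusters)
  } else {
    memb <- stats::cutree(h, h = cut$distance)
  }
  ids <- matrix$model_ids
  cl <- split(ids, memb)
  # stable ordering: clusters by their smallest member id
  cl <- cl[order(vapply(cl, min, numeric(1)))]
  big <- vapply(cl, length, 1L) >= min_size
  structure(list(clusters = unname(cl[big]),
                 unclustered = unname(unlist(cl[!big])),
                 cut = cut, min_size = min_size, rank_scores = NULL),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (min size %d), %d unclustered\n",
              length(x$clusters), x$min_size, length(x$unclustered)))
  if (!is.null(x$rank_scores))
    cat("  rank scores:", paste(sprintf("%.2f", x$rank_scores), collapse = ", "), "\n")
  invisible(x)
}

#' Rank clusters by the mean score of their best members
#'
#' Each cluster's rank score is the mean of its best \code{min(top_k,
#' size)} member scores; clusters are re-sorted ascending (ties broken by
#' the smaller leading model id) and members are sorted by score within
#' each cluster.
#'
#' @param clusters a \code{cluster_set}.
#' @param scores named numeric vector: score per model id.
#' @param top_k members averaged (default 4).
#' @return the re-ranked \code{cluster_set} with \code{rank_scores}.
#' @export
rank_clusters <- function(clusters, scores, top_k = 4) {
  sc <- function(id) scores[as.character(id)]
  cl <- lapply(clusters$clusters, function(m) m[order(sc(m), m)])
  rs <- vapply(cl, function(m) mean(sc(utils::head(m, top_k))), numeric(1))
  lead <- vapply(cl, function(m) min(m), numeric(1))
  ord <- order(rs, lead)
  clusters$clusters <- cl[ord]
  clusters$rank_scores <- rs[ord]
  clusters
}

#' Select the top models of each ranked cluster
#'
#' Concatenates, over clusters in rank order, each cluster's best
#' \code{min(models_per_cluster, size)} members; this is the input set for
#' the flexible refinement stage. The number selected varies with the
#' cluster sizes.
#'
#' @param clusters a ranked \code{cluster_set}.
#' @param models_per_cluster default 5.
#' @return numeric vector of model ids (may be empty, with a warning).
#' @export
select_top_clusters <- function(clusters, models_per_cluster = 5) {
  if (!length(clusters$clusters)) {
    warning("empty cluster set: nothing selected")
    return(numeric(0))
  }
  unlist(lapply(clusters$clusters, utils::head, models_per_cluster))
}

#' Persist an RMSD matrix as plain text
#' @param matrix an \code{rmsd_matrix}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_rmsd_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# mode", matrix$mode),
               paste("# models", paste(matrix$model_ids, collapse = " ")),
               sprintf("%.6f", matrix$distances)), con)
  invisible(path)
}

#' Write a cluster report TSV
#' @param clusters a (ranked) \code{cluster_set}.
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- do.call(rbind, lapply(seq_along(clusters$clusters), function(i)
    data.frame(cluster = i, size = length(clusters$clusters[[i]]),
               rank_score = if (is.null(clusters$rank_scores)) NA_real_
                            else clusters$rank_scores[i],
               members = paste(clusters$clusters[[i]], collapse = ","))))
  if (is.null(df)) df <- data.frame(cluster = integer(), size = integer(),
                                    rank_score = numeric(), members = character())
  df$rank_score <- sprintf("%.6f", df$rank_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
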