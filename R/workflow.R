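# Composition of the modules into the bound (6-stage) and unbound
# (12-stage) docking protocols, with persisted intermediates and a
# reproducible run log.

#' Workflow configuration
#'
#' Defaults follow the published protocol: true-interface restraints at
#' 3.9 A with 50% random discard per model, the vdW rigid-body weighting,
#' 1000 rigid models (200 per conformation for ensembles), average-linkage
#' clustering (2.5 A cut / min size 4 after refinement and for the bound
#' protocol; 50 flat clusters at the unbound rigid stage, 150 with an
#' ensemble), top-5 members per cluster passed to refinement, and
#' cluster-quality assessment over the top 5 members at the rigid stage
#' and top 4 after refinement.
#'
#' @param receptor,ligand structures (or PDB paths); \code{ligand} may be a
#'   conformer list for ensemble docking.
#' @param reference bound reference complex (\code{toy_complex} or
#'   list(receptor=, ligand=)) used for restraint truth and evaluation.
#' @param outdir output directory for persisted stage tables.
#' @param scenario \code{"ti-aa"} or \code{"tip-ap"}.
#' @param weights_stage rigid-body scoring preset (default
#'   \code{"rigid-vdw"}).
#' @param sampling a \code{\link{sampling_config}}.
#' @param cluster_distance Angstrom cut for distance-based clustering.
#' @param n_rigid_clusters flat clusters at the unbound rigid stage.
#' @param n_rigid_clusters_ensemble same, for ensemble docking.
#' @param min_cluster_size minimum reported cluster size.
#' @param models_per_cluster members passed on per cluster.
#' @param classical_mode if TRUE the unbound protocol refines the top 200
#'   ranked models instead of the cluster selection.
#' @param classical_top models refined in classical mode.
#' @param refine_steps,refine_stages flexible-refinement schedule.
#' @param interface_cutoff restraint/evaluation interface cutoff, Angstrom.
#' @param seed run seed (overrides the sampling config seed).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(receptor, ligand, reference, outdir = tempfile("run"),
                       scenario = c("ti-aa", "tip-ap"),
                       weights_stage = "rigid-vdw",
                       sampling = sampling_config(),
                       cluster_distance = 2.5, n_rigid_clusters = 50,
                       n_rigid_clusters_ensemble = 150,
                       min_cluster_size = 4, models_per_cluster = 5,
                       classical_mode = FALSE, classical_top = 200,
                       refine_steps = 500, refine_stages = 2,
                       interface_cutoff = 3.9, calibrate_bounds = TRUE,
                       seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.character(receptor)) receptor <- read_pdb(receptor, "receptor")
  if (is.character(ligand)) ligand <- read_pdb(ligand, "ligand")
  if (!is.null(seed)) sampling$seed <- as.integer(seed)
  structure(list(receptor = receptor, ligand = ligand, reference = reference,
                 outdir = outdir, scenario = scenario,
                 weights_stage = weights_stage, sampling = sampling,
                 cluster_distance = cluster_distance,
                 n_rigid_clusters = n_rigid_clusters,
                 n_rigid_clusters_ensemble = n_rigid_clusters_ensemble,
                 min_cluster_size = min_cluster_size,
                 models_per_cluster = models_per_cluster,
                 classical_mode = classical_mode,
                 classical_top = classical_top,
                 refine_steps = refine_steps, refine_stages = refine_stages,
                 interface_cutoff = interface_cutoff,
                 calibrate_bounds = calibrate_bounds),
            class = "run_config")
}

log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

echo_config <- function(config, con) {
  log_line(con, "# run configuration")
  flat <- c(scenario = config$scenario, weights = config$weights_stage,
            seed = config$sampling$seed, n_models = config$sampling$n_models,
            n_models_per_conformer = config$sampling$n_models_per_conformer,
            discard_fraction = config$sampling$discard_fraction,
            max_iter = config$sampling$max_iter,
            cluster_distance = config$cluster_distance,
            n_rigid_clusters = config$n_rigid_clusters,
            n_rigid_clusters_ensemble = config$n_rigid_clusters_ensemble,
            min_cluster_size = config$min_cluster_size,
            models_per_cluster = config$models_per_cluster,
            classical_mode = config$classical_mode,
            classical_top = config$classical_top,
            refine_steps = config$refine_steps,
            refine_stages = config$refine_stages,
            interface_cutoff = config$interface_cutoff)
  for (nm in names(flat)) log_line(con, nm, " = ", flat[[nm]])
}

stage_eval <- function(models, reference, path) {
  rec <- eval_records(models, reference)
  out <- rec
  out$score <- sprintf("%.6f", rec$score)
  out$il_rmsd <- sprintf("%.6f", rec$il_rmsd)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec
}

cluster_eval_records <- function(clusters, models, reference) {
  by_id <- models[order(vapply(models, function(m) m$model_id, numeric(1)))]
  ids <- vapply(by_id, function(m) m$model_id, numeric(1))
  lapply(clusters$clusters, function(mem)
    eval_records(by_id[match(mem, ids)], reference))
}

#' Run the bound docking protocol
#'
#' Six stages: partner topology, AIR-driven rigid-body docking, model
#' evaluation, RMSD matrix, distance-cut average-linkage clustering, and
#' cluster-based evaluation. No flexible refinement: the partners are
#' already in their bound conformations.
#'
#' @param config a \code{\link{run_config}}.
#' @return run report list: \code{run}, \code{records}, \code{clusters},
#'   \code{cluster_records}, \code{sr}, \code{cluster_sr}, \code{outdir}.
#' @export
run_bound <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logc <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logc))
  echo_config(config, logc)
  topo <- build_glycan_topology(config$ligand)
  log_line(logc, "stage topology: ", topo$n_units, " units, ",
           if (topo$is_linear) "linear" else "branched")
  rs <- build_airs(config$receptor, config$ligand, config$scenario,
                   interface_cutoff = config$interface_cutoff,
                   reference = as_complex_pair(config$reference),
                   calibrate_bounds = config$calibrate_bounds)
  log_line(logc, "stage restraints: ", length(rs$airs), " AIRs (",
           config$scenario, ")")
  weights <- scoring_weights(config$weights_stage)
  run <- generate_models(config$receptor, config$ligand, rs,
                         config$sampling, weights)
  write_score_table(run, file.path(config$outdir, "rigid_scores.tsv"))
  log_line(logc, "stage rigidbody: ", length(run$models), " models")
  records <- stage_eval(run$models, config$reference,
                        file.path(config$outdir, "rigid_eval.tsv"))
  mat <- rmsd_matrix(run$models, config$reference, config$scenario,
                     config$interface_cutoff)
  write_rmsd_matrix(mat, file.path(config$outdir, "rigid_rmsd_matrix.txt"))
  cl <- cluster_hier(mat, cut = list(distance = config$cluster_distance),
                     min_size = config$min_cluster_size)
  scores <- stats::setNames(vapply(run$models, function(m) m$score, numeric(1)),
                            vapply(run$models, function(m) m$model_id, numeric(1)))
  cl <- rank_clusters(cl, scores, top_k = 4)
  write_cluster_table(cl, file.path(config$outdir, "rigid_clusters.tsv"))
  log_line(logc, "stage clustrmsd: ", length(cl$clusters), " clusters, ",
           length(cl$unclustered), " unclustered")
  cl_rec <- cluster_eval_records(cl, run$models, config$reference)
  sr <- success_rate(list(records))
  cl_sr <- cluster_success_rate(list(cl_rec), top_members = 5)
  utils::write.table(sr, file.path(config$outdir, "sr_single.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cl_sr, file.path(config$outdir, "sr_cluster.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(run = run, records = records, clusters = cl, cluster_records = cl_rec,
       sr = sr, cluster_sr = cl_sr, outdir = config$outdir)
}

#' Run the unbound docking protocol
#'
#' Twelve stages: topology, rigid-body docking (1000 models, or 200 per
#' conformation for an ensemble), evaluation, RMSD matrix, flat clustering
#' into 50 clusters (150 with an ensemble), selection of the top 5 models
#' per cluster (or the top 200 ranked models in classical mode), their
#' evaluation, semi-flexible refinement, evaluation, a second RMSD matrix,
#' 2.5 A distance clustering, and cluster-based evaluation.
#'
#' @param config a \code{\link{run_config}}.
#' @return run report list with rigid and refined stages.
#' @export
run_unbound <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logc <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logc))
  echo_config(config, logc)
  is_ens <- !inherits(config$ligand, "pg_structure")
  topo <- build_glycan_topology(
    if (is_ens) config$ligand[[1]] else config$ligand)
  log_line(logc, "stage topology: ", topo$n_units, " units")
  rs <- build_airs(config$receptor,
                   if (is_ens) config$ligand[[1]] else config$ligand,
                   config$scenario,
                   interface_cutoff = config$interface_cutoff,
                   reference = as_complex_pair(config$reference),
                   calibrate_bounds = config$calibrate_bounds)
  log_line(logc, "stage restraints: ", length(rs$airs), " AIRs")
  weights <- scoring_weights(config$weights_stage)
  run <- generate_models(config$receptor, config$ligand, rs,
                         config$sampling, weights)
  write_score_table(run, file.path(config$outdir, "rigid_scores.tsv"))
  log_line(logc, "stage rigidbody: ", length(run$models), " models")
  rigid_records <- stage_eval(run$models, config$reference,
                              file.path(config$outdir, "rigid_eval.tsv"))
  mat <- rmsd_matrix(run$models, config$reference, config$scenario,
                     config$interface_cutoff)
  write_rmsd_matrix(mat, file.path(config$outdir, "rigid_rmsd_matrix.txt"))
  n_req <- if (is_ens) config$n_rigid_clusters_ensemble else config$n_rigid_clusters
  n_req <- min(n_req, length(run$models))
  cl_rigid <- cluster_hier(mat, cut = list(n_clusters = n_req),
                           min_size = config$min_cluster_size)
  scores <- stats::setNames(vapply(run$models, function(m) m$score, numeric(1)),
                            vapply(run$models, function(m) m$model_id, numeric(1)))
  cl_rigid <- rank_clusters(cl_rigid, scores, top_k = 4)
  write_cluster_table(cl_rigid, file.path(config$outdir, "rigid_clusters.tsv"))
  log_line(logc, "stage clustrmsd(rigid): requested ", n_req, ", reported ",
           length(cl_rigid$clusters))
  cl_rigid_rec <- cluster_eval_records(cl_rigid, run$models, config$reference)
  if (config$classical_mode) {
    sel_models <- utils::head(run$models, config$classical_top)
    log_line(logc, "stage selection: classical top ", length(sel_models))
  } else {
    sel_ids <- select_top_clusters(cl_rigid, config$models_per_cluster)
    ids <- vapply(run$models, function(m) m$model_id, numeric(1))
    sel_models <- run$models[match(sel_ids, ids)]
    log_line(logc, "stage seletopclusts: ", length(sel_models), " models")
  }
  stage_eval(sel_models, config$reference,
             file.path(config$outdir, "selected_eval.tsv"))
  refined <- lapply(sel_models, flex_refine, restraints = rs,
                    n_stages = config$refine_stages,
                    steps_per_stage = config$refine_steps,
                    surface_n_points = config$sampling$surface_n_points)
  sc <- vapply(refined, function(m) m$score, numeric(1))
  idr <- vapply(refined, function(m) m$model_id, numeric(1))
  refined <- refined[order(sc, idr)]
  write_score_table(refined, file.path(config$outdir, "flexref_scores.tsv"))
  log_line(logc, "stage flexref: ", length(refined), " models refined")
  ref_records <- stage_eval(refined, config$reference,
                            file.path(config$outdir, "flexref_eval.tsv"))
  report <- list(run = run, rigid_records = rigid_records,
                 rigid_clusters = cl_rigid,
                 rigid_cluster_records = cl_rigid_rec,
                 refined = refined, refined_records = ref_records,
                 requested_rigid_clusters = n_req, outdir = config$outdir)
  if (length(refined) >= 2) {
    mat2 <- rmsd_matrix(refined, config$reference, config$scenario,
                        config$interface_cutoff)
    write_rmsd_matrix(mat2, file.path(config$outdir, "flexref_rmsd_matrix.txt"))
    cl2 <- cluster_hier(mat2, cut = list(distance = config$cluster_distance),
                        min_size = config$min_cluster_size)
    scores2 <- stats::setNames(sc[order(sc, idr)], idr[order(sc, idr)])
    cl2 <- rank_clusters(cl2, scores2, top_k = 4)
    write_cluster_table(cl2, file.path(config$outdir, "flexref_clusters.tsv"))
    cl2_rec <- cluster_eval_records(cl2, refined, config$reference)
    report$refined_clusters <- cl2
    report$refined_cluster_records <- cl2_rec
    report$cluster_sr <- cluster_success_rate(list(cl2_rec), top_members = 4)
    utils::write.table(report$cluster_sr,
                       file.path(config$outdir, "sr_cluster.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(logc, "stage clustrmsd(flexref): ", length(cl2$clusters),
             " clusters")
  }
  report$sr <- success_rate(list(ref_records))
  utils::write.table(report$sr, file.path(config$outdir, "sr_single.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report
}
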