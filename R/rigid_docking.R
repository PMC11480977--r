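# Rigid-body docking: random starting poses, direct-search energy
# minimization over the six rigid degrees of freedom, model generation.

derive_seed <- function(seed, i, j = 0L) {
  ((seed %% 1000003) * 97561 + i * 1009 + j * 613) %% 2147483647
}

#' Apply a rigid pose to the ligand
#'
#' A pose is a unit quaternion plus a translation, applied about the
#' ligand's heavy-atom centroid.
#' @param ligand \code{pg_structure}.
#' @param pose list(quaternion=, translation=).
#' @return posed \code{pg_structure}.
#' @export
pose_ligand <- function(ligand, pose) {
  R <- quat_to_mat(pose$quaternion)
  ctr <- centroid(ligand)
  set_coords(ligand, rotate_about(str_coords(ligand), R, ctr,
                                  shift = pose$translation))
}

#' Random starting pose
#'
#' Rotation uniform over SO(3) (normalized 4-normal-deviate quaternion);
#' the ligand centroid is placed at a uniformly random direction from the
#' receptor centroid, at the sum of the two bounding radii plus
#' \code{start_separation}, guaranteeing a clash-free start.
#'
#' @param receptor,ligand the partners.
#' @param seed integer seed (deterministic pose per seed).
#' @param start_separation extra centroid gap, Angstrom (default 3).
#' @return pose list(quaternion=, translation=).
#' @export
randomize_pose <- function(receptor, ligand, seed = 1L, start_separation = 3) {
  with_seed(seed, {
    q <- random_quat()
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    dist <- bounding_radius(receptor) + bounding_radius(ligand) + start_separation
    target <- centroid(receptor, heavy_only = FALSE) + dist * u
    list(quaternion = q, translation = target - centroid(ligand))
  })
}

# Precomputed evaluation context for the docking hot loop: heavy-atom
# coordinate blocks, pair parameter matrices, resolved AIR atom indices.
docking_context <- function(receptor, ligand, restraints,
                            params = nonbonded_params(), cutoff = 8.5,
                            eps_r = 10, switch_width = 1.5) {
  pr <- resolve_params(receptor, params)
  pl <- resolve_params(ligand, params)
  pm <- pair_param_matrices(pr, pl, eps_r)
  list(
    rxyz = str_coords(receptor)[heavy_idx(receptor), , drop = FALSE],
    lxyz = str_coords(ligand)[heavy_idx(ligand), , drop = FALSE],
    EPS = pm$EPS, SIG = pm$SIG, QQ = pm$QQ,
    cutoff = cutoff, switch_width = switch_width,
    air_idx = air_indices(restraints, receptor, ligand),
    restraints = restraints
  )
}

ctx_pair_terms <- function(ctx, lxyz, grad = FALSE) {
  pair_energies(ctx$rxyz, lxyz, ctx$EPS, ctx$SIG, ctx$QQ, ctx$cutoff,
                ctx$switch_width, grad = grad)
}

ctx_air_energy <- function(ctx, lxyz, air_sub = NULL) {
  idx <- if (is.null(air_sub)) ctx$air_idx else ctx$air_idx[air_sub]
  sum(air_energies_from_coords(idx, ctx$rxyz, lxyz, ctx$restraints))
}

#' Minimize the rigid-body energy of a pose
#'
#' Direct-search (Nelder-Mead) minimization of \eqn{w^{min}_{air} E_{air}
#' + w_{vdW} E_{vdW} + w_{elec} E_{elec}} over the six rigid degrees of
#' freedom (exponential-map rotation increment plus translation), started
#' from the given pose and restarted once from the incumbent. The
#' restraints act on the search at full strength
#' (\code{min_air_weight = 1}) regardless of their small weight in the
#' ranking score -- restraint forces drive the docking, the stage weights
#' rank the results. Surface terms are not part of the minimization
#' objective; they are computed once at the end for the full score.
#'
#' @param receptor,ligand partners (ligand unposed).
#' @param pose starting pose from \code{\link{randomize_pose}}.
#' @param restraints \code{restraint_set} (already discarded, if desired).
#' @param weights \code{\link{scoring_weights}} for the stage.
#' @param max_iter Nelder-Mead iterations per restart (default 300).
#' @param params,cutoff,eps_r energy options.
#' @param surface_n_points sphere points for the final BSA/desolvation.
#' @param model_id,seed,source_conformer bookkeeping carried on the model.
#' @return object of class \code{docking_model}.
#' @export
rigid_minimize <- function(receptor, ligand, pose, restraints, weights,
                           max_iter = 300, params = nonbonded_params(),
                           cutoff = 8.5, eps_r = 10, surface_n_points = 240,
                           min_air_weight = 1.0, model_id = 1L,
                           seed = NA_integer_, source_conformer = 1L,
                           receptor_sasa = NULL) {
  ctx <- docking_context(receptor, ligand, restraints, params, cutoff, eps_r)
  ctr <- centroid(ligand)
  R0 <- quat_to_mat(pose$quaternion)
  t0 <- pose$translation
  lxyz0 <- str_coords(ligand)[heavy_idx(ligand), , drop = FALSE]
  posed_xyz <- function(p) {
    R <- rotmat_expmap(p[1:3]) %*% R0
    rotate_about(lxyz0, R, ctr, shift = t0 + p[4:6])
  }
  # single distance matrix serves the LJ, Coulomb and AIR terms
  r_on <- cutoff - 1.5
  rs_k <- restraints$force_constant; rs_sv <- restraints$switch_violation
  rs_lb <- restraints$lower_bound
  objective <- function(p) {
    lxyz <- posed_xyz(p)
    d2 <- cross_dist2(ctx$rxyz, lxyz)
    within <- which(d2 < cutoff^2)
    if (any(d2[within] <= 1e-12)) return(Inf)
    r <- sqrt(d2[within])
    s <- switch_fn(r, r_on, cutoff)
    sr6 <- (ctx$SIG[within] / r)^6
    e_lj <- sum(4 * ctx$EPS[within] * (sr6 * sr6 - sr6) * s)
    e_el <- sum(ctx$QQ[within] / r * s)
    ip3 <- d2^(-3)
    e_air <- 0
    for (ai in ctx$air_idx) {
      S <- if (ai$anchor_side == "receptor")
        sum(ip3[ai$anchor, ai$targets]) else sum(ip3[ai$targets, ai$anchor])
      d_eff <- S^(-1 / 6)
      v <- max(d_eff - ai$ub, rs_lb - d_eff, 0)
      e_air <- e_air + flat_bottom_energy(v, rs_k, rs_sv)
    }
    min_air_weight * e_air + weights$w_vdW * e_lj + weights$w_elec * e_el
  }
  p <- rep(0, 6)
  e0 <- objective(p)
  if (!is.finite(e0)) stop("non-finite energy at the starting pose")
  # two coarse rounds to travel, one fine round to settle into the basin
  for (scale in c(1, 1, 0.15)) {
    fit <- stats::optim(p, objective, method = "Nelder-Mead",
                        control = list(maxit = max_iter,
                                       parscale = scale * c(0.3, 0.3, 0.3, 2, 2, 2)))
    p <- fit$par
  }
  final <- if (fit$value <= e0) p else rep(0, 6)
  Rfin <- rotmat_expmap(final[1:3]) %*% R0
  qfin <- mat_to_quat(Rfin)
  pose_out <- list(quaternion = qfin, translation = t0 + final[4:6])
  lig_out <- pose_ligand(ligand, pose_out)
  pe <- ctx_pair_terms(ctx, str_coords(lig_out)[heavy_idx(lig_out), , drop = FALSE])
  ea <- ctx_air_energy(ctx, str_coords(lig_out)[heavy_idx(lig_out), , drop = FALSE])
  st <- surface_terms(receptor, lig_out, params, n_points = surface_n_points,
                      receptor_sasa = receptor_sasa)
  rep_ <- energy_report(E_vdW = pe$E_vdW, E_elec = pe$E_elec,
                        E_desolv = st$E_desolv, E_BSA = st$E_BSA, E_air = ea)
  structure(list(pose = pose_out, receptor = receptor, ligand = lig_out,
                 energies = rep_, score = haddock_score(rep_, weights),
                 model_id = as.integer(model_id), seed = seed,
                 source_conformer = as.integer(source_conformer),
                 stage = weights$stage, objective = fit$value),
            class = "docking_model")
}

# rotation matrix -> unit quaternion (w, x, y, z), w >= 0
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' @export
print.docking_model <- function(x, ...) {
  cat(sprintf("<docking_model> #%d (%s): score %.2f", x$model_id,
              if (is.null(x$stage)) "?" else x$stage, x$score))
  if (!is.null(x$energies))
    cat(sprintf(" [vdW %.2f, elec %.2f, desolv %.2f, BSA %.1f, air %.2f]",
                x$energies$E_vdW, x$energies$E_elec, x$energies$E_desolv,
                x$energies$E_BSA, x$energies$E_air))
  cat("\n")
  invisible(x)
}

#' Sampling configuration for rigid-body model generation
#'
#' Defaults follow the standard protocol: 1000 models from a single
#' conformation, or 200 per conformation when docking from an ensemble;
#' half of the AIRs are discarded independently for each model.
#'
#' @param n_models models from a single starting conformation.
#' @param n_models_per_conformer models per ensemble member.
#' @param seed integer run seed.
#' @param start_separation Angstrom (see \code{\link{randomize_pose}}).
#' @param max_iter minimizer iterations per restart.
#' @param discard_fraction AIR fraction discarded per model (default 0.5).
#' @param surface_n_points sphere points for final surface terms.
#' @param retry_limit resampled starts allowed on non-finite energies.
#' @return list of class \code{sampling_config}.
#' @export
sampling_config <- function(n_models = 1000, n_models_per_conformer = 200,
                            seed = 1L, start_separation = 3, max_iter = 300,
                            discard_fraction = 0.5, surface_n_points = 240,
                            retry_limit = 10) {
  stopifnot(n_models >= 1, n_models_per_conformer >= 1,
            discard_fraction >= 0, discard_fraction < 1)
  structure(list(n_models = n_models,
                 n_models_per_conformer = n_models_per_conformer,
                 seed = as.integer(seed), start_separation = start_separation,
                 max_iter = max_iter, discard_fraction = discard_fraction,
                 surface_n_points = surface_n_points,
                 retry_limit = retry_limit),
            class = "sampling_config")
}

#' Generate rigid-body docking models
#'
#' Draws random starting poses, an independent discarded-AIR subset per
#' model, minimizes each, and returns the models sorted by score
#' (ascending; ties by model id). Fully reproducible for a given seed.
#'
#' @param receptor receptor structure.
#' @param ligand a \code{pg_structure}, or a list/\code{pg_ensemble} of
#'   conformers (then \code{n_models_per_conformer} models are generated
#'   per member).
#' @param restraints full \code{restraint_set}.
#' @param config a \code{\link{sampling_config}}.
#' @param weights \code{\link{scoring_weights}} used both to drive the
#'   minimizer terms and for the final score.
#' @param params nonbonded table.
#' @return object of class \code{docking_run}: \code{$models} (sorted),
#'   \code{$config}, \code{$weights}.
#' @export
generate_models <- function(receptor, ligand, restraints, config, weights,
                            params = nonbonded_params()) {
  conformers <- if (inherits(ligand, "pg_structure")) list(ligand) else ligand
  n_conf <- length(conformers)
  per <- if (n_conf > 1) config$n_models_per_conformer else config$n_models
  rsasa <- sasa(receptor, n_points = config$surface_n_points)
  models <- vector("list", n_conf * per)
  id <- 0L
  for (ci in seq_len(n_conf)) {
    lig <- conformers[[ci]]
    for (mi in seq_len(per)) {
      id <- id + 1L
      mseed <- derive_seed(config$seed, id)
      sub <- if (config$discard_fraction > 0)
        random_discard(restraints, config$discard_fraction, seed = mseed)
      else restraints
      model <- NULL
      for (attempt in 0:config$retry_limit) {
        pose <- randomize_pose(receptor, lig, seed = derive_seed(mseed, attempt),
                               start_separation = config$start_separation)
        model <- tryCatch(
          rigid_minimize(receptor, lig, pose, sub, weights,
                         max_iter = config$max_iter, params = params,
                         surface_n_points = config$surface_n_points,
                         model_id = id, seed = mseed, source_conformer = ci,
                         receptor_sasa = rsasa),
          error = function(e) NULL)
        if (!is.null(model)) break
      }
      if (is.null(model))
        stop("run error: all starts failed for model ", id)
      models[[id]] <- model
    }
  }
  sc <- vapply(models, function(m) m$score, numeric(1))
  ids <- vapply(models, function(m) m$model_id, integer(1))
  structure(list(models = models[order(sc, ids)], config = config,
                 weights = weights),
            class = "docking_run")
}

#' @export
print.docking_run <- function(x, ...) {
  sc <- vapply(x$models, function(m) m$score, numeric(1))
  cat(sprintf("<docking_run> %d models (%s weights); score range [%.2f, %.2f]\n",
              length(x$models), x$weights$stage, min(sc), max(sc)))
  invisible(x)
}

#' Write a run's score table as TSV
#'
#' One row per model in score order: model id, per-term energies, score,
#' seed and source conformer. Numeric columns are printed with fixed
#' formatting so identical runs produce byte-identical tables.
#'
#' @param run a \code{docking_run} or list of \code{docking_model}s.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_score_table <- function(run, path) {
  models <- if (inherits(run, "docking_run")) run$models else run
  df <- do.call(rbind, lapply(models, function(m) {
    e <- if (is.null(m$energies)) energy_report() else m$energies
    data.frame(model_id = m$model_id, E_vdW = e$E_vdW, E_elec = e$E_elec,
               E_desolv = e$E_desolv, E_BSA = e$E_BSA, E_air = e$E_air,
               score = m$score, seed = m$seed,
               source_conformer = m$source_conformer,
               stage = if (is.null(m$stage)) NA_character_ else m$stage)
  }))
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  out$model_id <- sprintf("%d", df$model_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
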