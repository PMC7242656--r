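# hash of an arbitrary R configuration object (md5 of its canonical JSON)
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Read a model/task configuration file
#'
#' YAML (or JSON) with sections `arm`, `muscles` (list of 6 with `params` and
#' `path` fields), `task`, `limits` and `integrator`; every field defaults to
#' the reconstructed fixture of [default_model()] and unknown keys are
#' rejected.
#'
#' @param path file path, or `NULL` for the pure defaults
#' @return [arm_model()] object
#' @export
read_model_config <- function(path = NULL) {
  model <- default_model()
  if (is.null(path)) return(model)
  cfg <- yaml::read_yaml(path)
  known <- c("arm", "muscles", "task", "limits", "integrator")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config sections: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$arm)) {
    bad <- setdiff(names(cfg$arm), names(formals(arm_parameters)))
    if (length(bad)) stop("unknown arm keys: ", paste(bad, collapse = ", "))
    model$arm <- do.call(arm_parameters, modifyList(
      lapply(model$arm, identity)[names(formals(arm_parameters))], cfg$arm))
  }
  if (!is.null(cfg$muscles)) {
    for (nm in names(cfg$muscles)) {
      if (!nm %in% names(model$muscles)) stop("unknown muscle: ", nm)
      mc <- cfg$muscles[[nm]]
      bad <- setdiff(names(mc), c(names(formals(muscle_parameters)),
                                  "r_shoulder", "r_elbow", "l_ref"))
      if (length(bad)) stop("unknown muscle keys: ", paste(bad, collapse = ", "))
      pk <- intersect(names(mc), names(formals(muscle_parameters)))
      pars <- modifyList(unclass(model$muscles[[nm]]$params), mc[pk])
      model$muscles[[nm]]$params <- do.call(muscle_parameters, pars)
      pth <- model$muscles[[nm]]$path
      for (k in intersect(names(mc), c("r_shoulder", "r_elbow", "l_ref")))
        pth[[k]] <- mc[[k]]
      model$muscles[[nm]]$path <- muscle_path(pth$name, pth$r_shoulder,
                                              pth$r_elbow, pth$l_ref,
                                              pth$theta_ref)
    }
  }
  if (!is.null(cfg$task)) {
    bad <- setdiff(names(cfg$task), names(formals(task_spec)))
    if (length(bad)) stop("unknown task keys: ", paste(bad, collapse = ", "))
    tk <- unclass(model$task)
    model$task <- do.call(task_spec, modifyList(tk, cfg$task))
  }
  for (sec in c("limits", "integrator")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(model[[sec]]))
      if (length(bad)) stop("unknown ", sec, " keys: ",
                            paste(bad, collapse = ", "))
      model[[sec]] <- modifyList(model[[sec]], cfg[[sec]])
    }
  }
  model$cache <- new.env(parent = emptyenv())
  model
}

#' Write a trajectory as CSV with a JSON sidecar
#'
#' Columns `t, phi, psi, phi_dot, psi_dot, phi_ddot, psi_ddot, phi_dddot,
#' psi_dddot, tau1, tau2, tau1_dot, tau2_dot, x, z, x_dot, z_dot`; the sidecar
#' (`<path>.json`) carries `u`, `T`, `terminated_by` and a config hash.
#'
#' @param traj [simulate_reach()] trajectory
#' @param path CSV output path
#' @param config_id optional config hash recorded in the sidecar
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, config_id = NA_character_) {
  df <- data.frame(t = traj$t,
                   phi = traj$theta[, 1], psi = traj$theta[, 2],
                   phi_dot = traj$theta_dot[, 1], psi_dot = traj$theta_dot[, 2],
                   phi_ddot = traj$theta_ddot[, 1],
                   psi_ddot = traj$theta_ddot[, 2],
                   phi_dddot = traj$theta_dddot[, 1],
                   psi_dddot = traj$theta_dddot[, 2],
                   tau1 = traj$tau[, 1], tau2 = traj$tau[, 2],
                   tau1_dot = traj$tau_dot[, 1], tau2_dot = traj$tau_dot[, 2],
                   x = traj$x, z = traj$z,
                   x_dot = traj$x_dot, z_dot = traj$z_dot)
  write.csv(df, path, row.names = FALSE)
  side <- list(u = traj$u, T = traj$T, terminated_by = traj$terminated_by,
               dt = traj$dt, flagged = traj$flagged, config_id = config_id)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist)
#' @return `arm_trajectory` object
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(t = df$t, dt = side$dt,
                 theta = cbind(df$phi, df$psi),
                 theta_dot = cbind(df$phi_dot, df$psi_dot),
                 theta_ddot = cbind(df$phi_ddot, df$psi_ddot),
                 theta_dddot = cbind(df$phi_dddot, df$psi_dddot),
                 x = df$x, z = df$z, x_dot = df$x_dot, z_dot = df$z_dot,
                 tau = cbind(df$tau1, df$tau2),
                 tau_dot = cbind(df$tau1_dot, df$tau2_dot),
                 u = side$u, T = side$T, terminated_by = side$terminated_by,
                 flagged = isTRUE(side$flagged)),
            class = "arm_trajectory")
}

#' Write a reference set (one CSV per subject plus a JSON manifest)
#'
#' @param ref [generate_reference_set()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_reference_set <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ref$trajectories)) {
    s <- ref$trajectories[[i]]
    write.csv(data.frame(t = s$t, x = s$x, z = s$z, v = s$v),
              file.path(dir, sprintf("subject_%02d.csv", i)),
              row.names = FALSE)
  }
  jsonlite::write_json(list(n_subjects = ref$n_subjects, seed = ref$seed,
                            cfg = ref$cfg, synthetic = TRUE),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reference set written by [write_reference_set()]
#'
#' @param dir directory containing `subject_*.csv` and `manifest.json`
#' @return `reference_set` object
#' @export
read_reference_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^subject_\\d+\\.csv$",
                           full.names = TRUE))
  trajectories <- lapply(files, function(f) {
    df <- read.csv(f)
    list(t = df$t, x = df$x, z = df$z, v = df$v,
         T = df$t[length(df$t)], z_end = df$z[length(df$z)])
  })
  structure(list(trajectories = trajectories, n_subjects = man$n_subjects,
                 seed = man$seed, cfg = as.list(man$cfg)),
            class = "reference_set")
}

#' Write an optimization run to JSON (records) and CSV (convergence)
#'
#' @param result `bo_result` object
#' @param path JSON output path; a `<path>.best_so_far.csv` companion carries
#'   the per-iteration running minimum
#' @param config_id optional config hash
#' @return `path`, invisibly
#' @export
write_run_result <- function(result, path, config_id = NA_character_) {
  jsonlite::write_json(
    list(U = result$dataset$U, y = result$dataset$y,
         provenance = result$dataset$provenance,
         best_u = result$best_u, best_y = result$best_y,
         seed = result$seed, config_id = config_id),
    path, auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(iteration = seq_along(result$best_so_far),
                       best_so_far = result$best_so_far),
            paste0(path, ".best_so_far.csv"), row.names = FALSE)
  invisible(path)
}
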