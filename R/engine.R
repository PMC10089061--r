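#' Potential-energy decomposition of a configuration
#'
#' @param top A `cg_topology`.
#' @param coords N x 3 coordinates; defaults to the topology's native
#'   coordinates.
#' @return Tibble (`term`, `energy`) in kcal/mol, including the total.
#' @export
potential_energy <- function(top, coords = NULL) {
  coords <- coords %||% top$coords
  stopifnot(all(is.finite(coords)))
  e <- cg_energy_cpp(as.matrix(coords), .engine_topology(top))
  tibble(
    term = c("bond", "angle", "contact", "wca", "coulomb", "znlink",
             "cv_potential", "total"),
    energy = c(e$bond, e$angle, e$contact, e$wca, e$coulomb, e$znlink,
               e$cv_potential, e$total)
  )
}

#' Relax a configuration by damped steepest descent
#' @param top A `cg_topology`. @param coords Start coordinates.
#' @param n_steps Iterations. @param max_step Maximum displacement (A).
#' @return Relaxed N x 3 coordinate matrix.
#' @export
minimize_energy <- function(top, coords = NULL, n_steps = 500,
                            max_step = 0.5) {
  coords <- coords %||% top$coords
  cg_minimize_cpp(as.matrix(coords), .engine_topology(top), n_steps,
                  max_step)
}

#' Molecular-dynamics schedule
#'
#' @param n_steps Total integration steps (used with scalar `temperature`).
#' @param temperature Either a single temperature (K) or a data frame with
#'   columns `n_steps`, `temperature` for a piecewise program.
#' @param timestep_fs Timestep in femtoseconds.
#' @param friction_ps Langevin friction (1/ps); 0 disables the thermostat
#'   (plain velocity-Verlet dynamics).
#' @param store_stride Store every this-many steps.
#' @param seed Engine RNG seed.
#' @return An `md_schedule` list.
#' @export
md_schedule <- function(n_steps = 1e5, temperature = 300, timestep_fs = 10,
                        friction_ps = 1, store_stride = 100, seed = 1) {
  if (is.data.frame(temperature)) {
    seg_steps <- as.integer(temperature$n_steps)
    seg_temp <- temperature$temperature
  } else {
    seg_steps <- as.integer(n_steps)
    seg_temp <- temperature
  }
  stopifnot(timestep_fs > 0, all(seg_temp > 0), all(seg_steps > 0))
  structure(list(dt_ps = timestep_fs / 1000, gamma_ps = friction_ps,
                 seg_steps = seg_steps, seg_temp = seg_temp,
                 store_stride = as.integer(store_stride),
                 seed = as.integer(seed)),
            class = "md_schedule")
}

#' Bias specification for steered dynamics or metadynamics
#'
#' @param mode `"steered"` or `"metadynamics"`.
#' @param cv Collective variable: `"rg"` (mass-weighted over protein
#'   beads, metals excluded) or `"end_to_end"` (first/last backbone bead).
#' @param k Steering force constant in kcal/mol/nm^2 (the conventional
#'   unit for Rg pulling; presets 10, 25, 50). Converted internally to
#'   A^-2.
#' @param target_start,target_end Moving-restraint CV schedule (A);
#'   `target_start = NULL` uses the initial CV value.
#' @param hill_height Initial hill height (kcal/mol).
#' @param hill_width Hill sigma on the CV (A).
#' @param stride Hill deposition stride (steps).
#' @param bias_factor Well-tempered bias factor gamma (> 1).
#' @param grid CV grid range `c(min, max)` for the tabulated bias;
#'   `NULL` chooses from the start structure.
#' @param grid_n Bias grid points.
#' @return A `bias_spec` list.
#' @export
bias_spec <- function(mode = c("steered", "metadynamics"),
                      cv = c("rg", "end_to_end"), k = 25,
                      target_start = NULL, target_end = NULL,
                      hill_height = 0.5, hill_width = 0.5, stride = 500,
                      bias_factor = 10, grid = NULL, grid_n = 1024) {
  mode <- match.arg(mode)
  cv <- match.arg(cv)
  if (mode == "metadynamics" && bias_factor <= 1) {
    stop("bias_factor must exceed 1 in well-tempered metadynamics")
  }
  structure(list(mode = mode, cv = cv, k = k,
                 target_start = target_start, target_end = target_end,
                 hill_height = hill_height, hill_width = hill_width,
                 stride = as.integer(stride), bias_factor = bias_factor,
                 grid = grid, grid_n = as.integer(grid_n)),
            class = "bias_spec")
}

.cv_kind <- function(cv) switch(cv, rg = 1L, end_to_end = 2L)

#' Run Langevin dynamics
#'
#' BAOAB-discretised Langevin integration of the coarse-grained model,
#' optionally under a moving harmonic restraint (steered mode) or a
#' well-tempered metadynamics bias on the chosen collective variable.
#' Identical seeds give identical trajectories.
#'
#' @param top A `cg_topology`.
#' @param schedule An [md_schedule()].
#' @param bias A [bias_spec()] or NULL.
#' @param coords Start coordinates (default: topology natives).
#' @param cv_potential Internal: analytic potential on the CV.
#' @return A `cg_trajectory`: list with `frames` (N x 3 x n array),
#'   `summary` (per-frame tibble: time, temperature, CV, kinetic and
#'   per-term potential energies, bias force, restraint target), `hills`,
#'   `bias_grid`, `final_coords`, `diverged`.
#' @export
run_langevin <- function(top, schedule = md_schedule(), bias = NULL,
                         coords = NULL, cv_potential = NULL) {
  coords <- coords %||% top$coords
  cv_kind <- if (!is.null(bias)) .cv_kind(bias$cv) else 1L
  etop <- .engine_topology(top, cv_kind = cv_kind,
                           cv_potential = cv_potential)
  ebias <- .engine_bias(bias, top, coords, cv_kind, etop)
  res <- cg_run_cpp(as.matrix(coords), etop,
                    schedule[c("dt_ps", "gamma_ps", "seg_steps",
                               "seg_temp", "store_stride")],
                    ebias, schedule$seed)
  if (res$diverged) {
    warning("energy diverged; trajectory truncated at frame ",
            res$n_stored)
  }
  n <- res$n_stored
  idx <- seq_len(n)
  summary <- tibble(
    frame = idx, time_ps = res$time_ps[idx],
    temperature = res$temperature[idx], cv = res$cv[idx],
    ke = res$ke[idx], pe = res$pe[idx], bond = res$bond[idx],
    angle = res$angle[idx], contact = res$contact[idx],
    wca = res$wca[idx], coulomb = res$coulomb[idx],
    znlink = res$znlink[idx], cv_potential = res$cv_potential[idx],
    bias_force = res$bias_force[idx], target = res$target[idx]
  )
  frames <- array(res$frames, dim = dim(res$frames))[, , idx, drop = FALSE]
  structure(list(
    frames = frames, summary = summary, types = top$types,
    masses = top$masses,
    hills = tibble(s = as.numeric(res$hill_s),
                   height = as.numeric(res$hill_h)),
    bias_grid = tibble(
      cv = res$grid_min + res$grid_step * (seq_along(res$bias_grid) - 1),
      bias = as.numeric(res$bias_grid)),
    final_coords = res$final_coords, diverged = res$diverged,
    schedule = schedule, bias = bias
  ), class = "cg_trajectory")
}

.engine_bias <- function(bias, top, coords, cv_kind, etop) {
  if (is.null(bias)) {
    return(list(mode = 0L, cv_kind = 1L, k_cv = 0, target_start = 0,
                target_end = 0, hill_height = 0, hill_width = 1,
                hill_stride = 1000L, bias_factor = 10, grid_min = 0,
                grid_max = 100, grid_n = 64L))
  }
  cv0 <- current_cv(top, coords, bias$cv)
  grid <- bias$grid %||% c(max(cv0 * 0.3, 0.5), cv0 * 4)
  list(
    mode = if (bias$mode == "steered") 1L else 2L,
    cv_kind = cv_kind,
    k_cv = bias$k / 100,  # kcal/mol/nm^2 -> kcal/mol/A^2
    target_start = bias$target_start %||% cv0,
    target_end = bias$target_end %||% (cv0 * 2),
    hill_height = bias$hill_height, hill_width = bias$hill_width,
    hill_stride = bias$stride, bias_factor = bias$bias_factor,
    grid_min = grid[1], grid_max = grid[2], grid_n = bias$grid_n
  )
}

#' Current collective-variable value of a configuration
#' @param top A `cg_topology`. @param coords Coordinates.
#' @param cv `"rg"` or `"end_to_end"`.
#' @export
current_cv <- function(top, coords = NULL, cv = "rg") {
  coords <- coords %||% top$coords
  prot <- top$types == "BEAD"
  if (cv == "rg") {
    radius_of_gyration(coords[prot, , drop = FALSE],
                       masses = top$masses[prot])
  } else {
    end_to_end(coords[prot, , drop = FALSE])
  }
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", dim(x$frames)[3], " frames x ",
      dim(x$frames)[1], " sites",
      if (x$diverged) " [DIVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' @rdname run_langevin
#' @param x A `cg_trajectory`.
#' @param ... Unused.
#' @export
tidy.cg_trajectory <- function(x, ...) x$summary

#' Write trajectory frames as multi-model PDB or XYZ
#' @param traj A `cg_trajectory`. @param path Output path.
#' @param format `"xyz"` or `"pdb"`.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  n <- dim(traj$frames)[3]
  el <- ifelse(traj$types == "ZN", "Zn", "C")
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      fr <- traj$frames[, , i]
      writeLines(c(length(el), paste0("frame ", i),
                   sprintf("%-4s %12.5f %12.5f %12.5f", el,
                           fr[, 1], fr[, 2], fr[, 3])), con)
    }
  } else {
    lines <- character(0)
    for (i in seq_len(n)) {
      fr <- traj$frames[, , i]
      lines <- c(lines, sprintf("MODEL     %4d", i),
                 sprintf(paste0("%-6s%5d %-4s %3s %s%4d    ",
                                "%8.3f%8.3f%8.3f%6.2f%6.2f"),
                         ifelse(traj$types == "ZN", "HETATM", "ATOM"),
                         seq_along(el),
                         ifelse(traj$types == "ZN", "ZN", "CA"),
                         ifelse(traj$types == "ZN", "ZN", "GLY"), "A",
                         seq_along(el), fr[, 1], fr[, 2], fr[, 3], 1, 0),
                 "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}
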