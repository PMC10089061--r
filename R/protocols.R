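.PN_PER_KCAL_MOL_A <- 69.4786  # 1 kcal/mol/A in pN

#' Thermal unfolding protocol
#'
#' Stepwise temperature ramp (default 300, 500, 800 K) with the projection
#' CCS computed for every stored frame, plus a Gaussian KDE of the CCS
#' samples within each temperature slice. The spread of sampled CCS
#' (`delta_ccs`) is the conformational-heterogeneity read-out used to
#' compare species.
#'
#' @param top A `cg_topology`.
#' @param temps Increasing temperature ramp (K).
#' @param steps_per_temp Integration steps per temperature.
#' @param timestep_fs,friction_ps,store_stride,seed Passed to
#'   [md_schedule()].
#' @param radii A [radii_table()] for the CCS read-out.
#' @param ccs_args List of extra arguments for [pa_ccs()] per frame.
#' @param minimize_first Relax the start structure by damped descent
#'   before integrating (removes residual excluded-volume overlaps).
#' @return A `thermal_unfold_result`: list with `trajectory`, `ccs`
#'   (per-frame tibble), `kde` (named list of `ccs_distribution` per
#'   temperature), `summary` (per-temperature tibble with `delta_ccs`),
#'   `delta_ccs` (overall spread).
#' @export
thermal_unfold <- function(top, temps = c(300, 500, 800),
                           steps_per_temp = 20000, timestep_fs = 10,
                           friction_ps = 1, store_stride = 200, seed = 1,
                           radii = radii_table(),
                           ccs_args = list(n_orientations = 12,
                                           n_mc = 600),
                           minimize_first = TRUE) {
  if (any(diff(temps) <= 0)) stop("temperature ramp must be increasing")
  coords <- if (minimize_first) minimize_energy(top) else top$coords
  sched <- md_schedule(
    temperature = data.frame(n_steps = rep(steps_per_temp, length(temps)),
                             temperature = temps),
    timestep_fs = timestep_fs, friction_ps = friction_ps,
    store_stride = store_stride, seed = seed)
  traj <- run_langevin(top, sched, coords = coords)
  ccs <- do.call(trajectory_ccs,
                 c(list(traj, radii = radii, seed = seed), ccs_args))
  kde <- lapply(split(ccs, ccs$temperature), function(d) {
    if (nrow(d) < 2 || stats::var(d$ccs) == 0) return(NULL)
    kde_ccs(d$ccs)
  })
  summary <- ccs |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(ccs_mean = mean(.data$ccs), ccs_min = min(.data$ccs),
                     ccs_max = max(.data$ccs),
                     delta_ccs = max(.data$ccs) - min(.data$ccs),
                     .groups = "drop")
  structure(list(trajectory = traj, ccs = ccs, kde = kde,
                 summary = summary,
                 delta_ccs = max(ccs$ccs) - min(ccs$ccs)),
            class = "thermal_unfold_result")
}

#' @export
print.thermal_unfold_result <- function(x, ...) {
  cat("<thermal_unfold> overall delta-CCS ",
      format(x$delta_ccs, digits = 4), " A^2\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Steered pulling on a collective variable
#'
#' Moving harmonic restraint on Rg or the end-to-end distance, replicated
#' with different thermostat seeds. The pulling force -k (CV - target) is
#' recorded (in pN) along with the CV and, at a thinned set of frames, the
#' projection CCS; the per-replicate peak force and the work integral
#' (trapezoid of F dCV) summarise each pull.
#'
#' @param top A `cg_topology`.
#' @param bias A [bias_spec()] in steered mode (sets CV kind, force
#'   constant in kcal/mol/nm^2 and target schedule).
#' @param schedule An [md_schedule()]; its seed seeds replicate 1,
#'   replicate r uses `seed + r - 1`.
#' @param n_replicates Number of replicates (default 25).
#' @param ccs_every Compute CCS at every this-many stored frames
#'   (0 disables).
#' @param radii A [radii_table()].
#' @param minimize_first Relax the start structure before pulling.
#' @return An `smd_result`: list with `profiles` (list of per-replicate
#'   force-profile tibbles), `summary` (per-replicate peak force and
#'   work), `mean_peak_force`, `sd_peak_force`.
#' @export
smd_pull <- function(top, bias = bias_spec("steered", "rg", k = 25),
                     schedule = md_schedule(n_steps = 30000,
                                            store_stride = 100),
                     n_replicates = 25, ccs_every = 0,
                     radii = radii_table(), minimize_first = TRUE) {
  if (bias$mode != "steered") stop("bias must be in steered mode")
  if (bias$k <= 0) stop("force constant must be positive")
  coords <- if (minimize_first) minimize_energy(top) else top$coords
  profiles <- vector("list", n_replicates)
  peaks <- numeric(n_replicates)
  works <- numeric(n_replicates)
  truncated <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    sched_r <- schedule
    sched_r$seed <- schedule$seed + r - 1L
    traj <- run_langevin(top, sched_r, bias = bias, coords = coords)
    pr <- traj$summary[, c("frame", "time_ps", "cv", "target",
                           "bias_force")]
    pr$force_pN <- abs(pr$bias_force) * .PN_PER_KCAL_MOL_A
    if (ccs_every > 0) {
      sel <- seq(1, nrow(pr), by = ccs_every)
      ccs <- rep(NA_real_, nrow(pr))
      r_look <- lookup_radii(traj$types, radii)
      ccs[sel] <- vapply(sel, function(i) {
        pa_ccs(traj$frames[, , i], radii = r_look, probe = 0,
               n_orientations = 12, n_mc = 600,
               seed = sched_r$seed + i)$ccs
      }, numeric(1))
      pr$ccs <- ccs
    }
    # flag pulls that never reach the final target (chain fully extended)
    truncated[r] <- abs(pr$cv[nrow(pr)] - pr$target[nrow(pr)]) >
      0.2 * abs(pr$target[nrow(pr)] - pr$target[1])
    profiles[[r]] <- pr
    peaks[r] <- max(pr$force_pN)
    ord <- order(pr$cv)
    works[r] <- trapz(pr$cv[ord],
                      (pr$force_pN / .PN_PER_KCAL_MOL_A)[ord])
  }
  if (any(truncated)) {
    warning(sum(truncated), " replicate(s) did not reach the CV target ",
            "(flagged truncated)")
  }
  summary <- tibble(replicate = seq_len(n_replicates),
                    peak_force_pN = peaks, work_kcal_mol = works,
                    truncated = truncated)
  structure(list(profiles = profiles, summary = summary,
                 mean_peak_force = mean(peaks),
                 sd_peak_force = stats::sd(peaks),
                 n_replicates = n_replicates, bias = bias),
            class = "smd_result")
}

#' @export
print.smd_result <- function(x, ...) {
  cat("<smd_result> ", x$n_replicates, " replicates: mean peak force ",
      format(x$mean_peak_force, digits = 4), " +/- ",
      format(x$sd_peak_force, digits = 3), " pN\n", sep = "")
  invisible(x)
}

#' @rdname smd_pull
#' @param x An `smd_result`.
#' @param ... Unused.
#' @export
tidy.smd_result <- function(x, ...) x$summary

#' @rdname smd_pull
#' @export
glance.smd_result <- function(x, ...) {
  tibble(n_replicates = x$n_replicates,
         mean_peak_force_pN = x$mean_peak_force,
         sd_peak_force_pN = x$sd_peak_force,
         mean_work_kcal_mol = mean(x$summary$work_kcal_mol))
}

#' Well-tempered metadynamics on a collective variable
#'
#' Gaussian hills are deposited along the CV at a fixed stride with height
#' scaled by exp(-V_bias / ((gamma - 1) kB T)); the free-energy estimate is
#' F(s) = -(gamma / (gamma - 1)) V_bias(s), shifted to minimum zero.
#' Convergence is diagnosed from the decay of deposited hill heights.
#'
#' @param top A `cg_topology`.
#' @param bias A [bias_spec()] in metadynamics mode.
#' @param schedule An [md_schedule()].
#' @param cv_potential Optional analytic CV potential (for oracle tests):
#'   list(enabled, height, centre, halfwidth).
#' @param minimize_first Relax the start structure before biasing.
#' @return A `metadynamics_result`: list with `free_energy` tibble
#'   (`cv`, `free_energy` kcal/mol), `hills`, `converged`,
#'   `hill_decay_ratio` (late/early mean hill height), `trajectory`.
#' @export
wt_metadynamics <- function(top,
                            bias = bias_spec("metadynamics", "rg"),
                            schedule = md_schedule(n_steps = 2e5),
                            cv_potential = NULL, minimize_first = FALSE) {
  if (bias$mode != "metadynamics") stop("bias must be in metadynamics mode")
  coords <- if (minimize_first) minimize_energy(top) else top$coords
  traj <- run_langevin(top, schedule, bias = bias, coords = coords,
                       cv_potential = cv_potential)
  gb <- bias$bias_factor
  fe <- traj$bias_grid
  fe$free_energy <- -gb / (gb - 1) * fe$bias
  fe$free_energy <- fe$free_energy - min(fe$free_energy)
  nh <- nrow(traj$hills)
  k <- max(floor(nh / 10), 1)
  decay <- mean(traj$hills$height[(nh - k + 1):nh]) /
    mean(traj$hills$height[seq_len(k)])
  converged <- decay < 0.5
  if (!converged) {
    warning("hill heights have not decayed (ratio ",
            format(decay, digits = 3), "); bias may be unconverged")
  }
  structure(list(free_energy = fe[, c("cv", "free_energy")],
                 hills = traj$hills, converged = converged,
                 hill_decay_ratio = decay, trajectory = traj,
                 bias = bias),
            class = "metadynamics_result")
}

#' @export
print.metadynamics_result <- function(x, ...) {
  cat("<metadynamics_result> ", nrow(x$hills), " hills, decay ratio ",
      format(x$hill_decay_ratio, digits = 3),
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  invisible(x)
}

#' @rdname wt_metadynamics
#' @param x A `metadynamics_result`.
#' @param ... Unused.
#' @export
tidy.metadynamics_result <- function(x, ...) x$free_energy

#' Free-energy barrier between the two lowest minima of a profile
#' @param fe Tibble (`cv`, `free_energy`).
#' @param wells Optional CV positions of the two wells; default: the two
#'   deepest local minima.
#' @return Barrier height (kcal/mol) from the lower well.
#' @export
fe_barrier <- function(fe, wells = NULL) {
  y <- fe$free_energy
  if (is.null(wells)) {
    mins <- which(diff(sign(diff(y))) > 0) + 1
    if (length(mins) < 2) stop("fewer than two minima in the profile")
    mins <- mins[order(y[mins])][1:2]
  } else {
    mins <- vapply(wells, function(w) which.min(abs(fe$cv - w)),
                   integer(1))
  }
  mins <- sort(mins)
  top <- max(y[mins[1]:mins[2]])
  top - min(y[mins])
}

#' Pairwise correlations among per-species observables
#'
#' Pearson correlation and p-value for every pair of numeric columns
#' (h-bond counts, Zn-S bond counts, mean unfolding forces, free-energy
#' estimates, ...). Constant columns give an undefined r and are flagged.
#'
#' @param summaries Data frame: one row per species, numeric observable
#'   columns (non-numeric columns are carried as identifiers).
#' @return Tibble (`var1`, `var2`, `r`, `p`, `n`, `constant`).
#' @export
correlate_observables <- function(summaries) {
  num <- summaries[vapply(summaries, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 species")
  cols <- names(num)
  out <- list()
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (b <= a) next
      xa <- num[[a]]; xb <- num[[b]]
      const <- stats::sd(xa) == 0 || stats::sd(xb) == 0
      if (const) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::cor.test(xa, xb))
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- tibble(
        var1 = cols[a], var2 = cols[b], r = r, p = p,
        n = length(xa), constant = const)
    }
  }
  dplyr::bind_rows(out)
}
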