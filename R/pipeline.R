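#' Pipeline configuration
#'
#' Nested, fully serialisable configuration for the end-to-end stages.
#' When `out_dir` is set, each stage writes its tables as CSV/JSON next to
#' a copy of the effective configuration (with the seed), so every run is
#' reproducible from its outputs.
#'
#' @param seed Master seed.
#' @param out_dir Output directory or NULL (return tibbles only).
#' @param ms,ciu,sim Per-stage parameter lists; see Details in the
#'   package vignette.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            ms = list(), ciu = list(), sim = list()) {
  ms <- utils::modifyList(list(
    apo_charges = 3:5, zn_species = 4:7, z = 5,
    ss_truth = c(`4` = 8, `5` = 7, `6` = 7, `7` = 2),
    noise_sd = 0.005, resolution = 10000,
    ss_range = 0:10, retention_range = 0:6), ms)
  ciu <- utils::modifyList(list(
    zn_species = 4:7,
    midpoints = c(`4` = 90, `5` = 90, `6` = 110, `7` = 110),
    centroids = c(1000, 1150), widths = c(25, 25),
    transition_width = 5, energies = seq(50, 150, 2.5),
    noise_sd = 0.02), ciu)
  sim <- utils::modifyList(list(
    zn_species = c(0, 4, 7), z = 5, temps = c(300, 500, 800),
    steps_per_temp = 15000, smd_k = 25, smd_steps = 20000,
    n_replicates = 25, metad_steps = 0), sim)
  structure(list(seed = as.integer(seed), out_dir = out_dir, ms = ms,
                 ciu = ciu, sim = sim),
            class = "pipeline_config")
}

.write_stage <- function(config, stage, tables) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    if (is.data.frame(tables[[nm]])) {
      utils::write.csv(tables[[nm]],
                       file.path(config$out_dir,
                                 paste0(stage, "_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg,
                       file.path(config$out_dir,
                                 paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Native-MS stage: synthesize spectra and fit species
#'
#' Generates the apo charge-state distribution (reduced, z as configured)
#' and one oxidised spectrum per Zn-loaded species with the configured
#' ground-truth disulfide count, then recovers (n_ss, retention) for each
#' species by the grid-search fit.
#'
#' @param config A [pipeline_config()].
#' @return List with `species_table` (per-species fit vs truth), `csd`
#'   (apo charge-state summary).
#' @export
run_ms_stage <- function(config = pipeline_config()) {
  p <- config$ms
  base <- composition_from_sequence(mt2_sequence())
  cfg <- generator_config(seed = config$seed, noise_sd = p$noise_sd,
                          resolution = p$resolution)
  csd <- tibble(z = p$apo_charges,
                mz = vapply(p$apo_charges, function(z) {
                  species_mz(apply_species(base, 0, 0, z))
                }, numeric(1)))
  rows <- lapply(p$zn_species, function(nz) {
    truth <- unname(p$ss_truth[as.character(nz)])
    sp <- apply_species(base, nz, truth, p$z)
    obs <- synth_spectrum(list(sp), 1, cfg)
    fit <- fit_species(obs, base, n_zn = nz, z = p$z,
                       ss_range = p$ss_range,
                       retention_range = p$retention_range)
    tibble(n_zn = nz, z = p$z, n_ss_true = truth,
           n_ss_fit = fit$best$n_ss, retention_fit = fit$best$retention,
           rss = fit$best$rss, mz_avg = species_mz(sp))
  })
  out <- list(species_table = dplyr::bind_rows(rows), csd = csd)
  .write_stage(config, "ms", out)
  out
}

#' CIU stage: synthesize fingerprints and fit CIU50 per species
#'
#' @param config A [pipeline_config()].
#' @return List with `ciu50_table` (per-species fitted midpoint vs
#'   generating truth) and `fingerprints` (named list).
#' @export
run_ciu_stage <- function(config = pipeline_config()) {
  p <- config$ciu
  fps <- list()
  rows <- lapply(p$zn_species, function(nz) {
    true_mid <- unname(p$midpoints[as.character(nz)])
    cfg <- generator_config(seed = config$seed + nz,
                            noise_sd = p$noise_sd)
    fp <- synth_ciu_fingerprint(p$centroids, p$widths, true_mid,
                                p$transition_width, p$energies, cfg)
    fps[[paste0("Zn", nz)]] <<- fp
    fit <- fit_ciu50(fp, n_states = 2)
    if (nrow(fit$transitions) == 0) {
      return(tibble(n_zn = nz, ciu50_true = true_mid,
                    ciu50_fit = NA_real_, verdict = "no transition"))
    }
    tibble(n_zn = nz, ciu50_true = true_mid,
           ciu50_fit = fit$transitions$ciu50[1],
           width = fit$transitions$width[1],
           verdict = if (fit$converged) "ok" else "no convergence")
  })
  out <- list(ciu50_table = dplyr::bind_rows(rows), fingerprints = fps)
  .write_stage(config, "ciu", out["ciu50_table"])
  if (!is.null(config$out_dir)) {
    for (nm in names(fps)) {
      write_fingerprint_csv(fps[[nm]],
                            file.path(config$out_dir,
                                      paste0("ciu_fp_", nm, ".csv")))
    }
  }
  out
}

#' Simulation stage: thermal unfolding, steered pulls, correlations
#'
#' Builds dumbbell structures and topologies for the configured Zn
#' loadings, runs the thermal ramp with per-frame CCS and temperature-wise
#' KDE slices, the replicated steered pulls on Rg, optionally the
#' metadynamics free-energy estimate, and tabulates per-species summaries
#' with their pairwise correlations.
#'
#' @param config A [pipeline_config()].
#' @return List with `unfold_summary` (per-species delta-CCS per
#'   temperature), `force_summary` (per-species mean/sd peak force over
#'   replicates), `species_summary` (h-bond-free observable table:
#'   Zn-S links, contacts, forces, free-energy barrier if run),
#'   `correlations`.
#' @export
run_sim_stage <- function(config = pipeline_config()) {
  p <- config$sim
  seq <- mt2_sequence()
  unfold <- list(); force <- list(); species <- list()
  for (nz in p$zn_species) {
    map <- cluster_map(nz, seq)
    st <- make_dumbbell_structure(seq, map,
                                  generator_config(seed = config$seed))
    top <- build_topology(st, map, z = p$z)
    tu <- thermal_unfold(top, temps = p$temps,
                         steps_per_temp = p$steps_per_temp,
                         seed = config$seed)
    unfold[[length(unfold) + 1L]] <- dplyr::mutate(tu$summary, n_zn = nz)
    sm <- smd_pull(top, bias = bias_spec("steered", "rg", k = p$smd_k),
                   schedule = md_schedule(n_steps = p$smd_steps,
                                          store_stride = 200,
                                          seed = config$seed),
                   n_replicates = p$n_replicates)
    force[[length(force) + 1L]] <- dplyr::mutate(glance(sm), n_zn = nz)
    fe_b <- NA_real_
    if (p$metad_steps > 0) {
      md <- wt_metadynamics(
        top, bias = bias_spec("metadynamics", "rg"),
        schedule = md_schedule(n_steps = p$metad_steps,
                               seed = config$seed))
      fe_b <- tryCatch(fe_barrier(md$free_energy), error = function(e) NA_real_)
    }
    species[[length(species) + 1L]] <- tibble(
      n_zn = nz, zn_s_links = nrow(top$znlinks),
      n_contacts = nrow(top$contacts),
      inter_domain_contacts = sum(top$contacts$set == "inter"),
      mean_peak_force_pN = sm$mean_peak_force,
      delta_ccs = tu$delta_ccs, fe_barrier = fe_b)
  }
  species_summary <- dplyr::bind_rows(species)
  corr <- if (nrow(species_summary) >= 3) {
    correlate_observables(
      species_summary[, c("n_zn", "zn_s_links", "mean_peak_force_pN",
                          "delta_ccs")])
  } else {
    NULL
  }
  out <- list(unfold_summary = dplyr::bind_rows(unfold),
              force_summary = dplyr::bind_rows(force),
              species_summary = species_summary, correlations = corr)
  .write_stage(config, "sim", out)
  out
}
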