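#' Construct a CIU fingerprint
#'
#' A fingerprint is stored long: one row per (ccs, energy) cell, with each
#' energy column normalised to maximum 1.
#'
#' @param ccs CCS grid (A^2). @param energy_ev Energy grid (eV).
#' @param intensity Matrix, `length(ccs)` x `length(energy_ev)`.
#' @return A `ciu_fingerprint` tibble (`ccs`, `energy_ev`, `intensity`).
#' @export
ciu_fingerprint <- function(ccs, energy_ev, intensity) {
  stopifnot(is.matrix(intensity), nrow(intensity) == length(ccs),
            ncol(intensity) == length(energy_ev), all(diff(ccs) > 0))
  if (anyDuplicated(energy_ev)) stop("duplicate energy labels")
  ord <- order(energy_ev)
  energy_ev <- energy_ev[ord]
  intensity <- intensity[, ord, drop = FALSE]
  mx <- apply(intensity, 2, max)
  if (any(mx <= 0)) stop("empty energy column(s)")
  intensity <- sweep(intensity, 2, mx, `/`)
  out <- tidyr::expand_grid(energy_ev = energy_ev, ccs = ccs) |>
    dplyr::arrange(.data$energy_ev, .data$ccs)
  out$intensity <- as.vector(intensity)
  structure(out[, c("ccs", "energy_ev", "intensity")],
            class = c("ciu_fingerprint", class(out)))
}

#' @rdname ciu_fingerprint
#' @param fp A `ciu_fingerprint`.
#' @return `fp_matrix()`: the intensity matrix (rows = CCS bins, columns =
#'   energies, dimnames set).
#' @export
fp_matrix <- function(fp) {
  ccs <- sort(unique(fp$ccs)); en <- sort(unique(fp$energy_ev))
  m <- matrix(fp$intensity[order(fp$energy_ev, fp$ccs)],
              nrow = length(ccs), ncol = length(en),
              dimnames = list(NULL, format(en)))
  attr(m, "ccs") <- ccs; attr(m, "energy_ev") <- en
  m
}

#' Synthesize a CIU fingerprint with sequential state hand-off
#'
#' Ground-truth generator for collision induced unfolding data. State
#' occupancies follow a sequential logistic hand-off along the energy axis:
#' with f_i(E) the logistic step of transition i (midpoint, width), state 1
#' holds (1 - f_1), state i holds f_1...f_{i-1} (1 - f_i), and the last
#' state f_1...f_{n-1}; occupancies sum to one at every energy. Each state
#' contributes a Gaussian along CCS; seeded Gaussian intensity noise is
#' added and truncated at zero; each energy column is then normalised to
#' maximum 1.
#'
#' @param state_centroids State CCS centroids (A^2), increasing.
#' @param state_widths Gaussian sd per state (A^2).
#' @param transition_midpoints CIU50 ground truths (eV), strictly
#'   increasing; length = n states - 1.
#' @param transition_widths Logistic widths (eV).
#' @param energies Energy grid (eV), sorted.
#' @param cfg A [generator_config()]; `noise_sd` is relative to the global
#'   pre-normalisation maximum.
#' @param ccs_grid CCS grid; defaults to spanning the states at
#'   2 A^2 spacing.
#' @return A `ciu_fingerprint`.
#' @examples
#' fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
#'                             seq(50, 150, 2.5))
#' @export
synth_ciu_fingerprint <- function(state_centroids, state_widths,
                                  transition_midpoints, transition_widths,
                                  energies, cfg = generator_config(),
                                  ccs_grid = NULL) {
  ns <- length(state_centroids)
  stopifnot(ns >= 1, length(state_widths) == ns)
  if (ns > 1) {
    stopifnot(length(transition_midpoints) == ns - 1,
              length(transition_widths) == ns - 1)
    if (any(diff(transition_midpoints) <= 0) && ns > 2) {
      stop("transition midpoints must be strictly increasing")
    }
  }
  if (is.unsorted(energies)) stop("energies must be sorted")
  if (is.null(ccs_grid)) {
    ccs_grid <- seq(min(state_centroids) - 6 * max(state_widths),
                    max(state_centroids) + 6 * max(state_widths), by = 2)
  }
  occ <- state_occupancies(energies, transition_midpoints,
                           transition_widths, ns)
  m <- matrix(0, length(ccs_grid), length(energies))
  for (s in seq_len(ns)) {
    shape <- stats::dnorm(ccs_grid, state_centroids[s], state_widths[s])
    m <- m + outer(shape, occ[, s])
  }
  if (cfg$noise_sd > 0) {
    noise <- withr::with_seed(cfg$seed,
      stats::rnorm(length(m), 0, cfg$noise_sd * max(m)))
    m <- pmax(m + noise, 0)
  }
  ciu_fingerprint(ccs_grid, energies, m)
}

# occupancy matrix (n energies x n states) under sequential hand-off
state_occupancies <- function(energies, midpoints, widths, n_states) {
  if (n_states == 1) return(matrix(1, length(energies), 1))
  f <- sapply(seq_len(n_states - 1), function(i) {
    stats::plogis((energies - midpoints[i]) / widths[i])
  })
  f <- matrix(f, nrow = length(energies))
  occ <- matrix(0, length(energies), n_states)
  carried <- rep(1, length(energies))
  for (s in seq_len(n_states - 1)) {
    occ[, s] <- carried * (1 - f[, s])
    carried <- carried * f[, s]
  }
  occ[, n_states] <- carried
  occ
}

#' Assemble a fingerprint from CCS distributions
#'
#' @param ccsds List of `ccs_distribution`s, one per collision energy
#'   (energy taken from the `energy_ev` attribute).
#' @param ccs_grid Common CCS grid; defaults to the first distribution's
#'   grid, others are linearly resampled onto it.
#' @return A `ciu_fingerprint` (columns sorted by energy, each normalised
#'   to max 1).
#' @export
build_fingerprint <- function(ccsds, ccs_grid = NULL) {
  stopifnot(length(ccsds) >= 1)
  energies <- vapply(ccsds, function(d) attr(d, "energy_ev"), numeric(1))
  if (anyDuplicated(energies)) stop("duplicate energy labels")
  if (is.null(ccs_grid)) ccs_grid <- ccsds[[1]]$ccs
  m <- vapply(ccsds, function(d) {
    stats::approx(d$ccs, d$density, xout = ccs_grid, yleft = 0,
                  yright = 0)$y
  }, numeric(length(ccs_grid)))
  ciu_fingerprint(ccs_grid, energies, matrix(m, nrow = length(ccs_grid)))
}

#' Intensity-weighted CCS centroid per energy column
#' @param fp A `ciu_fingerprint`.
#' @return Tibble (`energy_ev`, `centroid`).
#' @export
fp_centroids <- function(fp) {
  fp |>
    dplyr::group_by(.data$energy_ev) |>
    dplyr::summarise(centroid = sum(.data$ccs * .data$intensity) /
                       sum(.data$intensity), .groups = "drop")
}

#' Mobility gate: select a CCS or arrival-time window
#'
#' Emulates the selection step of multistage (IMS-CA-IMS) cyclic-mobility
#' workflows: intensity outside the window is zeroed and the result
#' renormalised.
#'
#' @param x A `ccs_distribution`, `atd`, or `ciu_fingerprint`.
#' @param window Numeric length-2 interval on the CCS (or time) axis.
#' @param energy_ev For fingerprints: which energy column to gate
#'   (default: lowest).
#' @return Same type as the gated axis: a `ccs_distribution` or `atd`.
#' @export
gate_select <- function(x, window, energy_ev = NULL) {
  stopifnot(length(window) == 2)
  window <- sort(window)
  if (inherits(x, "ciu_fingerprint")) {
    en <- energy_ev %||% min(x$energy_ev)
    col <- dplyr::filter(x, .data$energy_ev == en)
    if (nrow(col) == 0) stop("energy level not present in fingerprint")
    x <- ccs_distribution(col$ccs, col$intensity, energy_ev = en)
  }
  axis <- if (inherits(x, "atd")) x$time_ms else x$ccs
  keep <- axis >= window[1] & axis <= window[2]
  if (!any(keep) || sum(x[[2]][keep]) == 0) stop("empty selection window")
  y <- ifelse(keep, x[[2]], 0)
  if (inherits(x, "atd")) {
    atd(x$time_ms, y, z = attr(x, "z"), mass_Da = attr(x, "mass_Da"),
        energy_ev = attr(x, "energy_ev"))
  } else {
    ccs_distribution(x$ccs, y, z = attr(x, "z"),
                     energy_ev = attr(x, "energy_ev"))
  }
}

#' Fraction of post-activation density returning to a compact region
#'
#' Quantifies (ir)reversibility in gated re-activation experiments: the
#' integral of the post-activation CCS density inside the compact region.
#' At or below `epsilon` the transition is called irreversible.
#'
#' @param pre,post `ccs_distribution`s on a shared grid.
#' @param compact_region Length-2 CCS interval of the compact conformer.
#' @param epsilon Irreversibility threshold on the returned fraction.
#' @return Tibble: `fraction_compact_pre`, `fraction_compact_post`,
#'   `irreversible`.
#' @export
interconversion_metric <- function(pre, post, compact_region,
                                   epsilon = 0.05) {
  stopifnot(length(compact_region) == 2)
  compact_region <- sort(compact_region)
  if (max(pre$ccs) < compact_region[1] ||
      min(pre$ccs) > compact_region[2]) {
    stop("compact region outside the CCS grid")
  }
  frac <- function(d) {
    keep <- d$ccs >= compact_region[1] & d$ccs <= compact_region[2]
    if (sum(keep) < 2) return(0)
    trapz(d$ccs[keep], d$density[keep])
  }
  tibble(fraction_compact_pre = frac(pre),
         fraction_compact_post = frac(post),
         irreversible = frac(post) <= epsilon)
}

#' Read / write a fingerprint CSV matrix
#'
#' Rows are CCS bins (first column `ccs`), remaining columns one per
#' energy with the energy in eV as the header.
#' @param path File path.
#' @export
read_fingerprint_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  en <- as.numeric(names(df)[-1])
  ciu_fingerprint(df[[1]], en, as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_fingerprint_csv
#' @param fp A `ciu_fingerprint`.
#' @export
write_fingerprint_csv <- function(fp, path) {
  m <- fp_matrix(fp)
  df <- data.frame(ccs = attr(m, "ccs"), m, check.names = FALSE)
  names(df) <- c("ccs", format(attr(m, "energy_ev")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
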