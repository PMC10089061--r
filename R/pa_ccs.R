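#' Default collision radii table
#'
#' Radii (A) added to the probe radius when projecting. CG residue beads
#' use 3.8 A (one bead per residue); Zn beads 1.4 A; atomic radii are
#' generic van der Waals values. The probe radius defaults to a He-like
#' 1.0 A; use 1.82 for an N2-like probe.
#'
#' @param probe Probe radius (A).
#' @return A `radii_table` list: `radii` named vector, `probe`, `default`.
#' @export
radii_table <- function(probe = 1.0) {
  stopifnot(probe >= 0)
  structure(list(
    radii = stats::setNames(
      c(3.8, 1.4, 1.7, 1.55, 1.52, 1.8, 1.2, 2.27),
      c("BEAD", "ZN", "C", "N", "O", "S", "H", "NA")),
    probe = probe, default = 1.7
  ), class = "radii_table")
}

lookup_radii <- function(types, table) {
  r <- table$radii[toupper(types)]
  r[is.na(r)] <- table$default
  unname(r) + table$probe
}

#' Projection-approximation collision cross section
#'
#' Monte Carlo estimate of the orientation-averaged projected (shadow)
#' area of the union of spheres: for each of `n_orientations` uniformly
#' random rotations, `n_mc` points are sampled over the projected bounding
#' box and tested against the union of disks (sphere radius + probe
#' radius). The CCS is the mean shadow area over orientations and the
#' standard error is taken across orientations. The projection
#' approximation ignores gas scattering, so absolute values carry the
#' usual PA bias; an optional global `scale` factor permits empirical
#' correction.
#'
#' @param coords N x 3 matrix (A), or a `bead_structure`.
#' @param radii Per-site collision radii (A, probe excluded), a
#'   [radii_table()], or NULL to look up from the structure's types.
#' @param probe Probe radius (A), used when `radii` is a bare vector.
#' @param n_orientations Number of random orientations.
#' @param n_mc Monte Carlo points per orientation.
#' @param seed RNG seed.
#' @param scale Global multiplicative calibration factor.
#' @param rotations Optional list of 3 x 3 rotation matrices replacing the
#'   random orientations (for oracle comparisons on fixed projections).
#' @return A `pa_ccs_result`: list with `ccs` (A^2), `se`, `n_orientations`,
#'   `n_mc`.
#' @examples
#' pa_ccs(matrix(0, 1, 3), radii = 2, probe = 1, seed = 1)  # ~ pi * 9
#' @export
pa_ccs <- function(coords, radii = NULL, probe = 1.0, n_orientations = 32,
                   n_mc = 2000, seed = 1, scale = 1.0, rotations = NULL) {
  if (inherits(coords, "bead_structure")) {
    if (is.null(radii)) radii <- radii_table(probe)
    types <- coords$type
    coords <- as.matrix(coords[, c("x", "y", "z")])
    r <- lookup_radii(types, radii)
  } else if (inherits(radii, "radii_table")) {
    stop("radii_table input needs a bead_structure with types")
  } else {
    coords <- as.matrix(coords)
    if (is.null(radii)) radii <- 1.7
    r <- rep_len(radii, nrow(coords)) + probe
  }
  stopifnot(nrow(coords) >= 1, ncol(coords) == 3, n_orientations >= 1,
            n_mc >= 1, all(r > 0))
  if (!is.null(rotations)) n_orientations <- length(rotations)
  areas <- withr::with_seed(seed, {
    vapply(seq_len(n_orientations), function(o) {
      R <- if (is.null(rotations)) random_rotation() else rotations[[o]]
      p <- coords %*% t(R)
      shadow_area_mc(p[, 1], p[, 2], r, n_mc)
    }, numeric(1))
  })
  structure(list(ccs = scale * mean(areas),
                 se = scale * stats::sd(areas) / sqrt(n_orientations),
                 n_orientations = n_orientations, n_mc = n_mc),
            class = "pa_ccs_result")
}

#' @export
print.pa_ccs_result <- function(x, ...) {
  cat("<pa_ccs> ", format(x$ccs, digits = 6), " +/- ",
      format(x$se, digits = 3), " A^2  (", x$n_orientations,
      " orientations x ", x$n_mc, " points)\n", sep = "")
  invisible(x)
}

# uniform random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# MC shadow area of the union of disks centred at (px, py) with radii r
shadow_area_mc <- function(px, py, r, n_mc) {
  xlim <- range(px - r, px + r)
  ylim <- range(py - r, py + r)
  sx <- stats::runif(n_mc, xlim[1], xlim[2])
  sy <- stats::runif(n_mc, ylim[1], ylim[2])
  hit <- rep(FALSE, n_mc)
  for (i in seq_along(px)) {
    hit <- hit | ((sx - px[i])^2 + (sy - py[i])^2 <= r[i]^2)
  }
  mean(hit) * diff(xlim) * diff(ylim)
}

#' CCS of every frame of a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param radii A [radii_table()].
#' @param n_orientations,n_mc,seed Passed to [pa_ccs()].
#' @return Tibble (`frame`, `time_ps`, `temperature`, `ccs`).
#' @export
trajectory_ccs <- function(traj, radii = radii_table(),
                           n_orientations = 16, n_mc = 800, seed = 1) {
  r <- lookup_radii(traj$types, radii)
  n <- dim(traj$frames)[3]
  ccs <- vapply(seq_len(n), function(i) {
    pa_ccs(traj$frames[, , i], radii = r, probe = 0,
           n_orientations = n_orientations, n_mc = n_mc,
           seed = seed + i)$ccs
  }, numeric(1))
  dplyr::mutate(traj$summary[, c("frame", "time_ps", "temperature")],
                ccs = ccs)
}
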