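.gas_mass <- c(N2 = 28.0134, He = 4.002602)

#' Travelling-wave ion mobility CCS calibration
#'
#' Standard power-law protocol: drift times are corrected for the
#' mass-dependent transfer delay, t' = t - edc * sqrt(m/z) / 1000, and
#' reference CCS values are reduced to CCS' = CCS * sqrt(mu) / z with mu
#' the ion-gas reduced mass; log(CCS') is then regressed on log(t') to
#' give CCS' = A * t'^B. Calibrations with R^2 below `min_r2` are flagged
#' as not accepted.
#'
#' @param calibrants Data frame with columns `t_ms` (drift time, ms),
#'   `ccs_A2` (reference CCS, A^2), `z` (charge), `mass_Da` (ion mass).
#' @param gas Buffer gas, `"N2"` (default) or `"He"`.
#' @param edc Enhanced-duty-cycle delay coefficient (instrument constant).
#' @param min_r2 Acceptance threshold on the log-log fit R^2.
#' @return A `tw_calibration`: list with `A`, `B`, `r2`, `gas`, `edc`,
#'   `accepted`, `t_range` (corrected-time span of the calibrants).
#' @export
calibrate_tw <- function(calibrants, gas = c("N2", "He"), edc = 1.41,
                         min_r2 = 0.98) {
  gas <- match.arg(gas)
  stopifnot(all(c("t_ms", "ccs_A2", "z", "mass_Da") %in% names(calibrants)))
  if (nrow(calibrants) < 3) stop("need at least 3 calibrant points")
  mz <- calibrants$mass_Da / calibrants$z
  tprime <- calibrants$t_ms - edc * sqrt(mz) / 1000
  if (any(tprime <= 0)) stop("negative corrected drift time(s)")
  mu <- reduced_mass(calibrants$mass_Da, .gas_mass[[gas]])
  ccsprime <- calibrants$ccs_A2 * sqrt(mu) / calibrants$z
  if (stats::sd(log(tprime)) == 0) {
    stop("calibrant drift times are identical: rank-deficient fit")
  }
  fit <- stats::lm(log(ccsprime) ~ log(tprime))
  y <- log(ccsprime)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(A = exp(stats::coef(fit)[[1]]), B = stats::coef(fit)[[2]],
                 r2 = r2, gas = gas, edc = edc,
                 accepted = r2 >= min_r2, t_range = range(tprime)),
            class = "tw_calibration")
}

reduced_mass <- function(m_ion, m_gas) m_ion * m_gas / (m_ion + m_gas)

#' @export
print.tw_calibration <- function(x, ...) {
  cat("<tw_calibration> CCS' = ", format(x$A, digits = 6), " * t'^",
      format(x$B, digits = 6), "  (", x$gas, ", R^2 = ",
      format(x$r2, digits = 6), if (x$accepted) ", accepted" else
        ", NOT accepted", ")\n", sep = "")
  invisible(x)
}

#' @rdname calibrate_tw
#' @param x A `tw_calibration`.
#' @param ... Unused.
#' @export
glance.tw_calibration <- function(x, ...) {
  tibble(A = x$A, B = x$B, r2 = x$r2, gas = x$gas, edc = x$edc,
         accepted = x$accepted)
}

#' Predict CCS from drift time (and back) through a calibration
#' @param cal A `tw_calibration`.
#' @param t_ms Drift times (ms). @param z Charge. @param mass_Da Ion mass.
#' @return CCS in A^2.
#' @export
ccs_from_time <- function(cal, t_ms, z, mass_Da) {
  tprime <- t_ms - cal$edc * sqrt(mass_Da / z) / 1000
  mu <- reduced_mass(mass_Da, .gas_mass[[cal$gas]])
  cal$A * tprime^cal$B * z / sqrt(mu)
}

#' @rdname ccs_from_time
#' @param ccs_A2 CCS values to invert.
#' @export
time_from_ccs <- function(cal, ccs_A2, z, mass_Da) {
  mu <- reduced_mass(mass_Da, .gas_mass[[cal$gas]])
  tprime <- (ccs_A2 * sqrt(mu) / z / cal$A)^(1 / cal$B)
  tprime + cal$edc * sqrt(mass_Da / z) / 1000
}

#' Construct an arrival time distribution
#'
#' @param time_ms Arrival-time grid (ms), strictly increasing.
#' @param intensity Non-negative intensities.
#' @param z Charge state. @param mass_Da Ion mass (Da).
#' @param energy_ev Collision-energy label (eV).
#' @return An `atd` tibble with metadata attributes.
#' @export
atd <- function(time_ms, intensity, z, mass_Da, energy_ev = NA_real_) {
  stopifnot(all(diff(time_ms) > 0), all(intensity >= 0))
  out <- tibble(time_ms = time_ms, intensity = intensity)
  structure(out, class = c("atd", class(out)),
            z = z, mass_Da = mass_Da, energy_ev = energy_ev)
}

#' Transform an ATD to a CCS distribution
#'
#' Maps the time axis through the calibration power law and renormalises
#' the density with the Jacobian dCCS/dt, so area is preserved; the result
#' integrates to 1. Times outside the calibrant span are flagged as
#' extrapolation.
#'
#' @param x An [atd()].
#' @param cal An accepted [calibrate_tw()] result.
#' @return A `ccs_distribution` tibble (`ccs`, `density`), unit area.
#' @export
atd_to_ccsd <- function(x, cal) {
  if (!cal$accepted) stop("calibration not accepted (R^2 too low)")
  z <- attr(x, "z"); mass <- attr(x, "mass_Da")
  tprime <- x$time_ms - cal$edc * sqrt(mass / z) / 1000
  if (any(tprime <= 0)) stop("corrected times non-positive")
  extrap <- any(tprime < cal$t_range[1]) || any(tprime > cal$t_range[2])
  if (extrap) warning("ATD extends outside the calibrated drift-time span")
  mu <- reduced_mass(mass, .gas_mass[[cal$gas]])
  scale <- cal$A * z / sqrt(mu)
  ccs <- scale * tprime^cal$B
  jac <- scale * cal$B * tprime^(cal$B - 1)
  dens <- x$intensity / jac
  ccs_distribution(ccs, dens, z = z, energy_ev = attr(x, "energy_ev"),
                   extrapolated = extrap)
}

#' Construct a CCS distribution
#'
#' @param ccs CCS grid (A^2), strictly increasing.
#' @param density Non-negative density values; renormalised to unit area.
#' @param z,energy_ev,extrapolated Metadata.
#' @return A `ccs_distribution` tibble.
#' @export
ccs_distribution <- function(ccs, density, z = NA_integer_,
                             energy_ev = NA_real_, extrapolated = FALSE) {
  stopifnot(all(diff(ccs) > 0), all(density >= 0))
  area <- trapz(ccs, density)
  if (area <= 0) stop("empty CCS distribution")
  out <- tibble(ccs = ccs, density = density / area)
  structure(out, class = c("ccs_distribution", class(out)),
            z = z, energy_ev = energy_ev, extrapolated = extrapolated)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Read / write an ATD CSV with metadata header lines
#'
#' Format: comment lines `#z=`, `#mass=`, `#energy_eV=` followed by a
#' two-column CSV (time_ms, intensity).
#' @param path File path.
#' @export
read_atd_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- function(key) {
    ln <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*=", "", ln[1])) else NA_real_
  }
  df <- utils::read.csv(path, comment.char = "#")
  atd(df[[1]], df[[2]], z = meta("z"), mass_Da = meta("mass"),
      energy_ev = meta("energy_eV"))
}

#' @rdname read_atd_csv
#' @param x An `atd`.
#' @export
write_atd_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#z=", attr(x, "z")),
               paste0("#mass=", attr(x, "mass_Da")),
               paste0("#energy_eV=", attr(x, "energy_ev"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}
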