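#' Plot a mass spectrum
#' @param object A `mass_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mass_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a CCS distribution
#' @param object A `ccs_distribution`.
#' @param ... Unused.
#' @export
autoplot.ccs_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ccs, y = .data$density)) +
    ggplot2::geom_area(alpha = 0.4, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(CCS ~ (ring(A)^2), ), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a CIU fingerprint as a heat map
#' @param object A `ciu_fingerprint`.
#' @param ... Unused.
#' @export
autoplot.ciu_fingerprint <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_ev, y = .data$ccs,
                                       fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "norm.\nintensity") +
    ggplot2::labs(x = "collision energy (eV)",
                  y = expression(CCS ~ (ring(A)^2))) +
    ggplot2::theme_minimal()
}

#' Plot the fitted CIU50 model over column centroids
#' @param object A `ciu50_result`.
#' @param ... Unused.
#' @export
autoplot.ciu50_result <- function(object, ...) {
  cen <- object$centroids
  grid <- tibble(energy_ev = seq(min(cen$energy_ev), max(cen$energy_ev),
                                 length.out = 200))
  grid$fit <- object$model(object$par, grid$energy_ev)
  ggplot2::ggplot(cen, ggplot2::aes(x = .data$energy_ev,
                                    y = .data$centroid)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$transitions$ciu50,
                        linetype = "dashed") +
    ggplot2::labs(x = "collision energy (eV)",
                  y = expression(centroid ~ CCS ~ (ring(A)^2))) +
    ggplot2::theme_minimal()
}

#' Plot per-replicate steered-MD force profiles
#' @param object An `smd_result`.
#' @param ... Unused.
#' @export
autoplot.smd_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    lapply(seq_along(object$profiles), function(r) {
      dplyr::mutate(object$profiles[[r]], replicate = r)
    }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv, y = .data$force_pN,
                                   group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "CV (Å)", y = "pulling force (pN)") +
    ggplot2::theme_minimal()
}

#' Plot a metadynamics free-energy profile
#' @param object A `metadynamics_result`.
#' @param ... Unused.
#' @export
autoplot.metadynamics_result <- function(object, ...) {
  ggplot2::ggplot(object$free_energy,
                  ggplot2::aes(x = .data$cv, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "CV (Å)", y = "free energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot thermal-unfolding KDE slices per temperature
#' @param object A `thermal_unfold_result`.
#' @param ... Unused.
#' @export
autoplot.thermal_unfold_result <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$kde), function(tmp) {
    if (is.null(object$kde[[tmp]])) return(NULL)
    dplyr::mutate(as_tibble(object$kde[[tmp]]), temperature = tmp)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ccs, y = .data$density,
                                   colour = .data$temperature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(CCS ~ (ring(A)^2)), y = "density",
                  colour = "T (K)") +
    ggplot2::theme_minimal()
}
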