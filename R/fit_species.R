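#' Grid-search species fit: disulfide count and proton retention
#'
#' Reproduces the native-MS species assignment: with the protein base
#' composition, Zn stoichiometry and charge fixed, the observed envelope is
#' compared against rendered isotope envelopes over an exhaustive grid of
#' disulfide counts and integer proton-retention offsets. Each candidate is
#' scaled to the data by optimal linear least squares; the reported species
#' minimises the residual sum of squares, with ties broken toward fewer
#' disulfides.
#'
#' Disulfide count and proton retention are exactly confounded in mass:
#' one extra disulfide (-2 H) is cancelled by two extra retained protons
#' (+2 H), so (n_ss, retention) is identified only up to this class. The
#' fewest-disulfide tie-break reports the canonical representative, the
#' member with retention 0 or 1; the class invariant is the net hydrogen
#' shift 2 n_ss - retention.
#'
#' @param observed A `mass_spectrum` (tibble with `mz`, `intensity`)
#'   covering the candidate envelopes.
#' @param base `elemental_composition` of the neutral reduced protein.
#' @param n_zn Fixed Zn2+ count.
#' @param z Fixed charge state.
#' @param ss_range Candidate disulfide counts (default 0:10).
#' @param retention_range Candidate integer H offsets (default 0:10).
#' @param n_na Fixed sodium-carrier count.
#' @param resolution Resolving power of the forward model; defaults to the
#'   `resolution` attribute of `observed` when present.
#' @return A `species_fit` object: list with `best` (one-row tibble),
#'   `candidates` (full grid with residuals and fitted abundances) and the
#'   fixed descriptors. `tidy()` returns the candidate grid, `glance()` the
#'   best row.
#' @examples
#' base <- composition_from_sequence(mt2_sequence())
#' obs <- render_spectrum(apply_species(base, 7, 2, 5))
#' fit_species(obs, base, n_zn = 7, z = 5)$best$n_ss
#' @export
fit_species <- function(observed, base, n_zn, z, ss_range = 0:10,
                        retention_range = 0:10, n_na = 0,
                        resolution = NULL) {
  stopifnot(is.data.frame(observed), all(c("mz", "intensity") %in%
                                           names(observed)))
  resolution <- resolution %||% attr(observed, "resolution") %||% 10000
  if (is.na(resolution)) resolution <- 10000
  grid <- tidyr::expand_grid(n_ss = sort(ss_range),
                             retention = sort(retention_range))
  obs <- observed$intensity
  res <- purrr::pmap(grid, function(n_ss, retention) {
    sp <- tryCatch(
      apply_species(base, n_zn, n_ss, z, n_na = n_na, retention = retention),
      error = function(e) NULL
    )
    if (is.null(sp)) return(list(rss = Inf, abundance = NA_real_))
    model <- suppressWarnings(
      render_spectrum(sp, resolution = resolution, grid = observed$mz)
    )$intensity
    denom <- sum(model^2)
    a <- if (denom > 0) sum(obs * model) / denom else 0
    list(rss = sum((obs - a * model)^2), abundance = a)
  })
  grid$rss <- vapply(res, `[[`, numeric(1), "rss")
  grid$abundance <- vapply(res, `[[`, numeric(1), "abundance")
  finite <- grid$rss[is.finite(grid$rss)]
  if (diff(range(finite)) <= 1e-12 * max(abs(finite), 1)) {
    stop("species fit unidentifiable: all candidate residuals equal ",
         "(flat or empty spectrum?)")
  }
  # ties toward fewer disulfides: order by rss, then n_ss, then retention
  ord <- order(grid$rss, grid$n_ss, grid$retention)
  best <- grid[ord[1], ]
  structure(list(best = best, candidates = grid, n_zn = n_zn, z = z,
                 n_na = n_na, resolution = resolution),
            class = "species_fit")
}

#' @export
print.species_fit <- function(x, ...) {
  cat("<species_fit> Zn", x$n_zn, " z=", x$z, ": best n_ss = ",
      x$best$n_ss, ", retention = ", x$best$retention,
      " (rss ", format(x$best$rss, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_species
#' @param x A `species_fit`.
#' @param ... Unused.
#' @export
tidy.species_fit <- function(x, ...) as_tibble(x$candidates)

#' @rdname fit_species
#' @export
glance.species_fit <- function(x, ...) {
  dplyr::mutate(x$best, n_zn = x$n_zn, z = x$z,
                n_candidates = nrow(x$candidates))
}

#' Read / write a two-column mass spectrum CSV
#' @param path File path.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  new_mass_spectrum(df[[1]], df[[2]])
}

#' @rdname read_spectrum_csv
#' @param spectrum A `mass_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[, c("mz", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}
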