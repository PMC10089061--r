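#' Generator configuration
#'
#' Bundles the knobs shared by the synthetic-data generators: the RNG seed
#' (fixed seed implies identical output), the relative intensity noise,
#' the resolving power used when rendering spectra, and the instrument bin
#' width.
#'
#' @param seed Integer RNG seed.
#' @param noise_sd Gaussian intensity noise, as a fraction of the maximum
#'   intensity; truncated so intensities stay non-negative.
#' @param resolution FWHM resolving power (m/z divided by peak FWHM).
#' @param bin_width Grid spacing (m/z for spectra, ms for ATDs, A^2 for CCS).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, noise_sd = 0.02, resolution = 10000,
                             bin_width = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            noise_sd >= 0, resolution > 0, bin_width > 0)
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 resolution = resolution, bin_width = bin_width),
            class = "generator_config")
}

#' Build a metalloprotein ion species
#'
#' Applies the species bookkeeping to a neutral, reduced, fully protonated
#' base composition: each bound Zn2+ displaces two thiol protons (-2 H),
#' each disulfide removes two hydrogens (-2 H), each sodium charge carrier
#' replaces one proton (-1 H, +1 Na), and each charging proton adds one H
#' and one charge. Partial proton retention inside the Zn clusters is
#' modelled as a single integer hydrogen offset for the whole ion
#' (`retention`, +1 H each), since per-site retention is not resolved.
#'
#' @param base `elemental_composition` of the neutral reduced protein.
#' @param n_zn Bound Zn2+ (0-7).
#' @param n_ss Disulfide bonds (0-10).
#' @param z Charge state (number of charges).
#' @param n_na Sodium adducts acting as charge carriers.
#' @param retention Integer H offset retained despite Zn displacement.
#' @return A `species_model`: the adjusted composition plus the species
#'   descriptors as attributes.
#' @examples
#' sp <- apply_species(composition_from_sequence(mt2_sequence()), 7, 0, 5)
#' species_mz(sp)
#' @export
apply_species <- function(base, n_zn, n_ss, z, n_na = 0, retention = 0) {
  stopifnot(n_zn >= 0, n_ss >= 0, z >= 0, n_na >= 0)
  if (n_na > z) stop("more sodium carriers than charges")
  h0 <- unclass(base)[["H"]]
  dh <- -2 * n_zn - 2 * n_ss - n_na + retention + z
  if (h0 + dh < 0) {
    stop("hydrogen count would become negative (", h0 + dh, ")")
  }
  comp <- unclass(base)
  comp["H"] <- comp["H"] + dh
  comp["Zn"] <- comp["Zn"] + n_zn
  comp["Na"] <- comp["Na"] + n_na
  structure(do.call(composition, as.list(comp)),
            class = c("species_model", "elemental_composition"),
            n_zn = n_zn, n_ss = n_ss, z = z, n_na = n_na,
            retention = retention)
}

#' @export
print.species_model <- function(x, ...) {
  cat("<species_model> Zn", attr(x, "n_zn"), " SS", attr(x, "n_ss"),
      " z=", attr(x, "z"), " Na", attr(x, "n_na"),
      " retention=", attr(x, "retention"), "\n", sep = "")
  if (attr(x, "z") > 0) {
    cat("  average m/z ", format(species_mz(x), digits = 8), "\n", sep = "")
  }
  invisible(x)
}

#' Mass and m/z of a species
#'
#' The species composition already includes the charging protons, so
#' m/z = mass / z (electron mass neglected).
#'
#' @param species A `species_model`.
#' @param kind `"average"` or `"monoisotopic"`.
#' @return Mass in Da, or m/z.
#' @export
species_mass <- function(species, kind = c("average", "monoisotopic")) {
  composition_mass(species, match.arg(kind))
}

#' @rdname species_mass
#' @export
species_mz <- function(species, kind = c("average", "monoisotopic")) {
  z <- attr(species, "z")
  if (is.null(z) || z == 0) stop("m/z undefined for a neutral species (z = 0)")
  species_mass(species, match.arg(kind)) / z
}

#' Fine isotope pattern of a composition
#'
#' Computes the isotope pattern by iterative per-element convolution of the
#' natural-abundance tables (binary exponentiation over atom counts),
#' merging peaks closer than `merge_tol` and pruning isotopologues below
#' `threshold` absolute probability. For small compositions the result
#' agrees with direct enumeration of all isotopologues.
#'
#' @param comp An `elemental_composition`.
#' @param threshold Absolute probability below which final peaks are pruned;
#'   must lie in (0, 1).
#' @param merge_tol Peaks closer than this (Da) are merged
#'   (abundance-weighted mean mass).
#' @return An `isotope_pattern` tibble with columns `mass` (Da, increasing)
#'   and `abundance` (max-normalised); attributes `total_prob` (summed
#'   probability retained before normalisation) and `threshold`.
#' @export
isotope_pattern <- function(comp, threshold = 1e-6, merge_tol = 1e-3) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  counts <- unclass(comp)
  if (sum(counts) == 0) stop("empty composition")
  # intermediate pruning far below the final threshold keeps the bound
  # total_prob > 1 - threshold * npeaks honest
  tiny <- threshold * 1e-3
  dist <- NULL
  for (el in names(counts)[counts > 0]) {
    iso <- .isotopes[[el]]
    base <- list(mass = iso$mass, prob = iso$abundance)
    eldist <- .dist_power(base, counts[[el]], tiny, merge_tol)
    dist <- if (is.null(dist)) eldist else
      .dist_convolve(dist, eldist, tiny, merge_tol)
  }
  keep <- dist$prob >= threshold
  dist <- list(mass = dist$mass[keep], prob = dist$prob[keep])
  out <- tibble(mass = dist$mass, abundance = dist$prob / max(dist$prob))
  structure(out, class = c("isotope_pattern", class(out)),
            total_prob = sum(dist$prob), threshold = threshold)
}

# distribution of n i.i.d. atoms by binary exponentiation
.dist_power <- function(base, n, tiny, merge_tol) {
  result <- NULL
  sq <- base
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) sq else
        .dist_convolve(result, sq, tiny, merge_tol)
    }
    n <- n %/% 2
    if (n > 0) sq <- .dist_convolve(sq, sq, tiny, merge_tol)
  }
  result
}

.dist_convolve <- function(a, b, tiny, merge_tol) {
  m <- outer(a$mass, b$mass, `+`)
  p <- outer(a$prob, b$prob)
  ord <- order(m)
  m <- m[ord]; p <- p[ord]
  # merge runs of peaks within merge_tol
  grp <- cumsum(c(TRUE, diff(m) > merge_tol))
  pm <- rowsum(p, grp)
  mm <- rowsum(p * m, grp) / pm
  keep <- pm >= tiny
  list(mass = as.numeric(mm[keep]), prob = as.numeric(pm[keep]))
}

#' Render a mass spectrum from ion species
#'
#' Forward model used by the species fit: every isotope peak of every
#' species becomes a Gaussian of FWHM = (m/z)/resolution centred at
#' mass/z; species envelopes are scaled by abundance and summed.
#'
#' @param species A `species_model` or list of them.
#' @param abundances Non-negative weights, one per species.
#' @param resolution FWHM resolving power.
#' @param grid m/z grid; defaults to spanning all envelopes at
#'   `bin_width` spacing.
#' @param bin_width Grid spacing when `grid` is NULL.
#' @param threshold Isotope-pattern pruning threshold.
#' @return A `mass_spectrum` tibble (`mz`, `intensity`) with metadata
#'   attributes.
#' @export
render_spectrum <- function(species, abundances = 1, resolution = 10000,
                            grid = NULL, bin_width = 0.05,
                            threshold = 1e-5) {
  if (inherits(species, "species_model")) species <- list(species)
  if (length(species) == 0) stop("empty species list")
  if (length(abundances) == 1) abundances <- rep(abundances, length(species))
  stopifnot(length(abundances) == length(species), all(abundances >= 0),
            resolution > 0)
  pats <- lapply(species, function(sp) {
    z <- attr(sp, "z")
    if (is.null(z) || z == 0) stop("cannot render a neutral species")
    pat <- isotope_pattern(sp, threshold = threshold)
    tibble(mz = pat$mass / z, ab = pat$abundance / sum(pat$abundance))
  })
  if (is.null(grid)) {
    lo <- min(vapply(pats, function(p) min(p$mz), 1)) - 2
    hi <- max(vapply(pats, function(p) max(p$mz), 1)) + 2
    grid <- seq(lo, hi, by = bin_width)
  }
  intensity <- rep(0, length(grid))
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    sigma <- (p$mz / resolution) / (2 * sqrt(2 * log(2)))
    for (j in seq_len(nrow(p))) {
      intensity <- intensity + abundances[i] * p$ab[j] *
        exp(-0.5 * ((grid - p$mz[j]) / sigma[j])^2)
    }
  }
  if (all(intensity == 0)) {
    warning("grid does not cover any isotope peak; empty spectrum")
  }
  new_mass_spectrum(grid, intensity, resolution = resolution)
}

new_mass_spectrum <- function(mz, intensity, resolution = NA_real_) {
  stopifnot(all(diff(mz) > 0), all(intensity >= 0))
  out <- tibble(mz = mz, intensity = intensity)
  structure(out, class = c("mass_spectrum", class(out)),
            resolution = resolution)
}

#' Synthesize a noisy native mass spectrum
#'
#' Renders the summed isotope envelopes of the given species and adds
#' seeded Gaussian intensity noise (sd = `cfg$noise_sd` of the maximum,
#' truncated at zero).
#'
#' @param species List of `species_model`s.
#' @param abundances Weights, one per species.
#' @param cfg A [generator_config()].
#' @param grid Optional m/z grid.
#' @return A `mass_spectrum` tibble.
#' @export
synth_spectrum <- function(species, abundances = 1, cfg = generator_config(),
                           grid = NULL) {
  sp <- render_spectrum(species, abundances, resolution = cfg$resolution,
                        grid = grid, bin_width = cfg$bin_width)
  if (cfg$noise_sd > 0) {
    noise <- withr::with_seed(cfg$seed,
      stats::rnorm(nrow(sp), 0, cfg$noise_sd * max(sp$intensity)))
    sp$intensity <- pmax(sp$intensity + noise, 0)
  }
  sp
}
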