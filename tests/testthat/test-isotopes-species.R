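test_that("single-element patterns match the natural-abundance tables", {
  pc <- isotope_pattern(composition(C = 1))
  expect_equal(nrow(pc), 2)
  expect_equal(pc$abundance[2] / pc$abundance[1], 0.0107 / 0.9893,
               tolerance = 1e-10)
  pz <- isotope_pattern(composition(Zn = 1))
  expect_equal(nrow(pz), 5)
  expect_equal(pz$abundance / max(pz$abundance),
               znmt:::.isotopes$Zn$abundance /
                 max(znmt:::.isotopes$Zn$abundance),
               tolerance = 1e-10)
})

test_that("water is dominated by its monoisotopic peak", {
  p <- isotope_pattern(composition(H = 2, O = 1), threshold = 1e-10,
                       merge_tol = 1e-8)
  expect_equal(p$mass[which.max(p$abundance)], 18.0106, tolerance = 1e-4)
  oracle <- enumerate_pattern(composition(H = 2, O = 1))
  expect_equal(p$mass[1], oracle$mass[1], tolerance = 1e-9)
})

test_that("convolution equals brute-force enumeration for small compositions", {
  cases <- list(
    composition(C = 3, H = 5, N = 1, O = 1),
    composition(S = 2, Zn = 1),
    composition(C = 2, O = 2, S = 1),
    composition(Zn = 2, S = 4),
    composition(H = 6, C = 2, O = 1)
  )
  for (comp in cases) {
    p <- isotope_pattern(comp, threshold = 1e-12, merge_tol = 1e-7)
    oracle <- enumerate_pattern(comp, merge_tol = 1e-7)
    oracle$rel <- oracle$prob / max(oracle$prob)
    keep <- oracle$rel >= 1e-9
    matched <- vapply(oracle$mass[keep], function(m) {
      j <- which.min(abs(p$mass - m))
      abs(p$mass[j] - m) < 1e-6
    }, logical(1))
    expect_true(all(matched))
    for (i in which(keep)) {
      j <- which.min(abs(p$mass - oracle$mass[i]))
      expect_equal(p$abundance[j], oracle$rel[i], tolerance = 1e-9)
    }
  }
})

test_that("retained pattern probability stays within the pruning bound", {
  comp <- composition_from_sequence(mt2_sequence())
  thr <- 1e-5
  p <- isotope_pattern(comp, threshold = thr)
  tp <- attr(p, "total_prob")
  expect_lte(tp, 1)
  expect_gt(tp, 1 - thr * nrow(p) - 1e-3)
})

test_that("species bookkeeping: Zn displaces 2 protons, disulfide removes 2 H", {
  base <- composition_from_sequence(mt2_sequence())
  apo <- apply_species(base, 0, 0, 5)
  zn7 <- apply_species(base, 7, 0, 5)
  mzn <- znmt:::.average_mass[["Zn"]]
  mh <- znmt:::.average_mass[["H"]]
  expect_equal(species_mass(zn7) - species_mass(apo), 7 * (mzn - 2 * mh),
               tolerance = 1e-9)
  # m/z monotone decreasing in n_ss at fixed z
  mzs <- vapply(0:5, function(ss) {
    species_mz(apply_species(base, 7, ss, 5))
  }, numeric(1))
  expect_true(all(diff(mzs) < 0))
  # two disulfides shift by ~2 x 2.016 / z
  expect_equal(mzs[1] - mzs[3], 2 * 2 * mh / 5, tolerance = 1e-6)
})

test_that("reduced Zn7MT2 5+ sits at the reported 1298 m/z", {
  base <- composition_from_sequence(mt2_sequence())
  sp <- apply_species(base, 7, 0, 5)
  expect_equal(species_mz(sp), 1298, tolerance = 5e-4)
})

test_that("neutral species have no m/z and H can never go negative", {
  base <- composition_from_sequence(mt2_sequence())
  expect_error(species_mz(apply_species(base, 0, 0, 0)), "undefined")
  expect_error(apply_species(composition(C = 1, H = 2), 7, 0, 0),
               "negative")
  expect_error(apply_species(base, 0, 0, 2, n_na = 3), "sodium")
})

test_that("sodium carriers swap a proton for Na", {
  base <- composition_from_sequence(mt2_sequence())
  hsp <- apply_species(base, 7, 0, 5, n_na = 0)
  nasp <- apply_species(base, 7, 0, 5, n_na = 2)
  mna <- znmt:::.average_mass[["Na"]]
  mh <- znmt:::.average_mass[["H"]]
  expect_equal(species_mass(nasp) - species_mass(hsp), 2 * (mna - mh),
               tolerance = 1e-9)
})

test_that("rendered spectra are linear in abundance and centred correctly", {
  base <- composition_from_sequence(mt2_sequence())
  sp <- apply_species(base, 7, 0, 5)
  s1 <- render_spectrum(sp, 1, resolution = 5000)
  s2 <- render_spectrum(sp, 2, resolution = 5000,
                        grid = s1$mz)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)
  centroid <- sum(s1$mz * s1$intensity) / sum(s1$intensity)
  expect_equal(centroid, 1298, tolerance = 1)
})

test_that("very high resolving power gives a delta-like peak at exact m/z", {
  sp <- apply_species(composition(C = 1), 0, 0, 1)
  grid <- seq(13.0, 13.02, by = 1e-5)
  s <- render_spectrum(sp, 1, resolution = 1e5, grid = grid)
  mono <- 12 + znmt:::.monoisotopic_mass[["H"]]
  expect_equal(s$mz[which.max(s$intensity)], mono, tolerance = 2e-5)
  # FWHM of ~1.3e-4 m/z: the peak occupies only a sliver of the grid
  expect_lt(sum(s$intensity > max(s$intensity) / 2) / length(grid), 0.02)
})

test_that("spectrum CSV round trip preserves the data", {
  base <- composition_from_sequence(mt2_sequence())
  s <- render_spectrum(apply_species(base, 4, 0, 5), bin_width = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$mz, s$mz)
  expect_equal(s2$intensity, s$intensity)
})
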