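# synthetic calibrants generated from a known power law
make_calibrants <- function(A = 400, B = 0.55, edc = 1.41, gas_mass = 28.0134,
                            noise_sd = 0, seed = 1) {
  cb <- tibble::tibble(
    mass_Da = c(12000, 15000, 20000, 25000, 30000),
    z = c(7, 8, 9, 10, 11),
    ccs_A2 = c(2000, 2600, 3200, 3900, 4500))
  mu <- znmt:::reduced_mass(cb$mass_Da, gas_mass)
  tp <- ((cb$ccs_A2 * sqrt(mu) / cb$z) / A)^(1 / B)
  cb$t_ms <- tp + edc * sqrt(cb$mass_Da / cb$z) / 1000
  if (noise_sd > 0) {
    cb$t_ms <- withr::with_seed(seed,
      cb$t_ms * (1 + stats::rnorm(nrow(cb), 0, noise_sd)))
  }
  cb
}

test_that("noiseless calibrants recover the generating power law", {
  cal <- calibrate_tw(make_calibrants())
  expect_equal(cal$A, 400, tolerance = 1e-6)
  expect_equal(cal$B, 0.55, tolerance = 1e-6)
  expect_true(cal$accepted)
})

test_that("1% timing noise still yields an accepted calibration", {
  cal <- calibrate_tw(make_calibrants(noise_sd = 0.01, seed = 4))
  expect_gte(cal$r2, 0.98)
})

test_that("degenerate calibrant sets are rejected", {
  cb <- make_calibrants()[c(1, 1, 1), ]
  expect_error(calibrate_tw(cb), "rank-deficient")
  expect_error(calibrate_tw(make_calibrants()[1:2, ]), "at least 3")
})

test_that("calibration round trip is the identity", {
  cal <- calibrate_tw(make_calibrants())
  ccs0 <- seq(900, 1400, by = 50)
  t <- time_from_ccs(cal, ccs0, z = 5, mass_Da = 6490)
  back <- ccs_from_time(cal, t, z = 5, mass_Da = 6490)
  expect_equal(back, ccs0, tolerance = 1e-9)
})

test_that("ATD -> CCSD transform preserves area and recovers the centroid", {
  cal <- calibrate_tw(make_calibrants())
  # build an ATD whose true CCS distribution is Gaussian at 1000 A^2
  ccs_true <- seq(850, 1150, length.out = 400)
  dens <- stats::dnorm(ccs_true, 1000, 30)
  t <- time_from_ccs(cal, ccs_true, z = 5, mass_Da = 6490)
  # intensity in time units = density in ccs units * dccs/dt
  x <- suppressWarnings(atd(t, dens * c(diff(ccs_true) / diff(t),
                                        tail(diff(ccs_true) / diff(t), 1)),
                            z = 5, mass_Da = 6490))
  d <- suppressWarnings(atd_to_ccsd(x, cal))
  expect_equal(znmt:::trapz(d$ccs, d$density), 1, tolerance = 1e-9)
  centroid <- sum(d$ccs * d$density) / sum(d$density)
  expect_equal(centroid, 1000, tolerance = 5)  # 0.5%
})

test_that("ATD CSV round trip keeps metadata", {
  x <- atd(seq(2, 8, 0.05), stats::dnorm(seq(2, 8, 0.05), 5, 0.5),
           z = 5, mass_Da = 6490, energy_ev = 75)
  path <- withr::local_tempfile(fileext = ".csv")
  write_atd_csv(x, path)
  x2 <- read_atd_csv(path)
  expect_equal(attr(x2, "z"), 5)
  expect_equal(attr(x2, "energy_ev"), 75)
  expect_equal(x2$intensity, x$intensity)
})

test_that("fingerprints keep every energy column at maximum one", {
  fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
                              seq(50, 150, 2.5),
                              generator_config(seed = 3))
  mx <- apply(fp_matrix(fp), 2, max)
  expect_equal(unname(mx), rep(1, length(mx)))
  # round trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_fingerprint_csv(fp, path)
  fp2 <- read_fingerprint_csv(path)
  expect_equal(fp2$intensity, fp$intensity, tolerance = 1e-9)
})

test_that("build_fingerprint reassembles the generator output", {
  fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
                              c(50, 100, 150),
                              generator_config(noise_sd = 0))
  cols <- lapply(unique(fp$energy_ev), function(e) {
    col <- fp[fp$energy_ev == e, ]
    ccs_distribution(col$ccs, col$intensity, energy_ev = e)
  })
  fp2 <- build_fingerprint(cols)
  expect_equal(fp_matrix(fp2), fp_matrix(fp), tolerance = 1e-9)
  expect_error(build_fingerprint(cols[c(1, 1)]), "duplicate")
})

test_that("a single state yields an energy-independent fingerprint", {
  fp <- synth_ciu_fingerprint(1000, 25, numeric(0), numeric(0),
                              seq(50, 150, 25),
                              generator_config(noise_sd = 0))
  m <- fp_matrix(fp)
  for (j in 2:ncol(m)) expect_equal(m[, j], m[, 1], tolerance = 1e-12)
})

test_that("the centroid curve crosses the midpoint CCS at the CIU50", {
  fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
                              seq(50, 150, 0.5),
                              generator_config(noise_sd = 0))
  cen <- fp_centroids(fp)
  cross <- cen$energy_ev[which.min(abs(cen$centroid - 1075))]
  expect_equal(cross, 90, tolerance = 0.51)
})

test_that("mobility gating zeroes outside the window and renormalises", {
  fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
                              seq(50, 150, 2.5),
                              generator_config(noise_sd = 0))
  # full-range window: identity up to renormalisation
  col <- gate_select(fp, c(0, 1e5), energy_ev = 50)
  expect_s3_class(col, "ccs_distribution")
  full <- gate_select(col, range(col$ccs))
  expect_equal(full$density, col$density, tolerance = 1e-12)
  # window on the compact state: unimodal at its centroid
  alpha <- gate_select(col, c(900, 1075))
  expect_equal(alpha$ccs[which.max(alpha$density)], 1000, tolerance = 4)
  expect_true(all(alpha$density[alpha$ccs > 1080] == 0))
  expect_error(gate_select(col, c(5000, 6000)), "empty selection")
})

test_that("interconversion metric flags irreversible unfolding", {
  grid <- seq(900, 1300, by = 2)
  compact <- ccs_distribution(grid, stats::dnorm(grid, 1000, 20))
  extended <- ccs_distribution(grid, stats::dnorm(grid, 1150, 20))
  m <- interconversion_metric(extended, extended, c(950, 1050))
  expect_lt(m$fraction_compact_post, 0.05)
  expect_true(m$irreversible)
  m2 <- interconversion_metric(compact, compact, c(900, 1100))
  expect_gt(m2$fraction_compact_post, 0.99)
  expect_false(m2$irreversible)
  expect_error(interconversion_metric(compact, compact, c(2000, 2100)),
               "outside")
})
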