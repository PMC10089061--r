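base_mt2 <- composition_from_sequence(mt2_sequence())

test_that("grid search recovers the generating disulfide count exactly", {
  for (truth in c(2, 8)) {
    sp <- apply_species(base_mt2, 7, truth, 5)
    obs <- render_spectrum(sp)
    fit <- fit_species(obs, base_mt2, n_zn = 7, z = 5)
    expect_equal(fit$best$n_ss, truth)
    expect_equal(fit$best$retention, 0)
    # best candidate residual is the grid minimum
    expect_true(all(fit$best$rss <= fit$candidates$rss))
  }
})

test_that("canonical proton-retention offsets are recovered exactly", {
  for (ret in c(0, 1)) {
    sp <- apply_species(base_mt2, 5, 4, 5, retention = ret)
    obs <- render_spectrum(sp)
    fit <- fit_species(obs, base_mt2, n_zn = 5, z = 5,
                       retention_range = 0:6)
    expect_equal(fit$best$retention, ret)
    expect_equal(fit$best$n_ss, 4)
  }
})

test_that("non-canonical truths map to the same mass-equivalence class", {
  # one disulfide and two retained protons cancel in mass, so the fit
  # returns the fewest-disulfide representative with an identical
  # hydrogen shift 2 n_ss - retention
  sp <- apply_species(base_mt2, 5, 4, 5, retention = 3)
  fit <- fit_species(render_spectrum(sp), base_mt2, n_zn = 5, z = 5,
                     retention_range = 0:6)
  expect_equal(2 * fit$best$n_ss - fit$best$retention, 2 * 4 - 3)
  expect_equal(fit$best$rss, 0, tolerance = 1e-10)
  expect_lte(fit$best$n_ss, 4)
})

test_that("random ground truths are recovered across the grid", {
  set.seed(42)
  for (i in 1:6) {
    truth_ss <- sample(0:9, 1)
    truth_ret <- sample(0:1, 1)  # canonical representatives
    nz <- sample(4:7, 1)
    sp <- apply_species(base_mt2, nz, truth_ss, 5, retention = truth_ret)
    obs <- render_spectrum(sp, bin_width = 0.1)
    fit <- fit_species(obs, base_mt2, n_zn = nz, z = 5,
                       ss_range = 0:10, retention_range = 0:6)
    expect_equal(fit$best$n_ss, truth_ss)
    expect_equal(fit$best$retention, truth_ret)
  }
})

test_that("fit survives moderate intensity noise", {
  sp <- apply_species(base_mt2, 6, 7, 5)
  obs <- synth_spectrum(list(sp), 1,
                        generator_config(seed = 5, noise_sd = 0.02))
  fit <- fit_species(obs, base_mt2, n_zn = 6, z = 5)
  expect_equal(fit$best$n_ss, 7)
})

test_that("a flat spectrum is reported as unidentifiable", {
  flat <- znmt:::new_mass_spectrum(seq(1200, 1210, 0.1),
                                   rep(0, 101))
  expect_error(fit_species(flat, base_mt2, n_zn = 7, z = 5),
               "unidentifiable")
})

test_that("tidy/glance expose the candidate grid and the winner", {
  sp <- apply_species(base_mt2, 7, 2, 5)
  fit <- fit_species(render_spectrum(sp), base_mt2, n_zn = 7, z = 5,
                     ss_range = 0:4, retention_range = 0:2)
  td <- tidy(fit)
  expect_equal(nrow(td), 5 * 3)
  gl <- glance(fit)
  expect_equal(gl$n_ss, 2)
  expect_equal(gl$n_zn, 7)
})

test_that("synthetic apo CSD covers charge states 3 to 5", {
  cfg <- generator_config(seed = 2, noise_sd = 0)
  species <- lapply(3:5, function(z) apply_species(base_mt2, 0, 0, z))
  s <- synth_spectrum(species, c(0.6, 1, 0.8), cfg)
  found <- vapply(species, function(sp) {
    mz <- species_mz(sp)
    sel <- abs(s$mz - mz) < 2
    any(s$intensity[sel] > 0.1 * max(s$intensity))
  }, logical(1))
  expect_true(all(found))
  mz_range <- range(vapply(species, species_mz, numeric(1)))
  expect_true(all(mz_range > 1000 & mz_range < 2100))
})

test_that("seeded spectrum synthesis is reproducible", {
  sp <- apply_species(base_mt2, 7, 0, 5)
  cfg <- generator_config(seed = 9, noise_sd = 0.05)
  expect_identical(synth_spectrum(list(sp), 1, cfg),
                   synth_spectrum(list(sp), 1, cfg))
})
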