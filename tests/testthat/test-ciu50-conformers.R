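test_that("noiseless two-state fingerprints give the exact midpoint", {
  for (mid in c(75, 90, 110)) {
    fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), mid, 5,
                                seq(50, 150, 2.5),
                                generator_config(noise_sd = 0))
    fit <- fit_ciu50(fp, 2)
    expect_equal(fit$transitions$ciu50, mid, tolerance = 1e-3)
    expect_equal(fit$transitions$ccs_from, 1000, tolerance = 1)
    expect_equal(fit$transitions$ccs_to, 1150, tolerance = 1)
  }
})

test_that("CIU50 estimates are unbiased and tight across seeded replicates", {
  mids <- vapply(1:200, function(s) {
    fp <- synth_ciu_fingerprint(c(1000, 1150), c(25, 25), 90, 5,
                                seq(50, 150, 2.5),
                                generator_config(seed = s,
                                                 noise_sd = 0.02))
    fit_ciu50(fp, 2)$transitions$ciu50
  }, numeric(1))
  expect_lt(abs(mean(mids) - 90), 1)
  expect_lt(stats::sd(mids), 3)
})

test_that("three-state fingerprints resolve both transitions", {
  fp <- synth_ciu_fingerprint(c(1000, 1100, 1200), c(20, 20, 20),
                              c(75, 115), c(4, 4), seq(50, 150, 2.5),
                              generator_config(seed = 2, noise_sd = 0.01))
  fit <- fit_ciu50(fp, 3)
  expect_equal(fit$transitions$ciu50, c(75, 115), tolerance = 3)
  expect_true(all(diff(fit$transitions$ciu50) > 0))
})

test_that("non-monotone transition midpoints are rejected", {
  expect_error(
    synth_ciu_fingerprint(c(1000, 1100, 1200), c(20, 20, 20),
                          c(115, 75), c(4, 4), seq(50, 150, 2.5)),
    "increasing")
})

test_that("KDE mode recovery and unit area", {
  x <- withr::with_seed(3, stats::rnorm(500, 1000, 20))
  d <- kde_ccs(x)
  expect_equal(znmt:::trapz(d$ccs, d$density), 1, tolerance = 1e-6)
  expect_equal(d$ccs[which.max(d$density)], 1000, tolerance = 3)
})

test_that("well-separated bimodal samples give two KDE modes", {
  x <- withr::with_seed(8, c(stats::rnorm(400, 1000, 15),
                             stats::rnorm(400, 1200, 15)))
  cf <- detect_conformers(kde_ccs(x))
  expect_equal(nrow(cf), 2)
  expect_equal(cf$centroid, c(1000, 1200), tolerance = 6)
})

test_that("zero-variance samples warn about a degenerate density", {
  expect_warning(kde_ccs(rep(1000, 10), bw = 1), "zero-variance")
  expect_error(kde_ccs(1000), "at least 2")
})

test_that("a single Gaussian is labelled as one alpha conformer", {
  grid <- seq(900, 1100, 1)
  d <- ccs_distribution(grid, stats::dnorm(grid, 1000, 20))
  cf <- detect_conformers(d)
  expect_equal(nrow(cf), 1)
  expect_equal(cf$label, "alpha")
  expect_equal(cf$centroid, 1000, tolerance = 1)
  expect_equal(cf$weight, 1)
})

test_that("four-component mixtures are recovered with faithful weights", {
  x <- withr::with_seed(5, c(stats::rnorm(500, 950, 20),
                             stats::rnorm(400, 1050, 20),
                             stats::rnorm(300, 1150, 20),
                             stats::rnorm(100, 1250, 20)))
  cf <- detect_conformers(kde_ccs(x))
  expect_equal(nrow(cf), 4)
  expect_equal(cf$label, c("alpha", "beta", "gamma", "delta"))
  expect_equal(cf$centroid, c(950, 1050, 1150, 1250), tolerance = 10)
  expect_equal(cf$weight, c(0.5, 0.4, 0.3, 0.1) / 1.3, tolerance = 0.1)
  expect_equal(sum(cf$weight), 1, tolerance = 1e-9)
})

test_that("a 5% minor conformer well separated from the base is retained", {
  x <- withr::with_seed(9, c(stats::rnorm(950, 1000, 20),
                             stats::rnorm(50, 1200, 20)))
  cf <- detect_conformers(kde_ccs(x))
  expect_equal(nrow(cf), 2)
  expect_equal(cf$weight[2], 0.05, tolerance = 0.03)
})

test_that("labels always ascend in CCS", {
  x <- withr::with_seed(11, c(stats::rnorm(300, 1100, 15),
                              stats::rnorm(300, 950, 15),
                              stats::rnorm(300, 1250, 15)))
  cf <- detect_conformers(kde_ccs(x))
  expect_true(all(diff(cf$centroid) > 0))
  expect_equal(cf$label, c("alpha", "beta", "gamma"))
})
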