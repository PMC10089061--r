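make_top <- function(n_zn, seed = 1) {
  st <- suppressMessages(make_dumbbell_structure(
    mt2_sequence(), cluster_map(n_zn), generator_config(seed = seed)))
  build_topology(st, map = cluster_map(n_zn), z = 5)
}

test_that("metadynamics recovers the analytic double-well barrier", {
  top <- toy_topology(sep = 5)
  cvpot <- list(enabled = TRUE, height = 3, centre = 7.5, halfwidth = 2.5)
  md <- wt_metadynamics(
    top,
    bias = bias_spec("metadynamics", "end_to_end", hill_height = 0.2,
                     hill_width = 0.3, stride = 500, bias_factor = 10,
                     grid = c(2.5, 12.5), grid_n = 512),
    schedule = md_schedule(n_steps = 2e6, temperature = 300,
                           store_stride = 2000, seed = 11),
    cv_potential = cvpot)
  # closed form on the CV: the double well plus the radial-measure entropy
  kbt <- 0.0019872041 * 300
  r <- seq(2.5, 12.5, length.out = 512)
  V <- 3 * ((r - 7.5)^2 - 2.5^2)^2 / 2.5^4
  Ft <- V - 2 * kbt * log(r)
  true_barrier <- fe_barrier(tibble::tibble(cv = r,
                                            free_energy = Ft - min(Ft)),
                             wells = c(5, 10))
  est <- fe_barrier(md$free_energy, wells = c(5, 10))
  expect_equal(est, true_barrier, tolerance = 0.1)
  expect_true(md$converged)
})

test_that("well-tempered hill heights decay", {
  top <- toy_topology(sep = 5)
  cvpot <- list(enabled = TRUE, height = 2, centre = 7.5, halfwidth = 2.5)
  md <- wt_metadynamics(
    top,
    bias = bias_spec("metadynamics", "end_to_end", hill_height = 0.3,
                     hill_width = 0.3, stride = 500, bias_factor = 8,
                     grid = c(2.5, 12.5)),
    schedule = md_schedule(n_steps = 5e5, store_stride = 5000, seed = 4),
    cv_potential = cvpot)
  h <- md$hills$height
  k <- floor(length(h) / 5)
  smoothed <- vapply(1:5, function(b) mean(h[((b - 1) * k + 1):(b * k)]),
                     numeric(1))
  expect_lt(md$hill_decay_ratio, 0.5)
  expect_true(all(diff(smoothed) <= 0.05 * smoothed[1]))
})

test_that("the bias reconstructs a featureless landscape to hill height", {
  top <- toy_topology(sep = 7.5)
  # soft tether keeps the pair bounded; the CV landscape is then fully
  # known (tether + radial entropy), so the estimate minus the truth
  # must be flat to about the hill height
  top$bonds <- tibble::tibble(i = 1L, j = 2L, r0 = 7.5, k = 0.4)
  md <- suppressWarnings(wt_metadynamics(
    top,
    bias = bias_spec("metadynamics", "end_to_end", hill_height = 0.2,
                     hill_width = 0.4, stride = 200, bias_factor = 10,
                     grid = c(5, 10)),
    schedule = md_schedule(n_steps = 6e5, store_stride = 3000, seed = 6)))
  fe <- md$free_energy
  kbt <- 0.0019872041 * 300
  truth <- 0.5 * 0.4 * (fe$cv - 7.5)^2 - 2 * kbt * log(fe$cv)
  core <- fe$cv > 6 & fe$cv < 9
  resid <- (fe$free_energy - truth)[core]
  expect_lt(max(resid) - min(resid), 3 * 0.2)
})

test_that("near-zero steering force produces no unfolding", {
  top <- make_top(7)
  sm <- suppressWarnings(smd_pull(
    top, bias = bias_spec("steered", "rg", k = 1e-4),
    schedule = md_schedule(n_steps = 5000, store_stride = 100, seed = 2),
    n_replicates = 2))
  expect_lt(sm$mean_peak_force, 1)  # pN
  cv_end <- sm$profiles[[1]]$cv[nrow(sm$profiles[[1]])]
  expect_equal(cv_end, sm$profiles[[1]]$cv[1], tolerance = 0.6)
})

test_that("pulling increases Rg and the projection CCS", {
  top <- make_top(0)
  sm <- suppressWarnings(smd_pull(
    top, bias = bias_spec("steered", "rg", k = 50),
    schedule = md_schedule(n_steps = 20000, store_stride = 200, seed = 3),
    n_replicates = 1, ccs_every = 20))
  pr <- sm$profiles[[1]]
  expect_gt(pr$cv[nrow(pr)], pr$cv[1])
  ccs <- pr$ccs[!is.na(pr$ccs)]
  expect_gt(ccs[length(ccs)], ccs[1])
  # work equals the trapezoid of force over CV on the stored samples
  ord <- order(pr$cv)
  w <- znmt:::trapz(pr$cv[ord],
                    (pr$force_pN / znmt:::.PN_PER_KCAL_MOL_A)[ord])
  expect_equal(sm$summary$work_kcal_mol[1], w, tolerance = 1e-9)
})

test_that("Zn-loaded and apo species give comparable peak forces", {
  sch <- md_schedule(n_steps = 8000, store_stride = 100, seed = 5)
  f <- vapply(c(4, 7), function(nz) {
    top <- make_top(nz)
    cv0 <- current_cv(top, minimize_energy(top), "rg")
    suppressWarnings(smd_pull(
      top, bias = bias_spec("steered", "rg", k = 25,
                            target_end = cv0 * 1.5),
      schedule = sch, n_replicates = 3))$mean_peak_force
  }, numeric(1))
  # weak dependence of the mean unfolding force on Zn loading
  expect_lt(abs(diff(f)) / mean(f), 0.5)
})

test_that("mean steered work bounds the free-energy difference (Jarzynski)", {
  top <- toy_topology(sep = 5)
  cvpot <- list(enabled = TRUE, height = 3, centre = 7.5, halfwidth = 2.5)
  md <- wt_metadynamics(
    top,
    bias = bias_spec("metadynamics", "end_to_end", hill_height = 0.2,
                     hill_width = 0.3, stride = 500, bias_factor = 10,
                     grid = c(2.5, 12.5), grid_n = 512),
    schedule = md_schedule(n_steps = 1e6, store_stride = 2000, seed = 12),
    cv_potential = cvpot)
  fe <- md$free_energy
  dF <- fe$free_energy[which.min(abs(fe$cv - 10))] -
    fe$free_energy[which.min(abs(fe$cv - 5))]
  works <- vapply(1:25, function(r) {
    tr <- run_langevin(
      top, md_schedule(n_steps = 2e4, store_stride = 100,
                       seed = 100 + r),
      bias = bias_spec("steered", "end_to_end", k = 500,
                       target_start = 5, target_end = 10),
      cv_potential = cvpot)
    s <- tr$summary
    ord <- order(s$cv)
    znmt:::trapz(s$cv[ord], abs(s$bias_force)[ord])
  }, numeric(1))
  expect_gte(mean(works), dF - 0.3)
})

test_that("thermal ramp rejects non-increasing programs", {
  top <- make_top(4)
  expect_error(thermal_unfold(top, temps = c(500, 300)), "increasing")
})

test_that("correlation report flags constants and exact correlations", {
  df <- tibble::tibble(species = c("a", "b", "c", "d"),
                       x = c(1, 2, 3, 4), y = c(2, 4, 6, 8),
                       z = c(8, 6, 4, 2), w = c(1, 1, 1, 1))
  ct <- correlate_observables(df)
  expect_equal(ct$r[ct$var1 == "x" & ct$var2 == "y"], 1, tolerance = 1e-12)
  expect_equal(ct$r[ct$var1 == "x" & ct$var2 == "z"], -1,
               tolerance = 1e-12)
  expect_true(all(ct$constant[ct$var1 == "w" | ct$var2 == "w"]))
  expect_true(all(is.na(ct$r[ct$constant])))
  # independent random columns: small r, large p
  rnd <- withr::with_seed(5, tibble::tibble(a = stats::rnorm(4),
                                            b = stats::rnorm(4)))
  ct2 <- correlate_observables(rnd)
  expect_gt(ct2$p, 0.05)
  expect_error(correlate_observables(df[1:2, ]), "at least 3")
})
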