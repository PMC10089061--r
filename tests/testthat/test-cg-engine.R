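mt2_topology <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- suppressMessages(make_dumbbell_structure(
        mt2_sequence(), cluster_map(7), generator_config(seed = 1)))
      cache <<- build_topology(st, z = 5)
    }
    cache
  }
})

test_that("topology mirrors the cluster map and places the charges", {
  top <- mt2_topology()
  expect_equal(nrow(top$znlinks), 28)  # 7 metals x 4 thiolates
  expect_equal(sum(top$beads$charge), 5)
  expect_true(all(top$beads$resname[top$beads$charge > 0] %in% c("K", "R")))
  expect_gt(sum(top$contacts$set == "inter"), 0)
  # metal-free topology has contacts only
  st0 <- suppressMessages(make_dumbbell_structure(
    mt2_sequence(), cluster_map(0), generator_config(seed = 1)))
  top0 <- build_topology(st0, map = cluster_map(0), z = 5)
  expect_equal(nrow(top0$znlinks), 0)
  expect_gt(nrow(top0$contacts), 0)
})

test_that("bonded terms vanish at the native geometry", {
  top <- mt2_topology()
  pe <- potential_energy(top)
  expect_equal(pe$energy[pe$term == "bond"], 0, tolerance = 1e-8)
  expect_equal(pe$energy[pe$term == "angle"], 0, tolerance = 1e-8)
  # native contacts sit at their minimum, -eps each
  expect_equal(pe$energy[pe$term == "contact"],
               -nrow(top$contacts) * top$params$contact_eps,
               tolerance = 1e-6)
})

test_that("two unit charges at 10 A give the vacuum Coulomb energy", {
  top <- toy_topology(sep = 10, charge = c(1, 1))
  pe <- potential_energy(top)
  expect_equal(pe$energy[pe$term == "coulomb"], 332.0636 / 10,
               tolerance = 1e-6)
})

test_that("stretching one Zn-S link costs the harmonic energy", {
  top <- toy_topology(sep = 2.3)
  top$znlinks <- tibble::tibble(i = 1L, j = 2L, r0 = 2.3, k = 50)
  e0 <- potential_energy(top)$energy
  expect_equal(e0[8], 0, tolerance = 1e-12)  # at rest length
  delta <- 0.4
  co <- top$coords
  co[2, 1] <- co[2, 1] + delta
  e1 <- potential_energy(top, co)$energy
  terms <- potential_energy(top)$term
  expect_equal((e1 - e0)[terms == "znlink"], 0.5 * 50 * delta^2,
               tolerance = 1e-9)
})

test_that("overlapping beads give a large finite energy, never NaN", {
  top <- mt2_topology()
  co <- top$coords
  co[2, ] <- co[1, ] + 1e-4
  pe <- potential_energy(top, co)
  expect_true(all(is.finite(pe$energy)))
  expect_gt(pe$energy[pe$term == "total"], 1e3)
})

test_that("kinetic energy satisfies equipartition at 300 K", {
  top <- mt2_topology()
  tr <- run_langevin(top, md_schedule(n_steps = 1e5, temperature = 300,
                                      store_stride = 100, seed = 3))
  s <- tr$summary[tr$summary$frame > 200, ]
  kb <- 0.0019872041
  per_bead <- mean(s$ke) / length(top$masses)
  expect_equal(per_bead, 1.5 * kb * 300, tolerance = 0.05)
})

test_that("zero-friction dynamics conserve energy to 0.1%", {
  top <- mt2_topology()
  tr <- run_langevin(top, md_schedule(n_steps = 1e4, timestep_fs = 1,
                                      friction_ps = 0, store_stride = 100,
                                      seed = 3))
  etot <- tr$summary$ke + tr$summary$pe
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("identical seeds give identical trajectories", {
  top <- mt2_topology()
  sch <- md_schedule(n_steps = 2000, store_stride = 100, seed = 7)
  t1 <- run_langevin(top, sch)
  t2 <- run_langevin(top, sch)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_langevin(top, md_schedule(n_steps = 2000, store_stride = 100,
                                      seed = 8))
  expect_false(identical(t3$frames, t1$frames))
})

test_that("Rg and end-to-end metrics agree with closed forms", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(4, 0, 0))), 2)
  expect_equal(radius_of_gyration(matrix(1, 1, 3)), 0)
  th <- 2 * pi * (0:99) / 100
  ring <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 10, tolerance = 1e-9)
  expect_error(radius_of_gyration(matrix(0, 2, 3), masses = c(0, 0)),
               "zero total mass")
  expect_equal(end_to_end(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 4))), 5)
})
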