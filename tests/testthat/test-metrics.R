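test_that("an ideal helix has the textbook i,i+4 backbone hydrogen bonds", {
  hx <- ideal_helix(20)
  hb <- count_hbonds(hx)
  expect_equal(as.integer(hb), 16)  # residues 1..16 donate to 5..20
  prs <- attr(hb, "pairs")
  expect_true(all(prs$acceptor_resno - prs$donor_resno %in% c(-4, 4)))
  expect_true(attr(hb, "inferred_h"))
})

test_that("isolated polar atoms far apart give no hydrogen bonds", {
  two_far <- tibble::tibble(
    elety = c("N", "O"), resname = c("GLY", "GLY"), resno = c(1, 5),
    element = c("N", "O"), x = c(0, 5), y = 0, z = 0)
  expect_equal(as.integer(count_hbonds(two_far)), 0)
})

test_that("h-bond counts are monotone in the distance cutoff", {
  hx <- ideal_helix(12)
  tight <- as.integer(count_hbonds(hx, dist_cutoff = 3.2))
  default <- as.integer(count_hbonds(hx, dist_cutoff = 3.5))
  loose <- as.integer(count_hbonds(hx, dist_cutoff = 4.0))
  expect_lte(tight, default)
  expect_lte(default, loose)
})

test_that("h-bonds are undefined for coarse-grained beads", {
  st <- suppressMessages(make_dumbbell_structure(
    mt2_sequence(), cluster_map(0), generator_config(seed = 1)))
  expect_error(count_hbonds(st), "coarse-grained")
})

test_that("salt bridges follow the charged-group distance criterion", {
  expect_equal(as.integer(count_salt_bridges(charged_pair(3.0))), 1)
  expect_equal(as.integer(count_salt_bridges(charged_pair(6.0))), 0)
  # monotone in cutoff
  expect_equal(as.integer(count_salt_bridges(charged_pair(4.5),
                                             cutoff = 5)), 1)
})

test_that("idealised cluster geometries reproduce the degree arithmetic", {
  # alpha-type Zn4Cys11: 16 edges over 11 thiolates forces 5 bridging
  g_a <- zn_s_graph(cluster_fixture_atoms(
    znmt:::.cluster_templates[["4x11"]]))
  expect_equal(glance(g_a)$n_edges, 16)
  expect_equal(glance(g_a)$n_cys, 11)
  expect_equal(glance(g_a)$n_bridging, 5)
  expect_equal(glance(g_a)$n_components, 1)
  # beta-type Zn3Cys9: 12 edges over 9 thiolates forces 3 bridging
  g_b <- zn_s_graph(cluster_fixture_atoms(
    znmt:::.cluster_templates[["3x9"]]))
  expect_equal(glance(g_b)$n_edges, 12)
  expect_equal(glance(g_b)$n_bridging, 3)
  expect_equal(glance(g_b)$n_components, 1)
})

test_that("the Zn-S graph is invariant under rigid motion", {
  at <- cluster_fixture_atoms(znmt:::.cluster_templates[["3x9"]])
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
  at2 <- at
  at2$x <- xyz[, 1] + 40; at2$y <- xyz[, 2] - 7; at2$z <- xyz[, 3]
  expect_equal(glance(zn_s_graph(at2)), glance(zn_s_graph(at)))
})

test_that("structures without metals give an empty graph", {
  at <- tibble::tibble(elety = "SG", resname = "CYS", resno = 1:3,
                       element = "S", x = c(0, 3, 6), y = 0, z = 0)
  g <- zn_s_graph(at)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$n_components, 0)
})

test_that("timeseries aligns metric values with stored frames", {
  st <- suppressMessages(make_dumbbell_structure(
    mt2_sequence(), cluster_map(4), generator_config(seed = 1)))
  top <- build_topology(st, map = cluster_map(4), z = 5)
  tr <- run_langevin(top, md_schedule(n_steps = 2000, store_stride = 100,
                                      seed = 1))
  ts <- timeseries(tr, "rg")
  expect_equal(nrow(ts), dim(tr$frames)[3])
  expect_equal(ts$time_ps, tr$summary$time_ps)
  expect_true(all(is.finite(ts$value)))
  # constant trajectory gives a constant series
  tr0 <- tr
  for (i in seq_len(dim(tr0$frames)[3])) tr0$frames[, , i] <- tr$frames[, , 1]
  ts0 <- timeseries(tr0, "rg")
  expect_equal(ts0$value, rep(ts0$value[1], nrow(ts0)))
})

test_that("Rg tracks the projection CCS along an unfolding pull", {
  st <- suppressMessages(make_dumbbell_structure(
    mt2_sequence(), cluster_map(0), generator_config(seed = 1)))
  top <- build_topology(st, map = cluster_map(0), z = 5)
  sm <- suppressWarnings(smd_pull(
    top, bias = bias_spec("steered", "rg", k = 50),
    schedule = md_schedule(n_steps = 15000, store_stride = 200, seed = 2),
    n_replicates = 1, ccs_every = 5))
  pr <- sm$profiles[[1]]
  ok <- !is.na(pr$ccs)
  expect_gt(stats::cor(pr$cv[ok], pr$ccs[ok]), 0.7)
})
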