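# shared fixtures and independent oracles, built in code at test time

# --- brute-force isotopologue enumeration (oracle for isotope_pattern) ---
# enumerates every isotopologue of a small composition (<= ~10 atoms)
enumerate_pattern <- function(comp, merge_tol = 1e-6) {
  counts <- unclass(comp)
  dist <- list(mass = 0, prob = 1)
  for (el in names(counts)[counts > 0]) {
    iso <- znmt:::.isotopes[[el]]
    k <- length(iso$mass)
    for (a in seq_len(counts[[el]])) {
      m <- as.vector(outer(dist$mass, iso$mass, `+`))
      p <- as.vector(outer(dist$prob, iso$abundance))
      dist <- list(mass = m, prob = p)
    }
  }
  ord <- order(dist$mass)
  m <- dist$mass[ord]; p <- dist$prob[ord]
  grp <- cumsum(c(TRUE, diff(m) > merge_tol))
  pm <- as.numeric(rowsum(p, grp))
  mm <- as.numeric(rowsum(p * m, grp) / pm)
  tibble::tibble(mass = mm, prob = pm)
}

# --- rasterised projection oracle for pa_ccs ---
# shadow area of one orientation on a fine grid
raster_shadow <- function(px, py, r, res = 0.05) {
  xs <- seq(min(px - r) - res, max(px + r) + res, by = res)
  ys <- seq(min(py - r) - res, max(py + r) + res, by = res)
  hit <- matrix(FALSE, length(xs), length(ys))
  for (i in seq_along(px)) {
    sel_x <- which(abs(xs - px[i]) <= r[i])
    sel_y <- which(abs(ys - py[i]) <= r[i])
    if (!length(sel_x) || !length(sel_y)) next
    dx2 <- (xs[sel_x] - px[i])^2
    dy2 <- (ys[sel_y] - py[i])^2
    hit[sel_x, sel_y] <- hit[sel_x, sel_y] |
      (outer(dx2, dy2, `+`) <= r[i]^2)
  }
  sum(hit) * res^2
}

# orientation-averaged grid-projection CCS over fixed or seeded rotations
grid_projection_ccs <- function(coords, radii, n_orientations = 16,
                                seed = 1, res = 0.05, rotations = NULL) {
  if (is.null(rotations)) {
    rotations <- withr::with_seed(seed, replicate(
      n_orientations, znmt:::random_rotation(), simplify = FALSE))
  }
  mean(vapply(rotations, function(R) {
    p <- coords %*% t(R)
    raster_shadow(p[, 1], p[, 2], radii, res = res)
  }, numeric(1)))
}

# --- minimal two-bead topology for engine oracle tests ---
toy_topology <- function(sep = 5, mass = 50, charge = c(0, 0)) {
  beads <- tibble::tibble(
    index = 1:2, type = "BEAD", resname = "G", resid = 1:2,
    domain = "alpha", x = c(0, sep), y = 0, z = 0, mass = mass,
    charge = charge, sigma = 0)
  structure(list(
    beads = beads,
    bonds = tibble::tibble(i = integer(0), j = integer(0),
                           r0 = numeric(0), k = numeric(0)),
    angles = tibble::tibble(i = integer(0), j = integer(0),
                            k_idx = integer(0), theta0 = numeric(0),
                            k = numeric(0)),
    contacts = tibble::tibble(i = integer(0), j = integer(0),
                              r0 = numeric(0), eps = numeric(0),
                              set = character(0)),
    znlinks = tibble::tibble(i = integer(0), j = integer(0),
                             r0 = numeric(0), k = numeric(0)),
    params = cg_params(wca_eps = 0), map = cluster_map(0), z = 0,
    coords = as.matrix(beads[, c("x", "y", "z")]),
    types = beads$type, masses = beads$mass), class = "cg_topology")
}

# --- ideal alpha-helix backbone built by internal-coordinate chaining ---
# (NeRF-style placement from bond lengths, angles and phi/psi/omega)
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  ang <- pi - angle
  d <- bond * c(cos(ang), sin(ang) * cos(torsion), sin(ang) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

ideal_helix <- function(n_res = 20, phi = -57, psi = -47) {
  phi <- phi * pi / 180; psi <- psi * pi / 180; omega <- pi
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2 * pi / 180; a_cacn <- 116.2 * pi / 180
  a_cnca <- 121.7 * pi / 180; a_caco <- 120.8 * pi / 180
  atoms <- list()
  # seed residue
  N <- c(0, 0, 0); CA <- c(b_nca, 0, 0)
  C <- place_atom(c(-1, 1, 0), N, CA, b_cac, a_ncac, phi)
  for (i in seq_len(n_res)) {
    O <- place_atom(N, CA, C, b_co, a_caco, psi + pi)
    atoms[[length(atoms) + 1]] <- tibble::tibble(
      elety = c("N", "CA", "C", "O"), resname = "ALA", resno = i,
      element = c("N", "C", "C", "O"),
      x = c(N[1], CA[1], C[1], O[1]), y = c(N[2], CA[2], C[2], O[2]),
      z = c(N[3], CA[3], C[3], O[3]))
    if (i == n_res) break
    N2 <- place_atom(N, CA, C, b_cn, a_cacn, psi)
    CA2 <- place_atom(CA, C, N2, b_nca, a_cnca, omega)
    C2 <- place_atom(C, N2, CA2, b_cac, a_ncac, phi)
    N <- N2; CA <- CA2; C <- C2
  }
  dplyr::bind_rows(atoms)
}

# simple two-residue charged pair at a set distance (salt-bridge fixture)
charged_pair <- function(dist) {
  tibble::tibble(
    elety = c("NZ", "OD1"), resname = c("LYS", "ASP"), resno = c(1, 2),
    element = c("N", "O"), x = c(0, dist), y = 0, z = 0)
}

# idealised metal cluster geometry realising a given edge template:
# metals on a ring with 4.4 A sides so bridging S at edge midpoints sit
# 2.2 A from both owners; terminal S 2.3 A along +z/-z (never closer than
# ~4.4 A to any other metal)
cluster_fixture <- function(template) {
  n_m <- length(template)
  if (n_m > 1) {
    ring_r <- 4.4 / (2 * sin(pi / n_m))
    ang <- 2 * pi * (seq_len(n_m) - 1) / n_m
    mx <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
  } else {
    mx <- matrix(0, 1, 3)
  }
  cys_ids <- sort(unique(unlist(template)))
  sx <- matrix(NA_real_, length(cys_ids), 3)
  term_used <- integer(n_m)
  term_dirs <- list(c(0, 0, 2.3), c(0, 0, -2.3))
  for (ci in seq_along(cys_ids)) {
    id <- cys_ids[ci]
    owners <- which(vapply(template, function(t) id %in% t, logical(1)))
    if (length(owners) == 2) {
      # alternate a small z offset so two bridges of one pair never coincide
      sx[ci, ] <- colMeans(mx[owners, , drop = FALSE]) +
        c(0, 0, 0.3 * (-1)^ci)
    } else {
      m <- owners[1]
      term_used[m] <- term_used[m] + 1L
      stopifnot(term_used[m] <= 2)
      sx[ci, ] <- mx[m, ] + term_dirs[[term_used[m]]]
    }
  }
  list(metal_xyz = mx, s_xyz = sx, cys_ids = cys_ids)
}

# cluster fixture as a bio3d-free atom table (ZN + CYS SG records)
cluster_fixture_atoms <- function(template) {
  fx <- cluster_fixture(template)
  dplyr::bind_rows(
    tibble::tibble(elety = "ZN", resname = "ZN",
                   resno = 1000 + seq_len(nrow(fx$metal_xyz)),
                   element = "Zn", x = fx$metal_xyz[, 1],
                   y = fx$metal_xyz[, 2], z = fx$metal_xyz[, 3]),
    tibble::tibble(elety = "SG", resname = "CYS", resno = fx$cys_ids,
                   element = "S", x = fx$s_xyz[, 1], y = fx$s_xyz[, 2],
                   z = fx$s_xyz[, 3]))
}
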