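#' Default coarse-grained force-field parameters
#'
#' One-bead-per-residue Go-like gas-phase model: harmonic bonds and angles
#' at native geometry, 12-10 native contacts, WCA excluded volume, in-vacuo
#' Coulomb between charged beads, and harmonic Zn-S cross-links mirroring
#' the cluster map.
#'
#' @param bond_k Harmonic bond constant (kcal/mol/A^2).
#' @param angle_k Harmonic angle constant (kcal/mol/rad^2).
#' @param contact_eps Native-contact well depth (kcal/mol).
#' @param contact_cutoff Native-contact distance cutoff (A).
#' @param zn_s_k Zn-S spring constant (kcal/mol/A^2).
#' @param zn_s_r0 Zn-S rest length (A).
#' @param wca_eps Excluded-volume strength (kcal/mol).
#' @param wca_sigma_bead,wca_sigma_zn WCA diameters (A).
#' @param dielectric Relative permittivity (1 = vacuum).
#' @param charge_mode `"peripheral_basic"` places unit charges on the most
#'   peripheral basic residues; `"uniform"` smears the total charge over
#'   all protein beads.
#' @return Named list of parameters.
#' @export
cg_params <- function(bond_k = 100, angle_k = 5, contact_eps = 1,
                      contact_cutoff = 8, zn_s_k = 50, zn_s_r0 = 2.3,
                      wca_eps = 1, wca_sigma_bead = 4.0,
                      wca_sigma_zn = 2.5, dielectric = 1.0,
                      charge_mode = c("peripheral_basic", "uniform")) {
  list(bond_k = bond_k, angle_k = angle_k, contact_eps = contact_eps,
       contact_cutoff = contact_cutoff, zn_s_k = zn_s_k, zn_s_r0 = zn_s_r0,
       wca_eps = wca_eps, wca_sigma_bead = wca_sigma_bead,
       wca_sigma_zn = wca_sigma_zn, dielectric = dielectric,
       charge_mode = match.arg(charge_mode))
}

#' Build a coarse-grained topology from a bead structure
#'
#' Bonds connect sequence neighbours at their native distance; angles keep
#' native backbone geometry; native contacts are pairs at least three
#' residues apart within the contact cutoff in the input structure,
#' partitioned into intra-alpha, intra-beta and inter-domain sets; Zn-S
#' harmonic links mirror the cluster map (four per metal). The `z` unit
#' positive charges are placed on the `z` most peripheral basic residues
#' (Lys/Arg, distance from the centre of mass), a documented heuristic;
#' uniform smearing is available via `params$charge_mode`.
#'
#' @param structure A [bead_structure()] (metals must match `map`).
#' @param map The [cluster_map()] used to build the structure.
#' @param z Net charge (number of unit charges placed).
#' @param params A [cg_params()] list.
#' @return A `cg_topology`.
#' @export
build_topology <- function(structure, map = attr(structure, "map"),
                           z = 5, params = cg_params()) {
  if (is.null(map)) map <- cluster_map(0)
  n_zn <- attr(map, "n_zn") %||% 0
  if (sum(structure$type == "ZN") != n_zn) {
    stop("structure has ", sum(structure$type == "ZN"),
         " metal beads but the map expects ", n_zn)
  }
  prot <- structure[structure$type == "BEAD", ]
  n <- nrow(prot)
  coords <- bead_coords(structure)
  dmat <- as.matrix(stats::dist(coords[seq_len(n), , drop = FALSE]))

  bonds <- tibble(
    i = seq_len(n - 1), j = 2:n,
    r0 = dmat[cbind(seq_len(n - 1), 2:n)], k = params$bond_k
  )
  angle_theta <- vapply(seq_len(max(n - 2, 0)), function(a) {
    v1 <- coords[a, ] - coords[a + 1, ]
    v2 <- coords[a + 2, ] - coords[a + 1, ]
    acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1))
  }, numeric(1))
  angles <- tibble(i = seq_len(max(n - 2, 0)), j = seq_len(max(n - 2, 0)) + 1,
                   k_idx = seq_len(max(n - 2, 0)) + 2,
                   theta0 = angle_theta, k = params$angle_k)

  pairs <- which(upper.tri(dmat) & dmat < params$contact_cutoff,
                 arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 3, , drop = FALSE]
  set <- ifelse(
    prot$domain[pairs[, 1]] == prot$domain[pairs[, 2]],
    paste0("intra_", prot$domain[pairs[, 1]]), "inter")
  contacts <- tibble(
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
    r0 = dmat[pairs], eps = params$contact_eps, set = set
  )

  znlinks <- if (n_zn > 0) {
    tibble(i = n + map$metal, j = map$cys,
           r0 = params$zn_s_r0, k = params$zn_s_k)
  } else {
    tibble(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0))
  }

  charge <- rep(0, nrow(structure))
  if (z > 0) {
    if (params$charge_mode == "uniform") {
      charge[seq_len(n)] <- z / n
    } else {
      com <- colMeans(coords[seq_len(n), , drop = FALSE])
      per <- sqrt(rowSums((coords[seq_len(n), , drop = FALSE] -
                             matrix(com, n, 3, byrow = TRUE))^2))
      basic <- which(prot$resname %in% c("K", "R"))
      if (length(basic) < z) basic <- order(per, decreasing = TRUE)
      chosen <- basic[order(per[basic], decreasing = TRUE)][seq_len(z)]
      charge[chosen] <- 1
    }
  }

  beads <- dplyr::mutate(
    structure, charge = charge,
    sigma = ifelse(.data$type == "ZN", params$wca_sigma_zn,
                   params$wca_sigma_bead))
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 contacts = contacts, znlinks = znlinks, params = params,
                 map = map, z = z, coords = coords,
                 types = structure$type, masses = structure$mass),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology> ", sum(x$types == "BEAD"), " beads + ",
      sum(x$types == "ZN"), " metals | ", nrow(x$bonds), " bonds, ",
      nrow(x$contacts), " contacts (",
      sum(x$contacts$set == "inter"), " inter-domain), ",
      nrow(x$znlinks), " Zn-S links | z = ", x$z, "\n", sep = "")
  invisible(x)
}

#' @rdname build_topology
#' @param x A `cg_topology`.
#' @param ... Unused.
#' @export
glance.cg_topology <- function(x, ...) {
  tibble(n_beads = sum(x$types == "BEAD"), n_metals = sum(x$types == "ZN"),
         n_bonds = nrow(x$bonds), n_angles = nrow(x$angles),
         n_contacts = nrow(x$contacts),
         n_contacts_inter = sum(x$contacts$set == "inter"),
         n_znlinks = nrow(x$znlinks), z = x$z)
}

# flatten to the C++ list layout
.engine_topology <- function(top, cv_kind = 1L, cv_potential = NULL) {
  n <- length(top$masses)
  ex <- rbind(
    as.matrix(top$bonds[, c("i", "j")]),
    if (nrow(top$angles)) cbind(top$angles$i, top$angles$k_idx),
    as.matrix(top$contacts[, c("i", "j")]),
    as.matrix(top$znlinks[, c("i", "j")])
  )
  if (is.null(ex)) ex <- matrix(0, 0, 2)
  prot_idx <- which(top$types == "BEAD")
  list(
    mass = top$masses, charge = top$beads$charge, sigma = top$beads$sigma,
    is_protein = as.integer(top$types == "BEAD"),
    bonds = as.matrix(top$bonds[, c("i", "j", "r0", "k")]),
    angles = as.matrix(top$angles[, c("i", "j", "k_idx", "theta0", "k")]),
    contacts = as.matrix(top$contacts[, c("i", "j", "r0", "eps")]),
    znlinks = as.matrix(top$znlinks[, c("i", "j", "r0", "k")]),
    exclusions = ex, wca_eps = top$params$wca_eps,
    dielectric = top$params$dielectric,
    cv_potential = cv_potential %||%
      list(enabled = FALSE, height = 0, centre = 0, halfwidth = 1),
    cv_kind = as.integer(cv_kind),
    e2e_index = c(min(prot_idx), max(prot_idx))
  )
}

#' Write a topology to JSON
#' @param top A `cg_topology`. @param path Output path.
#' @export
write_topology_json <- function(top, path) {
  jsonlite::write_json(
    list(beads = as.data.frame(top$beads), bonds = as.data.frame(top$bonds),
         angles = as.data.frame(top$angles),
         contacts = as.data.frame(top$contacts),
         znlinks = as.data.frame(top$znlinks), params = top$params,
         z = top$z),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
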