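#' Radius of gyration
#'
#' Mass-weighted RMS distance from the centre of mass. For bead
#' structures, metal beads are included only if `include_metals = TRUE`
#' (conformation metrics are conventionally computed over the protein
#' itself).
#'
#' @param x N x 3 coordinate matrix or a `bead_structure`.
#' @param masses Per-site masses; default equal (or the structure's).
#' @param include_metals Include metal beads of a `bead_structure`.
#' @return Rg in A.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1
#' @export
radius_of_gyration <- function(x, masses = NULL, include_metals = FALSE) {
  if (inherits(x, "bead_structure")) {
    if (!include_metals) x <- x[x$type != "ZN", ]
    masses <- masses %||% x$mass
    x <- bead_coords(x)
  }
  x <- as.matrix(x)
  masses <- masses %||% rep(1, nrow(x))
  if (sum(masses) <= 0) stop("zero total mass")
  com <- colSums(x * masses) / sum(masses)
  sq <- rowSums((x - matrix(com, nrow(x), 3, byrow = TRUE))^2)
  sqrt(sum(masses * sq) / sum(masses))
}

#' End-to-end distance (first to last protein bead / CA)
#' @param x A `bead_structure` or coordinate matrix.
#' @return Distance in A.
#' @export
end_to_end <- function(x) {
  if (inherits(x, "bead_structure")) x <- bead_coords(x[x$type != "ZN", ])
  x <- as.matrix(x)
  sqrt(sum((x[nrow(x), ] - x[1, ])^2))
}

# normalise input to an atom tibble: elety, resid(name), resno, element, x, y, z
.atom_table <- function(structure) {
  if (inherits(structure, "pdb")) {
    a <- structure$atom
    tibble(elety = a$elety, resname = a$resid, resno = a$resno,
           element = ifelse(is.na(a$elesy) | a$elesy == "",
                            substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
           x = a$x, y = a$y, z = a$z)
  } else if (is.data.frame(structure) &&
             all(c("elety", "resno", "x", "y", "z") %in% names(structure))) {
    as_tibble(structure)
  } else {
    stop("need an all-atom structure (bio3d pdb object or atom table)")
  }
}

#' Count hydrogen bonds in an all-atom structure
#'
#' Geometric criterion: donor-acceptor distance at most `dist_cutoff` and,
#' when a donor hydrogen is present or can be inferred, donor-H-acceptor
#' angle at least `angle_cutoff`. Donors are backbone amide N (except
#' proline) and polar side-chain N/O; acceptors are carbonyl and
#' side-chain O. Structures without hydrogens get backbone amide H
#' positions inferred from heavy-atom geometry; side-chain donors are then
#' tested on distance only (flagged via the `inferred_h` attribute).
#' Hydrogen bonds are undefined for coarse-grained bead structures and
#' raise an error.
#'
#' @param structure A bio3d `pdb` object or an atom tibble.
#' @param dist_cutoff Donor-acceptor heavy-atom cutoff (A).
#' @param angle_cutoff Minimum donor-H-acceptor angle (degrees).
#' @return Integer count of unique donor-acceptor pairs; attribute
#'   `pairs` holds the pair table.
#' @export
count_hbonds <- function(structure, dist_cutoff = 3.5, angle_cutoff = 120) {
  if (inherits(structure, "bead_structure")) {
    stop("hydrogen bonds are undefined for coarse-grained bead input")
  }
  at <- .atom_table(structure)
  at$elety <- trimws(at$elety)
  donors_bb <- at[at$elety == "N" & at$resname != "PRO", ]
  sc_names <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2", "ND2", "NE1",
                "OG", "OG1", "OH", "SG")
  donors_sc <- at[at$elety %in% sc_names & at$elety != "SG", ]
  acceptors <- at[grepl("^O", at$elety), ]
  if (nrow(acceptors) == 0 ||
      (nrow(donors_bb) + nrow(donors_sc)) == 0) {
    return(structure(0L, pairs = tibble()))
  }
  has_h <- any(grepl("^H", at$elety))
  # inferred backbone amide H: opposite the bisector of C(i-1)-N and CA-N
  hpos <- NULL
  if (!has_h && nrow(donors_bb) > 0) {
    hpos <- infer_amide_h(at, donors_bb)
  }
  pairs <- list()
  count <- 0L
  test_donor <- function(dxyz, hxyz) {
    dd <- sqrt(rowSums((acceptors[, c("x", "y", "z")] -
                          matrix(dxyz, nrow(acceptors), 3,
                                 byrow = TRUE))^2))
    ok <- dd <= dist_cutoff & dd > 0.1
    if (!is.null(hxyz) && any(ok)) {
      for (j in which(ok)) {
        axyz <- as.numeric(acceptors[j, c("x", "y", "z")])
        v1 <- dxyz - hxyz
        v2 <- axyz - hxyz
        ang <- acos(pmin(pmax(sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))),
                              -1), 1)) * 180 / pi
        if (ang < angle_cutoff) ok[j] <- FALSE
      }
    }
    ok
  }
  for (i in seq_len(nrow(donors_bb))) {
    dxyz <- as.numeric(donors_bb[i, c("x", "y", "z")])
    hxyz <- if (!is.null(hpos)) hpos[i, ] else NULL
    if (!is.null(hxyz) && anyNA(hxyz)) hxyz <- NULL
    ok <- test_donor(dxyz, hxyz)
    # exclude the donor's own residue
    ok <- ok & !(acceptors$resno == donors_bb$resno[i])
    count <- count + sum(ok)
    if (any(ok)) {
      pairs[[length(pairs) + 1L]] <- tibble(
        donor_resno = donors_bb$resno[i], donor = donors_bb$elety[i],
        acceptor_resno = acceptors$resno[ok],
        acceptor = acceptors$elety[ok])
    }
  }
  for (i in seq_len(nrow(donors_sc))) {
    dxyz <- as.numeric(donors_sc[i, c("x", "y", "z")])
    ok <- test_donor(dxyz, NULL)
    ok <- ok & !(acceptors$resno == donors_sc$resno[i])
    count <- count + sum(ok)
    if (any(ok)) {
      pairs[[length(pairs) + 1L]] <- tibble(
        donor_resno = donors_sc$resno[i], donor = donors_sc$elety[i],
        acceptor_resno = acceptors$resno[ok],
        acceptor = acceptors$elety[ok])
    }
  }
  structure(as.integer(count),
            pairs = if (length(pairs)) dplyr::bind_rows(pairs) else tibble(),
            inferred_h = !has_h)
}

infer_amide_h <- function(at, donors_bb) {
  t(vapply(seq_len(nrow(donors_bb)), function(i) {
    resno <- donors_bb$resno[i]
    nxyz <- as.numeric(donors_bb[i, c("x", "y", "z")])
    ca <- at[at$elety == "CA" & at$resno == resno, ]
    cprev <- at[at$elety == "C" & at$resno == resno - 1, ]
    if (nrow(ca) == 0 || nrow(cprev) == 0) return(c(NA_real_, NA, NA))
    v1 <- as.numeric(ca[1, c("x", "y", "z")]) - nxyz
    v2 <- as.numeric(cprev[1, c("x", "y", "z")]) - nxyz
    v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
    h <- -(v1 + v2)
    nxyz + 1.01 * h / sqrt(sum(h^2))
  }, numeric(3)))
}

#' Count salt bridges in an all-atom structure
#'
#' A salt bridge is counted when the minimum distance between side-chain
#' charged-group heavy atoms of a basic residue (Lys NZ; Arg NE/NH1/NH2;
#' His ND1/NE2) and an acidic residue (Asp OD1/OD2; Glu OE1/OE2; C-terminal
#' OXT) is at most `cutoff`.
#'
#' @param structure A bio3d `pdb` object or atom tibble.
#' @param cutoff Distance cutoff (A), default 4.0.
#' @return Integer count; attribute `pairs` lists residue pairs.
#' @export
count_salt_bridges <- function(structure, cutoff = 4.0) {
  at <- .atom_table(structure)
  at$elety <- trimws(at$elety)
  basic <- at[(at$resname == "LYS" & at$elety == "NZ") |
                (at$resname == "ARG" &
                   at$elety %in% c("NE", "NH1", "NH2")) |
                (at$resname == "HIS" & at$elety %in% c("ND1", "NE2")), ]
  acidic <- at[(at$resname == "ASP" & at$elety %in% c("OD1", "OD2")) |
                 (at$resname == "GLU" & at$elety %in% c("OE1", "OE2")) |
                 at$elety == "OXT", ]
  if (nrow(basic) == 0 || nrow(acidic) == 0) {
    return(structure(0L, pairs = tibble()))
  }
  pairs <- tidyr::expand_grid(b = seq_len(nrow(basic)),
                              a = seq_len(nrow(acidic)))
  pairs$d <- sqrt((basic$x[pairs$b] - acidic$x[pairs$a])^2 +
                    (basic$y[pairs$b] - acidic$y[pairs$a])^2 +
                    (basic$z[pairs$b] - acidic$z[pairs$a])^2)
  pairs$b_res <- basic$resno[pairs$b]
  pairs$a_res <- acidic$resno[pairs$a]
  hits <- pairs |>
    dplyr::group_by(.data$b_res, .data$a_res) |>
    dplyr::summarise(dmin = min(.data$d), .groups = "drop") |>
    dplyr::filter(.data$dmin <= cutoff)
  structure(nrow(hits), pairs = hits)
}

#' Zinc-thiolate connectivity graph
#'
#' Builds the bipartite metal-thiolate graph from coordinates: an edge is
#' drawn when a Zn-S (or Zn-Cys bead) distance is at most `cutoff`.
#' Cysteines of degree 2 are bridging, degree 1 terminal; metals with more
#' than 4 thiolates are flagged. Connected components correspond to the
#' metal-thiolate clusters (the alpha- and beta-domains of
#' metallothionein).
#'
#' @param structure A `bead_structure` (Zn beads + Cys residue beads) or a
#'   bio3d `pdb` object (ZN atoms + Cys SG atoms).
#' @param cutoff Edge distance cutoff (A); default 3.0 for bead input,
#'   2.6 for atomic.
#' @return A `cluster_graph`: list with `edges` (tibble: `metal`, `cys`,
#'   `dist`), `cys_degree`, `metal_degree`, `n_components`, `components`
#'   (membership per metal), `flagged_metals`.
#' @export
zn_s_graph <- function(structure, cutoff = NULL) {
  if (inherits(structure, "bead_structure")) {
    cutoff <- cutoff %||% 3.0
    zn <- structure[structure$type == "ZN", ]
    s <- structure[structure$type == "BEAD" & structure$resname == "C", ]
    zn_xyz <- bead_coords(zn); s_xyz <- bead_coords(s)
    zn_id <- zn$index; s_id <- s$resid
  } else {
    cutoff <- cutoff %||% 2.6
    at <- .atom_table(structure)
    at$elety <- trimws(at$elety)
    zn <- at[at$elety == "ZN" | at$resname == "ZN", ]
    s <- at[at$elety == "SG", ]
    zn_xyz <- as.matrix(zn[, c("x", "y", "z")])
    s_xyz <- as.matrix(s[, c("x", "y", "z")])
    zn_id <- zn$resno; s_id <- s$resno
  }
  if (nrow(zn_xyz) == 0) {
    return(structure(list(
      edges = tibble(metal = integer(0), cys = integer(0),
                     dist = numeric(0)),
      cys_degree = integer(0), metal_degree = integer(0),
      n_components = 0L, components = integer(0),
      flagged_metals = integer(0)), class = "cluster_graph"))
  }
  d <- sqrt(outer(rowSums(zn_xyz^2), rowSums(s_xyz^2), `+`) -
              2 * zn_xyz %*% t(s_xyz))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  edges <- tibble(metal = zn_id[hit[, 1]], cys = s_id[hit[, 2]],
                  dist = d[hit])
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("m", edges$metal),
               to = paste0("c", edges$cys)),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("m", zn_id),
                                   paste0("c", unique(s_id))))
  )
  comp <- igraph::components(g)
  metal_memb <- comp$membership[paste0("m", zn_id)]
  # components holding at least one metal = clusters
  n_comp <- length(unique(metal_memb))
  metal_degree <- stats::setNames(
    vapply(zn_id, function(m) sum(edges$metal == m), integer(1)),
    zn_id)
  cys_degree <- table(edges$cys)
  structure(list(
    edges = edges,
    cys_degree = cys_degree,
    metal_degree = metal_degree,
    n_components = n_comp,
    components = metal_memb,
    flagged_metals = zn_id[metal_degree > 4]
  ), class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("<cluster_graph> ", nrow(x$edges), " Zn-S edges, ",
      length(x$metal_degree), " metals, ", length(x$cys_degree),
      " thiolates, ", x$n_components, " cluster(s); ",
      sum(x$cys_degree == 2), " bridging / ", sum(x$cys_degree == 1),
      " terminal Cys\n", sep = "")
  invisible(x)
}

#' @rdname zn_s_graph
#' @param x A `cluster_graph`.
#' @param ... Unused.
#' @export
glance.cluster_graph <- function(x, ...) {
  tibble(n_edges = nrow(x$edges), n_metals = length(x$metal_degree),
         n_cys = length(x$cys_degree),
         n_bridging = sum(x$cys_degree == 2),
         n_terminal = sum(x$cys_degree == 1),
         n_components = x$n_components,
         n_flagged = length(x$flagged_metals))
}

#' Per-frame metric time series over a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param metric A function taking an N x 3 coordinate matrix (e.g.
#'   [radius_of_gyration()]), or one of `"rg"`, `"end_to_end"`.
#' @param ... Passed to the metric.
#' @return Tibble (`frame`, `time_ps`, `value`).
#' @export
timeseries <- function(traj, metric = "rg", ...) {
  fn <- if (is.function(metric)) {
    metric
  } else {
    switch(metric,
           rg = function(m, ...) radius_of_gyration(
             m[traj$types == "BEAD", , drop = FALSE],
             masses = traj$masses[traj$types == "BEAD"], ...),
           end_to_end = function(m, ...) end_to_end(
             m[traj$types == "BEAD", , drop = FALSE]),
           stop("unknown metric: ", metric))
  }
  n <- dim(traj$frames)[3]
  tibble(
    frame = seq_len(n), time_ps = traj$summary$time_ps,
    value = vapply(seq_len(n), function(i) fn(traj$frames[, , i], ...),
                   numeric(1))
  )
}
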