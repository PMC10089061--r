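# average residue masses (Da) for CG beads
.residue_mass <- vapply(.residue_formula, function(f) {
  sum(f * .average_mass[names(f)])
}, numeric(1))

#' Construct a bead structure
#'
#' One bead per residue plus one bead per metal, held as a tibble with
#' coordinates in A. Metal beads have type `"ZN"`, residue beads `"BEAD"`.
#'
#' @param df Tibble with columns `index`, `type`, `resname`, `resid`,
#'   `domain`, `x`, `y`, `z`, `mass`.
#' @param map The `cluster_map` the structure was built from (or NULL).
#' @param seq The `protein_sequence` (or NULL).
#' @return A `bead_structure`.
#' @export
bead_structure <- function(df, map = NULL, seq = NULL) {
  need <- c("index", "type", "resname", "resid", "domain", "x", "y", "z",
            "mass")
  stopifnot(all(need %in% names(df)))
  structure(as_tibble(df), class = c("bead_structure", class(as_tibble(df))),
            map = map, seq = seq)
}

#' @export
print.bead_structure <- function(x, ...) {
  cat("<bead_structure> ", sum(x$type == "BEAD"), " residue beads, ",
      sum(x$type == "ZN"), " metal beads, Rg = ",
      format(radius_of_gyration(x), digits = 4), " A\n", sep = "")
  NextMethod()
}

bead_coords <- function(x) unname(as.matrix(x[, c("x", "y", "z")]))

#' Generate a dumbbell two-domain bead structure
#'
#' Builds the one-bead-per-residue gas-phase starting structure:
#' a self-avoiding chain grown inside two compact spherical domains
#' (beta N-terminal, alpha C-terminal) joined by a short linker -- the
#' dumbbell architecture of metallothionein -- with one Zn bead per metal
#' of the cluster map placed amid its four thiolate beads. A damped
#' relaxation settles Zn-S distances at the 2.3 A rest length while
#' keeping chain connectivity and excluded volume. Deterministic under
#' `cfg$seed`; if the chain cannot be grown without clashes the seed is
#' perturbed and the attempt reported.
#'
#' @param seq A `protein_sequence`.
#' @param map A [cluster_map()]; use `cluster_map(0)` for apo.
#' @param cfg A [generator_config()] (only `seed` is used).
#' @param domain_sep Distance between domain centres (A).
#' @return A [bead_structure()].
#' @examples
#' st <- make_dumbbell_structure(mt2_sequence(), cluster_map(7),
#'                               generator_config(seed = 1))
#' @export
make_dumbbell_structure <- function(seq, map, cfg = generator_config(),
                                    domain_sep = 22) {
  aa <- strsplit(seq$residues, "")[[1]]
  n <- length(aa)
  if (nrow(map) > 0 && max(map$cys) > n) {
    stop("cluster map indexes residues beyond the sequence")
  }
  cys <- cys_positions(seq)
  # domain split: between the 9th and 10th Cys when available, else midpoint
  split_at <- if (length(cys) >= 10) {
    floor((cys[9] + cys[10]) / 2)
  } else {
    floor(n / 2)
  }
  n_beta <- split_at
  bond <- 3.8
  min_sep <- 3.4
  vol_per_bead <- 120  # A^3, protein-like packing
  r_beta <- (3 * vol_per_bead * n_beta / (4 * pi))^(1 / 3)
  r_alpha <- (3 * vol_per_bead * (n - n_beta) / (4 * pi))^(1 / 3)
  centres <- rbind(c(-domain_sep / 2, 0, 0), c(domain_sep / 2, 0, 0))

  seed <- cfg$seed
  coords <- NULL
  for (attempt in 1:20) {
    coords <- withr::with_seed(seed, try(
      grow_chain(n, n_beta, centres, c(r_beta, r_alpha), bond, min_sep),
      silent = TRUE))
    if (!inherits(coords, "try-error")) break
    message("chain growth clashed (attempt ", attempt,
            "); retrying with perturbed seed")
    seed <- seed + 7919L
  }
  if (inherits(coords, "try-error")) stop("could not grow a clash-free chain")

  n_zn <- attr(map, "n_zn") %||% 0
  metal_xyz <- NULL
  if (n_zn > 0) {
    metal_xyz <- t(vapply(seq_len(n_zn), function(m) {
      colMeans(coords[map$cys[map$metal == m], , drop = FALSE])
    }, numeric(3)))
    relaxed <- relax_structure(coords, metal_xyz, map, bond, min_sep,
                               centres, c(r_beta, r_alpha), n_beta)
    coords <- relaxed$coords
    metal_xyz <- relaxed$metals
  }

  domain <- c(rep("beta", n_beta), rep("alpha", n - n_beta))
  df <- tibble(
    index = seq_len(n), type = "BEAD", resname = aa, resid = seq_len(n),
    domain = domain, x = coords[, 1], y = coords[, 2], z = coords[, 3],
    mass = unname(.residue_mass[aa])
  )
  if (n_zn > 0) {
    dom_m <- attr(map, "domain_of_metal")
    df <- dplyr::bind_rows(df, tibble(
      index = n + seq_len(n_zn), type = "ZN", resname = "ZN",
      resid = n + seq_len(n_zn), domain = dom_m,
      x = metal_xyz[, 1], y = metal_xyz[, 2], z = metal_xyz[, 3],
      mass = .average_mass[["Zn"]]
    ))
  }
  bead_structure(df, map = map, seq = seq)
}

# self-avoiding random walk inside two spheres
grow_chain <- function(n, n_beta, centres, radii, bond, min_sep) {
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- centres[1, ] + c(0, radii[1] * 0.6, 0)
  for (i in 2:n) {
    dom <- if (i <= n_beta) 1 else 2
    placed <- FALSE
    for (try_i in 1:200) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      # bias the step toward the domain centre to stay compact
      to_centre <- centres[dom, ] - coords[i - 1, ]
      nc <- sqrt(sum(to_centre^2))
      if (nc > 1e-9) u <- u + 0.8 * to_centre / max(nc, radii[dom])
      u <- u / sqrt(sum(u^2))
      cand <- coords[i - 1, ] + bond * u
      if (sqrt(sum((cand - centres[dom, ])^2)) > radii[dom] + bond) next
      if (i > 2) {
        prev <- coords[seq_len(i - 2), , drop = FALSE]
        d2 <- rowSums((prev - matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (min(d2) < min_sep^2) next
      }
      coords[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) stop("stuck")
  }
  coords
}

# damped gradient relaxation: chain bonds, Zn-S springs, soft excluded
# volume and domain confinement
relax_structure <- function(coords, metals, map, bond, min_sep, centres,
                            radii, n_beta, n_iter = 400, step = 0.02) {
  n <- nrow(coords)
  nm <- nrow(metals)
  dom_idx <- c(rep(1, n_beta), rep(2, n - n_beta))
  r0_zns <- 2.3
  for (it in seq_len(n_iter)) {
    g_b <- matrix(0, n, 3)
    g_m <- matrix(0, nm, 3)
    # chain bonds
    dvec <- coords[-1, ] - coords[-n, ]
    dlen <- sqrt(rowSums(dvec^2))
    f <- 2 * (dlen - bond) / pmax(dlen, 1e-9)
    pull <- dvec * f
    g_b[-n, ] <- g_b[-n, ] - pull
    g_b[-1, ] <- g_b[-1, ] + pull
    # Zn-S springs
    for (e in seq_len(nrow(map))) {
      m <- map$metal[e]; c_i <- map$cys[e]
      dv <- metals[m, ] - coords[c_i, ]
      dl <- sqrt(sum(dv^2))
      f <- 4 * (dl - r0_zns) / max(dl, 1e-9)
      g_m[m, ] <- g_m[m, ] + f * dv
      g_b[c_i, ] <- g_b[c_i, ] - f * dv
    }
    # soft excluded volume between non-neighbour beads
    dmat <- as.matrix(stats::dist(coords))
    close <- which(dmat < min_sep & dmat > 0, arr.ind = TRUE)
    close <- close[close[, 1] < close[, 2] &
                     abs(close[, 1] - close[, 2]) > 1, , drop = FALSE]
    for (k in seq_len(nrow(close))) {
      i <- close[k, 1]; j <- close[k, 2]
      dv <- coords[j, ] - coords[i, ]
      dl <- dmat[i, j]
      f <- 2 * (dl - min_sep) / dl
      g_b[i, ] <- g_b[i, ] - f * dv
      g_b[j, ] <- g_b[j, ] + f * dv
    }
    # confinement
    for (d in 1:2) {
      sel <- which(dom_idx == d)
      dv <- coords[sel, , drop = FALSE] -
        matrix(centres[d, ], length(sel), 3, byrow = TRUE)
      dl <- sqrt(rowSums(dv^2))
      out <- dl > radii[d]
      if (any(out)) {
        f <- 2 * (dl[out] - radii[d]) / dl[out]
        g_b[sel[out], ] <- g_b[sel[out], ] + dv[out, , drop = FALSE] * f
      }
    }
    coords <- coords - step * g_b
    metals <- metals - step * g_m
  }
  list(coords = coords, metals = metals)
}

#' Write a bead structure as PDB (metals as HETATM ZN) or XYZ
#'
#' @param st A `bead_structure`.
#' @param path Output path.
#' @export
write_structure_pdb <- function(st, path) {
  is_zn <- st$type == "ZN"
  pdb <- bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(bead_coords(st))),
    type = ifelse(is_zn, "HETATM", "ATOM"),
    resno = st$resid,
    resid = ifelse(is_zn, "ZN", aa1_to_aa3(st$resname)),
    eleno = st$index,
    elety = ifelse(is_zn, "ZN", "CA"),
    chain = ifelse(st$domain == "beta", "B", "A")
  )
  invisible(path)
}

aa1_to_aa3 <- function(x) {
  map <- c(G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL",
           T = "THR", C = "CYS", L = "LEU", I = "ILE", N = "ASN",
           D = "ASP", Q = "GLN", K = "LYS", E = "GLU", M = "MET",
           H = "HIS", F = "PHE", R = "ARG", Y = "TYR", W = "TRP")
  out <- map[x]
  out[is.na(out)] <- x[is.na(out)]
  unname(out)
}

#' @rdname write_structure_pdb
#' @export
write_structure_xyz <- function(st, path) {
  lines <- c(
    nrow(st), "bead structure",
    sprintf("%-4s %12.5f %12.5f %12.5f",
            ifelse(st$type == "ZN", "Zn", "C"), st$x, st$y, st$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ coordinate file
#' @param path Path to an XYZ file.
#' @return Tibble with `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  parts <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  tibble(
    element = vapply(parts, `[[`, character(1), 1),
    x = as.numeric(vapply(parts, `[[`, character(1), 2)),
    y = as.numeric(vapply(parts, `[[`, character(1), 3)),
    z = as.numeric(vapply(parts, `[[`, character(1), 4))
  )
}
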