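# Fixed edge templates for the three cluster stoichiometries that occur in
# the Zn4-7 ladder. Each metal coordinates exactly 4 thiolates; bridging
# cysteines have degree 2. Indices are into the domain's Cys pool.
.cluster_templates <- list(
  "2x6"  = list(c(1, 2, 3, 5), c(3, 4, 5, 6)),
  "3x9"  = list(c(1, 2, 3, 9), c(3, 4, 5, 6), c(6, 7, 8, 9)),
  "4x11" = list(c(1, 2, 3, 5), c(3, 4, 5, 7), c(6, 7, 8, 9), c(6, 9, 10, 11))
)

.domain_occupancy <- list(
  # alpha = c(n metals, n Cys used), beta likewise
  "0" = list(alpha = c(0, 0),  beta = c(0, 0)),
  "4" = list(alpha = c(2, 6),  beta = c(2, 6)),
  "5" = list(alpha = c(3, 9),  beta = c(2, 6)),
  "6" = list(alpha = c(4, 11), beta = c(2, 6)),
  "7" = list(alpha = c(4, 11), beta = c(3, 9))
)

#' Zinc-thiolate cluster connectivity for Zn4-7 metallothionein-2
#'
#' Builds the bipartite metal-thiolate map for a given Zn loading, following
#' the domain-wise filling order established for Zn4-7MT2: Zn4 holds a
#' Zn2Cys6 cluster in each domain; the fifth and sixth Zn2+ bind to the
#' alpha-domain (Zn3Cys9, then Zn4Cys11); the seventh completes the
#' beta-domain Zn3Cys9 cluster. The beta-domain pool is the nine N-terminal
#' cysteines and the alpha-domain pool the eleven C-terminal cysteines, as
#' in the known metallothionein fold. Which specific cysteines bridge within
#' a cluster is not experimentally established; the packaged assignment is a
#' fixed, documented placeholder satisfying the degree arithmetic
#' (every metal tetrahedral, bridging Cys of degree 2).
#'
#' @param n_zn Number of bound Zn2+: 4, 5, 6, or 7 (0 gives the apo map
#'   with no edges, used for metal-free structures).
#' @param seq Sequence supplying Cys positions (default [mt2_sequence()]).
#' @return A `cluster_map`: tibble with columns `metal` (index), `cys`
#'   (residue position in `seq`), `domain` ("alpha"/"beta"); attributes
#'   `n_zn` and `domain_of_metal`.
#' @examples
#' cluster_map(7)
#' @export
cluster_map <- function(n_zn, seq = mt2_sequence()) {
  if (!n_zn %in% c(0, 4:7)) {
    stop("n_zn must be 4..7 (or 0 for the apo map), got ", n_zn)
  }
  cys <- cys_positions(seq)
  if (length(cys) < 20 && n_zn > 0) {
    stop("sequence has ", length(cys), " Cys; the packaged maps need 20")
  }
  occ <- .domain_occupancy[[as.character(n_zn)]]
  beta_pool  <- cys[seq_len(min(9, length(cys)))]
  alpha_pool <- cys[setdiff(seq_along(cys), seq_len(9))]

  rows <- list()
  metal_id <- 0L
  domain_of_metal <- character(0)
  for (dom in c("beta", "alpha")) {
    nm <- occ[[dom]][1]
    nc <- occ[[dom]][2]
    if (nm == 0) next
    tmpl <- .cluster_templates[[paste0(nm, "x", nc)]]
    pool <- if (dom == "beta") beta_pool else alpha_pool
    for (m in seq_len(nm)) {
      metal_id <- metal_id + 1L
      domain_of_metal <- c(domain_of_metal, dom)
      rows[[length(rows) + 1L]] <- tibble(
        metal = metal_id, cys = pool[tmpl[[m]]], domain = dom
      )
    }
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(metal = integer(0), cys = integer(0), domain = character(0))
  structure(edges, class = c("cluster_map", class(edges)),
            n_zn = n_zn, domain_of_metal = domain_of_metal)
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map> Zn", attr(x, "n_zn"), ", ", nrow(x), " Zn-S edges\n",
      sep = "")
  NextMethod()
}

#' Summarise a cluster map
#'
#' @param x A `cluster_map`.
#' @param ... Unused.
#' @return One row per domain: metals, distinct Cys, edges, bridging Cys
#'   (degree 2) and terminal Cys (degree 1).
#' @export
tidy.cluster_map <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      n_metal = dplyr::n_distinct(.data$metal),
      n_cys = dplyr::n_distinct(.data$cys),
      n_edges = dplyr::n(),
      n_bridging = sum(table(.data$cys) == 2),
      n_terminal = sum(table(.data$cys) == 1),
      .groups = "drop"
    )
}

#' Write/read a cluster map as JSON
#' @param map A `cluster_map`.
#' @param path Output path.
#' @export
write_cluster_map <- function(map, path) {
  jsonlite::write_json(
    list(n_zn = attr(map, "n_zn"),
         domain_of_metal = attr(map, "domain_of_metal"),
         edges = as.data.frame(map)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as_tibble(x$edges)
  structure(edges, class = c("cluster_map", class(edges)),
            n_zn = x$n_zn, domain_of_metal = x$domain_of_metal)
}
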