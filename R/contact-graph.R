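#' Atomic contact graph (Voronoi + distance rule)
#'
#' Two atoms are in contact when they are Voronoi neighbours in the 3-D
#' tessellation of atom centres (unweighted) AND their distance does not
#' exceed the sum of their radii plus the diameter of a water molecule
#' (2.75 Angstrom by default).  Voronoi adjacency is decided exactly per
#' candidate pair by a half-space feasibility test on the pair's bisector
#' plane, restricted to a generous box around the midpoint; degenerate
#' (zero-area) facets count as adjacent.
#'
#' @param s Structure with radii assigned.
#' @param water_diameter Distance-rule additive term in Angstrom (default 2.75).
#' @param box Half-width (Angstrom) of the bisector-plane search box around
#'   each candidate pair's midpoint (default 200).  The box is axis-aligned
#'   in a deterministic basis of the bisector plane; facets of compact
#'   structures live far inside it, so it only matters as an LP bound.
#' @return A `wet_contact_graph`: list with `nodes` (atom ids), `edges`
#'   (2-column atom-id matrix) and `adj` (adjacency list indexed by node
#'   position).
#' @export
build_contact_graph <- function(s, water_diameter = 2.75, box = 200) {
  stopifnot(inherits(s, "wet_structure"))
  a <- s$atoms
  if (nrow(a) < 2) stop("need at least 2 atoms to build a contact graph")
  if (anyNA(a$radius)) stop("radii not assigned; call assign_radii() first")
  em <- voronoi_contacts_cpp(as.matrix(a[, c("x", "y", "z")]), a$radius,
                             water_diameter, box, 1e-6)
  edges <- cbind(a$atom_id[em[, 1]], a$atom_id[em[, 2]])
  colnames(edges) <- c("a", "b")
  n <- nrow(a)
  adj <- vector("list", n)
  if (nrow(em)) {
    tab <- split(c(em[, 2], em[, 1]), c(em[, 1], em[, 2]))
    adj[as.integer(names(tab))] <- lapply(tab, as.integer)
  }
  adj[vapply(adj, is.null, TRUE)] <- list(integer(0))
  structure(list(nodes = a$atom_id, edges = edges, adj = adj,
                 water_diameter = water_diameter),
            class = "wet_contact_graph")
}

#' @export
print.wet_contact_graph <- function(x, ...) {
  cat(sprintf("<wet_contact_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# multi-source BFS over an adjacency list (node positions, not ids)
bfs_levels <- function(adj, sources, n) {
  lev <- rep(NA_integer_, n)
  lev[sources] <- 0L
  frontier <- sources
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lev[nxt])]
    lev[nxt] <- d
    frontier <- nxt
  }
  lev
}

#' Burial level of every atom
#'
#' The burial level BL of an atom is its graph distance in the contact graph
#' to the nearest exposed atom, an exposed atom being one with SASA above
#' `threshold` (10 Angstrom^2 by default).  Exposed atoms have BL 0; atoms
#' unreachable from any exposed atom (should not occur in real structures)
#' get `NA` and are counted in the `unreachable` attribute.
#'
#' @param g Contact graph from [build_contact_graph()].
#' @param sasa Per-atom SASA from [compute_sasa()] covering all graph nodes.
#' @param threshold Exposure cutoff in Angstrom^2.
#' @return A `wet_burial`: list with `bl` (integer vector named by atom id,
#'   `NA` = unreachable), `exposed` (logical, same names) and `threshold`.
#' @export
burial_levels <- function(g, sasa, threshold = 10) {
  stopifnot(inherits(g, "wet_contact_graph"))
  v <- sasa[as.character(g$nodes)]
  if (anyNA(v)) stop("SASA does not cover all graph nodes")
  exposed <- v > threshold
  if (!any(exposed)) stop("no exposed atoms: empty source set for burial levels")
  lev <- bfs_levels(g$adj, which(exposed), length(g$nodes))
  names(lev) <- g$nodes
  n_unreach <- sum(is.na(lev))
  if (n_unreach > 0) {
    warning(sprintf("%d atom(s) unreachable from the exposed set; BL set to NA",
                    n_unreach))
  }
  structure(list(bl = lev, exposed = setNames(exposed, g$nodes),
                 threshold = threshold, unreachable = n_unreach),
            class = "wet_burial")
}

#' Extract the protein-water-protein tripartite interface
#'
#' Interfacial waters are waters with at least one contact to each of the
#' two chains.  Each side's interface atoms are the chain's atoms contacting
#' either the opposite chain or an interfacial water.  Edges are all
#' contacts among the three node sets.
#'
#' @param g Contact graph of the (pruned) complex.
#' @param s The same structure the graph was built from.
#' @param chain1,chain2 Chain identifiers of the two interacting partners.
#' @return A `wet_interface`: list with `side1`, `side2`, `water` (atom id
#'   vectors), `edges` (2-column matrix of contacts within the interface),
#'   `chain1`, `chain2` and the `structure`.
#' @export
extract_interface <- function(g, s, chain1, chain2) {
  stopifnot(inherits(g, "wet_contact_graph"), inherits(s, "wet_structure"))
  a <- s$atoms
  if (!chain1 %in% a$chain) stop("chain not found: ", chain1)
  if (!chain2 %in% a$chain) stop("chain not found: ", chain2)
  pos <- match(g$nodes, a$atom_id)
  side_of <- rep(0L, length(g$nodes))       # 1, 2 = partner chains; 3 = water
  side_of[a$chain[pos] == chain1 & !a$is_water[pos]] <- 1L
  side_of[a$chain[pos] == chain2 & !a$is_water[pos]] <- 2L
  side_of[a$is_water[pos]] <- 3L

  e <- g$edges
  ei <- match(e[, 1], g$nodes)
  ej <- match(e[, 2], g$nodes)
  si <- side_of[ei]
  sj <- side_of[ej]

  # waters contacting both sides
  touches <- function(w_side, p_side) {
    ids <- c(e[si == 3L & sj == p_side, 1], e[sj == 3L & si == p_side, 2])
    unique(ids)
  }
  w1 <- touches(3L, 1L)
  w2 <- touches(3L, 2L)
  water <- sort(intersect(w1, w2))
  wset <- g$nodes %in% water

  # side atoms: contact the opposite chain or an interfacial water
  pick_side <- function(k, other) {
    direct <- c(e[si == k & sj == other, 1], e[sj == k & si == other, 2])
    via_w <- c(e[si == k & wset[ej], 1], e[sj == k & wset[ei], 2])
    sort(unique(c(direct, via_w)))
  }
  side1 <- pick_side(1L, 2L)
  side2 <- pick_side(2L, 1L)

  iset <- c(side1, side2, water)
  keep <- e[, 1] %in% iset & e[, 2] %in% iset
  structure(list(side1 = side1, side2 = side2, water = water,
                 edges = e[keep, , drop = FALSE],
                 chain1 = chain1, chain2 = chain2, structure = s),
            class = "wet_interface")
}

#' @export
print.wet_interface <- function(x, ...) {
  cat(sprintf(
    "<wet_interface> %s/%s: |I| = %d (%d + %d protein atoms, %d water)\n",
    x$chain1, x$chain2,
    length(x$side1) + length(x$side2) + length(x$water),
    length(x$side1), length(x$side2), length(x$water)))
  invisible(x)
}

#' Interfacial residues of a tripartite interface
#'
#' A residue is interfacial when at least one of its atoms is in the
#' interface (either protein side).
#'
#' @param iface A `wet_interface`.
#' @return data.frame with `chain`, `resno`, `ins`, `resname` and `side`.
#' @export
interface_residues <- function(iface) {
  a <- iface$structure$atoms
  out <- lapply(c(1, 2), function(k) {
    ids <- if (k == 1) iface$side1 else iface$side2
    sub <- a[match(ids, a$atom_id), c("chain", "resno", "ins", "resname")]
    sub <- unique(sub)
    if (nrow(sub)) sub$side <- k
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
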