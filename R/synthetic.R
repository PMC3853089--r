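#' Specification for a synthetic slab dimer
#'
#' Describes a fully determined toy two-chain complex: two parallel slabs of
#' carbon atoms on a cubic lattice (chains A and B), a sealing ring of atoms
#' around the inter-slab gap (split between the chains), and water oxygens
#' placed in the gap's lattice pockets.  Geometry defaults are chosen so
#' that planted waters survive exposure pruning and show the intended
#' burial-depth contrast between "core" (footprint centre) and "rim" (one
#' pocket ring in from the seal) placement.
#'
#' @param nx,ny,nz Atoms per axis in each slab (footprint `nx` x `ny`,
#'   `nz` layers per slab).
#' @param spacing Lattice constant in Angstrom; must exceed twice the
#'   largest radius so atoms never clash.
#' @param gap Distance between the two inner slab layers (Angstrom).
#' @param n_waters Number of gap waters to place.
#' @param core_frac Fraction of waters placed at core pockets (nearest the
#'   footprint centre); the rest go to the rim ring.
#' @param b_base Baseline B factor (Angstrom^2); a small deterministic
#'   spread is added so the reference-set standard deviation is positive.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `wet_slab_spec` list.
#' @export
slab_spec <- function(nx = 10, ny = 10, nz = 3, spacing = 3.5, gap = 5.0,
                      n_waters = 25, core_frac = 16 / 25, b_base = 20,
                      seed = 1) {
  radius_c <- radii_table("bondi")[["C"]]
  if (spacing <= 2 * radius_c)
    stop("spacing must exceed twice the largest atom radius (no clashes)")
  if (nx < 4 || ny < 4 || nz < 2) stop("slab too small: need nx, ny >= 4 and nz >= 2")
  if (n_waters < 0 || core_frac < 0 || core_frac > 1)
    stop("invalid water placement")
  structure(list(nx = nx, ny = ny, nz = nz, spacing = spacing, gap = gap,
                 n_waters = n_waters, core_frac = core_frac,
                 b_base = b_base, seed = seed),
            class = "wet_slab_spec")
}

# pocket grid: positions (i + 0.5, j + 0.5) * spacing for i in 0..nx-2,
# j in 0..ny-2, at the gap mid-plane.  ring depth = distance (in rings)
# from the outermost pocket ring.
pocket_grid <- function(spec) {
  i <- rep(0:(spec$nx - 2), times = spec$ny - 1)
  j <- rep(0:(spec$ny - 2), each = spec$nx - 1)
  depth <- pmin(i, spec$nx - 2 - i, j, spec$ny - 2 - j)
  data.frame(i = i, j = j,
             x = (i + 0.5) * spec$spacing, y = (j + 0.5) * spec$spacing,
             depth = depth)
}

choose_pockets <- function(spec) {
  p <- pocket_grid(spec)
  cx <- (spec$nx - 1) / 2 * spec$spacing
  cy <- (spec$ny - 1) / 2 * spec$spacing
  p$dc <- sqrt((p$x - cx)^2 + (p$y - cy)^2)
  n_core <- round(spec$core_frac * spec$n_waters)
  n_rim <- spec$n_waters - n_core
  ord_core <- p[order(p$dc, p$i, p$j), ]
  core <- head(ord_core[ord_core$depth >= 2, ], n_core)
  # rim = outermost pocket ring, right against the sealing ring: these
  # waters sit one contact away from exposed seal atoms (burial level 1)
  rim_pool <- p[p$depth == 0, ]
  rim_pool <- rim_pool[order(atan2(rim_pool$y - cy, rim_pool$x - cx),
                             rim_pool$i, rim_pool$j), ]
  rim <- head(rim_pool, n_rim)
  if (nrow(core) < n_core || nrow(rim) < n_rim)
    stop("slab footprint too small for the requested water placement")
  core$kind <- if (nrow(core)) "core" else character(0)
  rim$kind <- if (nrow(rim)) "rim" else character(0)
  rbind(core, rim)
}

#' Generate a synthetic slab dimer with planted ground truth
#'
#' Builds the structure described by a [slab_spec()]: chain A (slab below
#' the gap), chain B (slab above), a sealing ring of atoms around the gap
#' mid-plane (assigned half to each chain), and water oxygens in the chosen
#' gap pockets.  Atoms are grouped four per residue with names CA/CB/CG/CD
#' so residue-level operations (superposition on CA, mutation-site CG) are
#' exercisable.  The structure is emitted as PDB text and re-read, so the
#' regular reader is on the code path.
#'
#' @param spec A [slab_spec()].
#' @return List with `structure` (a `wet_structure`), `regions` (quadrant
#'   partition usable with [delta_bstar_profile()]), and `truth`: planted
#'   facts (water table with pocket indices and core/rim kind, per-water
#'   contacted protein atoms, per-residue expected water-contact counts,
#'   per-atom lattice depth, mutation-site suggestion).
#' @export
make_slab_dimer <- function(spec = slab_spec()) {
  stopifnot(inherits(spec, "wet_slab_spec"))
  s <- spec$spacing
  half_gap <- spec$gap / 2

  ij <- expand.grid(i = 0:(spec$nx - 1), j = 0:(spec$ny - 1),
                    l = 1:spec$nz)      # l = 1 is the inner (gap-facing) layer
  mk_slab <- function(chain, sign) {
    data.frame(chain = chain,
               i = ij$i, j = ij$j, l = ij$l,
               x = ij$i * s, y = ij$j * s,
               z = sign * (half_gap + (ij$l - 1) * s),
               kind = "slab", stringsAsFactors = FALSE)
  }
  slab_a <- mk_slab("A", -1)
  slab_b <- mk_slab("B", +1)

  # sealing ring: the boundary ring of the extended pocket grid, at z = 0
  ri <- (-1):(spec$nx - 1)
  rj <- (-1):(spec$ny - 1)
  ring <- expand.grid(i = ri, j = rj)
  on_ring <- ring$i %in% c(-1, spec$nx - 1) | ring$j %in% c(-1, spec$ny - 1)
  ring <- ring[on_ring, , drop = FALSE]
  cy <- (spec$ny - 1) / 2 * s
  wall <- data.frame(chain = ifelse((ring$j + 0.5) * s < cy, "A", "B"),
                     i = ring$i, j = ring$j, l = 0L,
                     x = (ring$i + 0.5) * s, y = (ring$j + 0.5) * s,
                     z = 0,
                     kind = "wall", stringsAsFactors = FALSE)

  prot <- rbind(slab_a, wall[wall$chain == "A", ],
                slab_b, wall[wall$chain == "B", ])
  prot <- prot[order(prot$chain, prot$l, prot$j, prot$i), ]
  # four atoms per residue, numbered per chain; wall and slab atoms never
  # share a residue (the wall group may end in a partial residue), so the
  # planted per-residue contact design stays clean
  atom_names <- c("CA", "CB", "CG", "CD")
  prot_by_chain <- split(prot, prot$chain)
  prot <- do.call(rbind, lapply(prot_by_chain, function(pc) {
    grp <- integer(nrow(pc))
    nxt <- 1L
    for (kind in unique(pc$kind)) {
      idx <- which(pc$kind == kind)
      grp[idx] <- nxt + (seq_along(idx) - 1L) %/% 4L
      nxt <- max(grp[idx]) + 1L
    }
    pc$resno <- grp
    pc$atom <- stats::ave(grp, grp, FUN = seq_along)
    pc$atom <- atom_names[pc$atom]
    pc
  }))
  prot$resname <- "SLB"
  prot$element <- "C"

  pk <- choose_pockets(spec)
  nw <- nrow(pk)
  waters <- data.frame(chain = rep("S", nw), i = pk$i, j = pk$j,
                       l = rep(NA_integer_, nw),
                       x = pk$x, y = pk$y, z = rep(0, nw), kind = pk$kind,
                       resno = 1000 + seq_len(nw),
                       atom = rep("O", nw), resname = rep("HOH", nw),
                       element = rep("O", nw), stringsAsFactors = FALSE)

  all <- rbind(prot, waters)
  n <- nrow(all)
  # deterministic B-factor spread; waters slightly hotter, as in real files
  all$b <- spec$b_base + ((seq_len(n) * 37) %% 11) / 2 +
    ifelse(all$kind %in% c("core", "rim"), 5, 0)
  all$occ <- 1

  tmp <- structure_from_atoms(
    all[, c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "occ", "b")],
    id = "slab-dimer")
  st <- read_structure(paste(write_pdb(tmp), collapse = "\n"),
                       id = "slab-dimer")

  # ---- planted truth -------------------------------------------------------
  a <- st$atoms
  prot_key <- paste(all$chain, all$i, all$j, all$l)
  # per-water contacted SLAB atoms: the 4 surrounding inner-layer atoms of
  # each slab (the distance rule allows nothing farther).  Rim waters also
  # touch sealing-ring atoms, which this table deliberately does not
  # enumerate: truth assertions are scoped to slab atoms.
  contacts <- lapply(seq_len(nrow(pk)), function(k) {
    ii <- pk$i[k] + c(0, 1, 0, 1)
    jj <- pk$j[k] + c(0, 0, 1, 1)
    idx <- c(match(paste("A", ii, jj, 1), prot_key),
             match(paste("B", ii, jj, 1), prot_key))
    a$atom_id[idx]
  })
  names(contacts) <- waters$resno
  # per-residue expected distinct-water contact counts
  res_of <- res_key(a$chain, a$resno, a$ins)
  prof <- table(unlist(lapply(contacts, function(v)
    unique(res_of[match(v, a$atom_id)]))))
  # per-atom expected water-contact counts (distinct waters per atom)
  y_truth <- table(unlist(contacts))

  depth <- pmin(all$i, spec$nx - 1 - all$i, all$j, spec$ny - 1 - all$j)
  lat_depth <- setNames(ifelse(all$kind == "slab", depth, NA), a$atom_id)

  wat_rows <- a[a$is_water, , drop = FALSE]
  water_tab <- data.frame(resno = waters$resno, i = pk$i, j = pk$j,
                          kind = pk$kind,
                          atom_id = wat_rows$atom_id[match(waters$resno,
                                                           wat_rows$resno)])

  regions <- quadrant_regions(st, spec)
  truth <- list(
    spec = spec,
    waters = water_tab,
    water_contacts = contacts,
    residue_water_counts = prof,
    atom_water_counts = y_truth,
    lattice_depth = lat_depth,
    mutation_site = min(region_residues(regions, "A")$resno))
  list(structure = st, regions = regions, truth = truth)
}

# quadrant partition of the slab footprint: residues are assigned by their
# centroid; the same residue numbers exist in both chains only if their
# centroids fall in the same quadrant, so the partition lists chains
# explicitly.
quadrant_regions <- function(st, spec) {
  a <- st$atoms[!st$atoms$is_water, , drop = FALSE]
  cx <- (spec$nx - 1) / 2 * spec$spacing
  cy <- (spec$ny - 1) / 2 * spec$spacing
  cen <- stats::aggregate(a[, c("x", "y")],
                          by = list(chain = a$chain, resno = a$resno), mean)
  reg <- ifelse(cen$x < cx,
                ifelse(cen$y < cy, "A", "C"),
                ifelse(cen$y < cy, "B", "D"))
  out <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(r) {
    sel <- cen[reg == r, ]
    split(sel$resno, sel$chain)
  })
  out[vapply(out, length, integer(1)) > 0]
}

#' Perturbed "mutant" copy of a structure
#'
#' Applies, deterministically for a given seed: Gaussian coordinate jitter,
#' removal of listed waters, and per-region B-factor shifts.  The copy is
#' re-emitted as PDB text and re-read, as a real mutant structure would be.
#'
#' @param s Structure to perturb (typically `make_slab_dimer()$structure`).
#' @param jitter_sd Coordinate jitter standard deviation (Angstrom) applied
#'   to every coordinate of every atom.
#' @param drop_waters Water residue numbers to remove (e.g. from
#'   `truth$waters$resno`).
#' @param bshift Named numeric vector, region name -> B-factor shift
#'   (Angstrom^2), applied to the atoms of that region's residues; needs
#'   `regions`.
#' @param regions Region partition (required when `bshift` is given).
#' @param seed Integer seed.
#' @return A `wet_structure`.
#' @export
make_mutant_copy <- function(s, jitter_sd = 0, drop_waters = NULL,
                             bshift = NULL, regions = NULL, seed = 1) {
  stopifnot(inherits(s, "wet_structure"))
  a <- s$atoms
  if (!is.null(drop_waters)) {
    wat_res <- a$resno[a$is_water]
    unknown <- setdiff(drop_waters, wat_res)
    if (length(unknown))
      stop("unknown water residue number(s): ", paste(unknown, collapse = ", "))
    keep <- !(a$is_water & a$resno %in% drop_waters)
    a <- a[keep, , drop = FALSE]
  }
  if (jitter_sd > 0) {
    n <- nrow(a)
    jit <- with_seed(seed, matrix(rnorm(3 * n, sd = jitter_sd), ncol = 3))
    a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
  }
  if (!is.null(bshift)) {
    if (is.null(regions))
      stop("bshift needs the `regions` partition")
    bad <- setdiff(names(bshift), names(regions))
    if (length(bad)) stop("unknown region(s) in bshift: ",
                          paste(bad, collapse = ", "))
    for (rn in names(bshift)) {
      rr <- region_residues(regions, rn)
      hit <- paste(a$chain, a$resno) %in% paste(rr$chain, rr$resno) & !a$is_water
      a$b[hit] <- a$b[hit] + bshift[[rn]]
    }
  }
  tmp <- new_structure(a, id = paste0(s$id, "-mut"))
  read_structure(paste(write_pdb(tmp), collapse = "\n"),
                 id = paste0(s$id, "-mut"))
}

#' Synthetic water-contact count vectors
#'
#' Fixture generator for [gini()]: `"equal"` gives identical counts (Gini
#' exactly 0), `"single-spike"` one positive count among zeros (Gini exactly
#' (n-1)/n), `"geometric"` i.i.d. geometric counts (a right-skewed
#' distribution with an analytically unremarkable Gini, for oracle
#' comparison).
#'
#' @param n Number of counts (>= 2).
#' @param pattern `"equal"`, `"single-spike"` or `"geometric"`.
#' @param seed Integer seed (used by `"geometric"` only).
#' @return A `wet_counts` with planted `pattern` attribute.
#' @export
make_counts <- function(n, pattern = c("equal", "single-spike", "geometric"),
                        seed = 1) {
  if (n < 2) stop("need n >= 2 counts")
  pattern <- match.arg(pattern)
  y <- switch(pattern,
    equal = rep(2L, n),
    `single-spike` = c(rep(0L, n - 1), 5L),
    geometric = {
      v <- with_seed(seed, rgeom(n, prob = 0.3))
      if (sum(v) == 0) v[n] <- 1L
      as.integer(v)
    })
  structure(list(y = setNames(y, seq_len(n)), n = n, pattern = pattern),
            class = "wet_counts")
}
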