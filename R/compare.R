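#' Water reappearance between two superposed interfaces
#'
#' A wild-type interfacial water "reappears" in the mutant when the two
#' oxygens are mutual nearest neighbours and closer than `cutoff` (1.0
#' Angstrom by default) after superposition.  Mutual-nearest pairs at or
#' beyond the cutoff are reported separately with their distance; waters
#' with no mutual-nearest partner are reported unmatched.
#'
#' @param wt_iface,mut_iface `wet_interface` objects of the two complexes.
#' @param transform Optional [pair_and_superimpose()] result mapping the
#'   mutant into the wild-type frame; `NULL` compares coordinates as-is.
#' @param cutoff Reappearance distance cutoff in Angstrom.
#' @return A `wet_watercorr`: `matched` (data.frame `wt_id`, `mut_id`,
#'   `distance`; all below cutoff), `mutual_far` (mutual nearest but at or
#'   beyond cutoff), `unmatched_wt`, `unmatched_mut` (atom ids) and
#'   `cutoff`.
#' @export
water_reappearance <- function(wt_iface, mut_iface, transform = NULL,
                               cutoff = 1.0) {
  stopifnot(inherits(wt_iface, "wet_interface"),
            inherits(mut_iface, "wet_interface"))
  wt_ids <- wt_iface$water
  mut_ids <- mut_iface$water
  empty <- function(extra_wt = wt_ids, extra_mut = mut_ids) {
    structure(list(matched = data.frame(wt_id = integer(0), mut_id = integer(0),
                                        distance = numeric(0)),
                   mutual_far = data.frame(wt_id = integer(0), mut_id = integer(0),
                                           distance = numeric(0)),
                   unmatched_wt = extra_wt, unmatched_mut = extra_mut,
                   cutoff = cutoff),
              class = "wet_watercorr")
  }
  if (length(wt_ids) == 0 || length(mut_ids) == 0) return(empty())
  W <- coords(wt_iface$structure, wt_ids)
  M <- coords(mut_iface$structure, mut_ids)
  if (!is.null(transform)) M <- apply_transform(M, transform)
  d2 <- outer(rowSums(W^2), rowSums(M^2), `+`) - 2 * W %*% t(M)
  d2[d2 < 0] <- 0
  nn_wt <- apply(d2, 1, which.min)   # nearest mutant water of each wt water
  nn_mut <- apply(d2, 2, which.min)  # nearest wt water of each mutant water
  mutual <- which(nn_mut[nn_wt] == seq_along(wt_ids))
  # recompute matched distances directly (the outer-product form cancels
  # catastrophically for near-identical coordinates)
  dist <- sqrt(rowSums((W[mutual, , drop = FALSE] -
                        M[nn_wt[mutual], , drop = FALSE])^2))
  pairs <- data.frame(wt_id = wt_ids[mutual], mut_id = mut_ids[nn_wt[mutual]],
                      distance = dist)
  pairs <- pairs[order(pairs$distance), , drop = FALSE]
  rownames(pairs) <- NULL
  ok <- pairs$distance < cutoff
  out <- empty(extra_wt = setdiff(wt_ids, pairs$wt_id),
               extra_mut = setdiff(mut_ids, pairs$mut_id))
  out$matched <- pairs[ok, , drop = FALSE]
  out$mutual_far <- pairs[!ok, , drop = FALSE]
  out
}

#' @export
print.wet_watercorr <- function(x, ...) {
  cat(sprintf("<wet_watercorr> %d reappearing (< %.2f A), %d mutual but far, %d/%d unmatched wt/mut\n",
              nrow(x$matched), x$cutoff, nrow(x$mutual_far),
              length(x$unmatched_wt), length(x$unmatched_mut)))
  invisible(x)
}

# Cgamma atoms of the mutation-site residues; sites: numeric resno vector
# (every chain) or data.frame(chain, resno)
mutation_site_cg <- function(s, sites) {
  a <- s$atoms
  if (is.data.frame(sites)) {
    pick <- paste(a$chain, a$resno) %in% paste(sites$chain, sites$resno)
  } else {
    pick <- a$resno %in% sites & !a$is_water
  }
  cg <- a[pick & a$atom == "CG", , drop = FALSE]
  if (nrow(cg) == 0)
    stop("no C-gamma (CG) atom found for the mutation site(s)")
  cg
}

#' Normalized B factors (B*)
#'
#' Z-scores the crystallographic B factor of every atom against a reference
#' set of non-water atoms at least `exclusion_radius` (15 Angstrom by
#' default) away from every mutation-site C-gamma: `B* = (B - mean) / sd`,
#' with the population standard deviation of the reference set.  Distances
#' use the minimum over all mutation-site C-gamma atoms (a homodimer has one
#' per chain).
#'
#' @param s Structure whose B factors are to be normalized.
#' @param mutation_sites Residue number(s) (applied to every chain) or a
#'   data.frame with `chain` and `resno`.
#' @param exclusion_radius Radius (Angstrom) around the mutation-site
#'   C-gamma atoms excluded from the reference set.
#' @return A `wet_bstar`: `bstar` (numeric vector named by atom id, all
#'   atoms including waters), `ref_mean`, `ref_sd`, `ref_ids`, `site_xyz`
#'   (coordinates of the mutation-site C-gamma atoms) and
#'   `dist_to_site` (per-atom minimum distance to a site C-gamma).
#' @export
normalize_bfactors <- function(s, mutation_sites, exclusion_radius = 15) {
  stopifnot(inherits(s, "wet_structure"))
  cg <- mutation_site_cg(s, mutation_sites)
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  site_xyz <- as.matrix(cg[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(site_xyz^2), `+`) - 2 * xyz %*% t(site_xyz)
  d2[d2 < 0] <- 0
  dmin <- sqrt(apply(d2, 1, min))
  ref <- !a$is_water & dmin >= exclusion_radius
  if (sum(ref) < 10)
    stop(sprintf("reference set too small (%d atoms; need >= 10)", sum(ref)))
  mu <- mean(a$b[ref])
  sigma <- sqrt(mean((a$b[ref] - mu)^2))   # population SD
  if (sigma == 0) stop("reference B factors have zero standard deviation")
  structure(list(bstar = setNames((a$b - mu) / sigma, a$atom_id),
                 ref_mean = mu, ref_sd = sigma,
                 ref_ids = a$atom_id[ref],
                 site_xyz = site_xyz,
                 dist_to_site = setNames(dmin, a$atom_id)),
            class = "wet_bstar")
}

# ---------------------------------------------------------------------------
# region partition
# ---------------------------------------------------------------------------

#' Read a region-partition config
#'
#' The partition maps named interface regions to per-chain residue lists.
#' Accepted input: a JSON file/string of the form
#' `{"A": {"A": [10, 11], "B": [10, 11]}, "B": {...}}` (region name ->
#' chain -> residue numbers) or an equivalent R list.
#'
#' @param x Path to a JSON file, a JSON string, or a list.
#' @return Named list: region -> (chain -> integer residue numbers).
#' @export
read_region_partition <- function(x) {
  if (is.character(x)) {
    x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("region partition must be a named list: region -> chain -> residues")
  lapply(x, function(ch) lapply(ch, as.integer))
}

#' Residues of one region as a data.frame
#'
#' @param partition Partition from [read_region_partition()].
#' @param region Region name.
#' @return data.frame with `chain` and `resno`.
#' @export
region_residues <- function(partition, region) {
  if (!region %in% names(partition)) stop("unknown region: ", region)
  ch <- partition[[region]]
  do.call(rbind, lapply(names(ch), function(c1)
    data.frame(chain = c1, resno = as.integer(ch[[c1]]))))
}

# region of each residue key; residues not covered go to `rest_region`
# (created on demand); rest_region = NULL makes uncovered residues an error
region_of_residues <- function(res, partition, rest_region = "D") {
  keys <- paste(res$chain, res$resno)
  reg <- rep(NA_character_, length(keys))
  for (rn in names(partition)) {
    rr <- region_residues(partition, rn)
    reg[keys %in% paste(rr$chain, rr$resno)] <- rn
  }
  if (anyNA(reg)) {
    if (is.null(rest_region)) {
      stop("residue(s) not covered by the region partition: ",
           paste(unique(keys[is.na(reg)]), collapse = ", "))
    }
    reg[is.na(reg)] <- rest_region
  }
  reg
}

# assign each interfacial water to a region: majority vote of the regions of
# its contacting interfacial residues; ties broken by the number of atom
# contacts into each candidate region, then alphabetically
water_regions <- function(iface, partition, rest_region = "D") {
  a <- iface$structure$atoms
  e <- iface$edges
  w1 <- e[, 1] %in% iface$water
  w2 <- e[, 2] %in% iface$water
  pw <- rbind(cbind(water = e[w1 & !w2, 1], atom = e[w1 & !w2, 2]),
              cbind(water = e[w2 & !w1, 2], atom = e[w2 & !w1, 1]))
  pos <- match(pw[, "atom"], a$atom_id)
  res <- data.frame(chain = a$chain[pos], resno = a$resno[pos])
  reg <- region_of_residues(res, partition, rest_region)
  rkey <- res_key(a$chain[pos], a$resno[pos], a$ins[pos])
  vapply(iface$water, function(w) {
    sel <- pw[, "water"] == w
    if (!any(sel)) return(rest_region %||% NA_character_)
    # one vote per distinct contacted residue
    votes <- tapply(reg[sel], rkey[sel], `[`, 1)
    tab <- sort(table(unlist(votes)), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      natm <- vapply(top, function(r) sum(reg[sel] == r), numeric(1))
      top <- top[natm == max(natm)]
    }
    sort(top)[1]
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized B-factor change profiled by region and burial level
#'
#' Computes, for a superposed wild-type/mutant pair: (a) per reappearing
#' water, the change in normalized B factor and the distance to the nearest
#' mutation-site C-gamma; (b) per interface region and burial level, the
#' mean change in normalized B factor over paired non-water interfacial
#' atoms.  Burial levels are those of the wild-type complex.
#'
#' @param wt_iface,mut_iface Interfaces of the two complexes.
#' @param wt_bstar,mut_bstar [normalize_bfactors()] results for the two
#'   structures.
#' @param corr [water_reappearance()] result for the pair.
#' @param partition Region partition (see [read_region_partition()]).
#' @param bl Burial map of the wild-type complex.
#' @param rest_region Name of the catch-all region for interfacial residues
#'   not listed in the partition (default `"D"`); `NULL` makes uncovered
#'   residues an error.
#' @return List with `waters` (data.frame `wt_id`, `mut_id`, `region`,
#'   `dist_to_site`, `dbstar`) and `atoms` (data.frame `region`, `bl`, `n`,
#'   `mean_dbstar`).
#' @export
delta_bstar_profile <- function(wt_iface, mut_iface, wt_bstar, mut_bstar,
                                corr, partition, bl, rest_region = "D") {
  stopifnot(inherits(corr, "wet_watercorr"), inherits(bl, "wet_burial"))
  aw <- wt_iface$structure$atoms
  am <- mut_iface$structure$atoms

  # (a) reappearing waters
  wreg <- water_regions(wt_iface, partition, rest_region)
  m <- corr$matched
  waters <- data.frame(
    wt_id = m$wt_id, mut_id = m$mut_id,
    region = unname(wreg[match(m$wt_id, wt_iface$water)]),
    dist_to_site = unname(wt_bstar$dist_to_site[as.character(m$wt_id)]),
    dbstar = unname(mut_bstar$bstar[as.character(m$mut_id)] -
                    wt_bstar$bstar[as.character(m$wt_id)]))

  # (b) paired non-water interfacial atoms by region x burial level
  prot <- c(wt_iface$side1, wt_iface$side2)
  pos_w <- match(prot, aw$atom_id)
  key_w <- atom_key(aw$chain[pos_w], aw$resno[pos_w], aw$ins[pos_w], aw$atom[pos_w])
  key_m <- atom_key(am$chain, am$resno, am$ins, am$atom)
  idx_m <- match(key_w, key_m)
  ok <- !is.na(idx_m)
  res <- data.frame(chain = aw$chain[pos_w][ok], resno = aw$resno[pos_w][ok])
  reg <- region_of_residues(res, partition, rest_region)
  blv <- bl$bl[as.character(prot[ok])]
  db <- unname(mut_bstar$bstar[as.character(am$atom_id[idx_m[ok]])] -
               wt_bstar$bstar[as.character(prot[ok])])
  keep <- !is.na(blv)
  agg <- stats::aggregate(db[keep],
                          by = list(region = reg[keep], bl = blv[keep]),
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  atoms <- data.frame(region = agg$region, bl = agg$bl,
                      n = as.integer(agg$x[, "n"]),
                      mean_dbstar = agg$x[, "mean"])
  atoms <- atoms[order(atoms$region, atoms$bl), ]
  rownames(atoms) <- NULL
  list(waters = waters, atoms = atoms)
}
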