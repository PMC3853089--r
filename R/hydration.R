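#' Wetness of an interface
#'
#' Fraction of interface atoms that are water oxygens, |I_W| / |I|, where I
#' is the full tripartite node set (water oxygens included).
#'
#' @param iface A `wet_interface`.
#' @return Fraction in \[0, 1\].
#' @export
wetness <- function(iface) {
  stopifnot(inherits(iface, "wet_interface"))
  n <- length(iface$side1) + length(iface$side2) + length(iface$water)
  if (n == 0) stop("empty interface")
  length(iface$water) / n
}

#' Relative water burial level (rWBL)
#'
#' Mean burial level of the interfacial water oxygens divided by the mean
#' burial level of all interface atoms (waters included in the denominator).
#' rWBL > 1 means water is buried deeper than the interface average, the
#' signature of a wet-core interface.
#'
#' @param iface A `wet_interface`.
#' @param bl Burial map from [burial_levels()] of the same complex.
#' @return Dimensionless ratio.
#' @export
rwbl <- function(iface, bl) {
  stopifnot(inherits(iface, "wet_interface"), inherits(bl, "wet_burial"))
  if (length(iface$water) == 0) stop("rWBL undefined: no interfacial water")
  all_ids <- c(iface$side1, iface$side2, iface$water)
  blw <- bl$bl[as.character(iface$water)]
  bla <- bl$bl[as.character(all_ids)]
  nw <- sum(is.na(blw)) + sum(is.na(bla))
  if (nw > 0) {
    warning(sprintf("excluding %d unreachable atom(s) from rWBL averages", nw))
    blw <- blw[!is.na(blw)]
    bla <- bla[!is.na(bla)]
  }
  if (length(blw) == 0) stop("rWBL undefined: no water with finite burial level")
  denom <- mean(bla)
  if (denom == 0) stop("rWBL undefined: mean interface burial level is 0")
  mean(blw) / denom
}

#' Water-contact counts of interfacial protein atoms
#'
#' For every non-water interface atom j, y_j is the number of distinct
#' interfacial water molecules it contacts (distinct waters, not edges).
#' These counts are the input of [gini()].
#'
#' @param iface A `wet_interface`.
#' @return A `wet_counts`: list with `y` (integer vector named by atom id)
#'   and `n` (number of non-water interface atoms).
#' @export
water_contact_counts <- function(iface) {
  stopifnot(inherits(iface, "wet_interface"))
  prot <- c(iface$side1, iface$side2)
  if (length(prot) + length(iface$water) == 0) stop("empty interface")
  y <- setNames(integer(length(prot)), prot)
  e <- iface$edges
  if (nrow(e)) {
    w1 <- e[, 1] %in% iface$water
    w2 <- e[, 2] %in% iface$water
    pw <- rbind(cbind(atom = e[w2 & !w1, 1], water = e[w2 & !w1, 2]),
                cbind(atom = e[w1 & !w2, 2], water = e[w1 & !w2, 1]))
    if (nrow(pw)) {
      pw <- unique(pw)
      tab <- table(factor(as.character(pw[, "atom"]), levels = names(y)))
      y[] <- as.integer(tab)
    }
  }
  structure(list(y = y, n = length(prot)), class = "wet_counts")
}

#' Gini coefficient of the water-contact distribution
#'
#' Unevenness of how interfacial water is shared among the non-water
#' interface atoms, via the Lorenz curve of the sorted (non-decreasing)
#' contact counts: the area between the Lorenz curve and the line of
#' equality divided by the area under the line of equality.  For the
#' piecewise-linear Lorenz curve this equals
#' `2 * sum(i * y_i) / (n * sum(y)) - (n + 1) / n`.
#'
#' @param counts A `wet_counts` from [water_contact_counts()], or a bare
#'   non-negative numeric vector of counts.
#' @return Value in \[0, 1\].
#' @export
gini <- function(counts) {
  y <- if (inherits(counts, "wet_counts")) as.numeric(counts$y) else as.numeric(counts)
  n <- length(y)
  if (n < 2) stop("gini needs at least 2 counts")
  if (any(y < 0)) stop("counts must be non-negative")
  tot <- sum(y)
  if (tot == 0) stop("gini undefined: all water-contact counts are zero")
  y <- sort(y)
  2 * sum(seq_len(n) * y) / (n * tot) - (n + 1) / n
}

#' Per-residue hydration profile
#'
#' For every interfacial residue, the number of distinct interfacial waters
#' contacting at least one of its atoms.
#'
#' @param iface A `wet_interface`.
#' @return data.frame with `chain`, `resno`, `ins`, `resname`, `side` and
#'   `n_water`.
#' @export
residue_hydration_profile <- function(iface) {
  stopifnot(inherits(iface, "wet_interface"))
  res <- interface_residues(iface)
  if (nrow(res) == 0) stop("empty interface")
  a <- iface$structure$atoms
  e <- iface$edges
  w1 <- e[, 1] %in% iface$water
  w2 <- e[, 2] %in% iface$water
  pw <- rbind(cbind(atom = e[w2 & !w1, 1], water = e[w2 & !w1, 2]),
              cbind(atom = e[w1 & !w2, 2], water = e[w1 & !w2, 1]))
  rk_atom <- res_key(a$chain, a$resno, a$ins)[match(pw[, "atom"], a$atom_id)]
  res$key <- res_key(res$chain, res$resno, res$ins)
  cnt <- vapply(res$key, function(k) {
    length(unique(pw[rk_atom == k, "water"]))
  }, integer(1))
  res$n_water <- unname(cnt)
  res$key <- NULL
  res
}

#' Interface area: half the SASA buried upon binding
#'
#' dSASA = (SASA(chain1 alone) + SASA(chain2 alone) - SASA(complex)) / 2,
#' computed on protein atoms only (waters excluded throughout, the standard
#' interface-size definition).
#'
#' @param s Structure with radii assigned (may still contain waters; they
#'   are ignored here).
#' @param chain1,chain2 Chain identifiers.
#' @param probe,n_points SASA parameters, see [compute_sasa()].
#' @return Area in Angstrom^2.
#' @export
delta_sasa <- function(s, chain1, chain2, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "wet_structure"))
  for (ch in c(chain1, chain2)) {
    if (!ch %in% s$atoms$chain[!s$atoms$is_water]) stop("chain not found: ", ch)
  }
  s1 <- subset_structure(s, chains = chain1, keep_water = FALSE)
  s2 <- subset_structure(s, chains = chain2, keep_water = FALSE)
  s12 <- subset_structure(s, chains = c(chain1, chain2), keep_water = FALSE)
  (sum(compute_sasa(s1, probe, n_points)) +
   sum(compute_sasa(s2, probe, n_points)) -
   sum(compute_sasa(s12, probe, n_points))) / 2
}

#' Full interface hydration analysis of a complex
#'
#' Runs the whole pipeline on one structure: assign radii, prune exposed
#' waters, build the contact graph, compute burial levels, extract the
#' tripartite interface, and summarize its hydration.
#'
#' @param s Structure from [read_structure()] (radii need not be assigned).
#' @param chain1,chain2 The two interacting chains.
#' @param radii Radii table, see [radii_table()].
#' @param probe,n_points SASA parameters.
#' @param sasa_threshold Exposure cutoff (Angstrom^2) for both water pruning
#'   and burial levels.
#' @param water_diameter Contact-rule additive distance (Angstrom).
#' @param with_delta_sasa Also compute [delta_sasa()] (three extra SASA
#'   passes)?
#' @return A `wet_hydration` list: the pruned `structure`, `sasa`, `graph`,
#'   `burial`, `interface`, and `summary` (n_water, n_atoms, wetness, rwbl,
#'   gini, mean_bl_water, mean_bl_all, delta_sasa).
#' @export
interface_hydration <- function(s, chain1, chain2, radii = "bondi",
                                probe = 1.4, n_points = 960,
                                sasa_threshold = 10, water_diameter = 2.75,
                                with_delta_sasa = TRUE) {
  s <- assign_radii(s, radii)
  s <- prune_exposed_waters(s, sasa_threshold, probe, n_points)
  sasa <- compute_sasa(s, probe, n_points)
  g <- build_contact_graph(s, water_diameter)
  bl <- burial_levels(g, sasa, sasa_threshold)
  iface <- extract_interface(g, s, chain1, chain2)
  all_ids <- c(iface$side1, iface$side2, iface$water)
  n_atoms <- length(all_ids)
  n_water <- length(iface$water)
  blw <- bl$bl[as.character(iface$water)]
  bla <- bl$bl[as.character(all_ids)]
  cnt <- if (n_atoms > n_water && n_water > 0) water_contact_counts(iface) else NULL
  smry <- list(
    id = s$id,
    chain1 = chain1, chain2 = chain2,
    radii_table = s$radii_table,
    n_water = n_water,
    n_atoms = n_atoms,
    wetness = if (n_atoms > 0) n_water / n_atoms else NA_real_,
    mean_bl_water = if (n_water > 0) mean(blw, na.rm = TRUE) else NA_real_,
    mean_bl_all = if (n_atoms > 0) mean(bla, na.rm = TRUE) else NA_real_,
    rwbl = if (n_water > 0 && n_atoms > 0 && mean(bla, na.rm = TRUE) > 0)
             mean(blw, na.rm = TRUE) / mean(bla, na.rm = TRUE) else NA_real_,
    gini = if (!is.null(cnt) && sum(cnt$y) > 0 && cnt$n >= 2) gini(cnt) else NA_real_,
    delta_sasa = if (with_delta_sasa)
      delta_sasa(s, chain1, chain2, probe, n_points) else NA_real_,
    prune_iterations = attr(s, "prune_iterations"))
  structure(list(structure = s, sasa = sasa, graph = g, burial = bl,
                 interface = iface, summary = smry),
            class = "wet_hydration")
}

#' @export
print.wet_hydration <- function(x, ...) {
  m <- x$summary
  cat(sprintf("<wet_hydration> %s chains %s/%s (radii: %s)\n",
              ifelse(is.na(m$id), "unnamed", m$id), m$chain1, m$chain2,
              m$radii_table))
  cat(sprintf("  waters %d | interface atoms %d | wetness %.3f\n",
              m$n_water, m$n_atoms, m$wetness))
  cat(sprintf("  mean BL water %.2f | mean BL interface %.2f | rWBL %.3f\n",
              m$mean_bl_water, m$mean_bl_all, m$rwbl))
  cat(sprintf("  gini %.3f | dSASA %.1f A^2\n", m$gini, m$delta_sasa))
  invisible(x)
}
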