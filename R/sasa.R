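#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley style estimate: quasi-uniform test points on each atom's
#' probe-expanded sphere, a point counting as accessible when outside every
#' other atom's expanded sphere.  The point set is a deterministic
#' golden-section spiral, so results are exactly reproducible for a given
#' `n_points`.
#'
#' @param s Structure with radii assigned (see [assign_radii()]).
#' @param probe Probe radius in Angstrom (water probe, default 1.4).
#' @param n_points Test points per atom (default 960; >= 100).
#' @param subset Optional atom ids to evaluate (all atoms still occlude).
#' @return A `wet_sasa` numeric vector (Angstrom^2) named by atom id, with
#'   `probe` and `n_points` attributes.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960, subset = NULL) {
  stopifnot(inherits(s, "wet_structure"))
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 100) stop("n_points must be at least 100")
  a <- s$atoms
  if (anyNA(a$radius)) stop("radii not assigned; call assign_radii() first")
  idx <- if (is.null(subset)) seq_len(nrow(a)) else match(subset, a$atom_id)
  if (anyNA(idx)) stop("unknown atom id(s) in subset")
  v <- sasa_cpp(as.matrix(a[, c("x", "y", "z")]), a$radius, probe,
                as.integer(n_points), as.integer(idx))
  structure(setNames(v, a$atom_id[idx]), probe = probe, n_points = n_points,
            class = "wet_sasa")
}

#' Iteratively remove bulk-exposed water
#'
#' A water with SASA above `sasa_threshold` is treated as bulk solvent and
#' removed; removal can expose deeper waters, so the procedure repeats until
#' no water exceeds the threshold.  Retained waters are treated as part of
#' the complex (they occlude in every SASA pass).  Non-water atoms are never
#' removed.
#'
#' @param s Structure with radii assigned.
#' @param sasa_threshold Exposure cutoff in Angstrom^2 (default 10).
#' @param probe,n_points SASA parameters, see [compute_sasa()].
#' @param max_iter Safety cap on the number of sweeps.
#' @return The pruned structure, with attributes `prune_iterations` and
#'   `removed_waters` (atom ids of removed water oxygens).
#' @export
prune_exposed_waters <- function(s, sasa_threshold = 10, probe = 1.4,
                                 n_points = 960, max_iter = 100) {
  stopifnot(inherits(s, "wet_structure"))
  if (sasa_threshold <= 0) stop("sasa_threshold must be positive")
  removed <- integer(0)
  iter <- 0L
  wat_ids <- s$atoms$atom_id[s$atoms$is_water]
  sasa_w <- if (length(wat_ids)) compute_sasa(s, probe, n_points, subset = wat_ids)
            else numeric(0)
  repeat {
    drop <- wat_ids[sasa_w > sasa_threshold]
    if (length(drop) == 0 || iter >= max_iter) break
    iter <- iter + 1L
    removed <- c(removed, drop)
    a_old <- s$atoms
    dropped <- a_old[a_old$atom_id %in% drop, , drop = FALSE]
    s <- subset_structure(s, atom_ids = setdiff(a_old$atom_id, drop))
    wat_ids <- setdiff(wat_ids, drop)
    if (!length(wat_ids)) { sasa_w <- numeric(0); break }
    # only waters whose expanded sphere overlapped a removed water can change
    a <- s$atoms
    wi <- match(wat_ids, a$atom_id)
    affected <- rep(FALSE, length(wat_ids))
    for (k in seq_len(nrow(dropped))) {
      lim <- a$radius[wi] + dropped$radius[k] + 2 * probe
      d2 <- (a$x[wi] - dropped$x[k])^2 + (a$y[wi] - dropped$y[k])^2 +
            (a$z[wi] - dropped$z[k])^2
      affected <- affected | d2 < lim^2
    }
    sasa_w <- sasa_w[as.character(wat_ids)]
    if (any(affected)) {
      upd <- compute_sasa(s, probe, n_points, subset = wat_ids[affected])
      sasa_w[as.character(wat_ids[affected])] <- upd
    }
  }
  if (iter >= max_iter) warning("prune_exposed_waters: max_iter reached")
  attr(s, "prune_iterations") <- iter
  attr(s, "removed_waters") <- removed
  s
}
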