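#' Kabsch least-squares rotation
#'
#' Optimal rigid transform (proper rotation + translation) mapping point set
#' `Q` onto `P` in the least-squares sense.  The transform acts on row
#' vectors: `Q %*% rotation + translation`.
#'
#' @param P,Q k x 3 matrices of paired coordinates (k >= 3).
#' @return List with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (over the fitted points).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("P and Q must be k x 3 matrices with equal k")
  if (nrow(P) < 3) stop("need at least 3 paired atoms for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)                       # 3x3
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cp - as.numeric(cq %*% R)
  fit <- sweep(Q %*% R, 2, t, `+`)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fit - P)^2))))
}

apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% transform$rotation, 2, transform$translation, `+`)
}

#' Apply a superposition to a structure
#'
#' @param s A `wet_structure`.
#' @param transform A [kabsch()] / [pair_and_superimpose()] result.
#' @return The structure with transformed coordinates.
#' @export
transform_structure <- function(s, transform) {
  xyz <- apply_transform(coords(s), transform)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# residue table of a structure's protein atoms, with optional chain mapping
residue_table <- function(s, chain_map = NULL) {
  a <- s$atoms[!s$atoms$is_water, , drop = FALSE]
  if (!is.null(chain_map)) {
    keep <- a$chain %in% names(chain_map)
    a <- a[keep, , drop = FALSE]
    a$chain <- unname(chain_map[a$chain])
  }
  a
}

#' Pair residues and superimpose two structures
#'
#' Residues are paired by chain, residue number and insertion code (residue
#' names may differ, so point substitutions pair up).  A Kabsch fit is
#' computed over the paired atoms selected by `selection` (default alpha
#' carbons); per-residue RMSDs are then computed over all heavy atoms shared
#' by each residue pair, after applying the single global transform.
#'
#' @param wt,mut Structures to compare; `mut` is mapped onto `wt`.
#' @param selection Atom name(s) used for the fit (default `"CA"`).
#' @param chain_map Optional named character vector mapping `mut` chain ids
#'   to `wt` chain ids (e.g. `c(B = "A")` to superpose subunit B of a
#'   homodimer onto subunit A).  Default: identity on shared chains.
#' @param strict Error if some residues cannot be paired (default); with
#'   `FALSE`, unpaired residues are dropped with a warning.
#' @param trim_cycles Optional cycles of outlier rejection (pairs beyond
#'   mean + 2 sd of the fit distances are dropped and the fit repeated);
#'   0 (default) reproduces the plain one-pass fit.
#' @return A `wet_superposition`: `rotation`, `translation` (mapping `mut`
#'   into the `wt` frame), `global_rmsd` (over the fitted selection),
#'   `pairing` (residue pairs) and `per_residue_rmsd` (data.frame with
#'   `chain`, `resno`, `ins`, `resname_wt`, `resname_mut`, `n_atoms`,
#'   `rmsd`).
#' @export
pair_and_superimpose <- function(wt, mut, selection = "CA", chain_map = NULL,
                                 strict = TRUE, trim_cycles = 0) {
  stopifnot(inherits(wt, "wet_structure"), inherits(mut, "wet_structure"))
  aw <- residue_table(wt)
  am <- residue_table(mut, chain_map)
  kw <- unique(res_key(aw$chain, aw$resno, aw$ins))
  km <- unique(res_key(am$chain, am$resno, am$ins))
  unpaired <- c(setdiff(kw, km), setdiff(km, kw))
  if (length(unpaired)) {
    msg <- paste0("unpaired residue(s): ",
                  paste(head(unpaired, 10), collapse = ", "),
                  if (length(unpaired) > 10) sprintf(" ... (%d total)", length(unpaired)))
    if (strict) stop(msg) else warning(msg)
  }
  shared <- intersect(kw, km)
  if (!length(shared)) stop("no residues in common")

  akw <- atom_key(aw$chain, aw$resno, aw$ins, aw$atom)
  akm <- atom_key(am$chain, am$resno, am$ins, am$atom)
  rkw <- res_key(aw$chain, aw$resno, aw$ins)
  rkm <- res_key(am$chain, am$resno, am$ins)

  sel_w <- aw[aw$atom %in% selection & rkw %in% shared, , drop = FALSE]
  sel_keys <- intersect(atom_key(sel_w$chain, sel_w$resno, sel_w$ins, sel_w$atom), akm)
  if (length(sel_keys) < 3)
    stop("fewer than 3 paired atoms in the fit selection")
  Pw <- as.matrix(aw[match(sel_keys, akw), c("x", "y", "z")])
  Qm <- as.matrix(am[match(sel_keys, akm), c("x", "y", "z")])
  fit <- kabsch(Pw, Qm)
  if (trim_cycles > 0) {
    for (cyc in seq_len(trim_cycles)) {
      d <- sqrt(rowSums((apply_transform(Qm, fit) - Pw)^2))
      keep <- d <= mean(d) + 2 * stats::sd(d)
      if (all(keep) || sum(keep) < 3) break
      Pw <- Pw[keep, , drop = FALSE]
      Qm <- Qm[keep, , drop = FALSE]
      fit <- kabsch(Pw, Qm)
    }
  }

  # per-residue RMSD over shared heavy atoms, single global transform
  xyz_m <- apply_transform(am[, c("x", "y", "z")], fit)
  per_res <- lapply(shared, function(k) {
    iw <- which(rkw == k)
    shared_atoms <- intersect(akw[iw], akm)
    if (!length(shared_atoms)) return(NULL)
    pi <- match(shared_atoms, akw)
    qi <- match(shared_atoms, akm)
    dx <- as.matrix(aw[pi, c("x", "y", "z")]) - xyz_m[qi, , drop = FALSE]
    data.frame(chain = aw$chain[pi[1]], resno = aw$resno[pi[1]],
               ins = aw$ins[pi[1]], resname_wt = aw$resname[pi[1]],
               resname_mut = am$resname[qi[1]],
               n_atoms = length(shared_atoms),
               rmsd = sqrt(mean(rowSums(dx^2))),
               stringsAsFactors = FALSE)
  })
  per_res <- do.call(rbind, per_res)
  per_res <- per_res[order(per_res$chain, per_res$resno, per_res$ins), ]
  rownames(per_res) <- NULL

  structure(list(rotation = fit$rotation, translation = fit$translation,
                 global_rmsd = fit$rmsd, selection = selection,
                 chain_map = chain_map, pairing = shared,
                 per_residue_rmsd = per_res),
            class = "wet_superposition")
}

#' @export
print.wet_superposition <- function(x, ...) {
  cat(sprintf("<wet_superposition> %d residues paired; fit on %s: RMSD %.3f A\n",
              length(x$pairing), paste(x$selection, collapse = ","),
              x$global_rmsd))
  invisible(x)
}

#' Per-frame RMSD against a reference structure
#'
#' For each frame, atoms are matched to the reference by chain, residue
#' number, insertion code and atom name over the requested selection; the
#' frame is (optionally) superposed on the reference over that selection and
#' the RMSD reported.
#'
#' @param frames List of structures (e.g. from [read_models()]).
#' @param reference Reference structure.
#' @param atom_names Atom-name filter (default `"CA"`); `NULL` = all heavy
#'   atoms.
#' @param residues Optional data.frame with `chain` and `resno` restricting
#'   the selection (e.g. one interface region, see
#'   [region_residues()]).
#' @param superpose Least-squares superpose each frame on the selection
#'   before measuring (default `TRUE`); `FALSE` measures in the frames' own
#'   coordinates.
#' @return data.frame with `frame` and `rmsd` (Angstrom).
#' @export
rmsd_over_frames <- function(frames, reference, atom_names = "CA",
                             residues = NULL, superpose = TRUE) {
  stopifnot(inherits(reference, "wet_structure"))
  if (inherits(frames, "wet_structure")) frames <- list(frames)
  ar <- reference$atoms[!reference$atoms$is_water, , drop = FALSE]
  if (!is.null(atom_names)) ar <- ar[ar$atom %in% atom_names, , drop = FALSE]
  if (!is.null(residues)) {
    want <- paste(residues$chain, residues$resno)
    ar <- ar[paste(ar$chain, ar$resno) %in% want, , drop = FALSE]
  }
  if (nrow(ar) == 0) stop("selection matches no atoms in the reference")
  keys <- atom_key(ar$chain, ar$resno, ar$ins, ar$atom)
  P <- as.matrix(ar[, c("x", "y", "z")])
  out <- vapply(seq_along(frames), function(i) {
    af <- frames[[i]]$atoms
    kf <- atom_key(af$chain, af$resno, af$ins, af$atom)
    idx <- match(keys, kf)
    if (anyNA(idx)) {
      stop(sprintf("frame %d: %d selected atom(s) missing", i, sum(is.na(idx))))
    }
    Q <- as.matrix(af[idx, c("x", "y", "z")])
    if (superpose && nrow(Q) >= 3) {
      kabsch(P, Q)$rmsd
    } else {
      sqrt(mean(rowSums((Q - P)^2)))
    }
  }, numeric(1))
  data.frame(frame = seq_along(frames), rmsd = out)
}
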