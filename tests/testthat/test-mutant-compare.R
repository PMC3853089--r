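# --- superposition ----------------------------------------------------------

test_that("kabsch recovers rigid motions exactly", {
  set.seed(21)
  P <- matrix(rnorm(30), ncol = 3)
  # identical sets: identity rotation, zero RMSD
  f0 <- kabsch(P, P)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(f0$rmsd, 0, tolerance = 1e-10)
  # rigidly moved copy: recovered to numerical precision
  R <- random_rotation(4); t <- c(3, -7, 11)
  Q <- sweep(P %*% R, 2, t, `+`)
  f1 <- kabsch(P, Q)
  expect_equal(f1$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(f1$rotation), 1, tolerance = 1e-12)
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("pair_and_superimpose pairs by residue and reports per-residue RMSD", {
  sd1 <- make_slab_dimer(slab_spec(nx = 6, ny = 6, nz = 2, n_waters = 0))
  wt <- sd1$structure
  R <- random_rotation(8); t <- c(5, 5, -2)
  mut <- rigid_move(wt, R, t)
  sup <- pair_and_superimpose(wt, mut)
  expect_equal(sup$global_rmsd, 0, tolerance = 1e-8)
  expect_true(all(sup$per_residue_rmsd$rmsd < 1e-8))
  expect_equal(det(sup$rotation), 1, tolerance = 1e-12)

  # a displaced residue shows up in per-residue RMSD but not elsewhere
  mut2 <- wt
  hit <- mut2$atoms$chain == "A" & mut2$atoms$resno == 5
  mut2$atoms$x[hit] <- mut2$atoms$x[hit] + 0.4
  sup2 <- pair_and_superimpose(wt, mut2)
  pr <- sup2$per_residue_rmsd
  expect_gt(pr$rmsd[pr$chain == "A" & pr$resno == 5], 0.3)
  expect_lt(max(pr$rmsd[!(pr$chain == "A" & pr$resno == 5)]), 0.1)

  # unpaired residues error under strict pairing, with the residues named
  mut3 <- subset_structure(wt, atom_ids =
    wt$atoms$atom_id[!(wt$atoms$chain == "B" & wt$atoms$resno == 1)])
  expect_error(pair_and_superimpose(wt, mut3), "unpaired")
  expect_warning(pair_and_superimpose(wt, mut3, strict = FALSE), "unpaired")
})

test_that("chain_map pairs relabeled chains for self-comparison", {
  sd1 <- make_slab_dimer(slab_spec(nx = 5, ny = 5, nz = 2, n_waters = 0))
  s <- sd1$structure
  # a rigidly moved copy whose chain labels are swapped: mapping the labels
  # back must recover a perfect superposition
  s2 <- rigid_move(s, random_rotation(6), c(4, 0, -3))
  s2$atoms$chain <- chartr("AB", "BA", s2$atoms$chain)
  sup <- pair_and_superimpose(s, s2, chain_map = c(A = "B", B = "A"))
  expect_equal(sup$global_rmsd, 0, tolerance = 1e-8)
  # swapped labels without the map cannot pair cleanly
  expect_gt(pair_and_superimpose(s, s2)$global_rmsd, 0.5)
})

# --- water reappearance -----------------------------------------------------

fake_water_iface <- function(xyz, chain = "S") {
  n <- nrow(xyz)
  a <- data.frame(chain = rep(chain, n), resno = 9000 + seq_len(n),
                  ins = rep("", n), resname = rep("HOH", n),
                  atom = rep("O", n), element = rep("O", n),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  occ = rep(1, n), b = rep(0, n), radius = rep(1.52, n),
                  is_water = rep(TRUE, n))
  a$atom_id <- seq_len(n)
  st <- structure(list(atoms = a, id = "w"), class = "wet_structure")
  structure(list(side1 = integer(0), side2 = integer(0),
                 water = a$atom_id, edges = matrix(integer(0), 0, 2),
                 chain1 = "A", chain2 = "B", structure = st),
            class = "wet_interface")
}

test_that("identical water sets all reappear at distance zero", {
  W <- matrix(runif(30, 0, 10), ncol = 3)
  corr <- water_reappearance(fake_water_iface(W), fake_water_iface(W))
  expect_equal(nrow(corr$matched), 10)
  expect_true(all(corr$matched$distance < 1e-12))
})

test_that("mutual-nearest pairs beyond the cutoff do not reappear", {
  w1 <- matrix(c(0, 0, 0), ncol = 3)
  w2 <- matrix(c(1.5, 0, 0), ncol = 3)
  corr <- water_reappearance(fake_water_iface(w1), fake_water_iface(w2))
  expect_equal(nrow(corr$matched), 0)
  expect_equal(nrow(corr$mutual_far), 1)
  expect_equal(corr$mutual_far$distance, 1.5, tolerance = 1e-12)
})

test_that("empty water sets give all-unmatched without error", {
  W <- matrix(runif(9, 0, 5), ncol = 3)
  corr <- water_reappearance(fake_water_iface(W),
                             fake_water_iface(W[0, , drop = FALSE]))
  expect_equal(nrow(corr$matched), 0)
  expect_length(corr$unmatched_wt, 3)
})

test_that("reappearance is symmetric and monotone in the cutoff", {
  set.seed(33)
  W <- matrix(runif(45, 0, 12), ncol = 3)
  M <- W + matrix(rnorm(45, sd = 0.5), ncol = 3)
  M <- rbind(M[1:12, ], matrix(runif(9, 0, 12), ncol = 3))
  iw <- fake_water_iface(W); im <- fake_water_iface(M)
  ab <- water_reappearance(iw, im)
  ba <- water_reappearance(im, iw)
  expect_equal(ab$matched$wt_id, ba$matched$mut_id[match(ab$matched$mut_id,
                                                         ba$matched$wt_id)])
  expect_equal(nrow(ab$matched), nrow(ba$matched))
  n_prev <- -1
  for (cut in c(0.25, 0.5, 1, 2, 4)) {
    n_cur <- nrow(water_reappearance(iw, im, cutoff = cut)$matched)
    expect_gte(n_cur, n_prev)
    n_prev <- n_cur
  }
})

# --- B-factor normalization -------------------------------------------------

test_that("normalize_bfactors matches direct evaluation on a toy structure", {
  sd1 <- make_slab_dimer(slab_spec(nx = 6, ny = 6, nz = 2, n_waters = 4,
                                   core_frac = 0))
  s <- sd1$structure
  site <- sd1$truth$mutation_site
  nb <- normalize_bfactors(s, site)
  # hand evaluation of the same quantity
  a <- s$atoms
  cg <- a[a$atom == "CG" & a$resno == site & !a$is_water, ]
  d <- sapply(seq_len(nrow(a)), function(i)
    min(sqrt((a$x[i] - cg$x)^2 + (a$y[i] - cg$y)^2 + (a$z[i] - cg$z)^2)))
  ref <- !a$is_water & d >= 15
  mu <- mean(a$b[ref]); sg <- sqrt(mean((a$b[ref] - mu)^2))
  expect_equal(unname(nb$bstar), (a$b - mu) / sg, tolerance = 1e-12)
  expect_setequal(nb$ref_ids, a$atom_id[ref])
  # anchor points of the z-score
  i0 <- which.min(abs(a$b - mu))
  expect_equal(unname(nb$bstar[i0]), (a$b[i0] - mu) / sg)
})

test_that("B* is shift-invariant and equivariant under scaling of B", {
  sd1 <- make_slab_dimer(slab_spec(nx = 6, ny = 6, nz = 2, n_waters = 0))
  s <- sd1$structure
  site <- sd1$truth$mutation_site
  b0 <- normalize_bfactors(s, site)
  s_shift <- s; s_shift$atoms$b <- s$atoms$b + 7.3
  expect_equal(normalize_bfactors(s_shift, site)$bstar, b0$bstar,
               tolerance = 1e-10)
  s_scale <- s; s_scale$atoms$b <- s$atoms$b * 2.5
  expect_equal(normalize_bfactors(s_scale, site)$bstar, b0$bstar,
               tolerance = 1e-10)
})

test_that("normalize_bfactors validates reference set and sites", {
  sd1 <- make_slab_dimer(slab_spec(nx = 4, ny = 4, nz = 2, n_waters = 0))
  s <- sd1$structure
  # a huge exclusion radius leaves nothing to normalize against
  expect_error(normalize_bfactors(s, sd1$truth$mutation_site,
                                  exclusion_radius = 100),
               "reference set too small")
  expect_error(normalize_bfactors(s, 99999), "C-gamma")
  s2 <- make_slab_dimer(slab_spec(nx = 6, ny = 6, nz = 2, n_waters = 0))$structure
  s2$atoms$b <- 15
  expect_error(normalize_bfactors(s2, 1), "zero standard deviation")
})

# --- delta B* profile -------------------------------------------------------

test_that("identical structures give an all-zero dBstar profile", {
  sd1 <- make_slab_dimer()
  h <- interface_hydration(sd1$structure, "A", "B", with_delta_sasa = FALSE)
  nb <- normalize_bfactors(sd1$structure, sd1$truth$mutation_site)
  corr <- water_reappearance(h$interface, h$interface)
  prof <- delta_bstar_profile(h$interface, h$interface, nb, nb, corr,
                              sd1$regions, h$burial)
  expect_true(all(abs(prof$waters$dbstar) < 1e-12))
  expect_true(all(abs(prof$atoms$mean_dbstar) < 1e-12))
  expect_equal(nrow(prof$waters), length(h$interface$water))
})

test_that("a region-confined B shift localizes in the dBstar profile", {
  sd1 <- make_slab_dimer()
  wt <- sd1$structure
  mut <- make_mutant_copy(wt, bshift = c(A = 5), regions = sd1$regions,
                          seed = 3)
  hw <- interface_hydration(wt, "A", "B", with_delta_sasa = FALSE)
  hm <- interface_hydration(mut, "A", "B", with_delta_sasa = FALSE)
  site <- sd1$truth$mutation_site
  bw <- normalize_bfactors(wt, site)
  bm <- normalize_bfactors(mut, site)
  corr <- water_reappearance(hw$interface, hm$interface)
  prof <- delta_bstar_profile(hw$interface, hm$interface, bw, bm, corr,
                              sd1$regions, hw$burial)
  at <- prof$atoms
  mean_by_region <- tapply(at$mean_dbstar, at$region, mean)
  # the shifted region dominates; roughly delta/sigma above the others
  expect_gt(mean_by_region[["A"]],
            max(mean_by_region[c("B", "C", "D")]) + 0.5 * 5 / bw$ref_sd)
  # the shift reaches every burial level of region A (it is uniform there)
  expect_true(all(at$mean_dbstar[at$region == "A"] >
                  max(at$mean_dbstar[at$region != "A"])))
})

test_that("missing region coverage errors when no rest region is allowed", {
  sd1 <- make_slab_dimer(slab_spec(nx = 6, ny = 6, nz = 2, n_waters = 4,
                                   core_frac = 0))
  h <- interface_hydration(sd1$structure, "A", "B", with_delta_sasa = FALSE)
  nb <- normalize_bfactors(sd1$structure, sd1$truth$mutation_site)
  corr <- water_reappearance(h$interface, h$interface)
  partial <- sd1$regions["A"]
  expect_error(
    delta_bstar_profile(h$interface, h$interface, nb, nb, corr, partial,
                        h$burial, rest_region = NULL),
    "not covered")
})

# --- trajectory-frame RMSD --------------------------------------------------

test_that("rmsd_over_frames: reference frames, rigid motion, displacement", {
  sd1 <- make_slab_dimer(slab_spec(nx = 5, ny = 5, nz = 2, n_waters = 0))
  ref <- sd1$structure
  # identical frames -> 0; rigidly moved frame -> 0 after superposition
  fr_rigid <- rigid_move(ref, random_rotation(12), c(1, 2, 3))
  out <- rmsd_over_frames(list(ref, fr_rigid), ref)
  expect_equal(out$rmsd, c(0, 0), tolerance = 1e-8)

  # one CA displaced by d among N selected: without superposition the RMSD
  # is exactly d / sqrt(N); with superposition it cannot exceed that
  fr <- ref
  ca <- which(fr$atoms$atom == "CA")
  d <- 1.2
  fr$atoms$x[ca[1]] <- fr$atoms$x[ca[1]] + d
  N <- length(ca)
  raw <- rmsd_over_frames(list(fr), ref, superpose = FALSE)$rmsd
  expect_equal(raw, d / sqrt(N), tolerance = 1e-12)
  fit <- rmsd_over_frames(list(fr), ref)$rmsd
  expect_lte(fit, raw + 1e-12)

  # per-region selection and frame-mismatch error
  regA <- region_residues(sd1$regions, "A")
  outA <- rmsd_over_frames(list(fr), ref, residues = regA, superpose = FALSE)
  expect_true(is.finite(outA$rmsd))
  fr_bad <- subset_structure(ref, atom_ids = ref$atoms$atom_id[-ca[1]])
  expect_error(rmsd_over_frames(list(ref, fr_bad), ref), "frame 2")
})

test_that("multi-model PDB text round-trips into frames", {
  sd1 <- make_slab_dimer(slab_spec(nx = 4, ny = 4, nz = 2, n_waters = 0))
  s <- sd1$structure
  s2 <- rigid_move(s, random_rotation(2), c(0.5, 0, 0))
  txt <- c("MODEL        1", write_pdb(s)[-length(write_pdb(s))],
           "ENDMDL",
           "MODEL        2", write_pdb(s2)[-length(write_pdb(s2))],
           "ENDMDL", "END")
  frames <- read_models(txt)
  out <- rmsd_over_frames(frames, s)
  # frame 2 passed through 3-decimal PDB coordinates: tolerance reflects that
  expect_equal(out$rmsd, c(0, 0), tolerance = 5e-3)
})
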