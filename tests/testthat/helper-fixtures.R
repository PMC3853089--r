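# Programmatic fixtures: everything is built in code at test time.

# quick structure from bare coordinates (one chain, 4 atoms per residue)
toy_structure <- function(xyz, element = "C", chain = "A", radii = "bondi",
                          water = rep(FALSE, nrow(xyz)), b = 0) {
  n <- nrow(xyz)
  if (length(element) == 1) element <- rep(element, n)
  if (length(chain) == 1) chain <- rep(chain, n)
  if (length(b) == 1) b <- rep(b, n)
  df <- data.frame(chain = chain,
                   resno = ifelse(water, 9000 + seq_len(n),
                                  (seq_len(n) - 1) %/% 4 + 1),
                   resname = ifelse(water, "HOH", "GLY"),
                   atom = ifelse(water, "O", paste0("C", seq_len(n))),
                   element = ifelse(water, "O", element),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = b)
  assign_radii(structure_from_atoms(df), radii)
}

# random atom cloud for Voronoi-oracle comparisons
random_cloud <- function(n, seed, side = 14) {
  set.seed(seed)
  list(xyz = matrix(runif(3 * n, 0, side), ncol = 3),
       radii = runif(n, 1.4, 1.9))
}

# solid lattice block with a single-vacancy well in the top face and two
# stacked waters: the outer pokes out of the mouth (clearly exposed), the
# inner fills the mouth vacancy and is shielded only by the outer.
# Verified construction: pruning removes both in exactly two sweeps.
cascade_well_structure <- function() {
  sp <- 3.4; n <- 5; nz <- 4; c0 <- 2
  pos <- NULL
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (k in 0:(nz - 1)) {
    if (i == c0 && j == c0 && k == 3) next
    pos <- rbind(pos, c(i, j, k) * sp)
  }
  zi <- 3 * sp + 0.5
  wat <- rbind(c(c0 * sp, c0 * sp, zi + 2.9),
               c(c0 * sp, c0 * sp, zi))
  xyz <- rbind(pos, wat)
  toy_structure(xyz, water = c(rep(FALSE, nrow(pos)), TRUE, TRUE))
}

# solid lattice block with one interior vacancy holding a cavity water
cavity_structure <- function() {
  sp <- 3.4; n <- 5; c0 <- 2
  pos <- NULL
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) for (k in 0:(n - 1)) {
    if (i == c0 && j == c0 && k == c0) next
    pos <- rbind(pos, c(i, j, k) * sp)
  }
  xyz <- rbind(pos, c(c0, c0, c0) * sp)
  toy_structure(xyz, water = c(rep(FALSE, nrow(pos)), TRUE))
}

# a small hand-written PDB: one CA, one water oxygen, one hydrogen
MINI_PDB <- c(
  "HEADER    TEST                                    01-JAN-00   XXXX",
  "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
  "ATOM      2  HA  GLY A   1       1.000   0.000   0.000  1.00 10.00           H",
  "HETATM    3  O   HOH A 101       5.000   0.000   0.000  1.00 20.00           O",
  "END")

# random rotation matrix (det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigidly move a structure
rigid_move <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}
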