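# a hand-wired interface object for statistic-level tests
fake_interface <- function(side1, side2, water, edges) {
  n <- length(side1) + length(side2) + length(water)
  a <- data.frame(chain = c(rep("A", length(side1)), rep("B", length(side2)),
                            rep("S", length(water))),
                  resno = seq_len(n), ins = rep("", n),
                  resname = rep("GLY", n),
                  atom = rep("C1", n), element = rep("C", n),
                  x = seq_len(n), y = rep(0, n), z = rep(0, n),
                  occ = rep(1, n), b = rep(0, n),
                  radius = rep(1.7, n),
                  is_water = c(rep(FALSE, length(side1) + length(side2)),
                               rep(TRUE, length(water))))
  a$resname[a$is_water] <- "HOH"
  a$atom_id <- seq_len(n)
  st <- structure(list(atoms = a, id = "fake"), class = "wet_structure")
  structure(list(side1 = side1, side2 = side2, water = water,
                 edges = matrix(as.integer(edges), ncol = 2),
                 chain1 = "A", chain2 = "B", structure = st),
            class = "wet_interface")
}

test_that("wetness is the water share of the tripartite node set", {
  i_dry <- fake_interface(1:3, 4:6, integer(0),
                          rbind(c(1, 4), c(2, 5), c(3, 6)))
  expect_equal(wetness(i_dry), 0)
  i_wet <- fake_interface(1:3, 4:6, 7L, rbind(c(1, 4), c(1, 7), c(4, 7)))
  expect_equal(wetness(i_wet), 1 / 7)
  i_empty <- fake_interface(integer(0), integer(0), integer(0),
                            matrix(integer(0), 0, 2))
  expect_error(wetness(i_empty), "empty")
})

test_that("rwbl is the ratio of mean burial levels (waters in denominator)", {
  i <- fake_interface(1:2, 3:4, 5:6,
                      rbind(c(1, 5), c(3, 5), c(2, 6), c(4, 6)))
  mk_bl <- function(v) structure(list(bl = setNames(as.integer(v), 1:6),
                                      threshold = 10), class = "wet_burial")
  # identical BL everywhere -> exactly 1
  expect_equal(rwbl(i, mk_bl(c(2, 2, 2, 2, 2, 2))), 1)
  # waters {2,2}, full interface {0,1,2,2,2,2}: 2 / 1.5
  expect_equal(rwbl(i, mk_bl(c(0, 1, 2, 2, 2, 2))), 4 / 3)
  # no water -> undefined
  i0 <- fake_interface(1:2, 3:4, integer(0), rbind(c(1, 3)))
  expect_error(rwbl(i0, mk_bl(1:6)), "no interfacial water")
  # all-zero mean -> undefined
  expect_error(rwbl(i, mk_bl(c(0, 0, 0, 0, 0, 0))), "mean interface burial")
})

test_that("water contact counts are distinct waters, not edges", {
  # one water contacting 3 side-1 atoms and 2 side-2 atoms
  i <- fake_interface(1:4, 5:7, 8L,
                      rbind(c(1, 8), c(2, 8), c(3, 8), c(5, 8), c(6, 8),
                            c(4, 5)))
  y <- water_contact_counts(i)$y
  expect_equal(unname(y[as.character(1:7)]), c(1, 1, 1, 0, 1, 1, 0))
  # dry interface -> all zero
  i_dry <- fake_interface(1:2, 3:4, integer(0), rbind(c(1, 3)))
  expect_true(all(water_contact_counts(i_dry)$y == 0))
  # sum of y equals the number of water-protein edges
  expect_equal(sum(y), 5)
})

test_that("gini matches hand values and rejects degenerate input", {
  expect_equal(gini(c(2, 2, 2, 2)), 0)
  expect_equal(gini(c(0, 0, 0, 4)), 0.75)       # Lorenz areas X = 6, Y = 8
  expect_error(gini(c(3)), "at least 2")
  expect_error(gini(c(0, 0, 0)), "undefined")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("gini properties: scale and permutation invariance, spike maximum", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    y <- rpois(n, 2)
    if (sum(y) == 0) y[1] <- 1
    g <- gini(y)
    expect_equal(gini(3.7 * y), g, tolerance = 1e-12)
    expect_equal(gini(sample(y)), g, tolerance = 1e-12)
    expect_gte(g, 0); expect_lte(g, 1)
    expect_equal(g, gini_lorenz_oracle(y), tolerance = 1e-12)
  }
  for (n in c(2, 5, 17, 100)) {
    spike <- c(rep(0, n - 1), 8)
    expect_equal(gini(spike), (n - 1) / n, tolerance = 1e-12)
    expect_equal(gini_lorenz_oracle(spike), (n - 1) / n, tolerance = 1e-12)
  }
})

test_that("residue hydration profile counts distinct waters per residue", {
  # residue with two atoms touching the same water counts it once
  a <- data.frame(chain = c("A", "A", "B", "S"), resno = c(1, 1, 2, 9001),
                  ins = "", resname = c("GLY", "GLY", "GLY", "HOH"),
                  atom = c("C1", "C2", "C1", "O"), element = c("C", "C", "C", "O"),
                  x = 1:4, y = 0, z = 0, occ = 1, b = 0, radius = 1.7,
                  is_water = c(FALSE, FALSE, FALSE, TRUE))
  a$atom_id <- 1:4
  st <- structure(list(atoms = a, id = "fake"), class = "wet_structure")
  i <- structure(list(side1 = 1:2, side2 = 3L, water = 4L,
                      edges = matrix(as.integer(c(1, 4, 2, 4, 3, 4)),
                                     ncol = 2, byrow = TRUE),
                      chain1 = "A", chain2 = "B", structure = st),
                 class = "wet_interface")
  prof <- residue_hydration_profile(i)
  expect_equal(prof$n_water[prof$chain == "A"], 1)
  expect_equal(prof$n_water[prof$chain == "B"], 1)
})

test_that("planted slab dimer round-trips wetness, counts and profile", {
  sd1 <- make_slab_dimer()
  h <- interface_hydration(sd1$structure, "A", "B", with_delta_sasa = FALSE)
  i <- h$interface
  # planted water set recovered exactly
  expect_setequal(i$water, sd1$truth$waters$atom_id)
  expect_equal(wetness(i), length(i$water) /
                 (length(i$side1) + length(i$side2) + length(i$water)))
  # per-atom counts match the planted contact design on slab atoms
  cnt <- water_contact_counts(i)
  ytruth <- sd1$truth$atom_water_counts
  for (id in names(ytruth)) {
    expect_equal(unname(cnt$y[id]), as.integer(ytruth[[id]]))
  }
  a <- h$structure$atoms
  slab <- as.character(a$atom_id[!a$is_water & abs(a$z) > 1])  # not seal ring
  zero_expected <- setdiff(intersect(names(cnt$y), slab), names(ytruth))
  expect_true(all(cnt$y[zero_expected] == 0))
  # per-residue profile matches the planted design on slab residues
  prof <- residue_hydration_profile(i)
  key <- paste(prof$chain, prof$resno, ".", sep = "|")
  truth_prof <- sd1$truth$residue_water_counts
  hit <- key %in% names(truth_prof)
  expect_equal(prof$n_water[hit],
               as.integer(truth_prof[key[hit]]), ignore_attr = TRUE)
})

test_that("delta_sasa: zero without contact, closed form for two spheres", {
  # far-apart one-atom chains: no buried area
  df <- data.frame(chain = c("A", "B"), resno = 1, resname = "GLY",
                   atom = "C1", element = "C", x = c(0, 40), y = 0, z = 0)
  s_far <- assign_radii(structure_from_atoms(df))
  expect_equal(delta_sasa(s_far, "A", "B"), 0, tolerance = 1e-9)
  # overlapping spheres against the analytic buried-cap area
  for (d in c(2.2, 3.0)) {
    df$x <- c(0, d); df$element <- c("C", "O")
    s <- assign_radii(structure_from_atoms(df))
    expect_equal(delta_sasa(s, "A", "B", n_points = 4096),
                 two_sphere_delta_sasa(1.7, 1.52, d, 1.4),
                 tolerance = 0.01 * two_sphere_delta_sasa(1.7, 1.52, d, 1.4))
  }
  expect_error(delta_sasa(s_far, "A", "Q"), "chain not found")
})

test_that("delta_sasa is non-negative for overlapping dimers", {
  sd1 <- make_slab_dimer(slab_spec(nx = 5, ny = 5, nz = 2, n_waters = 0))
  s <- assign_radii(sd1$structure)
  expect_gt(delta_sasa(s, "A", "B"), 0)
})

test_that("rwbl directionality: wet-core > 1, dry-core-wet-rim < 1", {
  h_wet <- interface_hydration(make_slab_dimer(slab_spec(core_frac = 1))$structure,
                               "A", "B", with_delta_sasa = FALSE)
  expect_gt(h_wet$summary$rwbl, 1)
  h_dry <- interface_hydration(make_slab_dimer(slab_spec(core_frac = 0))$structure,
                               "A", "B", with_delta_sasa = FALSE)
  expect_lt(h_dry$summary$rwbl, 1)
})
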