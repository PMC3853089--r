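# Independent oracles used to freeze expected values.  Each is a different
# route to the same quantity than the implementation takes.

# --- Gini: geometric Lorenz-area construction -------------------------------
# Trapezoid area under the piecewise-linear Lorenz curve of the sorted
# counts, versus the triangle under the line of equality.
gini_lorenz_oracle <- function(y) {
  y <- sort(as.numeric(y))
  n <- length(y)
  cum <- cumsum(c(0, y))
  area_lorenz <- sum((cum[-1] + cum[-(n + 1)]) / 2)   # unit horizontal steps
  area_equality <- n * sum(y) / 2
  (area_equality - area_lorenz) / area_equality
}

# --- burial levels: Floyd-Warshall distance-to-set --------------------------
fw_levels_oracle <- function(edges, n, exposed) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    D[i, j] <- 1; D[j, i] <- 1
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  apply(D[, exposed, drop = FALSE], 1, min)
}

# --- Voronoi adjacency: exhaustive half-space test by vertex enumeration ----
# Feasibility of {closer to the pair than to every other atom} on the
# bisector plane, boxed at +/- L; a bounded non-empty polygon has a vertex.
# The box is axis-aligned in the canonical bisector-plane basis (the same
# deterministic construction the package documents), so both routes test
# the identical region; only the feasibility algorithm differs.
canonical_plane_basis <- function(dhat) {
  ax <- if (abs(dhat[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- c(dhat[2] * ax[3] - dhat[3] * ax[2],
          dhat[3] * ax[1] - dhat[1] * ax[3],
          dhat[1] * ax[2] - dhat[2] * ax[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dhat[2] * e1[3] - dhat[3] * e1[2],
          dhat[3] * e1[1] - dhat[1] * e1[3],
          dhat[1] * e1[2] - dhat[2] * e1[1])
  cbind(e1, e2)
}

voronoi_edges_oracle <- function(xyz, radii, wd = 2.75, L = 200, tol = 1e-6) {
  n <- nrow(xyz)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- xyz[j, ] - xyz[i, ]
    dist <- sqrt(sum(d^2))
    if (dist > radii[i] + radii[j] + wd) next
    dhat <- d / dist
    B <- canonical_plane_basis(dhat)
    m <- (xyz[i, ] + xyz[j, ]) / 2
    oth <- setdiff(1:n, c(i, j))
    A <- t(vapply(oth, function(k) {
      g <- xyz[k, ] - xyz[i, ]
      2 * c(sum(g * B[, 1]), sum(g * B[, 2]))
    }, numeric(2)))
    cc <- vapply(oth, function(k) {
      g <- xyz[k, ] - xyz[i, ]
      sum(xyz[k, ]^2) - sum(xyz[i, ]^2) - 2 * sum(g * m)
    }, numeric(1))
    A <- rbind(A, c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    cc <- c(cc, L, L, L, L)
    nc <- nrow(A)
    feas <- FALSE
    for (p in 1:(nc - 1)) {
      for (q in (p + 1):nc) {
        dt <- A[p, 1] * A[q, 2] - A[p, 2] * A[q, 1]
        if (abs(dt) < 1e-12) next
        v <- solve(A[c(p, q), ], cc[c(p, q)])
        if (all(A %*% v <= cc + tol)) { feas <- TRUE; break }
      }
      if (feas) break
    }
    if (feas) edges <- rbind(edges, c(i, j))
  }
  edges
}

# --- SASA closed forms ------------------------------------------------------
isolated_sphere_sasa <- function(r, probe) 4 * pi * (r + probe)^2

# exposed areas of two intersecting probe-expanded spheres at distance d
two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  stopifnot(d < R1 + R2, d > abs(R1 - R2))
  x1 <- (d^2 - R2^2 + R1^2) / (2 * d)
  x2 <- (d^2 - R1^2 + R2^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1),
    4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2))
}

# interface area of the two-sphere "dimer": half of (sum of isolated areas
# minus complex area) == pi * (R1 h1 + R2 h2)
two_sphere_delta_sasa <- function(r1, r2, d, probe) {
  iso <- isolated_sphere_sasa(r1, probe) + isolated_sphere_sasa(r2, probe)
  (iso - sum(two_sphere_sasa(r1, r2, d, probe))) / 2
}
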