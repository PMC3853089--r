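---
title: "Quantifying buried-water topology in protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying buried-water topology in protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetcore)
```

## The problem

Crystal structures of protein complexes report ordered water, and at some
interfaces that water is not decoration: a cluster of tens of molecules can
be buried at the very core of the subunit interface, held by conserved
residues, and load-bearing for the quaternary structure. `wetcore`
quantifies that topology — how much water an interface holds, how deeply it
is buried relative to the rest of the interface, and how unevenly it is
distributed — and compares a wild-type/mutant structure pair to ask whether
a mutation loosened the water cluster.

## The pipeline and its assumptions

**Heavy atoms only.** Hydrogens are dropped on reading; crystallographic
hydrogen placement is unreliable at typical resolutions and all criteria
below are defined on heavy atoms. Water is represented by its oxygen.

**Bulk-water pruning.** A water molecule is part of the complex only if it
is not exchangeable with bulk solvent. The operational criterion: waters
with SASA above a threshold (default 10 Å²) are removed, and because a
removal can expose the next water shell, the sweep repeats to a fixed
point. Retained waters occlude in every SASA pass — they are treated as
part of the complex throughout. The procedure is idempotent by
construction and the iteration count is recorded.

**Contact graph.** Atoms are in contact when they are Voronoi neighbours
of the tessellation of atom centres *and* within
`r_a + r_b + water_diameter`. The distance term (default 2.75 Å, one water
diameter) keeps Voronoi adjacencies that are close enough for a single
water to bridge; the Voronoi term removes distance-close pairs that are
geometrically occluded by an intervening atom. The tessellation is
unweighted (atom centres, not power-diagram); radii enter only through the
distance rule. All retained atoms — both chains and waters — are
tessellation sites.

**Tripartite interface.** Interfacial waters contact both chains; each
side's interface atoms contact the opposite chain or an interfacial water;
the interface `I` is the union of the three sets with all contacts among
them as edges. A residue with at least one interface atom is an
interfacial residue.

**Burial level.** `BL_a` is the unweighted graph distance from atom `a` to
the nearest exposed atom (SASA above the same 10 Å² threshold), computed
by multi-source BFS over the whole complex graph — not per chain, since
burial in a complex is a property of the assembly. Exposed atoms have
`BL = 0`; the map is 1-Lipschitz along edges. Atoms unreachable from any
exposed atom (possible in pathological graphs, not in real structures) get
an `NA` sentinel, are counted, and are excluded from averages with a
warning.

**Descriptors.**

- wetness `= |I_W| / |I|`, with water oxygens counted in the denominator
  (the convention that reproduces published wetness values of obligate
  interfaces at ~0.05);
- `rWBL = mean BL(I_W) / mean BL(I)`, undefined for a dry interface;
- the Gini coefficient of the per-atom water-contact counts `y_j`
  (distinct waters, not edges), computed as the Lorenz-area ratio of the
  non-decreasingly sorted counts, equal to
  `2 Σ i·y_i / (n Σ y_i) − (n+1)/n`. It is undefined (not zero) when no
  interface atom touches water. Printed shortcut formulas for this
  quantity are sometimes dimensionally inconsistent; the Lorenz-area
  definition is authoritative here and a geometric-area oracle arbitrates
  in the test suite. Higher Gini = more
  uneven, the standard orientation.
- `ΔSASA = [SASA(chain1) + SASA(chain2) − SASA(complex)] / 2` on protein
  atoms only; isolated-chain SASA is water-free by construction, so waters
  are excluded from the complex term as well.

**Wild-type vs mutant.** Residues pair by chain + residue number +
insertion code (names may differ, so point substitutions pair). A single
Kabsch fit on paired Cα atoms maps the mutant into the wild-type frame; no
iterative outlier rejection is applied by default (a `trim_cycles` option
exists) because regression targets should not depend on a rejection
schedule. Per-residue RMSD uses all heavy atoms shared by the paired
residues — at a substitution site only the shared atoms. A wild-type water
*reappears* when it and a mutant water are mutually nearest and within
1.0 Å. `B* = (B − mean)/sd` uses non-water atoms at least 15 Å from every
mutation-site Cγ (min over both chains of a homodimer) as the reference
set; the standard deviation is the population form (divide by N — at
reference sizes of thousands the difference from the sample form is
immaterial, but it is fixed for reproducibility). ΔB* is profiled per
interface region and per wild-type burial level over paired non-water
interface atoms.

**Regions** are user configuration (JSON, region → chain → residue
numbers), not computed: published region boundaries of specific interfaces
are drawn on structure figures, not defined algorithmically. Residues not
listed fall into a catch-all region (default `"D"`); with no catch-all,
uncovered residues are an error. Waters inherit the region of the
majority of their contacting interfacial residues; ties break by the
number of atom contacts into each candidate region, then alphabetically.

## Numerical choices

**SASA** uses a deterministic golden-section spiral (default 960 points,
probe 1.4 Å) — standard probe, and a point count at which doubling changes
an isolated-sphere value by well under 0.5%. Closed-form validation
against the two-overlapping-spheres cap formula is run at 4096 points in
the tests because the 960-point estimator has up to ~0.65% error on that
worst-case geometry; density is an explicit argument, the default is
unchanged. Sphere sampling counts interior cavities as accessible surface;
this matters for the synthetic generator (below).

**Voronoi adjacency** is decided exactly per candidate pair: on the pair's
bisector plane, "some point is at least as close to the pair as to atom
c" is a half-plane, and adjacency is feasibility of the intersection,
solved by a randomized-incremental (Seidel) 2-D LP with a deterministic
shuffle. Two conventions are part of the definition and are shared with
the brute-force oracle used in tests: (i) the search is confined to a
±200 Å box, axis-aligned in a canonical deterministic basis of the
bisector plane — real facets live far inside it, but near-degenerate
configurations can have eps-thin feasible slivers tens of Å out, where a
basis-dependent box boundary would otherwise make the answer
basis-dependent; (ii) degenerate zero-area facets count as adjacent,
implemented by relaxing every half-plane constant by 1e-6 before solving,
so exact four-point ties (common in lattice-built synthetic structures)
are adjudicated deterministically. Coincident atom centres are treated as
adjacent. Coplanar or collinear inputs need no special casing — the
per-pair test does not degenerate the way a global tessellation does.

**Distances** between matched waters are recomputed with the direct
difference formula rather than taken from the outer-product distance
matrix, which loses ~7 significant digits to cancellation near zero.

## The synthetic stated world

`make_slab_dimer()` builds a dimer whose every property is known by
construction: two 10×10×3 carbon slabs (chains A and B) on a 3.5 Å cubic
lattice, inner layers 5.0 Å apart, and a sealing ring of atoms around the
gap mid-plane, split between the chains. Waters sit in the gap's lattice
pockets: "core" waters at the footprint centre, "rim" waters in the
outermost pocket ring against the seal. The seal is essential: sphere
sampling treats any probe-reachable pocket as exposed, so an unsealed gap
mouth would let exposure pruning eat the rim waters. With it, every
planted water survives pruning, core waters sit at burial level 3 and rim
waters at level 1, so a wet-core placement yields rWBL well above 1 and a
dry-core-wet-rim placement below 1 — the directional behaviour the
descriptors must reproduce. Atoms group four per residue (named
CA/CB/CG/CD so Cα superposition and Cγ mutation-site logic run unchanged);
wall and slab atoms never share a residue, keeping the planted per-residue
contact design clean. Regions A–D are footprint quadrants. The generator
emits PDB text and re-reads it, so fixtures exercise the real parser, and
all randomness (mutant jitter, geometric count vectors) runs in a private
RNG stream restored afterwards.

What the generator does *not* emulate: real protein geometry (bond
lengths, packing heterogeneity, element mix), crystallographic noise,
partial-occupancy water, or water networks with hydrogen-bond structure. A
green synthetic test therefore establishes that the algorithms implement
their definitions and recover planted truths — not that any particular
biological interface will reproduce published descriptor values; that is
what the accession-based regression tests are for, and they require the
reference PDB entries to be available.

## Limitations

- Interfaces are analyzed pairwise; a tetramer's interfaces are extracted
  one chain pair at a time by the caller.
- No structure repair, missing-atom modelling, or symmetry-mate
  generation; what is in the file is what is analyzed.
- Molecular-dynamics trajectories are consumed only as multi-model PDB
  frames for RMSD profiling; no simulation is performed.
- SASA counts sealed internal cavities as accessible; for exposure
  pruning this is conservative (a cavity-adjacent water is "exposed" only
  if the cavity is large), but it is a known divergence from
  solvent-excluded-surface definitions.
- The B* reference set is pooled over the whole complex; per-chain
  normalization is not offered.
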