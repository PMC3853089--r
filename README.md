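# wetcore

Topology of buried water in protein–protein interfaces.

Most protein–protein interfaces are "dry-core–wet-rim": water sits at the
solvent-exposed rim and thins out toward the buried core. Some obligate
interfaces invert this — a large water cluster is locked deep inside the
core — and such interfaces can be fragile: a point mutation at the edge of
the cluster can let flexibility propagate along the water into the core and
destabilize the complex. `wetcore` is for structural biologists who want to
quantify that topology from a crystal structure and to compare a
wild-type/mutant pair.

## The model

From a PDB/mmCIF structure with solvent records, `wetcore`:

1. **Prunes bulk water.** A water with solvent accessible surface area
   (SASA) above 10 Å² is bulk solvent; it is removed and SASA is
   recomputed until no exposed water remains. Retained waters are part of
   the complex. SASA is a deterministic Shrake–Rupley estimate
   (probe 1.4 Å, 960 golden-spiral points per atom).
2. **Builds an atomic contact graph** on heavy atoms: an edge joins atoms
   that are Voronoi neighbours (exact per-pair half-space test) *and*
   within `r_a + r_b + 2.75 Å` (sum of van der Waals radii plus one water
   diameter).
3. **Extracts the tripartite interface** between chains 1 and 2: the
   interfacial waters (waters contacting both chains), and each chain's
   atoms contacting the other chain or an interfacial water. The node set
   is `I`, its waters `I_W`.
4. **Scores hydration topology.** With the burial level `BL_a` of atom *a*
   = contact-graph distance to the nearest exposed atom (SASA > 10 Å²):

   - wetness = `|I_W| / |I|`
   - relative water burial level
     `rWBL = mean(BL over I_W) / mean(BL over I)` — above 1 means water is
     buried deeper than the interface average (wet core);
   - Gini coefficient of the water-contact counts `y_j` (number of
     distinct interfacial waters touching non-water interface atom *j*),
     via the Lorenz curve of the sorted counts — how unevenly the water is
     shared;
   - interface area `ΔSASA = [SASA(1) + SASA(2) − SASA(complex)] / 2`.

5. **Compares a wild-type/mutant pair.** Kabsch superposition on paired Cα
   atoms with per-residue all-heavy-atom RMSD; water "reappearance"
   (mutual-nearest water pairs within 1.0 Å); and normalized B factors
   `B* = (B − mean) / sd` z-scored against non-water atoms ≥ 15 Å from the
   mutation-site Cγ, profiled as ΔB* per interface region and burial
   level.

A synthetic slab-dimer generator (`make_slab_dimer()`) plants a known
interface — water count, core/rim burial, per-residue contact design,
region partition — so the entire pipeline is testable without downloading
any structure.

## Worked example

```r
library(wetcore)

sd <- make_slab_dimer(slab_spec(seed = 1))     # 25 waters: 16 core, 9 rim
h  <- interface_hydration(sd$structure, "A", "B")
h
#> <wet_hydration> slab-dimer chains A/B (radii: bondi)
#>   waters 25 | interface atoms 262 | wetness 0.095
#>   mean BL water 2.28 | mean BL interface 1.23 | rWBL 1.861
#>   gini 0.663 | dSASA 1626.5 A^2
```

rWBL 1.86 says the planted waters sit almost twice as deep as the average
interface atom — a wet core. Gini 0.66 says a minority of atoms holds most
water contacts (the cluster is localized). Now a "mutant": jitter every
coordinate by 0.1 Å, delete 3 core waters, heat region A's B factors by
+5 Å²:

```r
mut <- make_mutant_copy(sd$structure, jitter_sd = 0.1,
                        drop_waters = head(sd$truth$waters$resno[
                          sd$truth$waters$kind == "core"], 3),
                        bshift = c(A = 5), regions = sd$regions, seed = 7)
sup  <- pair_and_superimpose(sd$structure, mut)
hm   <- interface_hydration(mut, "A", "B", with_delta_sasa = FALSE)
corr <- water_reappearance(h$interface, hm$interface, sup)
corr
#> <wet_watercorr> 22 reappearing (< 1.00 A), 0 mutual but far, 3/0 unmatched wt/mut

bw <- normalize_bfactors(sd$structure, sd$truth$mutation_site)
bm <- normalize_bfactors(mut, sd$truth$mutation_site)
prof <- delta_bstar_profile(h$interface, hm$interface, bw, bm, corr,
                            sd$regions, h$burial)
round(tapply(prof$atoms$mean_dbstar, prof$atoms$region, mean), 2)
#>     A     B     C     D
#>  2.56 -0.13 -0.13 -0.14
```

The pipeline recovers exactly the planted facts: 22 of 25 waters reappear,
and the B-factor perturbation localizes to region A across its burial
levels.

## Command line

`exec/wetcore` wraps the same functions:

```sh
wetcore synth   --out toy.pdb --truth truth.json --seed 3
wetcore stats   --pdb toy.pdb --chains A,B --out toy_stats     # JSON + per-atom TSV
wetcore compare --wt wt.pdb --mut mut.pdb --chains A,B --site 104 \
                --regions regions.json --out cmp
wetcore traj-rmsd --ref ref.pdb --frames frames.pdb --out traj
```

`regions.json` maps region name → chain → residue numbers, e.g.
`{"A": {"A": [102, 104, 112], "B": [102, 104, 112]}}`; interfacial residues
not listed fall into region `"D"`.

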