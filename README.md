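# blocklen

Statistical profiling of protein side-chain conformations from PDB
coordinate files, built around the **distal-block length**
d<sub>Block</sub>: the distance (Å) from a residue's Cα to the mass center
of its side chain's terminal rigid group (the *distal block* — e.g. the
guanidinium of ARG, the CE–NZ pair of LYS, the aromatic ring of PHE, the
hydroxyl oxygen of TYR). Together with the backbone torsions φ, ψ and the
first side-chain torsion χ₁ — all reported on [0°, 360°), with
φ = φ_R + 360° for negative Ramachandran-convention values — this gives a
compact four-feature description of each residue that separates extended
from folded side chains.

The package is aimed at structural bioinformaticians comparing how two
structure sets distribute side-chain conformations — for instance
high-resolution crystallographic models against cryo-EM models, where
systematic biases toward shorter side chains show up as extra mass at low
d<sub>Block</sub>. It provides:

* **structure I/O** — a PDB reader (first MODEL, heavy atoms) with explicit
  selection policies: first chain vs all chains, first alternate location,
  standard residues only; peptide linkage decided by a C–N < 2.0 Å rule so
  chain breaks never produce nonsense torsions;
* **geometry** — torsions in the 0–360° convention and d<sub>Block</sub>
  from a configurable, shipped block table (18 residue types; GLY/ALA have
  no block);
* **a synthetic conformer generator** — GLY–X–GLY tripeptides built
  NeRF-style at exact user-specified torsions from Engh–Huber-type ideal
  geometry, mixture sampling with per-torsion Gaussian noise, a hard-sphere
  clash screen, multi-MODEL PDB output and ground-truth tables;
* **profiles** — 5° / 0.05 Å binned densities, normalization of a curve
  pair by the reference set's peak (npdf: the reference peaks at exactly
  1), peak-normalized 2D histograms whose cells are population ratios
  against the modal conformation, peak detection, interval masses, and a
  two-set comparison that reports contiguous "B above A" intervals;
* **a pipeline + CLI** — manifest-driven end-to-end runs
  (`run_profile()`), plot rendering (npdf overlays, χ₁-colored
  Ramachandran, 2D histograms, 3D scatter), and a thin `exec/blocklen`
  script with `extract`, `profile`, `compare`, `simulate` and `plot`
  subcommands.

## Worked example

Build an ideal all-*trans* lysine and measure its features:

```r
library(blocklen)
trip <- build_residue("LYS", phi_r = -62, psi_r = -41,
                      chis = c(180, 180, 180, 180))
extract_records(trip, source = "ideal")[2, c("res_type", "phi", "psi", "chi1", "dblock")]
#>   res_type phi psi chi1 dblock
#> 2      LYS 298 319  180  5.748
```

φ_R = −62° appears as 298° in the 0–360° convention, and the extended
lysine's block length is 5.75 Å — the modal value for LYS in
high-resolution structure sets (5.7 Å) within the covalent-geometry
tolerance.

Now compare a reference ensemble against one with 30% of its mass moved to
a shorter rotamer (χ₄ = 60°), the synthetic analogue of a set biased toward
shorter side chains:

```r
spec_a <- synthetic_spec("LYS", list(
  list(phi = -62, psi = -41, chis = rep(180, 4), weight = 1, sigma = 5)),
  n_samples = 4000, seed = 1)
spec_b <- synthetic_spec("LYS", list(
  list(phi = -62, psi = -41, chis = rep(180, 4), weight = 0.7, sigma = 5),
  list(phi = -62, psi = -41, chis = c(180, 180, 180, 60), weight = 0.3, sigma = 5)),
  n_samples = 4000, seed = 2)
recs_a <- sample_ensemble(spec_a)$truth; recs_a$res_type <- "LYS"
recs_b <- sample_ensemble(spec_b)$truth; recs_b$res_type <- "LYS"
cmp <- compare_sets(recs_a, recs_b, "LYS", features = "dblock")
cmp
#> <set_comparison> LYS: 4000 vs 4000 records
#>   dblock: 1 B-above-A interval(s): (5.05, 5.3]
cmp$features$dblock$exceedance
#>     lo  hi mass_a mass_b
#> 1 5.05 5.3      0  0.304
```

The comparison flags exactly the region where set B carries its extra
short-side-chain mass: B's npdf exceeds A's over (5.05, 5.3] Å — covering
the shifted component's ideal length of 5.17 Å — holding 30.4% of B's
records versus ~0% of A's. The shifted component also appears as a second
npdf peak at 5.175 Å next to the shared extended peak at 5.725 Å.

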