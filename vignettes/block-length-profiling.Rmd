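---
title: "Profiling side-chain conformations with distal-block lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling side-chain conformations with distal-block lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocklen)
```

## The model

A protein side chain's conformation is usually described by its torsion
angles, but a complementary one-number summary is how far its terminal
chemical group sits from the backbone. `blocklen` describes each residue by
four features:

* the backbone torsions $\varphi$ (C$_{i-1}$–N–C$\alpha$–C) and $\psi$
  (N–C$\alpha$–C–N$_{i+1}$),
* the first side-chain torsion $\chi_1$ (N–C$\alpha$–C$\beta$–X$\gamma$), and
* the **distal-block length** $d_{\mathrm{Block}}$: the Euclidean distance
  from C$\alpha$ to the mass center of the side chain's *distal block*, its
  terminal rigid group (the guanidinium of ARG, the C$\epsilon$–N$\zeta$ pair
  of LYS, the aromatic ring of PHE, the hydroxyl oxygen of TYR, ...).

All angles are reported on $[0^\circ, 360^\circ)$: a signed
Ramachandran-convention angle $\varphi_R \in (-180^\circ, 180^\circ]$ maps to
$\varphi = \varphi_R$ when $\varphi_R \ge 0$ and $\varphi = \varphi_R +
360^\circ$ otherwise. This puts the well-populated negative-$\varphi$ region
in one contiguous range (an $\alpha$-helical $\varphi_R = -62^\circ$ becomes
$298^\circ$) at the cost of splitting nothing that is densely populated. The
boundary $-180^\circ$ is mapped to $180^\circ$, a single representative for
the wrap point.

$d_{\mathrm{Block}}$ separates extended from folded conformations: an
all-*trans* lysine has $d_{\mathrm{Block}} \approx 5.75$ Å while
*gauche* combinations fold it below 4 Å. Because the block is a rigid group,
its length responds only to the rotatable torsions between C$\alpha$ and the
block, which makes it a compact, binnable statistic for comparing how two
structure sets (for example crystallographic models versus cryo-EM models)
distribute side-chain conformations.

## The block table

The partition of each side chain into blocks is configuration, not code: the
shipped table (`inst/extdata/block_table.tsv`, 18 entries — GLY and ALA have
no block) lists each type's ordered block atoms, their atomic masses, and the
four $\chi_1$ atoms. Mass centers are computed over heavy atoms only;
deposited structures rarely contain hydrogens, so including them would make
the statistic depend on a modeling choice rather than on the conformation.
The $\gamma$ atom follows the standard convention (CG; CG1 for ILE/VAL; OG
for SER; OG1 for THR; SG for CYS).

The terminal-group assignments for the four headline residues (LYS
{CE, NZ}, ILE {CD1}, PHE ring, TYR {OH}, ARG guanidinium) are calibrated: on
ideal-geometry conformers in the modal rotamer they reproduce the modal block
lengths reported for large high-resolution crystallographic sets —
5.7 Å (LYS, all-*trans*), 3.88 Å (ILE, $\chi_1 = 300^\circ$,
$\chi_2 = 180^\circ$), 3.78 Å (PHE) and 6.43 Å (TYR, both
$\chi_1 = 300^\circ$, $\chi_2 = 90^\circ$), each within $\pm 0.15$ Å:

```{r calibration}
for (cs in list(list("LYS", c(180, 180, 180, 180)),
                list("ILE", c(300, 180)),
                list("PHE", c(300, 90)),
                list("TYR", c(300, 90)))) {
  trip <- build_residue(cs[[1]], phi_r = -120, psi_r = 130, chis = cs[[2]])
  cat(sprintf("%s  dBlock = %.3f A\n", cs[[1]],
              block_length(central_residue(trip))))
}
```

The remaining 13 types use the chemically terminal rigid group; those
choices are documented in the table file and can be replaced wholesale with
`read_block_table()` for sensitivity analyses.

## The synthetic conformer generator

Real structure sets of the size needed for stable profiles are external
data; the package instead ships a generator that builds single side chains
in GLY–X–GLY tripeptides at *exact, user-specified torsions* from standard
covalent geometry (Engh–Huber-type bond lengths and angles), NeRF-style:
each atom is placed from three reference atoms by bond length, bond angle
and torsion. Key geometric choices:

* The C$\beta$ improper torsion is derived from the three bond angles at
  C$\alpha$ by spherical trigonometry (about $-123^\circ$), which fixes the
  L configuration; branch offsets (VAL C$\gamma2$ at $\chi_1 + 120^\circ$,
  ILE C$\gamma2$ at $\chi_1 + 230^\circ$, THR C$\gamma2$ at $\chi_1 +
  238^\circ$, LEU C$\delta2$ at $\chi_2 + 120^\circ$) were fixed against
  measured values in deposited structures.
* Aromatic rings are rigid planar templates driven by $\chi_1/\chi_2$; the
  six-membered ring is a regular hexagon (1.383 Å, 120°), so it closes
  exactly. The five-membered rings of HIS/TRP/PRO use experimental internal
  angles and close approximately; the residual closure error is well below
  anything the 0.05 Å binning can resolve.
* PRO uses a fixed endo-pucker template and exposes no free $\chi$.
* Flanking-glycine torsions are fixed constants; they affect no feature of
  the central residue.

`sample_ensemble()` draws from a mixture of torsion components (component
chosen by weight, independent Gaussian noise per torsion) and redraws
clash-failing conformers — a pair of heavy atoms three or more bonds apart
closer than 2.0 Å — up to 100 times, keeping ensembles physical without
biasing component frequencies. Everything is reproducible from the spec's
seed.

What the generator emulates is the *geometry* of conformational variation:
exact torsions, ideal covalent parameters, Gaussian angular spread. What it
does not emulate: experimental coordinate error, refinement restraints,
backbone-dependent rotamer correlations, crystal contacts, or the
heterogeneous resolution of real data sets. Tests passing on synthetic
ensembles therefore validate the *measurement and binning machinery*, not
claims about any particular experimental data set.

## Profiles, npdf and 2D histograms

Features are binned into half-open bins $[e, e + w)$ anchored at 0, with
default widths 5° for angles and 0.05 Å for block lengths; densities are
count/(N·width). A *normalized* pdf (npdf) divides **both** curves of a
comparison by the peak density of the designated reference set, so the
reference peaks at exactly 1 and the other curve is read as a ratio against
the reference's mode (it may exceed 1). 2D histograms (default
$(\varphi, d_{\mathrm{Block}})$; any feature pair is supported) are
normalized by their own modal cell, so each cell holds a population ratio in
$[0, 1]$ relative to the most popular conformation.

Numerical choices, made once:

* **Bin anchors at 0** for both angles and lengths, giving reproducible bin
  centers (2.5°, 0.025 Å offsets).
* **Peak calling**: a local maximum must be strictly greater than both
  neighbours; plateaus resolve to their leftmost bin; peaks below 5% of the
  global maximum are suppressed by default (single-count bins at realistic
  sample sizes produce spurious maxima below that level). Both thresholds
  are arguments.
* **Exceedance calls** in `compare_sets()` (where set B's npdf is above set
  A's) must persist over at least 2 consecutive bins. A visual "curve B is
  above curve A in this region" judgment has no single formalization; the
  minimal-width rule makes the call testable and robust to one-bin noise
  while leaving genuinely narrow features (≥ 0.1 Å wide at default binning)
  detectable.
* **Degenerate geometry** (collinear torsion quadruples, missing atoms)
  always yields a missing feature, never an imputed value; missing-feature
  counts are logged per structure.
* No smoothing, no kernel density estimation, and no significance testing:
  the comparisons are descriptive, and adding inferential machinery would
  suggest a precision the underlying selection policies cannot support.

## Selection policies

Crystallographic sets conventionally contribute one chain per structure
(`chains = "first"`) and the first alternate location of each atom in file
order; EM sets contribute all chains, because NCS copies are modeled
independently and each is a conformation observation. The policy is explicit
configuration (`selection_policy()`), not inferred from the file. Adjacent
residues are treated as peptide-bonded only when the C–N distance is below
2.0 Å, so chain breaks suppress $\varphi/\psi$ across gaps. Non-standard
residues (including MSE) are dropped and counted by default; the analysis
covers the 20 standard types.

## Problem sizes and known limitations

The validation suites run at desk scale by design: modal-length calibration
uses single conformers; rotamer grids enumerate 9–81 conformers;
mode-recovery suites use two-component mixtures at $n = 10^4$ samples and
$\sigma = 5^\circ$ across 5 seeds; comparison suites use $n = 6 \times 10^3$
per set. At these sizes the 0.05 Å bin grid resolves component modes to one
bin with large margin; the sizes are stated here so that profile noise in
other applications can be judged against them.

Limitations worth knowing:

* $\chi_2$–$\chi_4$ distributions, block orientation, and ring-flip
  symmetry (PHE/TYR/ASP/GLU two-fold ambiguity) are out of scope; symmetric
  rotamers are counted as distinct.
* The generator's clash screen is a hard-sphere heavy-atom rule, not an
  energy; grids over $\chi$ space are "clash-free", not Boltzmann-weighted.
* The ideal-geometry TYR hydroxyl lies almost on the $\chi_2$ rotation
  axis, so its clash-free grid spans only ~0.002 Å of block length — the
  spread seen in real data comes from covalent-geometry variation that the
  generator deliberately does not model.
* mmCIF input is not supported; PDB-format text is the only input dialect.
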