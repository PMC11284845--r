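---
title: "Untangling transition-state conformer ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untangling transition-state conformer ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsel)
```

## The problem

Selectivity between two competing reaction pathways under Curtin–Hammett
conditions is governed entirely by the free energies of the transition
states (TSs), not by the reactant conformer populations: interconversion
among reactant conformers is fast relative to the product-forming steps.
Modern conformer-generation tools produce large ensembles of TS
structures per pathway, and turning such an ensemble into a product ratio
requires a modelling commitment about *interconvertibility*:

* If all TS conformers of a pathway interconvert freely (rotamers
  separated by negligible barriers), they form one thermodynamic pool.
  The pool behaves like a single TS at the Boltzmann-weighted ensemble
  energy
  $\Delta G^{\mathrm{ens}} = \sum_j w_j\,\Delta G_j^{\ddagger}$, with
  $w_j = e^{-\Delta G_j^{\ddagger}/RT}\big/\sum_k e^{-\Delta G_k^{\ddagger}/RT}$.
  This weighted arithmetic mean always lies *above* the pool minimum, so
  each extra high-energy conformer raises the apparent barrier.
* If no two conformers interconvert (families locked behind high
  second-order saddle points), each is a parallel pathway and Eyring rate
  constants add:
  $k_{\mathrm{eff}} = \tfrac{k_B T}{h} \sum_j e^{-\Delta G_j^{\ddagger}/RT}$,
  equivalent to an effective barrier
  $\Delta G^{\ddagger}_{\mathrm{eff}} = -RT\ln\sum_j e^{-\Delta G_j^{\ddagger}/RT}$,
  which always lies *at or below* the pool minimum, so each extra
  low-energy conformer (including an accidental duplicate) lowers it — a
  duplicate of the lowest TS by up to $RT\ln 2 \approx 0.41$ kcal/mol at
  298 K.

The product ratio in either case is
$[\mathrm{a}]/[\mathrm{b}] = e^{-\Delta\Delta G^{\ddagger}/RT}$.
Because the two treatments err in opposite directions, the same raw
ensemble can be post-processed into essentially any selectivity. The
package's *cluster-resolved* treatment is the hybrid that is correct when
the clustering is: Boltzmann-average within each interconvertible family,
then sum rates across families. It collapses algebraically to the pure
Boltzmann treatment when each pathway is a single cluster and to pure
rate summation when every cluster is a singleton — both collapses are
asserted numerically in the test suite.

Two concealed error modes motivate the clustering machinery:

* **Repeated conformers.** The same TS can appear several times in an
  ensemble, possibly with the atom indices of symmetry-equivalent atoms
  permuted (a rotated tert-butyl or phenyl), defeating naive RMSD
  deduplication. `duplicate_sensitivity()` quantifies the resulting
  barrier distortion under rate summation.
* **Interconversion errors.** Treating locked families as one Boltzmann
  pool (or free rotamers as parallel pathways) biases the prediction in a
  direction set by the energy ordering, not by chemistry.

## The clustering workflow

`cluster_ensemble()` chains five stages.

**1. Compound dissimilarity** (`compound_matrix()`). Three pairwise
metrics, each defensible on its own but incommensurate with the others:

* *Symmetry-corrected heavy-atom RMSD* (Å): the minimum over all
  element-preserving isomorphisms of the two heavy-atom bond graphs of the
  Kabsch RMSD (optimal translation + proper rotation). Restricting the
  rotation to determinant +1 means mirror images do **not** superimpose:
  enantiomeric TSs are chemically distinct pathways. Hydrogens are
  excluded throughout — they dominate atom counts but carry little
  conformational signal. Isomorphisms are enumerated with VF2 (igraph)
  with element labels as vertex colors; enumeration is capped (default
  10 000) because the automorphism count is exponential in the worst
  case, and a hit sets a `truncated` flag and keeps the identity-like map
  so the result never exceeds the naive RMSD.
* *Torsion distance* (degrees): torsions are detected once on the first
  structure — one canonical quadruple per rotatable bond (a non-ring
  heavy-heavy bond whose atoms each have a second heavy neighbor;
  reference atoms are the lowest-index heavy neighbors) — and evaluated
  on every frame by atom index. The metric is the mean circular
  difference, in [0, 180]. Because the quadruples are index-based, a
  frame whose equivalent atoms were index-permuted can read a different
  angle if the permutation touches a reference atom; the RMSD metric is
  the symmetry-aware one, and the synthetic template below is built so
  its automorphisms avoid the torsion path entirely.
* *Energy distance* (kcal/mol): $|E_i - E_j|$. Requesting it with
  incomplete energies is a configuration error rather than a silent
  degradation; `cluster_ensemble()` drops the metric with a warning when
  energies are absent.

Each component is min–max normalized to [0, 1] before fusion, and the
fused matrix is the weighted mean (equal weights by default). Raw
Å/degrees/kcal·mol⁻¹ cannot be averaged directly; min–max is the simplest
scale-free choice and is recorded in the run log. A component whose
spread is below 1e−10 (relative) is treated as constant and mapped to
all-zero: ensembles of exact copies produce ~1e−16 RMSD float noise that
naive normalization would amplify to full scale. Genuinely small spreads
— ensembles differing by 0.01 kcal/mol — sit far above this guard.

**2. Embedding** (`embed_mds()`). Classical (Torgerson) metric MDS into
`min(n − 1, 5)` dimensions by default. k-means needs coordinates, not
distances; classical MDS is deterministic, and the Kruskal-type stress is
reported so a poor embedding is visible in the run log.

**3. Model selection** (`choose_k()`). For each k in 2..min(10, n − 1),
k-means (10 restarts, seeds derived from the top-level seed) scored by
mean silhouette width; the argmax wins, ties toward smaller k. The
silhouette is undefined at k = 1, yet a single interconvertible family is
a common and important answer. The declared policy: if the best
silhouette over all candidate k is below 0.40, declare one cluster. 0.40
is the conventional boundary between "weak/artificial" and "reasonable"
silhouette structure; it is configurable
(`single_cluster_threshold`) and recorded in the log.

**4. Partition.** k-means at the chosen k, re-run under the same derived
seed that scored it, so the returned labels are exactly the scored
partition.

**5. Representatives** (`pick_representatives()`). The minimum-energy
member of each cluster (ties → lowest index); this is the structure one
would re-optimize at a higher level of theory. Without energies the
member nearest the cluster centroid in the embedding is used instead.

## Selectivity arithmetic

Constants: R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹, k_B/h = 2.083661×10¹⁰
s⁻¹ K⁻¹, default T = 298.15 K (printed ratios are insensitive to the
0.15 K difference from "298 K" at the reported precision). All
exponentials are shift-stable (minimum subtracted before
exponentiation), so spreads of hundreds of kcal/mol neither overflow nor
underflow. Percentages are rounded to integers forced to sum to 100,
the larger side absorbing the remainder — matching the conventional
"98:2" presentation.

The ensemble free energy is the Boltzmann-weighted *arithmetic mean* of
the conformer energies, not the partition-function free energy
$-RT\ln\sum_j e^{-G_j/RT}$ (that is the rate-sum expression): the mean is
the quantity with the "always above the pool minimum" property that makes
the repeated-high-conformer pitfall visible, and the package keeps the
two deliberately distinct.

The reference-state mole fraction is neglected (standard under
Curtin–Hammett conditions); symmetry numbers for degenerate TSs are not
auto-applied — a user expresses degeneracy by listing a conformer twice
*deliberately*, since accidental duplication is exactly the pitfall the
tool flags. In `read_pathway_csv()` a missing `cluster` column makes
every conformer its own cluster, which reduces cluster-resolved to rate
summation; this is the conservative choice (no interconversion assumed)
and clustering output can be merged in via `labels_path`.

## The synthetic generator

`generate_ensemble()` plants known structure so the whole pipeline is
testable without external data: torsional families of one molecule
(large rotor-angle separation), small intra-family coordinate jitter,
family-level energy offsets, and index permutations of
symmetry-equivalent atoms.

The template (`make_rotor_template()`) is a small HO–CF2–C(H)(CH3)–OH
fragment rather than the obvious para-substituted ring. The reason is a
subtle interaction: on a ring rotor the torsion reference atoms are
themselves the symmetry-equivalent pair (the two ortho carbons), so an
automorphism permutation flips the measured dihedral by ~180° and
corrupts the torsion metric for permuted members. The CF2 fluorine pair
is symmetry-equivalent (the graph's only non-trivial automorphism) but
lies off the torsion path O1–C2–C3–O4, so a permuted copy defeats naive
index-based RMSD — the planted error mode — while torsions stay
well-defined. The geometry is an idealized tetrahedral construction;
energies are *assigned* (offset + Gaussian noise), not computed: the
generator emulates the clustering-relevant features of real TS ensembles
(families, jitter, offsets, permutations) and nothing else. A green
recovery test therefore establishes that the pipeline separates
well-separated torsional families under realistic jitter — not that it
reproduces any particular quantum-chemistry ensemble.

Defaults are the stated world of the tests: two families at 0° and 180°,
offsets 0 and 3.2 kcal/mol (the family gap observed in real TS
ensembles), 10 members each, jitter σ = 0.05 Å, energy noise σ = 0.05
kcal/mol (well under the family gap, so planted recovery is
unambiguous), permute fraction 0.25. A warning fires when family angles
are closer than 5× the angular jitter the coordinate noise induces
(≈ √2·σ/1.4 rad for reference atoms ~1.4 Å off the axis), since the
planted structure may then be unrecoverable. Jitter is applied after the
torsion is set, so the expected intra-family RMSD scales as ≈ σ√2.

## Numerical choices and degenerate inputs

* Silhouette ties across k: smaller k wins (parsimony).
* Representative energy ties: lowest structure index.
* k-means candidates are also capped by the number of *distinct*
  embedded points; an all-identical ensemble short-circuits to k = 1.
* A single-frame ensemble is trivially one cluster (logged as a
  warning in the CLI).
* Energy-unit autodetection: |E| > 100 in an XYZ comment is read as
  Hartree (×627.5094740631); relative TS energies are small, absolute
  electronic energies are hundreds of Hartree. Explicit unit tokens or
  the `energy_unit` flag override.
* Bond perception: distance ≤ 1.25 × sum of single-bond covalent radii
  (Cordero-style table). 1.25 is a common heuristic; perception is
  rigid-motion invariant and the bond count is monotone in the
  tolerance.

## Known limitations

* The torsion metric is index-based and not symmetry-aware (see above);
  with the default metric set the symmetry-corrected RMSD and energy
  metrics dominate when permutations are present.
* Exact isomorphism handling is exponential; the cap trades completeness
  for boundedness and is surfaced via the `truncated` flag, never
  silently.
* Ensembles must be conformers of one molecule (isomorphic heavy-atom
  graphs); there is no maximum-common-substructure matching.
* No tunneling corrections, variational TS theory, microkinetics or
  temperature-dependent free-energy interpolation: the arithmetic is
  exactly the three treatments above.
* Clustering quality on real ensembles depends on the metric weights and
  the silhouette threshold; the defaults are sensible, not universal,
  and every run log records them.
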