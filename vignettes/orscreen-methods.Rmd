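---
title: "Methods and design notes for orscreen"
author: "orscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for orscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

orscreen implements the desk-scale computational core of an in silico
olfactory-receptor / odorant workflow: assessing predicted receptor
structures, partitioning an odorant descriptor space into clusters and
picking representative molecules, and statistically evaluating docking
scores produced by external engines. This vignette documents the models and
procedures, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, and the numerical
decisions a maintainer should know about.

## Structural comparison

### Superposition and the iterative-pruning RMSD

Two structures are compared on their paired C-alpha atoms. Pairing is by
identical residue numbering (`pair_residues(..., "numbering")`) or, for
structures with different numbering or gaps, by a global
Needleman-Wunsch sequence alignment (BLOSUM62, affine gap open 10 /
extend 0.5, the conventional protein defaults) with only aligned non-gap
columns paired. The rigid fit is the standard Kabsch least-squares
superposition, computed from the SVD of the 3x3 cross-covariance, with the
usual determinant sign correction so reflections are never returned.

A plain all-pair RMSD is dominated by flexible loops and locally divergent
regions. `pruned_rmsd()` therefore iterates the common pruning protocol:
after each fit, with `N` current pairs of which `E` exceed the distance
cutoff, the

```
r = max(1, min(floor(0.10 * N), floor(0.50 * |E|)))
```

farthest pairs are removed (ties broken toward the earlier residue for
determinism) and the fit recomputed, until no pair exceeds the cutoff. The
default cutoff is 2.0 Angstrom. Percentages are taken of the *current*
pair count at each cycle, and the `max(1, ...)` floor guarantees progress;
pruning stops (flagged non-converged) rather than drop below 3 pairs.
The result reports both the first-fit all-pair RMSD and the final pruned
RMSD with the retained pair list, so the "core" agreement and the global
agreement are always shown together.

### Ensemble observables

`ensemble_rmsd()` fits every model of a multi-MODEL ensemble to a chosen
reference and records its RMSD, emulating an RMSD-versus-time trajectory
series. `rmsf()` uses the mean structure as the fluctuation reference,
computed in two passes (fit to model 1, average, refit to the average):
the reference-structure choice is a genuine open point in this kind of
analysis and the iterated mean is the standard convention. Because any
least-squares superposition absorbs a fraction of a localized displacement
(about 1/n of it goes into the translation alone), a single atom moved by
1 Angstrom in an n-atom selection reports an RMSF slightly below 1; the
tests quantify this. `radius_of_gyration()` supports uniform and
mass-weighted centroids.

### Benchmark summarisation

`summarize_rmsd_table()` reduces a structure-by-method RMSD table to
per-method mean/sd/min/max, skipping missing cells with a warning. The
package ships a 15-structure GPCR prediction benchmark
(`inst/extdata/gpcr_rmsd_unpruned.csv` and `..._pruned.csv`, four
prediction protocols per structure) whose per-method means are recomputed
by the acceptance script.

## Geometry quality control

`phi_psi()` computes backbone dihedrals with the standard atan2 torsion
(IUPAC sign, reported in [-180, 180)); a peptide C-N distance above
2.5 Angstrom is treated as a chain break, leaving the adjacent dihedrals
undefined. Residues are classed General / Gly / Pro / PrePro, glycine and
proline having famously different accessible regions.

`classify_rama()` labels each defined pair Favored / Allowed / Outlier by
point-in-polygon tests with full torus wraparound (the polygons are tested
against all +/-360 translates of the point). The shipped region table
(`rama_region_table()`) is a simplified polygonal rendering of the
high-resolution contour conventions: rectangles-on-the-torus around the
alpha, beta and left-handed-alpha basins, widened for glycine (near
symmetric), narrowed for proline (ring-pinned phi), and shifted for
pre-proline. Published contour sets differ between tools and versions, so
the table is deliberately an explicit, swappable asset rather than a
hard-coded truth; percentages computed from it are comparable between runs
of this package but not directly against other software. The
classification of the canonical alpha point (-63, -43) as Favored and of
the implausible upper-right quadrant point (+100, +150) as a General-class
Outlier are pinned by tests.

`bond_angle_deviations()` flags backbone bonds (N-CA, CA-C, C-O, peptide
C-N) and angles (N-CA-C, CA-C-N, C-N-CA, CA-C-O) deviating more than
`z_threshold` (default 4) standard deviations from the Engh-Huber-style
ideal table (`ideal_backbone_table()`). The table is backbone-only: that
subset suffices to exercise the counting mechanism, and the helix
generator builds from the same table so an unperturbed helix scores zero
flags by construction.

`clashscore()` counts unordered heavy-atom pairs whose van der Waals
spheres interpenetrate by at least 0.4 Angstrom, normalised per 1000
atoms. Pairs within three covalent bonds are excluded; connectivity is
inferred from backbone templates (N-CA, CA-C, C-O, CA-CB, peptide C-N)
plus distance-based bonding (< 1.9 Angstrom) for side-chain and
non-standard atoms — full per-residue chemistry templates would change
nothing for the backbone-scale structures this package evaluates.
Neighbour search uses spatial grid hashing (cell size = the largest
possible contact distance), giving linear scaling; the hash path is
tested for exact equality against an all-pairs search.

`sasa()` is a deterministic Shrake-Rupley: each heavy atom is covered
with a Fibonacci-lattice point set (default 960 points; fewer than 32 is
refused as too coarse for meaningful areas) at radius r + 1.4 Angstrom
(water probe), and a point is accessible when outside every neighbour's
expanded sphere. Against closed-form references the defaults land within
1% for an isolated atom and within 2% of the spherical-cap solution for
two overlapping atoms.

## Chemical-space clustering and representative selection

The intended input is a molecules-by-descriptors table (the package reads
a CSV with id and optional SMILES columns). Descriptor *computation* from
SMILES is out of scope by design — any engine can feed the CSV — which
keeps the clustering core testable without a cheminformatics dependency.

Processing order: `clean_descriptors()` (drop non-finite and constant
columns), `correlation_filter()` (drop any column with |Pearson r| above
0.95 against an already-kept column; keep-first order makes the result
deterministic since some member of each correlated pair must go),
`pca_descriptors()` (z-score standardisation, components ordered by
variance, sign fixed so the largest-magnitude loading is positive), then
K-means on the retained scores. The retained dimension defaults to 2 —
clustering and plotting happen in the same plane — and can be set by count
or cumulative-variance target.

K-means is Lloyd's algorithm from k-means++ seeding, best of `n_init = 10`
restarts by the objective `WCSS = sum_j sum_i ||x_i - c_j||^2`; empty
clusters are repaired by reseeding at the farthest point, and convergence
is declared at a centroid shift below 1e-8. A practical numerical note:
nearest-centroid assignment must use an exact argmin — R's `max.col`
declares ties at about 1e-5 relative tolerance and breaks them randomly,
which silently corrupts degenerate configurations such as k close to n.

Cluster-number selection (`select_k()`) evaluates every k in the range
(default 2-10) with five criteria:

* a Gaussian log-likelihood built from the WCSS,
  `ln L = -(n m / 2)(ln(2 pi sigma^2) + 1)` with the isotropic MLE
  `sigma^2 = WCSS / (n m)`, feeding `AIC = 2p - 2 ln L` and
  `BIC = p ln n - 2 ln L`. The parameter count is `p = k m + 1`
  (k centroids in m dimensions plus one shared variance); both the
  variance policy and the parameter count are single points of truth in
  the code and easy to swap. Only differences across k matter for
  selection, but the constants are kept so the values are absolute.
  `BIC - AIC = p (ln n - 2)` identically, which the tests pin.
* mean silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` (singleton
  points are scored 0 and flagged),
* Davies-Bouldin with sigma_i the mean member-centroid distance,
* Calinski-Harabasz from the between/within dispersion traces,
* the WCSS curve itself, returned for elbow inspection.

The chosen k is the mode of the five criterion winners, ties broken by the
BIC winner. A `weak_structure` flag is raised when the best silhouette
over the whole range stays below 0.5: in the Kaufman-Rousseeuw reading,
values below that band mean weak or artificial structure. (A stricter
0.3 cut was considered and rejected: splitting a single isotropic 2-D
Gaussian — the no-structure null — already yields mean silhouettes around
0.32-0.37, so 0.3 would miss exactly the case the flag exists for. The
well-separated study condition sits near 0.9, far from either band.)

Representatives are chosen per cluster by centroid proximity in the PCA
space, `d_i = sqrt(sum_j (x_ij - c_j)^2)`, taking the `m_per_cluster = 4`
nearest molecules in increasing-distance order (ties by input order);
with 5 clusters this yields the canonical 20 selections. Clusters smaller
than the request return all members and are flagged truncated.

## Docking-score statistics

Scores arrive as a validated CSV (receptor, ligand, engine, value,
optional pre-binarised responsiveness label; binarisation thresholds are
the caller's responsibility because they are assay-specific).
`kruskal_wallis()` is the rank-based omnibus test across receptors (tie
correction reported; the all-identical degenerate case is reported as
H = 0, p = 1). `dunn_posthoc()` computes the pairwise z statistics from
the pooled rank means with tie correction; p-values are two-sided and
Bonferroni-adjusted by default, capped at 1.00 — a conservative,
assumption-free default for the small numbers of receptor pairs involved.
With two groups and no adjustment, the Dunn z-squared equals the
Kruskal-Wallis H, which the tests verify numerically.

`roc_auc()` uses the Mann-Whitney rank formulation (half credit for
ties), so the AUC is exactly the probability that a random active
outranks a random inactive; the stored step curve integrates to the same
number by construction. Orientation defaults to `lower_is_active`
because binding energies are better when more negative; CNN-style
pose scores should use `higher_is_active`.

## Synthetic generators: what they emulate, and what not

All generators are pure functions of their parameters and seed.

* `build_helix()` constructs N/CA/C/O backbones by natural-extension
  (NeRF) internal-to-Cartesian placement from the ideal geometry table
  and prescribed phi/psi/omega. It exists so that dihedral computation can
  be tested as an exact round trip and so geometry QC has a known-clean
  input. It produces no side chains, no hydrogens and no packing — it is
  a geometric fixture, not a physical protein.
* `perturb_structure()` applies a rigid motion, optional i.i.d. Gaussian
  coordinate noise and a fixed displacement of a residue subset,
  producing "core + outlier" pairs with known ground truth for the
  pruning protocol.
* `gen_mixture()` draws a Gaussian mixture in descriptor space. The
  defaults are the package's reference study condition: 5 components in
  2-D, unit sigma, 30 points each, centres on a pentagon of circumradius
  10 (pairwise separation about 11.8 sigma) — well-separated so that
  cluster-number recovery is a sharp test. Passing smaller `separation`
  gives a deliberately hard mode for diagnostic behaviour, and
  `nuisance = TRUE` appends an exact linear copy and a near-copy
  (r about 0.96) to exercise the correlation filter. Real descriptor sets
  are not Gaussian, not isotropic and not label-balanced; passing these
  tests shows the selection machinery is correct, not that real chemical
  space has five clusters.
* `gen_scores()` draws per-receptor Gaussian energies with an activity
  shift delta, so the true AUC is the binormal value Phi(delta / sqrt 2)
  and test assertions have an analytic target. Real docking scores are
  heavier-tailed and engine-correlated; the generator emulates location
  shifts and labels only.

## Problem sizes and determinism

The shipped tests and the acceptance script use deliberately small
problem sizes — helices of 10-400 residues, 150-point mixtures, 20
recovery seeds, 1000 null replicates, 4000-score ROC samples — chosen so
the whole suite re-runs in well under a minute while keeping every
stochastic assertion's sampling error an order of magnitude inside its
band. Every stochastic routine takes an explicit seed, seeds are applied
in a local RNG scope (the caller's RNG state is restored), and identical
inputs give bitwise-identical outputs; the command-line layer writes a
manifest (command, parameters, seed, package version) next to every
output set.

## Known limitations

* The Ramachandran polygons are simplified conventions, not fitted
  contours; absolute favored/outlier percentages are not comparable to
  other tools.
* The geometry report exposes clashscore, Ramachandran and covalent
  deviations separately; it deliberately does not combine them into a
  single resolution-calibrated score, whose calibration constants belong
  to a specific external implementation.
* mmCIF and binary trajectory formats are not read; multi-MODEL PDB is
  the ensemble interchange format.
* Rotamer, C-beta deviation and backbone-CA geometry outlier analyses
  are out of scope.
* The alignment pairing mode aligns the concatenated sequence of
  CA-bearing residues; receptors with duplicated chain architecture
  should be paired chain by chain upstream.
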