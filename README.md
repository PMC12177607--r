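# orscreen

Desk-scale tools for an in silico olfactory-receptor / odorant workflow.
Olfactory receptors (ORs) are GPCRs with essentially no experimental
structures, so their study runs on predicted models, clustered odorant
libraries and docking scores — and every step needs quantitative quality
control. orscreen provides that computational core as a tested R library
with a command-line layer:

* **Structure comparison** — PDB (multi-MODEL) I/O, Kabsch superposition,
  and the iterative-pruning RMSD protocol: pairs more than 2.0 Å apart are
  progressively removed (per cycle, the fewer of the 10% farthest pairs or
  50% of the cutoff-exceeding pairs) and the fit recomputed until the
  retained structural core all sits within the cutoff. Ensemble
  observables: per-model RMSD series, per-residue RMSF against the
  iterated mean structure, radius of gyration.
* **Geometry QC** — backbone φ/ψ dihedrals with Ramachandran
  classification per residue class (General/Gly/Pro/PrePro), bond/angle
  deviation counts against ideal backbone geometry, steric clashscore
  (≥ 0.4 Å van der Waals overlap per 1000 atoms), and Shrake–Rupley
  solvent-accessible surface area.
* **Chemical-space clustering** — descriptor cleaning, Pearson |r| > 0.95
  collinearity filtering, PCA, K-means (k-means++/Lloyd) with
  cluster-number selection by consensus of AIC, BIC, silhouette,
  Davies–Bouldin and Calinski–Harabasz
  (AIC = 2p − 2 ln L̂, BIC = p ln n − 2 ln L̂ with the Gaussian likelihood
  built from WCSS = Σ<sub>j</sub> Σ<sub>i</sub> ‖x<sub>i</sub><sup>(j)</sup> − c<sub>j</sub>‖²),
  and representative-molecule selection by centroid proximity
  d<sub>i</sub> = √Σ<sub>j</sub>(x<sub>ij</sub> − c<sub>j</sub>)² in PCA space.
* **Docking-score statistics** — Kruskal–Wallis across receptors, Dunn's
  post hoc with Bonferroni capping, ROC/AUC (Mann–Whitney rank form,
  lower-is-active orientation for binding energies).
* **Synthetic generators** — seeded ideal-geometry helices, core+outlier
  structure pairs, Gaussian-mixture descriptor sets and two-population
  score tables, so every analysis is testable offline with known ground
  truth.

## Worked example

Summarise a structure-prediction benchmark (15 experimental GPCR
structures × 4 prediction protocols, unpruned RMSD in Å; bundled under
`inst/extdata/`):

```r
library(orscreen)
tab <- read.csv(system.file("extdata", "gpcr_rmsd_unpruned.csv",
                            package = "orscreen"), check.names = FALSE)
summarize_rmsd_table(tab)
#>                method  n  mean     sd   min   max
#> 1 hybrid_af_templates 15 2.090 0.5741 1.145 3.428
#> 2     hybrid_human_af 15 2.146 0.5954 1.403 3.333
#> 3                 af3 15 2.551 0.5386 1.741 3.279
#> 4                 af2 15 2.244 0.6679 1.403 3.359
```

The hybrid protocol using homologous templates has the lowest mean RMSD
(2.090 Å); the direct AF3 predictions average 2.551 Å on the same set.

Pruned-RMSD comparison of a structure against a noisy copy with six
displaced residues:

```r
ref <- build_helix(40)
mob <- perturb_structure(ref, translation = c(4, 0, 0), noise_sd = 0.3,
                         displaced = 35:40, displacement = c(6, 0, 0),
                         seed = 7)
pruned_rmsd(ref, mob)
#> superposition: RMSD 1.921 A over 40 pairs; pruned 0.525 A over 34 pairs
#> (4 iterations, cutoff 2.0 A)
```

The six planted outliers are exactly the pairs removed: the all-pair RMSD
(1.92 Å) reflects the displaced tail, while the 34-pair core agrees to
0.53 Å — the separation of conserved core from divergent region that the
pruning protocol exists for.

Cluster a descriptor set and pick representatives:

```r
gm <- gen_mixture(seed = 11)            # 5 planted components, 150 molecules
sel <- select_k(gm$dm$values, k_range = 2:8, seed = 11)
sel$k                                   # consensus of 5 criteria -> 5
km <- sel$fits[[paste0("k", sel$k)]]
reps <- select_representatives(km, centroid_distances(gm$dm$values, km),
                               m_per_cluster = 4, ids = gm$dm$ids)
reps
#> representative_set: 20 molecules (4 per cluster requested)
head(as.data.frame(reps), 4)
#>   cluster     id index  distance
#> 1       1 mol145   145 0.2377669
#> 2       1 mol133   133 0.2994012
#> 3       1 mol131   131 0.4029913
#> 4       1 mol147   147 0.4057943
```

Evaluate docking scores:

```r
sc <- gen_scores(receptors = c("OR51E1", "OR51E2"), shifts = c(0, -1),
                 n_ligands = 60, delta = 1.2, seed = 3)
kruskal_wallis(split(sc$value, sc$receptor))
#> Kruskal-Wallis: H = 11.6391, df = 1, p = 0.0006458
e1 <- sc[sc$receptor == "OR51E1", ]
roc_auc(e1$value, e1$responsive)
#> ROC: AUC = 0.870 (30 active / 30 inactive, lower_is_active)
```

The Kruskal–Wallis test detects the 1 kcal/mol location shift between the
receptors, and the AUC of 0.87 says a random active ligand out-scores a
random inactive one 87% of the time under the energy ordering.

Assess a model's geometry:

```r
quality_report(build_helix(30))
#> geometry report: 30 residues | Ramachandran favored 100.0% / outliers 0.0%
#> | bad bonds 0 (0.00%) | bad angles 0 (0.00%) | clashscore 0.0
#> | SASA 1714 A^2
```

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/orscreen`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "orscreen", package = "orscreen"))')" \
    compare-structures ref.pdb model.pdb --cutoff 2.0 --out results/
```

Subcommands: `compare-structures`, `assess-structure`, `ensemble-analyze`,
`summarize-benchmark`, `cluster-ligands`, `eval-docking`, `simulate
helix|mixture|scores`. Every run writes its outputs plus a
`manifest.json` (command, parameters, seed, package version) sufficient to
reproduce it.

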