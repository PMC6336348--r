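# rifsite

Predict protein–protein binding sites on a receptor structure from
ensembles of rigid-body docked poses of *unrelated* probe proteins.

Protein interfaces act as generic "sticky" surface patches: probes that
share no relationship with a receptor's biological partner still dock
preferentially at the cognate binding site. `rifsite` exploits this by
counting, for every receptor residue *i*, the number of docked poses in
which the residue contacts the probe (any atom within 3.5 Å of any
probe atom):

    N_i = Σ_k I(R_ik),   I(R_ik) = 1 if residue i is at the interface of pose k

The **Residue Interface Frequency** `N_i` ranks the residues; the top
K = 15 are the predicted binding site. Prediction significance is
assessed against the hypergeometric chance model

    P(X = x) = C(M, x) C(N−M, K−x) / C(N, K)

where `N` is the pool of residues touched at least once during docking
and `M` the annotated interface residues inside it, with a
complementary resampling Z-score (200 random K-draws from the pool,
significance at Z > 1.97). Residue-level quality is reported as
precision / recall / F-score and ROC/AUC over the `N_i` score.

The package is aimed at structural bioinformaticians who have (or can
generate) rigid-body pose ensembles: it provides the contact
statistics, ranking, significance and evaluation machinery, a generic
adapter for externally docked pose transforms, a built-in geometric
pose sampler for exercising the stack, and a fully seeded synthetic
benchmark generator with a known interface-enrichment model for
calibration studies.

## Worked example

A 150-residue toy receptor with a known 15-residue interface patch, and
a 2000-pose synthetic ensemble whose patch centres favour the true
interface threefold:

```r
library(rifsite)

toy   <- make_toy_receptor(n_residues = 150, interface_size = 15, seed = 42)
model <- synthetic_pose_model(n_poses = 2000, enrichment = 3)
ens   <- sample_contact_ensemble(toy$structure, toy$annotation, model, seed = 43)

prof <- compute_rif(ens, residue_ids(toy$structure), receptor_id = "toy")
prof
#> rif_profile 'toy': 2000 poses, 150/150 residues sampled, max N_i = 315

top <- rank_top_k(prof, 15)
head(top)
#> [1] "A:53" "A:40" "A:74" "A:66" "A:61" "A:32"

significance_from_profile(prof, toy$annotation, mode = "upper_tail", seed = 44)
#> rif_significance: x=14 of K=15 (M=15, N=150); p=1.248e-17 [upper_tail] *
#>   resampling null: mu=1.470 sigma=1.129 Z=11.095 *

precision_recall_f(top, toy$annotation)
#> rif_metrics: TP=14 FP=1 FN=1 | precision=0.933 recall=0.933 F=0.933

roc_auc(prof, toy$annotation)$auc
#> [1] 0.9990123
```

Reading the output: 14 of the 15 top-ranked residues lie on the true
interface. Under the chance model (15 interface residues in a
150-residue sampled pool) that overlap has an upper-tail probability of
~1e-17, and sits 11 standard deviations above the resampling null mean
of 1.47 — the prediction is unambiguously significant, with an F-score
of 0.93 against the annotation.

Real structures enter through `read_structure()` (PDB), cognate
complexes through `annotate_interface()`, and externally docked poses
through `import_pose_transforms()` (plain-text rotation+translation
tables). `run_predict()`, `run_evaluate()`, `run_simulate()` and
`run_benchmark()` orchestrate full runs and write TSV/JSON reports; the
same four commands are available from the shell via `exec/rifsite`.

See `vignettes/rif-method.Rmd` for the model, its assumptions, the
synthetic generator's scope, and calibration behaviour.

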