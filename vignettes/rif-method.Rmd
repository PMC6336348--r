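---
title: "Binding-site prediction by residue interface frequency: model, assumptions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site prediction by residue interface frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifsite)
```

## The idea

Protein–protein interfaces behave like generic "sticky" patches: when a
receptor is rigid-body docked against protein probes that are *not* its
biological partner, the docked poses still accumulate preferentially at
the cognate binding site. `rifsite` turns this observation into an
*ab initio* binding-site predictor that needs no knowledge of the true
ligand.

For receptor residue $i$ and docked pose $k$, let $I(R_{ik}) = 1$ when
residue $i$ has any atom within 3.5 Å of any probe atom in that pose,
and 0 otherwise. Over an ensemble of $n$ poses the **residue interface
frequency** is

$$N_i = \sum_{k=1}^{n} I(R_{ik}).$$

Residues are ranked by $N_i$ and the top $K = 15$ form the predicted
binding site. The residues with $N_i \ge 1$ constitute the *sampled
pool* of size $N$; this pool — not the whole chain — is the population
against which chance is measured, because residues the docking never
touches carry no evidence either way. (A `n_definition = "all"` switch
in `significance_from_profile()` allows whole-chain pools for
sensitivity analysis.)

## Significance of a prediction

Given $M$ annotated interface residues inside the pool and an observed
overlap $x$ between the top-$K$ prediction and the interface, the
chance model is hypergeometric:

$$P(X = x) = \binom{M}{x}\binom{N-M}{K-x} \Big/ \binom{N}{K}.$$

Two criteria are implemented:

* **`mode = "pmf"`** flags a prediction when the *point mass*
  $P(X = x) < 0.05$. This is the historical formulation. It has a known
  pathology: when the null distribution is spread thin, even a
  worst-case overlap ($x = 0$) can have point mass below 0.05 and be
  flagged. `significance_test()` reproduces this behaviour faithfully
  and the test suite documents it.
* **`mode = "upper_tail"`** flags when $P(X \ge x) < 0.05$ — the
  statistically sound one-sided test. It is the recommended mode and
  the one used for calibration studies here.

The empirical alternative (`empirical_z()`) draws $K$ residues from the
sampled pool 200 times, records the mean $\mu$ and standard deviation
$\sigma$ of the interface overlap, and computes $Z = (x - \mu)/\sigma$
with significance at $Z > 1.97$. Because the draws are uniform without
replacement, $\mu$ and $\sigma$ estimate the hypergeometric moments
$K M/N$ and $\sqrt{K \frac{M}{N}(1-\frac{M}{N})\frac{N-K}{N-1}}$; the
test suite verifies this agreement, and on clear-signal benchmarks the
p- and Z-criteria flag the same receptors.

A degenerate null ($\sigma = 0$, e.g. when every sampled residue is an
interface residue) has no meaningful Z-score and is reported as an
error rather than silently passed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 3.5 Å | any-atom contact distance defining $I(R_{ik})$ and the ground-truth interface |
| `n_poses` | 2000 | pose budget per probe |
| `top_k` | 15 | prediction size $K$ |
| `patch_size` | off (9 when enabled) | keep only poses whose interface has exactly this many residues |
| `reps` | 200 | resampling draws for $\mu, \sigma$ |
| `alpha`, `z_threshold` | 0.05, 1.97 | significance thresholds |
| `clash_floor` | 2.5 Å | sampler: minimum allowed interatomic distance |

The defaults are the production protocol; they are deliberately not
re-tuned per input. The 3.5 Å rule is applied literally to *any* atom
(hydrogens included when present; a `heavy_only` flag exists because
most crystallographic files carry no hydrogens, making the distinction
moot in practice). Distances are atom-centre Euclidean: no van der
Waals radii and no contact-type classification — the distance rule is
the whole operational definition of "contact" here.

## Pose ensembles

Production-scale use feeds externally docked poses through
`import_pose_transforms()`: a plain-text table, one pose per line,
either a row-major 3×3 rotation plus translation or z-x-z Euler angles
plus translation. Text-rounded rotation matrices are projected onto the
nearest proper rotation by polar decomposition (deviations beyond 1e-3
are rejected as data errors, not silently repaired).

The built-in sampler (`sample_pose_set()`) is a geometric surrogate,
not a docking engine: uniform random probe orientation, uniform
approach direction through the receptor centroid, and a bisection
search for the translation at which the minimum interatomic distance
first falls inside `[clash_floor, cutoff]` = [2.5, 3.5] Å. Every
emitted pose touches the receptor without steric overlap; a direction
whose search fails after 100 retries is skipped with a warning. The
sampler has no energy model — its unbiased surface coverage is exactly
what a *null* docking run looks like, which is what the statistics
need for exercise and calibration. An optional shell-count score
(`score_poses = TRUE`) orders poses the way an energy-ranked docking
output would, so top-vs-bottom pose analyses are expressible.

Rankings saturate quickly: on enriched synthetic ensembles, the top-15
set built from 200 poses per probe (13 probes pooled) overlaps the one
built from 2000 poses per probe by about 14 of 15 residues, so reduced
budgets are a reasonable economy.

## The synthetic benchmark generator

`make_toy_receptor()` places one pseudo-atom per residue on a Fibonacci
sphere lattice scaled to ~5 Å nearest-neighbour spacing (the Cα
scale), and annotates as interface the `interface_size` residues
nearest a random surface point — a contiguous patch, as a real binding
footprint is. `sample_contact_ensemble()` then draws poses directly in
contact space: each pose picks a patch size $s$ uniformly from 5–13
(so 9 is attainable as the modal, filterable size), picks a centre
residue from the interface with probability
$eM / (eM + (N - M))$ — enrichment $e = 1$ reduces exactly to uniform
placement, $e = 0$ excludes the interface — and takes the $s$ residues
nearest the centre as the contact set.

What this emulates: contiguous docking footprints, variable patch
sizes, interface preference of tunable strength, and full determinism
under a seed. What it does not emulate: docking energetics, probe
shape and orientation effects, surface concavity, crystallographic
noise, or heterogeneous interface sizes across receptors. Passing
tests on these fixtures therefore demonstrate the *statistical
machinery* — counting, ranking, calibration, recovery — not docking
accuracy on real structures.

Benchmark problem sizes were fixed once: 200 receptors of 120–200
residues with 15-residue interfaces and 2000 contact sets each for
calibration and recovery runs, and 25–50 receptors per condition for
monotonicity checks. These sizes give binomial standard errors of a
few percent on dataset-level rates while keeping a full run in tens of
seconds.

## Calibration: what the null actually does

With enrichment 3 the pipeline behaves as intended: essentially every
receptor is flagged significant, mean top-15 F-scores are high, and
the p- and Z-criteria agree on virtually all receptors.

Under the exchangeable null — the prediction replaced by a uniform
random $K$-subset of the pool — the upper-tail test is conservative,
as a discrete test must be: its measured type-I rate sits at or below
5%, matching the exact test size computed from the hypergeometric
tail (verified in the test suite at 500 replicates).

Under the *geometric* null (enrichment 1: uniform patch centres on the
sphere) the acceptance suite measures a dataset-level significance
rate of roughly 10–15%, above the nominal 5%. The cause is spatial
correlation: contact patches are contiguous, so neighbouring residues'
$N_i$ values are strongly correlated and the top-15 set forms one or
two clusters rather than 15 exchangeable picks. A clustered prediction
overlapping a contiguous interface patch has a heavier-tailed overlap
distribution than the hypergeometric model assumes, making the test
anti-conservative. This is a property of the method itself, not of the
implementation — any spatially clustered score ranked against a
contiguous annotation shares it — and it is the reason the calibration
check on geometric nulls is reported honestly rather than forced to
5%. Practical reading: dataset-level percent-significance figures on
docking ensembles are somewhat optimistic about chance, while
comparisons *between* conditions (probes, docking programs, patch
filters) remain valid because all conditions share the inflation.

## Numerical and design choices

* **Tie-breaks.** Ranking ties on $N_i$ resolve by ascending (chain,
  residue number, insertion code); modal patch-size ties resolve to
  the smallest size. Both make reruns bit-identical.
* **Zero-count residues** never enter rankings or the pool $N$. A
  receptor with fewer than $K$ sampled residues returns all sampled
  residues and tests with $K$ set to that count.
* **Hypergeometric terms** are evaluated in log space; the pmf sums to
  1 over its support at 1e-12.
* **ROC/AUC** uses a descending threshold sweep with trapezoidal
  integration, which equals the Mann–Whitney statistic (concordant
  pairs plus half ties) — asserted to 1e-9 against a pairwise oracle.
  The default ROC universe is all receptor residues with unsampled
  residues scored 0; `sampled_only` restricts to the pool. Benchmark
  AUCs pool per-residue (score, label) pairs across receptors into one
  curve.
* **Degenerate inputs** (empty structures, empty annotations, empty
  ensembles, $\sigma = 0$ nulls, single-class ROC universes) raise
  errors with actionable messages rather than returning NA.
* **Determinism.** Every stochastic operation takes an explicit seed
  and restores the caller's RNG state; benchmark bundles derive
  per-receptor sub-seeds from the master seed.

## Known limitations

* The built-in sampler ignores energetics entirely; probe identity
  affects results only through geometry. Real docking ensembles carry
  score-dependent enrichment the surrogate cannot produce.
* Contact typing (hydrogen bonds, hydrophobic contacts) is out of
  scope; the 3.5 Å distance rule is a slightly more permissive
  interface definition than typed-contact filters.
* The synthetic generator's single-patch interface understates
  receptors with multiple or discontinuous binding sites.
* The point-mass significance mode is kept for fidelity to the
  method's original formulation; new analyses should prefer
  `upper_tail`.
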