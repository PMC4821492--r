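---
title: "Low-resolution protein topology search by SSE assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-resolution protein topology search by SSE assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssefold)
```

## The model

De novo structure prediction is intractable at atomic detail because the
conformational space of a polypeptide chain is astronomically large.
`ssefold` implements the classic low-resolution reduction: the protein is
represented only by its secondary structure elements (SSEs) — α-helices
and β-strands built as rigid bodies from idealized dihedral angles,
(φ, ψ) = (−60°, −40°) for helices and (−135°, 135°) for strands, with
Engh–Huber-style bond geometry and ω fixed trans — and each side chain is
collapsed to a single Cβ "superatom" (glycine receives a virtual Cβ so
every residue has a uniform interaction center).  Loop regions are never
built; instead the *feasibility* of closing each loop is scored from the
Euclidean gap between consecutive SSEs.  This reduction lets a Monte
Carlo search change the overall topology in a handful of moves.

### Scoring

Model quality is the weighted sum of knowledge-based terms derived via
the inverse Boltzmann relation

$$E = -RT \,\ln \frac{P_{obs}}{P_{back}},$$

so features enriched in observed structures relative to chance score
negative.  `derive_potential()` implements exactly this: histograms of
observed and background samples on shared bins, with never-observed bins
given a finite ceiling (+5·rt by default) so the Metropolis engine never
sees non-finite scores, and observed-but-background-empty bins flagged.
The energy scale rt defaults to 1, i.e. dimensionless score units.

The terms, with their tunable constants (`score_constants()`):

* **burial** — per-residue neighbor count (cosine-switched Cβ–Cβ
  distances between 4.0 and 11.4 Å) evaluated against a per-amino-acid
  potential.
* **residue pairing** — a generic Cβ–Cβ distance potential on the 0–8 Å
  interaction support, with its well in the contact band around 5.5 Å.
* **SSE packing** — shortest axis–axis distance × acute crossing angle,
  against a 2-D table; zero beyond a 12 Å cutoff.
* **loop closure** — for sequence-adjacent placed SSEs with L loop
  residues, quadratic penalty on any gap beyond 2.56·L + 2.0 Å.
* **radius of gyration** — quadratic deviation from the expected globule
  size 2.5·m^(1/3) Å for m placed residues (two-sided: both collapsed
  and over-expanded models are penalized; the term can be disabled by
  zeroing its weight).
* **clashes** — residue–residue (Cβ pairs from different SSEs closer
  than 3 Å, linear in overlap) and SSE–SSE (bounding cylinders of radius
  2.3 Å for helices, 1.9 Å for strands).
* **restraints** — flat-bottom per restraint: zero inside the bounds,
  quadratic outside, capped at 10, scaled by confidence; a restraint
  with an unplaced endpoint contributes a neutral value (default 1).

The packaged default potentials (`default_potentials()`) are
**synthetic**: they are shaped like statistics-derived tables — the
burial preference follows the Kyte–Doolittle hydropathy scale, the
pairing and packing wells sit at the field's canonical contact and
packing geometries — but they are generated from analytic priors through
the package's own inverse-Boltzmann machinery, not from PDB statistics.
Each table is constructed as background × enhancement, which makes the
preferred feature band a negative basin while leaving uninformative
regions near zero; the pairing table is additionally truncated to its
8 Å physical support so that distant residue pairs carry no information
rather than a normalization artifact.  Users with real statistics can
drop in their own `potential_table` objects.

### The staged Monte Carlo Metropolis search

Each trajectory starts from an empty model and runs six stages.  Stages
1–5 apply large-scale perturbations — adding an SSE from the pool,
removing one, large rigid translations (uniform in a 10 Å ball) and
rotations (uniform axis, ≤ 180°), 180° flips, swapping the placements of
two SSEs, and rigid moves of sequence-connected SSE *domains* — while
the clash weights ramp up through the schedule (0, 125, 250, 375, 500),
letting early stages rearrange topology freely and late stages enforce
excluded volume.  Stage 6 applies only small perturbations (1 Å / 10°)
to settle into the local minimum, keeping the final clash weight.  Each
proposal is accepted by the Metropolis criterion
min(1, exp(−Δ/T)).

The production protocol samples 20,000 independent trajectories per
target (`mcm_config_production()`); the package default is 200, a desk
scale at which the test suite explores the toy topologies in minutes on
one CPU.  Parameters the protocol leaves open were fixed here once and
exposed in `mcm_config()` / `move_spec()`:

* move mix in stages 1–5: add 0.20, remove 0.10, translate 0.25, rotate
  0.25, flip 0.10, swap 0.05, domain 0.05; stage 6 splits evenly between
  small translations and rotations;
* temperature: geometric decay from 5 to 0.1 score units across the six
  stages;
* 300 steps per stage;
* one emitted model per trajectory (its final state): an ensemble of
  n models means n independent minimizations, not snapshots along one
  chain.

A run is fully determined by its seed.

### Model selection

After sampling, records pass a completeness filter: the fraction of
pool-SSE residues actually placed ranks the models and the lowest 25–50%
are dropped (50% when sampling essentially saturated completeness,
max ≥ 0.95 — making the fraction depend on the maximum completeness
reached is the protocol's intent, the concrete cutoff is this package's
choice; `choose_filter_fraction()`).  Ties are resolved by keeping the better
scores.

The survivors are split by score — the best-scoring 20% form the *low*
stratum, the rest *high* — and each stratum is clustered independently
on the pairwise RMSD100 model distance (Cα RMSD after optimal
superposition over shared residues, length-normalized).  Clustering is
k-medoids (PAM, from the `cluster` package) rather than k-means: the
pipeline consumes *medoids* — actual members — and the input is a
distance matrix, not a vector space.  k is scanned (default 1–8) and
chosen to maximize mean inter-medoid separation minus mean cluster
radius — the scalarization of the stated "minimize radii, maximize
separation" objective is this package's choice — subject to all radii
≤ 5 Å whenever any k achieves that; clusters holding fewer than 0.5% of
all models are dropped.

### Evaluation metrics

* **GDT_TS** = (P₁+P₂+P₄+P₈)/4, where P_t is the largest percentage of
  matched Cα atoms superposable within t Å of the reference.  For
  matched sets of ≤ 12 residues the search enumerates every residue
  subset of size ≥ 3 and is therefore exact; larger sets use an
  LGA-style heuristic seeded from sliding sequence windows (lengths
  3–8) with iterative extension over the residues currently inside the
  threshold.  The exact small-set branch exists because window-seeded
  iteration demonstrably misses the optimum on a noticeable fraction of
  short instances, and short instances are exactly where exactness is
  affordable.  Matched residues are the intersection of placed model
  residues and reference residues — SSE-only models are partial by
  design, so GDT_TS values are over the matched set.
* **RMSD100** — the length-normalized Cα RMSD is implemented in the
  metric's standard form RMSD / (1 + ln √(n/100)).  The short form
  RMSD / ln(n/100) sometimes printed for this metric is degenerate at
  n = 100 (division by zero) and negative below; the standard form
  coincides with plain RMSD at n = 100.  n < 20 is rejected as
  meaningless to normalize; the pairwise model distance falls back to
  plain RMSD there.
* **contact order** — the *absolute* variant (mean |i−j| over Cβ pairs
  within 8 Å at separation ≥ 3): reported fold-complexity values in the
  tens rule out the relative (length-divided) form.
* **enrichment** e = |TP|/|P|·10, with P the 10% most accurate models
  (lowest RMSD100; GDT_TS supported as an alternative) and PS the 10%
  best-scoring; 10% cutoffs use floor(|S|/10) and ties break by model
  id.  e ranges 0–10 with 1 = random selection.
* **μ₁₀** — mean GDT_TS of the ten most accurate models, an
  ensemble-level accuracy summary robust to sampling noise.

### Relaxation mode

`relax_from_reference()` starts every trajectory from the reference's
SSE placements (idealized bodies superposed onto the reference
coordinates) and applies only stage-6 small perturbations.  This probes
whether near-native conformations are score-favorable — the
sampling-vs-scoring diagnostic — without claiming monotone score
improvement: only Metropolis-accepted endpoints are reported.

## What the synthetic fixtures emulate — and what they do not

`generate_toy_structure()` builds four named topologies (helix hairpin,
three-helix bundle, β-hairpin, and a ferredoxin-like βαββαβ fold with
two helices and four strands) from idealized SSEs placed so that every
loop gap is physically closable and the clean constructs are clash-free.
`generate_decoy_set()` produces perturbed copies with a controlled
RMSD100 range and scores with a controlled rank correlation ρ to
accuracy (Gaussian-copula construction: exact at ρ ∈ {−1, 0, 1},
within ~0.05 elsewhere).  `generate_restraints()` samples true contacts
from a reference and swaps in a controlled fraction of
clearly-non-contacting decoy pairs, emulating predicted-contact (TP),
correct-contact (TC), NOE (TS) and cross-link (TX) restraint regimes.
All generators are seed-deterministic.

These fixtures exercise every code path, but they are idealized: real
proteins have bent strands, sheet twist (which this package does not
impose at construction — it can only emerge from packing scores),
non-ideal dihedrals, and real knowledge-based potentials carry
statistics the synthetic tables only sketch.  Passing tests demonstrate
the machinery is correct and internally consistent at desk scale, not
that the default potentials predict real folds.

## Numerical choices and degenerate inputs

* Coordinates in Å, residue indices 1-based inclusive, PDB conventions
  throughout; TSVs are tab-separated with headers.
* One-residue SSEs are rejected (no axis), as are rotations that are
  not orthonormal within 1e-8.
* Cluster-count ties within 1e-9 of the objective resolve to the
  smaller k; identical models yield k = 1 with radius 0.
* Decoys with no shared residues get twice the largest observed
  pairwise distance rather than NA, so clustering keeps them apart.
* ss2 rows must sum to 1 within ±0.01 (renormalized) and are rejected
  beyond that; restraint confidences outside [0, 1] are parse errors.
* PDB input: first model, one chain, altloc blank/'A'; insertion codes
  are collapsed by sequential renumbering with the original numbering
  kept as an attribute.

## Worked desk-scale example

```{r example, eval = FALSE}
ref <- generate_toy_structure(toy_spec("helix_hairpin"))
pool <- attr(ref, "pool")

records <- run_fold(ref$sequence, pool,
                    mcm_config(models_to_sample = 200, seed = 1))
kept <- filter_by_completeness(records, choose_filter_fraction(records))
clusters <- cluster_models(kept)
metrics <- ensemble_metrics(kept, ref)
print(metrics)
```

The test suite runs this pipeline (and the restraint-assisted variant)
at 200-model ensembles over multiple seeds, with 150-300 Monte Carlo
steps per stage; the
`scripts/acceptance.R` entry point recomputes the enrichment anchors on
1,000-decoy ensembles with 500 randomization trials.  Problem sizes
were chosen as the smallest at which every property of interest is
stably observable.

## Known limitations

* β-sheet hydrogen-bond registry is not modelled; sheets are only
  favored geometrically via packing and pairing terms.
* The default potentials are synthetic (above); absolute scores are not
  comparable to any published force field.
* GDT_TS above 12 matched residues is a heuristic and can in principle
  undershoot the optimum, as any LGA-style search can.
* The search samples independent trajectories; there is no replica
  exchange, loop construction, or all-atom refinement.
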