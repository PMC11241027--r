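---
title: "Methods: descriptors, model search and validation in cdbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, model search and validation in cdbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbind)
```

# The modeling problem

β-cyclodextrin (β-CD) forms inclusion complexes with small phenolic guests;
the strength of that binding — expressed as a docking binding score or a
semi-empirical complexation energy, both negative kJ/mol quantities —
controls how well the host masks the guest's bitterness. `cdbind`
implements a QSAR treatment of this problem: molecular descriptors are
computed for each guest, a genetic algorithm searches for small descriptor
subsets, ordinary least squares links the chosen subset to the
log-transformed binding quantity, and the model is validated internally
(leave-one-out), externally (a held-out test set) and structurally (an
applicability domain).

The response is always `log10(|binding quantity in kJ/mol|)`. Base 10 is
used because binding scores near −4 kJ/mol then land near 0.6, the
magnitude regime in which these models are usually discussed; natural logs
would place the same value near 1.4. Absolute values are taken because all
favorable binding quantities are negative.

# Molecular graphs and conformers

SMILES/SDF parsing, kekulization and aromatic-ring perception are delegated
to ChemmineR/ChemmineOB (OpenBabel). The package works on the
hydrogen-depleted graph by default — the convention for the descriptors
used here — while implicit hydrogen counts are retained, and
`add_hydrogens()` produces the explicit-hydrogen variant for autocorrelation
conventions that keep polar hydrogens.

3D descriptors need coordinates. The conformer generator `embed_3d()` is a
seeded distance-geometry routine: bond-length targets come from
covalent-radius sums scaled by bond order (single ×1.00, aromatic ×0.93,
double ×0.87, triple ×0.78), 1–3 distances from the central atom's ideal
angle (109.47°/120°/180° for sp³/sp²/sp), and chord targets inside aromatic
rings from regular-polygon geometry (which forces ring planarity). The
targets are embedded by classical MDS, perturbed by a seeded Gaussian
jitter (σ = 0.05 Å) to break degeneracies, and refined by BFGS on a
weighted stress function with a 2.4 Å short-range repulsion between
unconstrained pairs. The generator is deliberately deterministic:
regeneration with the same graph and seed is bit-identical, which makes
every downstream 3D descriptor reproducible. It produces one plausible
relaxed conformer, not an ensemble, and it does not handle stereochemistry
— acceptable here because the two 3D descriptors in use (H0e, Mor10u) probe
coarse geometry, not torsional detail.

# The nine descriptors

* **nR06** — number of six-membered rings, counted over the *full cycle
  space*, not a minimal ring basis. This matters for bridged bicyclics:
  the 2-oxabicyclo[2.2.2]octane core of eucalyptol holds three distinct
  6-cycles, while a minimal basis would report two.
* **ATS4m** — Broto–Moreau autocorrelation of lag 4, mass-weighted:
  `ATS_k = Σ_{d(i,j)=k} w_i w_j` with weights relative to carbon, reported
  as `log(1 + ATS_k)`. Zero when no pair exists at the lag.
* **BEle3** — third-lowest eigenvalue of the Burden matrix with Sanderson
  electronegativity weights on the diagonal. Off-diagonal conventions
  (recorded as package constants so alternates can be swapped): bonded
  pairs 0.1 × conventional bond order (aromatic = 1.5), +0.01 for terminal
  bonds, 0.001 for all non-bonded pairs.
* **S3K** — Kier α-modified 3-path shape index,
  `(A+α−1)(A+α−3)²/(P3+α)²` (odd A) or `(A+α−3)(A+α−2)²/(P3+α)²` (even A),
  with P3 the count of distinct 3-edge simple paths and α the sum of
  `r_i/r_Csp3 − 1` over Kier's hybridization-dependent covalent radii. The
  hybridization dependence (sp² carbon 0.67 Å vs sp³ 0.77 Å) is what makes
  aromatic molecules score below same-size aliphatic chains, on top of
  their larger P3.
* **EEig03r** — third-largest eigenvalue of the bond-resonance-weighted
  edge adjacency matrix: bonds are nodes, bonds sharing an atom are linked
  with weight `sqrt(w_f w_h)`, w = conventional bond order. The "r" weight
  table is a package constant; branching raises the spectrum.
* **H0e** — GETAWAY H autocorrelation of lag 0, Sanderson-weighted:
  `Σ_i h_ii w_i²` over the diagonal of the molecular influence matrix
  `H = M(MᵀM)⁻¹Mᵀ` of centered coordinates. H is computed through an SVD
  pseudo-inverse with singular values below 10⁻³ of the largest dropped, so
  planar molecules are treated as genuinely rank-2 (trace 2) and linear
  ones as rank-1 — the exact identities the tests assert.
* **GATS8e** — Geary autocorrelation of lag 8 with Sanderson
  electronegativity weights,
  `c(k) = [Σ_{d=k}(w_i−w_j)²/(2N_k)] / [Σ_i(w_i−w̄)²/(A−1)]`. Defined as 0
  for empty lags and constant weights so small molecules never produce
  missing cells. The weighting follows the "e" suffix convention
  (electronegativity); the weight scheme is exposed as a parameter for
  anyone preferring the mass-weighted reading.
* **Mor10u** — 3D-MoRSE signal 10, unweighted:
  `Σ_{i<j} sin(s·r_ij)/(s·r_ij)` with s = signal − 1 = 9 Å⁻¹ under the
  standard 32-signal convention (signal 1 is s = 0, where each term is 1).
* **TPSA** — Ertl fragment-contribution polar surface area over N/O
  fragments (hydroxyl 20.23, ether 9.23, carbonyl 17.07, aromatic O 13.14,
  plus the neutral nitrogen fragment table). Molecules without N or O
  score 0.

Exact numeric parity with the closed-source commercial descriptor engine
that popularized these names cannot be asserted; every descriptor is
instead verified against construction-level oracles (independent dense
eigensolvers, brute-force pair enumeration, hand-evaluated closed forms)
and against atom-reindexing invariance.

# Data set, responses and the split

The packaged table carries 20 β-CD–ligand complexes: HOMO/LUMO/gap (eV),
the docking binding score and the semi-empirical binding affinity (kJ/mol).
The loader validates a checksum and the internal identity
gap = HOMO − LUMO (±10⁻⁴ eV). Ligand structures are canonical literature
structures for the 20 named compounds, packaged as SMILES; the docking
orientation tag (upright/inverted) is carried as metadata only. The table
contains no binding-energy column — those values were never published — so
binding-energy (Model 3-style) workflows run on synthetic tables from
`gen_complex_table()`, which are labelled synthetic throughout.

The train/test split is systematic, not random: compounds are sorted by
ascending response and every fifth rank goes to the test set, giving 16
training and 4 test compounds at n = 20. Ties are broken by ascending
compound id, which makes the split a pure function of the response values.

Descriptors are z-score normalized with means and standard deviations
estimated on the training subset only and stored with the fitted model, so
new molecules are projected onto the training scale. The three published
equations are interpreted as operating on normalized descriptors — their
coefficient magnitudes (all below 0.5 for responses spanning ~0.4–2) are
only consistent with autoscaled inputs. Because the original descriptor
values and normalization parameters were never published, this package's
own descriptor matrix defines the scale, and reproducing the original
models' training statistics is explicitly not claimed; the frozen
equations are shipped for structural interpretation (coefficient signs and
magnitudes) and for reference-point evaluation.

# GA-MLR model search

The genetic algorithm searches fixed-size descriptor subsets. Design
choices, each of which the search description leaves open and is therefore
fixed here as package policy:

* **Fitness**: leave-one-out Q² of the subset's OLS model (default), with
  training R² selectable. Q² is the stricter and more conventional choice
  for small QSAR training sets.
* **Selection**: rank-proportional roulette — robust to fitness scaling.
* **Crossover**: single-point on the sorted gene lists, repaired to keep
  genes distinct.
* **Mutation**: per-gene replacement by a random non-member at the
  configured rate.
* **Elitism**: the single best individual is carried over unchanged, which
  makes the best-so-far trace provably non-decreasing — an invariant the
  tests assert on every run.
* **Budget**: defaults are population 500, 3000 generations, mutation rate
  0.35 — the production-scale settings; "iterations" is read as
  generations. Tests and examples use reduced settings (population 50, 100
  generations), at which the GA still recovers a planted 3-of-30 signal in
  ≥ 95 % of seeds and matches exhaustive search on 10-descriptor pools.
* **Determinism**: the whole run is a pure function of the data and the
  seed; the caller's RNG state is restored afterwards.

Rank-deficient candidate subsets score −∞ rather than aborting the search.

# Validation statistics

R² and RMSE follow their standard definitions; MAE, CCC and F are included
in the battery with the conventional formulas: CCC is Lin's concordance
with population (1/n) moment estimators, and F = (R²/k)/((1−R²)/(n−k−1)),
reported as +Inf for exact fits. Q²_LOO uses PRESS with the denominator
taken around the full training mean (not fold-wise means), the common QSAR
convention. The leave-one-out loop is computed through the exact OLS
deleted-residual identity `e_i/(1−h_ii)`; the explicit refit loop is kept
as a selectable method and the two are asserted identical to 10⁻⁹ across
random problems. MAE ≤ RMSE and Q² ≤ R² hold by construction and are
asserted as report invariants.

# Applicability domain

Leverages of training and query compounds are hat-diagonal values against
the training design with intercept; the warning threshold is
h\* = 3(k+1)/n (0.75 for a 3-descriptor model on 16 compounds). Response
outliers are flagged at |standardized residual| > 3, with residuals
standardized by their sample standard deviation; a studentized variant
(dividing additionally by √(1−h)) is selectable since the plain form is a
convention, not a law. A residual vector with zero variance returns all
zeros and no flags. Test-set leverages are computed against the training
design — the Williams-plot convention that lets a structurally unusual
test compound exceed h\*.

# Synthetic data

`gen_dataset()` draws descriptor pools as equicorrelated Gaussians
(`X_j = √ρ Z₀ + √(1−ρ) Z_j`, default ρ = 0.3) and responses as a linear
signal in a k-column subset plus Gaussian noise. Equicorrelation is the
simplest structure that gives the pool the collinearity that makes subset
selection nontrivial; ρ = 0.3 keeps the selection problem honest without
making the planted subset unidentifiable at the n = 100 test scale. What
the generator does *not* emulate: real descriptor blocks are heterogeneous
(counts, spectra, surface areas) with heavy-tailed and discrete marginals,
and real responses can be nonlinear in the descriptors — so passing
recovery tests shows the machinery is correct, not that three descriptors
suffice for any particular chemistry. `gen_complex_table()` additionally
produces schema-compatible synthetic complex tables with a binding-energy
column in the log₁₀ magnitude regime of the packaged affinities (1–2),
enabling end-to-end binding-energy workflows that the real data cannot
support.

# Numerical choices and degenerate inputs

* Pseudo-inverse tolerance for the influence matrix: 10⁻³ relative —
  large enough that a numerically near-planar embedded aromatic is treated
  as planar, small enough not to truncate genuine 3D structure.
* Zero-variance descriptor columns abort normalization with the column
  named; duplicated design columns abort fitting with the collinear
  columns named.
* Geary and ATS empty-lag conventions return 0 (documented above) rather
  than NA.
* Split ties break by ascending compound id; GA fitness ties resolve to
  the first-ranked individual.
* Problem sizes in the test suite (n = 100, p = 30 pools; 100-seed GA
  recovery; 200-seed OLS coverage) were chosen as the smallest scales at
  which the statistical properties under test are stable.

# Known limitations

* Descriptor values are this package's own implementations of the named
  descriptor families; they agree with the published constructions but not
  necessarily to the last digit with any specific commercial engine, so
  models fitted here should be applied to descriptors computed here.
* The conformer generator yields one deterministic conformer; descriptor
  values for highly flexible molecules (e.g. long-chain acids) depend on
  that choice.
* Charged species and stereochemistry are out of scope; TPSA implements
  the neutral N/O fragment table.
* With n = 20 and a 4-compound external set, external R² is an unstable
  statistic; the package reports it because it is part of the standard
  battery, but the Williams plot and Q² carry more information at this
  scale.
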