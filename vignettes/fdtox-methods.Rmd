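---
title: "Models and methods behind fdtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fdtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdtox)
```

`fdtox` models the protein-binding profiles of fullerene derivatives (FDs)
and screens them for aquatic-toxicity structural alerts. This vignette is the
package's own account of the models it implements, the conventions it fixes
where the underlying methods admit choices, and what its synthetic data can
and cannot show.

## The data model

A compound table holds an id, a SMILES, a recorded train/test label, and 12
binding-score responses: the average binding score over a large protein
panel, a best-complex binding affinity, and docking scores against ten
proteins chosen for their similarity to aquatic-species proteins (amine
oxidases 1D6U/1GOS/1H82, hormone receptors 1E3K/1GS4/1UOM/3ERT, cytochromes
1OG5/2F9Q/2J0D). An optional 13th column carries the acetylcholinesterase
(*Torpedo californica*, PDB 1VOT) score, the mechanistic anchor for
aquatic neurotoxicity. Binding scores are shape-complementarity docking
outputs and are always **inputs** to this package: nothing here re-docks.
When a real table is supplied (`read_dataset()`), its recorded 127/42 split
is honored verbatim and never re-derived; supplied descriptor columns
(e.g. a QikProp `QPpolrz`) take precedence over computed ones, with
provenance recorded per column.

## The synthetic generator

The study's compound and binding tables live in a supplementary appendix
that is not distributed with this package, so every downstream stage is
developed and tested against a seeded generator that emulates the table's
structure.

**Structures.** Each compound is a cage core decorated with functional-group
motifs drawn from a grammar (amines, ammonium, nitro on vinyl and phenyl,
acrylate, acrylonitrile, phosphoric ester, fluoride, benzylic fluoride,
amide, alcohol, carboxylic acid, pyridyl, alkyl) with per-motif inclusion
probabilities and multiplicity ranges. The default core is a saturated
dodecahedral C20 cage built programmatically from the dodecahedral graph:
fullerene-like topology with 20 CH positions that can each accept one
substituent. An aromatic cage was rejected as the default because aromatic
cage carbons carry no hydrogens, so substituent attachment would require
valence surgery; the saturated cage keeps the attachment chemistry honest
while staying small and fast. A literal C60 option exists for pristine
reference compounds: its graph is constructed as the Cayley graph of the
alternating group A5 with a (2,3,5) generating pair, which yields the
truncated icosahedron with the involution edges forming a valid Kekulé
matching (the 30 double bonds at hexagon–hexagon fusions). Ring-closure
labels of attached branches are renumbered so they can never collide with
labels still open in the core SMILES.

**Responses.** Two latent factors drive all responses: molecular size (heavy
atom count) and a polarizability increment sum, both standardized against
reference moments of the grammar (estimated once from a fixed-seed
composition simulation, so the factors do not depend on the particular
sample) and orthogonalized by Gram–Schmidt. Response `k` is

`y_k = 5800 + 700 (a_k1 f1 + a_k2 f2 + e_k)`, `e_k ~ N(0, s_k^2)`,

which makes the implied correlation matrix analytic:
`corr(y_i, y_j) = a_i'a_j / sqrt((|a_i|^2+s_i^2)(|a_j|^2+s_j^2))`
(`analytic_response_correlation()`). The default loadings and noise scales
were chosen once so that the off-diagonal correlations span roughly
0.58–0.97 with the weak-signal 1D6U response near 0.66 against the average
binding score, matching the correlation window the study reports, and so
that scores span roughly 4000–7800 with pristine cages lowest (reference
pristine scores in the study sit at 4240–4646). The affine scale places the
centre at 5800 score units with 700 units per latent SD. These are the study
conditions of the package; they are fixed, not tuning knobs.

**What the generator does not emulate.** Real docking scores contain
protein-specific binding-pocket effects, saturation at large ligand sizes,
and heteroscedastic noise; the generator's responses are exactly affine in
two structural factors. Consequently models that can exploit that linearity
(notably the DCW descriptor, which sees the same attribute counts that drive
the latent factors) fit the synthetic data *better* than they fit real
docking data — passing tests show the machinery is correct and calibrated,
not that real-data performance will be equally high.

## Descriptor conventions

The drug-like panel has no universal definition, so the package fixes one
deterministic convention per slot:

| Slot | Convention |
|---|---|
| H-acceptors | N + O atom count (Lipinski-style) |
| H-donors | N/O bearing at least one H (OpenBabel) |
| PSA | Ertl topological polar surface area (OpenBabel) |
| TSA | additive van-der-Waals surface: per-atom `4*pi*r^2` scaled by `max(0.2, 1 - 0.23*degree)`, plus 40% of a free H sphere per hydrogen |
| RPSA | PSA / TSA, clipped to [0, 1] |
| cLogP | Wildman–Crippen atom contributions (OpenBabel) |
| cLogS | ESOL-style: `0.16 - 0.63 cLogP - 0.0062 MW + 0.066 RB - 0.74 AP` |
| drug-likeness | `1 -` mean of four clipped penalties (cLogP vs 2.5, MW vs 400, PSA vs 60, rotatable bonds vs 15) |
| rotatable bonds | non-ring single bonds between two non-terminal heavy atoms |
| ring closures | cyclomatic number `bonds - atoms + components` |
| small rings | distinct simple rings of size 3–7 (unique atom sets); exceeds SSSR in bridged cages, a constant offset within a shared-core series |
| aromatic rings/atoms | SMARTS ring patterns `a1...a1` of sizes 5–7 / `[a]` count |
| stereo centers | stereo-specified bracket atoms (`@`) in the input SMILES; unspecified potential centers are not counted |
| symmetric atoms | atoms in non-singleton classes after colour refinement (element + degree seeds) on the H-depleted graph; bond orders are not distinguished |

These are reproducible, citable approximations; bit-exact parity with any
particular descriptor program is a non-goal. The polarizability proxy is an
element-level additive increment table (shipped as
`inst/extdata/polarizability_increments.csv`, values calibrated to
Miller-style atomic additivity); it is strictly additive over fragments and
errors on elements outside the table rather than guessing.

`topological_diameter()` is the graph diameter (in bonds) of the largest
connected component: 0 for a single heavy atom, 3 for benzene, 5 for
n-hexane, 9 for C60.

## DCW optimal descriptor

Attributes are tokens of the canonical SMILES (order 1) or lexicographically
sorted adjacent token pairs plus the single tokens (order 2). Canonical
SMILES, not input SMILES, so training does not depend on how structures were
written. An attribute is *active* when it occurs in at least `threshold`
training compounds (default 3); inactive attributes keep weight 0 and
contribute nothing, and attributes never seen in training are counted and
reported, not silently ignored. Optimization is greedy hill climbing over
`epochs` passes (default 30), each pass making one `±step` move (default
0.1) per active attribute; a move is kept iff the absolute training Pearson
correlation does not decrease, so the accepted-|r| trajectory is
non-decreasing by construction. Defaults follow common practice for
SMILES-attribute correlation-weight models; all are arguments. The
calibration line is fitted on the training set only, and prediction uses
frozen weights and calibration.

## Counter-propagation ANN

Choices the underlying literature leaves open, fixed here and exposed as
arguments:

* planar (non-toroidal) square lattice, neuron index row-major;
* triangular neighbourhood kernel `1 - d/(radius+1)` with lattice Euclidean
  distance `d`, so the BMU always receives the full learning rate and the
  kernel vanishes just beyond the radius; radius decays linearly from
  `grid/2` to 0 (final epochs update the BMU alone);
* learning rate decays linearly `0.5 -> 0.01`;
* per-column min–max normalization from the training data; query objects
  outside the hull are clipped to [0, 1] with a warning;
* presentation order reshuffled every epoch from the run seed; ties in the
  BMU search break to the lowest row-major index.

Because every update is a convex combination of quantities in [0, 1], the
weights stay in the normalized hull — an invariant the tests assert. The
quantization error (mean BMU distance per epoch) is reported for
diagnostics; it is non-increasing endpoint-to-endpoint on essentially all
seeded runs, though not monotone per epoch (the shrinking radius can trade
local quantization for global ordering). Prediction is a pure lookup of the
BMU's output weights, so identical descriptor rows share a BMU and repeated
calls are identical. `cpann_loo()` retrains `n` times with per-fold
normalization, which keeps the left-out object fully outside its fold's
fitting path.

## Q² conventions

The QSAR literature uses "Q²" both for the squared Pearson correlation
between observed and predicted values and for the PRESS-based
`1 - RSS/SS`. The two differ exactly when predictions are miscalibrated: a
constant shift leaves the squared correlation at 1 while the PRESS form
penalizes it. The package computes **both** everywhere (`q2_pearson()`,
`q2_press()`), reports the squared-correlation form as the headline number,
and warns when predictions are anti-correlated with observations (where the
squared-correlation form is deceptive).

## Applicability domain

Leverage of a query `x` against the training design `X` (intercept
included): `h = x'(X'X)^{-1}x`; training leverages are the hat-matrix
diagonal and sum to `p + 1`. The warning threshold is the customary
`h* = 3(p+1)/n` (the threshold multiplier is an argument). Standardized
residuals divide by the training residual SD with `p + 1` degrees-of-freedom
correction; compounds with `|std residual| > 3` are response outliers.
Flags are invariant to affine rescaling of the response and leverages to
invertible linear recombination of the predictors — both asserted in tests.

## Structural alerts

The authoritative alert patterns live behind a web service login, so the
package ships its own SMARTS approximations written from each alert's
printed chemical name (TA662/TA665 amines, TA642 ammonium, TA628/TA11521
nitro variants, TA667 activated alkenes/alkynes, TA617 phosphoric esters,
TA626 nitriles, TA631/TA1176 acids, TA1181 secondary amides, TA659
alcohols, TA638/TA634 halides). The contract of each pattern is its paired
positive/negative control (28 structures shipped as
`inst/extdata/alert_controls.csv`), not parity with any external service.
Match counting deduplicates symmetry-equivalent atom mappings; alerts with
several depiction variants (charged/neutral nitro) sum the mutually
exclusive variant counts. Whether "activated" alkenes require a specific
electron-withdrawing pattern is not printed in the source naming; the
shipped TA667 accepts carbonyl, nitrile, nitro and sulfonyl activation. The
screening report groups compounds by their shared alert set and flags
compounds whose predicted score is at or above 5000 score units (the
default "low concern" boundary, an argument) yet carry no alert — the case
that warrants manual review.

## Registry and pipeline

`build_registry()` fits the six model families per response (72 models):
OLS and a multi-output CPANN on all 28 descriptors, OLS and CPANN on
QPpolrz + TD, and OLS and CPANN on the endpoint-specific DCW. The shared
28th descriptor of the ALL models is the DCW trained on the average binding
score — the study's own unifying reference response — since a single shared
column is needed and the source does not say which endpoint its shared DCW
used. Constant or aliased predictor columns (synthetic tables can produce
invariant slots such as stereo-center counts) are dropped from the ALL
design and recorded in the registry rather than raising, because the
registry contract is 72 fitted models. The standalone `fit_ols()` keeps the
strict rank check and names collinear columns.

The package is an R library, so the pipeline surface is a function:
`run_pipeline()` chains generation/loading, descriptors, DCW, the registry,
the Williams table of the two-descriptor regression, CPANN map export,
alert screening and the ranked prioritization table, writing a JSON
manifest with MD5 digests of every artifact; equal config and seeds give
byte-identical outputs.

## Problem sizes and numerical choices

Unit tests run on 24–60-object problems with 4–8 neuron lattices and tens
of epochs; the acceptance checks run the full study dimensions (169
compounds, 127/42 split, 14 × 14 lattice, 400 epochs, leave-one-out over
127 objects) — sizes chosen so the entire suite completes in a few minutes
on one CPU while still exercising the study-scale configuration.
Generator-model agreement is asserted at n = 2000 within ±0.05 per
correlation entry; at n = 169 sampling noise is larger, so the acceptance
block compares correlation extremes on the Fisher-z scale within three
standard errors. Min–max spans of constant columns are set to 1 to avoid
division by zero (the column maps to 0). Single-heavy-atom molecules are
reconstructed from their token directly because the external SDF round-trip
is not well-formed for them; structure conversion runs through the
`obabel` executable because the in-process conversion entry point is
unstable on fused cage polycycles, while property calculation and SMARTS
matching run in-process.

## Known limitations

* Descriptor values are package conventions, not reproductions of any
  specific commercial or desktop descriptor program.
* The DCW engine implements token/pair attributes only, not the full
  attribute zoo of correlation-weight software (ring indices, atom-pair
  proportions, hybrid descriptors).
* Alert SMARTS are name-derived approximations whose contract is the
  shipped control set.
* Synthetic responses are affine in two structural factors; real docking
  scores are not, so absolute performance numbers on synthetic data
  overstate real-data performance for attribute-based models.
* The literal C60 core supports pristine compounds only; decorated
  generation uses the C20 proxy cage.
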