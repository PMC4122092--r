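---
title: "Interface residue prediction with hidden Markov SVMs and order-profile propensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface residue prediction with hidden Markov SVMs and order-profile propensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmsvmPPI)
```

## The problem and the modelling stance

Protein–protein binding sites are stretches of surface residues. Two
empirical regularities make them predictable from sequence-derived evidence
alone: interface residues are more conserved than other surface residues
(visible in evolutionary profiles), and they tend to show higher solvent
accessibility than the rest of the surface. A third regularity is
*structural*: interface residues are not scattered — they come in contiguous
sequence segments. This package therefore labels whole chains at once with a
linear-chain max-margin model (a hidden Markov support vector machine,
HM-SVM) whose transition weights can express "interface residues follow
interface residues", instead of classifying residues independently.

The unit of data is a `ProteinChain`: sequence, a PSI-BLAST profile (both
the 20 log-odds and the 20 weighted-percentage columns), per-residue
absolute accessible surface area (ASA), and 0/1/NA interface labels.
`dataset_type` records whether minor-interface residues were counted as
negatives (`type_I`) or positives (`type_II`) when the labels were made;
the package treats labels as given either way.

## Features

Each residue contributes a per-position feature vector; row *i* of the
design matrix concatenates these vectors over offsets −w…+w (default
w = 6, so windows span 13 positions; out-of-chain offsets contribute an
all-zero pad block).

**Scaled PSSM (20 values).** PSI-BLAST log-odds are integers roughly in
[−12, 12]; they are squashed elementwise through the logistic
1/(1+e^(−x)) into (0, 1), the usual scaling when PSSMs feed a margin
classifier. The field-standard PSI-BLAST invocation (10 iterations,
E-value 0.001 against a nonredundant database) is assumed but not run by
the package: the `.pssm` ASCII file is the interface.

**Relative ASA (1 value).** Absolute ASA divided by the residue type's
nominal maximum area (a Rost & Sander-style table shipped as
`maxASATable()`, overridable), clipped to [0, 1.2] because DSSP
occasionally exceeds the nominal maxima. A residue is a *surface* residue
when its relative ASA is at least `surfaceThreshold` (default 0.05,
boundary inclusive). Unknown residue types divide by the table mean.

**Order-profile propensity (1 value, the full model only).** The
percentage columns are smoothed into a frequency distribution per position
(`(pct + k)` renormalised; all-zero rows, which PSI-BLAST emits, become
uniform). The *order profile* at a position is the set of amino acids whose
frequency exceeds a threshold (default 0.15), written as an alphabetically
sorted string — `"KR"` means lysine and arginine co-dominate the column. If
nothing exceeds the threshold the symbol falls back to the argmax letter
(alphabetically first on ties): an empty catch-all symbol would be
uninformative. The propensity of a symbol *o* is a smoothed log-odds of its
occurrence among interface versus non-interface surface residues of the
training chains:

$$\mathrm{score}(o) = \log\frac{c_{int}(o)+\kappa}{N_{int}+\kappa S}
 - \log\frac{c_{surf}(o)+\kappa}{N_{surf}+\kappa S},$$

with pseudocount κ (default 1) and S the number of distinct symbols seen.
The form is monotone in the occurrence difference, bounded by the
pseudocount, sign-symmetric, and has a single interpretable
hyperparameter. Unseen symbols receive the formula's value at zero counts.
The table is *global* (one score per symbol, not per sequence position) —
the alternative was considered and rejected as data-hungrier with no
mechanism in this model to exploit position specificity. Because the raw
score is a log-odds with a scale of several units while every other
feature lives in (0, 1), the feature column is squashed through the same
logistic as the PSSM values; without this, a propensity column that is
pure noise measurably degrades the learner (see the ablation below).

The propensity table is a learned statistic: inside cross-validation it is
fitted on the training fold only. Buried residues receive the default
score, stay in the chain so transitions pass through them, but by default
contribute neither training loss nor evaluation counts.

The frequency threshold is configurable; 0.15 was fixed as the default
from the grid {0.05, 0.10, 0.15, 0.20, 0.25} as the value at which typical
smoothed profile columns yield one- to three-letter symbols — small enough
to be discriminative, large enough to recur across chains.

## The sequence labeler

A labeling $y \in \{\mathrm{NEG}, \mathrm{POS}\}^L$ is scored by

$$F(x, y) = \sum_i \left( W_{y_i}\cdot x_i + b_{y_i} \right)
 + \sum_{i\ge 2} T_{y_{i-1}, y_i},$$

with zeroth-order emissions and first-order transitions (the standard
HM-SVM model class). All potentials are plain doubles — these are scores,
not probabilities, so no log-space machinery is needed. Decoding is
Viterbi; exact ties are broken toward NEG at every backtracking step, which
makes predictions conservative and bitwise reproducible. Ranking scores for
ROC analysis are *max-marginals*, $s_i$ = (best path score with $y_i$ =
POS) − (best with $y_i$ = NEG), computed by one forward and one backward
max recursion; the sign of $s_i$ agrees with the Viterbi label except at
exact ties. The model emits discrete labels, so some per-residue ranking
score has to be constructed for AUC; max-marginals are this package's
choice and are flagged as such.

Two trainers share the joint feature map (emission sums per label, label
counts, transition counts):

* **Averaged structured perceptron** — the reference trainer. Chains are
  visited in a seeded shuffled order; each mistake adds the feature
  difference of the gold versus predicted path, with emission and bias
  components restricted to trainable (surface, labelled) positions. If an
  epoch completes without mistakes the current separating weights are
  returned; otherwise the averaged weights are returned with a warning.
* **One-slack margin-rescaling cutting plane** — the SVM^hmm-style
  optimiser and the default. The objective is
  $\tfrac12\lVert(W,b,T)\rVert^2 + c\,\xi$ over the single slack of the
  joint constraint set; margins and Hamming losses are averaged over
  chains, which makes this equivalent to the n-slack objective
  $\tfrac12\lVert w\rVert^2 + (c/n)\sum_i \xi_i$ (the normalisation
  SVM^hmm applies internally). Each round finds the most violated
  constraint by loss-augmented Viterbi (Hamming loss over trainable
  positions added to the potential), appends it to the working set and
  re-solves the dual QP; training stops when the most violated constraint
  is violated by at most ε. Defaults c = 0.1, ε = 1 follow the settings
  this model class is conventionally run with.

The working-set dual — maximise $l^\top\alpha - \tfrac12
\alpha^\top G \alpha$ over $\{\alpha \ge 0, \sum\alpha \le c\}$ — is solved
by projected coordinate ascent plus pairwise (SMO-style) transfers, the
latter needed for progress when the budget constraint is active, iterated
to a KKT residual below 1e−8. The dual objective is asserted
non-decreasing across rounds (an internal error otherwise), and the
per-round log (primal, dual, violation, working-set size) is stored in the
fitted model.

### What ε = 1 does and does not promise

ε is measured in chain-averaged Hamming units: training stops when no
joint labeling is violated by more than one averaged mislabeled residue
per chain beyond the current slack. That tolerance deliberately permits
the optimiser to stop while a handful of training residues are still
inside the margin. On a noise-free strongly separable synthetic set
(50 chains × 40 residues) the perceptron reaches exactly zero training
errors, while the cutting plane at c = 0.1, ε = 1 stops with roughly half
a percent of training residues mislabeled; the same optimiser driven to
c = 10, ε = 0.01 reaches exactly zero. This is a property of the tolerance
semantics, not of the data or the solver, and is worth knowing when
comparing against SVM^hmm runs: matching its published settings does not
imply interpolation of the training set.

## Evaluation protocol

Metrics are computed from confusion counts over *surface residues with
known labels* (configurable to all residues), interface being the positive
class: Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc, F1 (via precision),
MCC (denominator factored into four square roots so it cannot overflow,
result clamped to [−1, 1] against 1-ulp excursions), and rank-based
Mann–Whitney AUC with half-credit ties, identical to the trapezoidal area
under the full ROC curve. Specificity here is the TN-based definition;
because part of the interface-prediction literature prints *precision*
under an "Sp" heading, precision is always reported alongside, explicitly
labelled — no attempt is made to guess which convention any given external
table used.

Cross-validation is chain-level: chains, never residues, are shuffled into
k near-equal folds by a seeded assignment (default fivefold, seed 1), so
no chain contributes to both training and test. Both the propensity table
and the model are fitted per fold on training chains only; corrupting
test-fold labels provably leaves the trained model bit-identical (this is
a test). Single pooled numbers are micro-averages over the summed
confusion counts; per-fold reports are kept as well. A fold whose
evaluated residues are single-class gets an NA AUC with a diagnostic
rather than a hard error.

The ablation harness trains the baseline feature set (PSSM + relative ASA,
D = 21·(2w+1) = 273) and the full set (+ propensity, D = 22·(2w+1) = 286)
under identical folds, seeds and hyperparameters.

## The synthetic benchmark: what it emulates, and what it does not

The generator produces, per chain: contiguous interface segments (a
Poisson number at `interfaceSegmentRate` per 100 residues, lengths uniform
in `segmentLengthRange`, placed without overlap — adjacent segments may
abut and merge; sampled segments that cannot fit within 60% of a chain are
dropped so the interface stays a minority class, and genuinely infeasible
configurations raise errors), relative ASA from a Beta(2,3) baseline with
a mean elevation `asaShift` at interfaces, Dirichlet-sampled frequency
profiles quantised to integer percentages, sequences sampled from those
profiles, and integer log-odds derived deterministically from the
quantised percentages. Defaults (60 chains of 30–80 residues, 2.5 segments
per 100 residues of length 5–12, giving roughly a fifth of residues in
interfaces; `asaShift` 0.25; `compositionShift` 0.6) mirror the broad
statistics of curated complex benchmarks, where around a quarter of
surface residues are interface.

The composition signal deserves its own paragraph. A naive implementation
— shifting the interface Dirichlet mean toward an enriched letter subset —
leaks the entire signal into the PSSM features, because the synthetic
log-odds derive from the same profile; a linear baseline then reads the
signal directly and the propensity feature has nothing left to add. The
generator therefore plants a *co-occurrence* signal: every position's
profile mean is boosted toward a pair of letters from the enriched subset
(default {K, R, Y, W}), drawn within one half of the subset at interface
positions ({K,R} or {Y,W}) and across halves elsewhere ({K,Y}, {K,W},
{R,Y}, {R,W}). Per-letter marginal frequencies are then identical between
classes — no linear functional of single-letter features has any
first-order signal — while the order-profile symbol at a position is
diagnostic. This is precisely the set-level conservation pattern the
propensity feature exists to capture, and it is what makes the ablation a
meaningful test rather than a tautology.

A second generator samples labels from a *planted* HM-SVM: features are
i.i.d. Gaussian and label paths are drawn from the Gibbs distribution of
the planted potentials at a chosen temperature by exact forward filtering
/ backward sampling. At temperature → 0 the samples coincide with the
planted Viterbi labels; at temperature 1 with persistent transition
weights, label runs are measurably longer than i.i.d. (a runs-statistic
test) and a model retrained on 200 sampled chains recovers held-out
ranking with AUC ≈ 0.9.

What the synthetic data does **not** emulate: real evolutionary profiles
(column dependencies along the sequence, alignment-depth artefacts),
homology between chains, 3D geometry (interfaces contiguous in space but
split in sequence), or the label noise of real interface definitions.
Passing tests on this benchmark therefore demonstrate correctness of the
machinery and the intended qualitative behaviour of the features — not
expected accuracy on real complexes, which depends on profile databases
and dataset curation outside the package's scope.

## Numerical and design choices, in one place

* Coordinates: 1-based inclusive in every file format (PSI-BLAST/DSSP
  convention), 0-based never exposed; matrices in memory are plain
  1-based R objects.
* PSSM columns are remapped from the file's header letter order (PSI-BLAST
  native) to alphabetical; the parser accepts any header order.
* Frequency smoothing divides by the actual row sum, which equals the
  nominal `(100 + 20k)` denominator when percentage rows sum to 100 and
  keeps rows exactly on the simplex when they do not (PSI-BLAST rounding).
* Symbol canonical order is alphabetical — symbols are deterministic hash
  keys.
* Decoding tie-breaks prefer NEG everywhere (argmax takes the first
  maximum with NEG first).
* The QP conforms to a KKT-residual < 1e−8 contract; no solver brand is
  mandated.
* Model archives are JSON with every double printed as `%.17g`, so
  weights, biases, transitions and propensity tables round-trip
  bit-exactly; a schema version field makes incompatible archives an
  explicit error.
* All randomness flows from one root seed through named sub-streams
  (`deriveSeed`), so the generator, fold assignment and perceptron
  shuffling are independently reproducible, and every pipeline stage is
  bit-identical across reruns.
* Checks in the test suite run at deliberately small problem sizes —
  hundreds of decoder instances with L ≤ 10 against exhaustive
  enumeration, 50-chain training sets, 200-chain recovery simulations,
  fivefold ablations on 50 chains — chosen so the full suite completes in
  minutes on one core while leaving each property statistically
  unambiguous.

## Known limitations

* The propensity is symbol-global; position-specific propensities would
  need far more training data and a different backoff scheme.
* AUC from a margin decoder requires a score construction; max-marginals
  are principled but not calibrated probabilities.
* The one-slack trainer's working set grows linearly with rounds; for
  datasets orders of magnitude larger than the intended scale, constraint
  pruning would be the first addition.
* Running PSI-BLAST and DSSP, PDB parsing, homology filtering and
  interface definition are out of scope: the package starts from their
  outputs.
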