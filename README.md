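# hmsvmPPI

Per-residue prediction of protein–protein binding sites from sequence-derived
evidence, for structural bioinformaticians who have PSI-BLAST profiles and
DSSP accessibility values for their chains but no structure of the complex.
Interface residues cluster into contiguous stretches along the sequence, so
the package treats the problem as *sequence labeling* rather than per-residue
classification: a hidden Markov support vector machine (HM-SVM) scores whole
label paths and is decoded by Viterbi.

## The model

Each residue *i* of a chain is described by a window of per-position feature
vectors at offsets −w…+w (default w = 6, zero-padded at chain ends). A
position contributes:

* **20 PSSM features** — PSI-BLAST log-odds squashed through the logistic
  1/(1+e^(−x));
* **1 relative accessibility** — DSSP-style absolute ASA divided by the
  residue type's nominal maximum area, clipped to [0, 1.2];
* **1 order-profile propensity** (the full model only) — the position's
  frequency profile (PSI-BLAST weighted percentages, smoothed) is reduced to
  an *order profile*: the set of amino acids with frequency above a threshold
  *t* (default 0.15), written as a sorted letter string. A training-time table
  scores each symbol *o* by a smoothed log-odds of its occurrence among
  interface versus other surface residues,

      score(o) = log[(c_int(o)+κ)/(N_int+κS)] − log[(c_surf(o)+κ)/(N_surf+κS)],

  with pseudocount κ and S distinct symbols; the score is logistically
  squashed onto the same (0,1) scale as the other features.

The labeler scores a labeling y ∈ {interface, non-interface}^L by the
linear-chain potential

    F(x, y) = Σ_i ( W[y_i]·x_i + b[y_i] ) + Σ_i T[y_{i−1}, y_i],

and predicts argmax_y F(x, y) (Viterbi; ties resolved to non-interface).
Training is either an averaged structured perceptron or a one-slack
margin-rescaling cutting-plane SVM (objective ½‖(W,b,T)‖² + c·ξ, most violated
constraints found by loss-augmented Viterbi under a Hamming loss over surface
residues; defaults c = 0.1, ε = 1). Per-residue ranking scores for ROC
analysis are max-marginals: the best path score forcing residue *i* positive
minus the best forcing it negative.

Evaluation follows the conventional protocol: chain-level fivefold
cross-validation, metrics over surface residues (Sn, Sp = TN/(TN+FP),
precision, Acc, F1, MCC, rank AUC), pooled over folds.

## Worked example

Simulate a labelled benchmark with the built-in generator (contiguous
interface segments, a co-occurrence composition signal readable from order
profiles, elevated interface accessibility) and run the two-predictor
ablation:

```r
library(hmsvmPPI)

cfg <- generatorConfig(nChains = 40, lengthRange = c(30, 60),
                       compositionShift = 2, asaShift = 0.25, seed = 11)
chains <- generateDataset(cfg)
chains
#> ChainSet: 40 chains, 1775 residues total

abl <- runAblation(chains, trainingConfig(c = 0.1, epsilon = 1),
                   featureConfig(), k = 5, seed = 1)
reportTable(abl)
#>                    Method      Sp %     Sn %     F1 %    Acc %       MCC    AUC %  Prec %
#> 1            HM-SVM basic 100.00000  0.00000  0.00000 82.60870 0.0000000 80.61830  0.0000
#> 2 HM-SVM basic+propensity  99.51524 95.39474 96.50582 98.79863 0.9579003 99.91617 97.6431
```

The baseline (PSSM + ASA) ranks residues reasonably (AUC ≈ 81%) but, at these
hyperparameters, never commits to the minority interface label — its
sensitivity is 0. Adding the order-profile propensity makes the interface
class explicitly predictable: sensitivity 95%, MCC 0.96, AUC ≈ 99.9%. That
gap is the package's central claim in miniature: set-level profile
information that no linear combination of single-letter PSSM features can
express is exactly what the propensity feature supplies.

```r
model <- trainHMSVM(chains, trainingConfig(), featureConfig())
model
#> HMSVMModel: feature set 'basic+propensity', D = 286, half-window 6
#>   |W| = 0.8561, |trans| = 0.2221, bias = (0.1019, -0.1019)
head(sort(propensityScores(model@propensity), decreasing = TRUE), 4)
#>       KR       WY      KNR      FWY
#> 6.312925 6.268800 2.764746 2.477063
```

The top-scoring symbols are the planted interface co-occurrence pairs.

A command-line front end with `generate`, `featurize`, `train`, `predict`,
`evaluate` and `ablate` subcommands is installed at
`inst/scripts/hmsvm-tool.R`; datasets are directories of FASTA + PSI-BLAST
ASCII PSSM + ASA TSV (or `.dssp`) + label TSV files tied together by a YAML
manifest.

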