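# sidefx

Predicting drug side-effect profiles from chemical structure, with
interpretable output: `sidefx` implements sparse canonical correlation
analysis (SCCA) between a binary substructure-fingerprint matrix `X`
(drugs × fragment bits, e.g. the 881 PubChem keys) and a binary
side-effect matrix `Y` (drugs × adverse-reaction keywords, e.g. SIDER
terms). Each canonical component is a small set of chemical fragments
paired with a small set of side-effects that co-occur across drugs — the
kind of correlated ensemble a medicinal chemist can inspect — and the
fitted model scores potential side-effects for any new molecule from its
fingerprint alone.

## Method in brief

After centering and scaling, within-set covariances are approximated by
the identity, so CCA reduces to the SVD of the cross-product matrix
`Z = Xnᵀ Yn` (ordinary CCA, `occa()`). SCCA additionally imposes
`‖α‖₁ ≤ c₁√p` and `‖β‖₁ ≤ c₂√q` with fractions `c₁, c₂ ∈ (0, 1]`, and
solves each component as a penalized rank-one matrix decomposition —
alternating soft-thresholded updates with the threshold set by bisection —
followed by deflation `Z ← Z − d·αβᵀ`. Predictions for a query fingerprint
`x` use either the pseudo-inverse reconstruction `ŷ = (Bᵀ)⁻ Aᵀ x̃`
(de-normalized), or the default correlation-weighted score
`s(x) = B Λ Aᵀ x̃` with `Λ = diag(ρ₁…ρ_m)`. Baselines (random assignment,
Tanimoto k-NN, per-label SVM) and a 5-fold cross-validation harness with
pooled ROC/AUC, per-label AUC and per-drug top-k accuracy round out the
toolkit. The methods vignette (`vignettes/fragment-scca.Rmd`) documents
every modeling and numerical choice.

## Worked example

```r
library(sidefx)

# synthetic benchmark: 500 drugs, 50 fingerprint bits, 40 side-effect
# terms, two planted fragment/side-effect components carried by 20% of
# drugs each, 5% bit-flip noise on planted cells, 5% background
comps <- list(planted_component(1:5,  1:5,  drug_frac = 0.2, flip_noise = 0.05),
              planted_component(6:10, 6:10, drug_frac = 0.2, flip_noise = 0.05))
sim <- generate_planted_dataset(500, 50, 40, comps,
                                background_rate = 0.05, seed = 42)

model <- scca(sim$X, sim$Y, c1 = 0.3, c2 = 0.3, m = 2)
model
#> SCCA model: 50 substructures, 40 side-effects, 2 components
#> canonical correlations: 0.925 0.914

sets <- extract_component_sets(model)
sets[[1]]$substructures$feature         # planted bits fp006..fp010
#> [1] "fp006" "fp010" "fp007" "fp008" "fp009"

rep <- run_cv_experiment(sim$X, sim$Y,
                         list(name = "scca",
                              params = list(c1 = 0.3, c2 = 0.3, m = 4)),
                         K = 5, seed = 7, topk = c(10))
rep
#> CV evaluation: scca
#>   global AUC:      0.7445
#>   mean label AUC:  0.6014 (over 40 defined side-effects)
#>   top10 accuracy:   0.2406 (mean over drugs)
```

The two fitted components recover the planted fragment and side-effect
sets exactly (the top-weighted features are the planted columns), with
training canonical correlations ≈ 0.92. The pooled cross-validated AUC of
0.744 sits essentially at the information ceiling for these noise
settings: about half of the positive cells are independent background
noise, and a clairvoyant predictor that knows the planted truth scores
≈ 0.747 on the same data.

Scoring a new molecule:

```r
scores <- predict(model, sim$X[1, ])             # weighted score, eq-(7)-style
profile <- predict(model, sim$X[1, ], method = "pinv")  # profile estimate
```

## Command-line interface

A launcher installs to `exec/sidefx` with subcommands `simulate`, `fit`,
`predict`, `components`, `baseline` and `evaluate` (YAML-configured CV
experiments); every stochastic step takes an explicit `--seed`. Example:

```sh
sidefx simulate --n 500 --p 50 --q 40 --seed 42 --out data/
sidefx fit --x data/X.tsv --y data/Y.tsv --c1 0.3 --c2 0.3 --m 2 --seed 1 --out model/
sidefx predict --model model/ --x data/X.tsv --out scores.tsv
```

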