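---
title: "Network stratification of longitudinal multi-omic cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network stratification of longitudinal multi-omic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `psnstrat`: the model each stage
implements, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, the numerical choices made where
the design was genuinely open, and the known limitations. It states no
empirical result that the package's tests or `scripts/acceptance.R` do not
themselves compute.

## The problem

Progression cohorts for Parkinson's disease follow three diagnostic groups
— clinically diagnosed patients (PD), prodromal participants with early
indicators but no diagnosis (PL), and healthy controls (HC) — across annual
visits, collecting transcriptomic counts, DNA methylation, genotypes, CSF
protein panels and clinical covariates. Coverage is ragged: participants
drop out, miss visits, or miss single assays, and some assays are nearly
absent from whole subgroups (e.g. a protein panel collected almost
exclusively outside the genetic subgroup). A stratification method for such
data must (i) integrate any subset of modalities, (ii) retain every
participant present in at least one of them, and (iii) support asking *which
modalities are informative at which disease stage*.

## Pipeline stages

### Feature selection

Each modality is reduced before any similarity is computed, so that
near-uniform similarity from thousands of uninformative features does not
wash out the network. The rules, by modality family:

* **Counts (mRNA-, miRNA-like)** — for each pairwise class contrast
  (PD–PL, PD–HC, PL–HC): counts are normalised by median-of-ratios size
  factors; each feature gets a Wald test of the log mean difference with a
  method-of-moments negative-binomial dispersion (`Var = μ + αμ²`, pooled
  within groups), referred to a t distribution with `n₁+n₂−2` degrees of
  freedom; p-values are Benjamini–Hochberg adjusted per contrast; a feature
  is selected if `padj < 0.05` in *any* contrast (aggregation across the
  three contrasts is a union). This is a deliberately simple per-feature
  test, not a reimplementation of shrinkage-based differential-expression
  packages; the t (rather than normal) reference is a small-sample
  correction for the noisy moment-based dispersion, whose far-tail
  anti-conservativeness would otherwise inflate chance selections.
* **Methylation** — a top-`k` variance filter (default cap 300,000 sites,
  sized for genome-wide arrays; ties broken lexicographically by feature ID
  so selection is deterministic), then elastic net.
* **Protein / severity panels** — multinomial elastic-net regression
  (`glmnet`), mixing parameter 0.5, features with any class coefficient
  `|ω| > 0` at the cross-validated penalty. Two conservative conventions
  guard against chance selections: the one-standard-error penalty
  (`lambda.1se`), and a fallback that declares "no informative features
  found" unless the cross-validated model beats the intercept-only model by
  more than one SE of CV deviance. Both matter because selection is computed
  transductively (below): a handful of chance-selected features would
  otherwise leak label information into the network.
* **Genotypes** — mean-centred PCA; the first 20 components become derived
  features. Loadings and centres are stored and reused to project
  later-time-point or held-out data; since genotypes are time-invariant,
  the projection is fit once at baseline.
* **Clinical** — no selection (six covariates).

Whenever a rule selects nothing, all features are retained
(`fallback_used` is recorded).

### Patient similarity networks and fusion

Per modality, similarity between participants' selected-feature vectors is
Pearson correlation when the modality has at least 10 features (mapped to
`(1+r)/2` so affinities are nonnegative), otherwise the scaled Euclidean
kernel `exp(−d²/(μ·σ²))` with `σ` averaging the two participants' mean
k-nearest-neighbour distances and their own distance. Each similarity
matrix is sparsified to a weighted KNN graph (`k = 15` by default; each node
keeps its `k` most similar neighbours, ties broken by participant ID; the
edge set is union-symmetrised).

Affinities are aligned to the union of participants — a participant absent
from one modality is inserted into that modality's affinity with uniform
weight `1/n`, so fusion operates on aligned matrices while the participant's
actual information comes from the modalities that measured them — and fused
by similarity network fusion: each modality's matrix is row-normalised into
a full kernel `P_v` (half the probability mass on the diagonal) and a sparse
local kernel `S_v` over `snf_K = 20` neighbours, then `snf_t = 20` rounds of
`P_v ← S_v · mean(P_{-v}) · S_vᵀ` (re-normalised and symmetrised each
round), and finally the average of the `P_v` is re-normalised and
symmetrised. With a single modality the update diffuses the modality's own
kernel; fusing a duplicated modality is *exactly* equivalent to the
single-modality case. The diagonal is pinned at `1/2` by the normalisation
convention and ignored downstream (self-loops are added explicitly by the
classifier's adjacency normalisation). Note that prolonged cross-diffusion
homogenises similarity ranks *within* tight clusters: the fused network
preserves cluster-level structure (verified spectrally in the tests) but
not the exact identity of each node's k nearest neighbours.

None of the fusion parameters are prescribed by prior work at the values
used here; `k`, `snf_K`, `snf_t` and the bandwidth scale `μ = 0.5` are
standard fusion practice, exposed in `graph_params()`, and documented as
package defaults rather than asserted as anyone else's.

### The multi-modal-encoder GCN

Each modality's selected matrix is compressed by a two-layer encoder: a
shared fixed-width first layer (`layer1_dim`, default 64 in the experiment
drivers; 128 in `fit_gcn_mme()`'s signature for larger runs) with ReLU, and
a per-modality second layer (`layer2_dims`, tunable; `tune_layer2()`
performs a coordinate search over a grid, default `{8, 16, 32, 64}`
maximising mean validation F1). Participants missing from a modality
receive the per-dimension *median* of present participants' second-layer
outputs — median, not mean, imputation, computed from all present
participants (not training participants only), mirroring the transductive
construction. Each modality is then linearly decompressed to a shared
latent dimension (`shared_dim`, default 32/64) and the element-wise mean
over modalities forms the node features. A two-layer graph convolutional
network (`Ĥ = σ(D̃^{-1/2}(W+I)D̃^{-1/2} H Θ)`, hidden width 64, dropout 0.5
between convolutions) over the fused network emits class logits.

Training is full-batch Adam (learning rate 0.01, weight decay 5e-4 on
weight matrices), cross-entropy on the training mask only, class-weighted
by inverse class size (cohorts of this kind are imbalanced, with HC the
smallest class; weighting is on by default and exposed in
`train_config()`), early stopping on validation loss with patience 30 and
restoration of the best parameters. The forward and backward passes are
explicit matrix algebra; the gradient of the median-imputation step is
routed to the row(s) attaining each per-dimension median (split evenly for
even counts) and is verified against finite differences in the test suite.
Given a seed, training is bitwise deterministic.

### Evaluation and ablation

Stratified 5-fold cross-validation: each fold is the 20% test set; the
remaining 80% is stratified-split 85/15 into training and validation
(68%/12%/20% overall; validation counts are allocated across classes by
largest remainder so the 12% is exact). Metrics are accuracy, class-size
weighted F1 (`Σ_c (n_c/N)·F1_c`, zero convention for empty denominators)
and improvement over the majority-class baseline. Feature selection and
network construction are computed once per time point on all participants
(the transductive design); metrics are reported only on test masks. This
leaks a small amount of label information through selection — see
*Limitations*.

The ablation trains every nonempty modality combination on identical splits
restricted to each combination's participant union. "Comparable
performance" for the reporting tie rule is operationalised as mean accuracy
within one pooled standard error of the best; among comparable combinations
the largest participant count is reported. The severity-score comparator
(`baseline_severity_model()`) runs the *identical* pipeline on the severity
modality alone, so the comparison isolates information content rather than
classifier differences.

### Longitudinal transfer

`subset_longitudinal()` restricts to participants present at every time
point in at least one included modality and fixes a single stratified 80/20
train/test partition reused at every time point, so all cells of the
transfer matrix are evaluated on the same test set. `train_at(t)` runs the
full pipeline at time `t`; `test_at(t')` rebuilds the network and node
features from time-`t'` data *using the features selected at `t'`*, then
applies the frozen model.

A frozen encoder expects the train-time feature set, so a reconciliation
rule is needed when the test-time selection differs. Two strategies are
implemented: the default restricts the first-layer weights to the
intersection of train- and test-time selected features (exact, no refit);
the alternative (`"lsq"`) refits only the first affine layer by least
squares so the full test-time feature set reproduces the shared-feature
pre-activations. The intersection rule is the default because it is
deterministic and parameter-free; the genotype modality always intersects
fully (its PCA projection is fit once at baseline). The choice is recorded
in run manifests.

## The synthetic cohort generator

The generator is first-class, tested code; it emulates the *structure* of a
longitudinal Parkinson's cohort so every downstream stage is exercisable
without restricted data:

* three classes with subgroup taxonomy (genetic/idiopathic PD;
  genetic/RBD/hyposmia PL; controls), default sizes 60/50/40 with HC
  smallest and subgroup fractions taken from the year-0 ratios of a large
  progression cohort (PD: 42% genetic; PL: 77% genetic, 12% RBD, 11%
  hyposmia);
* six modality families: negative-binomial counts with per-participant
  lognormal library-size factors (dispersion 0.2), methylation-like beta
  values simulated as Gaussians on the logit scale (keeping `(0,1)` support
  while allowing additive effects), Gaussian protein panels, time-invariant
  genotype-PC-like features whose signal separates risk-variant carriers
  (genetic-subgroup PD and PL) from everyone else — so the genotype modality
  can distinguish carriers from controls but not PD from PL — a clinical
  block (age, sex, education plus three lifestyle scores), and a severity
  scale with class-dependent baseline and class-dependent time slope;
* effect sizes parameterised as the separation between adjacent class means
  in units of the feature noise SD on each family's natural scale, with a
  per-time-point schedule (constant for genotypes, optionally strengthening
  over time for methylation-like signals); alternatively an explicit
  per-time-point, per-class offset grid (`class_offsets`) — used to emulate
  *disease drift*, where the prodromal class sits at a fixed distance from
  controls at every visit while the PD class moves further from the
  prodromal group as disease progresses. The drift mechanism, not a
  symmetric widening of all class gaps, is what reproduces the published
  longitudinal phenomenology: a model trained late in the disease course
  transfers back to earlier visits losing accuracy mainly by misclassifying
  PD participants as prodromal (they sit below the late threshold early
  on), while prodromal and control predictions stay stable. Under symmetric
  widening, early visits are uninformative for every model and early-trained
  models would transfer *up* better than late-trained models transfer
  *down* — the opposite ordering. An optional per-participant
  progression-rate multiplier (`progression_sd`, lognormal) superimposes
  slow and fast progressors on the PD drift, emulating the hard-to-classify
  PD subset real cohorts show; it is off in the packaged experiments
  because boundary placement under strong rate heterogeneity reverses the
  early-time misclassification asymmetry;
* year-over-year dropout at a configurable rate outside a designated
  longitudinal core (default 40% of each class) that never drops out,
  guaranteeing the longitudinal module a usable all-time-point subset;
* per-modality row missingness with two invariants: every enrolled
  participant remains present in at least one modality at every enrolled
  time point, and a subgroup restriction can remove a modality from (all
  but one of) the participants outside the allowed subgroups, mirroring a
  protein panel nearly absent from the genetic subgroup.

Generation is bitwise deterministic given the seed. What the generator does
**not** emulate: raw sequencing reads or genotype calls, probe-level
methylation artefacts, batch effects, correlated feature blocks
(co-expression structure), medication effects, or participants converting
between classes over time. Passing tests on these cohorts therefore
demonstrate that the pipeline recovers the *kinds* of structure it assumes
— planted class separation, modality-specific information, time-varying
signal — not that it would achieve any particular accuracy on real patient
data.

## Numerical choices and degenerate inputs

* Pearson correlation of a constant participant vector is undefined; it is
  substituted with 0 (and 1 on the diagonal).
* KNN and local-kernel neighbour ties are broken by participant-ID order,
  making every graph deterministic.
* A PCA request beyond the matrix rank returns the available rank with a
  message.
* Variance-filter ties are broken lexicographically by feature ID.
* The null-calibration experiment in the acceptance material uses a
  *balanced* 50/50/50 cohort: with class-weighted loss, an uninformed
  predictor scores exactly the majority rate only under balance; under
  imbalance the weighting itself induces a −1/15-scale offset that would
  measure the loss prior rather than label leakage.
* Experiment problem sizes in tests and the acceptance script (cohorts of
  150 participants, hundreds of features per modality, 2–4 time points,
  encoder widths 16–64) are desk-scale choices that keep a full
  brute-force ablation and a 4×4 transfer matrix comfortably runnable on a
  single CPU; all dimensions scale up through configuration.

## Limitations

* **Transductive leakage.** Selection and network construction use all
  participants (including test participants' labels, through selection).
  This mirrors the transductive design the method follows, and its cost is
  measurable: on null cohorts an occasional chance-selected 1–2-feature
  signature can lift improvement-over-majority to roughly +0.07 (about one
  seed in ten at n = 150). The conservative elastic-net conventions above
  exist precisely to keep this small; the differential test's FDR threshold
  admits its nominal share of chance features by construction.
* **Transductivity proper.** Every node must be present in the graph at
  training time, so the longitudinal analysis is restricted to participants
  observed at all time points — a survivor-bias-prone subset. Inductive
  graph models would lift this restriction and are out of scope here.
* **No medication or trajectory modelling.** Class labels are treated as
  fixed per participant; conversion events and treatment effects are not
  represented, in the generator or the models.
* The per-feature differential test is an intentionally simple
  approximation (no dispersion shrinkage, no GLM offsets beyond size
  factors); it is suitable for selection, not for inference about
  individual features.
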