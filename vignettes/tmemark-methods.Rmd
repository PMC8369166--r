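---
title: "tmemark: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmemark: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmemark)
```

# The modeling idea

Response to immune-checkpoint blockade depends on the state of the whole
tumor microenvironment — which immune cells are present, which signaling
programs are running, which ligand–receptor circuits are wired up — not
on any single transcript. `tmemark` encodes that state as five
*views*: compact feature matrices derived from bulk RNA-seq through
prior knowledge, regresses them against a panel of published
transcriptome-based surrogates of immune response treated as *tasks*,
and reads biomarkers and patient-level predictions off the fitted
multi-task models. Because ground-truth response labels are scarce, the
surrogates act as abundant proxy targets during training; actual
responder labels enter only at evaluation time.

# The five views

**Cell fractions.** Bulk TPM is modeled as a non-negative mixture of
cell-type-specific TPM profiles. We solve, per sample, non-negative
least squares over the signature genes (Lawson–Hanson active set) and
define `Other = 1 − Σ immune fractions` exactly; when noise pushes the
raw sum above 1, fractions are rescaled first. Because non-regulatory
CD4 T cells and Tregs are hard to separate, the reported CD4 column is
their sum while Treg remains its own column — 11 features for the
canonical 10-type signature. NNLS is the simplest estimator satisfying
this contract; the robust-regression refinements of full deconvolution
suites are deliberately out of scope.

**Pathway activity.** Each pathway is a linear functional of gene-level
z-scores: genes are put on log2(TPM+1), z-scored *across samples* with a
population (n-denominator) SD, and combined with signed model weights.
Constant genes get z = 0; a pathway whose genes are all absent is
dropped with a warning. Genes used by the response scores can be
excluded from the pathway model so targets and features do not share
transcripts — without this the regression would partially learn an
identity.

**TF activity.** A rank-based normalized enrichment score: per sample,
genes are ranked (average ranks on ties), mapped to quantiles
q = (rank − 0.5)/n — the −0.5 keeps Φ⁻¹ finite at both extremes — and
to normal scores z = Φ⁻¹(q). A regulon's score is
Σ mor·z / √(n targets). Only confidence grades A and B are used by
default and a TF needs ≥5 present targets; both are arguments. The
score is invariant to any strictly monotone transform of a sample's
expression, so TPM vs log-TPM is immaterial here.

**LR pairs.** A pair's weight is the minimum of log2(TPM+1) over *all*
constituent genes, ligand and receptor complexes pooled — an interaction
is only as strong as its scarcest component. The database is first
filtered to pairs expressible in the TME: every gene ≥10 TPM in at least
one prior cell type, and at least one ordered (sender, receiver)
combination — autocrine included — in which all ligand genes pass in the
sender and all receptor genes in the receiver. Feature columns that are
identical across all samples (pairs sharing their limiting gene) are
merged, names joined with `_`. The grouping rule in the literature
("involving the same gene") is ambiguous; exact-duplicate merging is our
interpretation and is recorded as such, with the group membership stored
so new cohorts map onto trained features deterministically.

**CC pairs.** Communication between aggregated cell types (12
TME-aggregated types plus one pan-cancer type → 13² = 169 ordered
pairs). Each LR pair is statically assigned to the (sender, receiver)
aggregated pairs licensed by the prior expression table; per patient the
pair is *active* when all its genes reach 10 TPM in the bulk profile,
and the CC score is Σ 1/f over assigned active pairs, f being the
fraction of a designated reference cohort in which the pair is active —
rare interactions discriminate patients more. Frequencies are computed
once on the reference cohort and stored with the model; pairs with
f = 0 are excluded rather than producing infinities. The patient-level
activity rule is our extension of the cell-type-level threshold (the
source method defines activity only at the prior level); the alternative
— weight > 0 — was rejected because it makes nearly every pair active in
every patient.

Any external feature matrix (e.g. proteomics) can ride along as a view;
features with any missing value are dropped at construction and logged,
mirroring the rule used for protein panels.

# Response scores and task selection

The score engine implements functional forms, not fixed gene lists:
geometric mean of TPM + pseudocount (default 0.01, to survive zeros);
weighted mean on a chosen transform, optionally after rank-normalizing
each gene across samples to [0, 1] via (rank − 1)/(n − 1); a count of
strictly satisfied gene-pair inequalities (ties never count, so the
score is monotone-transform invariant); and a first principal component
whose sign — intrinsically arbitrary — is anchored to the mean of
designated already-computed tasks, flipping when the correlation is
negative and warning when it is exactly zero. Published gene lists are
supplied as YAML/GMT configuration; the synthetic prior generator ships
a six-score panel wired to its own marker blocks. Task selection keeps
scores whose median Pearson correlation with the other scores — median
across cohorts — exceeds 0.4; constant columns would have undefined
correlations and are treated as 0 with a warning.

# The learners

**RMTLR.** The objective is

$$\frac{1}{N}\sum_{i=1}^N \lVert y_i - \beta_0 - x_i\beta\rVert_2^2
  + \lambda \sum_{j=1}^p \big((1-\alpha)\lVert\beta_j\rVert_2
  + \alpha\lVert\beta_j\rVert_2^2\big),$$

with β_j the j-th feature *row* shared across tasks, so the group-lasso
term zeroes a feature for all tasks or none. Note the convention:
(1 − α) weighs the group-lasso term and α the ridge term — the reverse
of glmnet's. We implement the objective as printed and provide a
`convention = "swapped"` escape hatch that maps α ↦ 1 − α for users
accustomed to the other parameterization. Optimization is block
coordinate descent: with c_j the doubled partial-residual correlation,

$$\beta_j \leftarrow c_j\,
  \frac{(\lVert c_j\rVert - \lambda(1-\alpha))_+}
       {\lVert c_j\rVert\,(d_j + 2\lambda\alpha)},$$

which for standardized features reduces to
(2‖r_j‖ − λ(1−α))₊ / (2 + 2λα). The inner loop is compiled (Rcpp); the
objective is provably non-increasing per sweep and the test suite checks
the groupwise KKT conditions and agreement with an independent
proximal-gradient minimizer to 1e−6 relative. Convergence is declared
when the largest coefficient change in a sweep drops below `tol`
(default 1e−6; `max_iter` 10,000). λ_max — the smallest λ zeroing every
row — is computed from the data; for α = 1 the group weight vanishes and
is floored at 1e−3 purely to keep the path generator defined.
Hyperparameters are tuned by 5-fold cross-validation over a geometric
λ path (default 20 points down to 0.01·λ_max) with warm starts, mean
squared error averaged over tasks and folds, ties broken toward the
stronger penalty. Whether the original procedure tuned α or fixed it is
not documented; we default to a fixed α = 0.5 during ensemble training
and expose the grid.

**BEMKL.** Each view yields a Gaussian kernel
K(x, x′) = exp(−‖x−x′‖²/2σ²) with σ defaulting to the median pairwise
training distance (no width is documented in the source method; the
median heuristic is the field's standard default). The regression
f(x) = aᵀ(Σ_m e_m k_m(x)) + b is fitted by deterministic variational
mean-field updates with gamma priors (all shapes/rates default 1) on the
per-element precision of a, the intermediate-representation noise, the
bias, the kernel weights, and the output noise. Kernel weights e are a
single factor shared across tasks; sample weights a and bias b are per
task. Our factorization treats b and e as separate mean-field factors
(the reference implementation keeps them jointly Gaussian); on the
scales tested this changes fitted values negligibly and keeps the
update algebra transparent. 200 iterations are the default;
updates are deterministic, so fits are exactly reproducible. One
practical caveat discovered during development and now asserted in
tests: the mean-field pair (a, e) can jointly collapse toward the prior
when the target is far from unit scale — the training protocol always
standardizes Y, which avoids the regime entirely.

# Training protocol, biomarkers, prediction

Training repeats 100 times: each run draws a random 20% test split,
standardizes the training block (features and tasks), standardizes the
held-out block *with the training statistics*, tunes (RMTLR) or uses
configured priors (BEMKL), fits, and records held-out Spearman
correlations per task. Run seeds derive from the master seed by a
counter scheme, so run r is identical whether you request 10 or 1,000
runs. Multiple views are concatenated column-wise for RMTLR and enter
BEMKL as separate kernels.

Biomarkers summarize the 100 RMTLR fits: per feature and task the median
run-weight (nonzero ⇔ selected by the regularization in ≥50% of runs),
then the median across tasks; a feature is *robust* when that final
median is nonzero. Significance against zero is tested per task on the
100 run-weights. The natural two-sample rank-sum test against a
degenerate all-zero sample is ill-defined, so we use the one-sample
signed-rank test — an interpretation, flagged here. Features significant
in fewer than half the tasks carry a low-consistency flag (the "X" of
the heatmap convention), and the across-task variance of the per-task
medians is reported as a stability diagnostic. Task clustering uses
1 − Pearson correlation distance with average linkage (k = 4 by
default); the source method names neither algorithm nor linkage, so both
are arguments.

Prediction on a new cohort derives the views with the stored provenance
(LR grouping, CC frequencies), averages the 100 run-models per task,
averages tasks within a view, and averages views into the ensemble score
— an arithmetic mean, asserted exact in the tests. TMB enters either as
a tertile penalty P + c·γ (c = −1/0/+1 for low/moderate/high) or as a
weighted average (1−η)·P_scaled + η·TMB with classes mapped to 0/0.5/1;
min–max scaling of P is per evaluation cohort, since no reference
population is documented for it. Tertiles split ties by stable sample
order. Evaluation uses the rank-formulation AUC with tie correction,
vertical ROC averaging on a fixed FPR grid, and Wilcoxon tests (exact
for ≤25 observations, tie-corrected normal approximation with continuity
correction above) with effect size r = Z/√n.

# The synthetic world

`make_priors()` allocates disjoint gene blocks: high-expression marker
blocks per cell type (signature columns normalized to TPM scale), sparse
signed pathway weights, regulons with mostly-activating targets, and an
LR database over 24 fine TME cell types (two per aggregated type) plus a
pan-cancer type, constructed so every pair passes the 10 TPM filter.
`make_cohort()` draws cell fractions from a Dirichlet over the immune
types plus a tumor-like "other" component — default α = (0.5, …, 0.5, 5),
i.e. tumor-dominated mixtures with immune content of realistic scale —
forms bulk TPM as signature × fractions plus a flat other-cell profile
(zero on marker genes, so the noiseless world is exactly identifiable),
multiplies pathway/TF block genes by 2^(gain·activity·sign) with
per-sample standard-normal activities, toggles LR pair genes between an
active and an inactive level across the 10 TPM threshold, applies
multiplicative lognormal noise (σ default 0.1 on the log scale, chosen
to keep TPM positive with coefficient of variation near 10%), and
renormalizes each sample to 10⁶. Responder labels follow
logistic(intercept + effect·z) where z standardizes a latent immune
activity (0.8·CD8 fraction + 0.4·mean of two spiked pathway activities);
the intercept is solved for the target prevalence (default 0.35,
typical of ICB trial cohorts; default effect size 2 on the log-odds
scale).

What the generator does *not* emulate: real TCGA expression
distributions, gene–gene correlation beyond the block structure, batch
effects, cancer-type heterogeneity, and realistic LR co-expression. A
green end-to-end test therefore establishes that the machinery recovers
planted structure and propagates signal to held-out predictions — not
that any particular clinical performance would be attained on real
cohorts.

# Numerical and design notes

* NNLS uses a gradient-scale tolerance for the active-set entering test
  but a relative machine-precision guard on the coefficients, so
  genuinely tiny fractions (~1e−4) are retained; an earlier
  coefficient-scale tolerance silently zeroed them.
* z-scoring inside views uses the population (n) denominator;
  standardizers inside training use the sample (n−1) SD, matching the
  conventions of each context. Constant columns map to 0 and are
  flagged.
* Model serialization is self-describing JSON at full double precision
  (17 significant digits); round-trips are exact for integers and below
  1e−12 for reals, and a version field makes stale files an explicit
  error.
* On pure-noise targets, minimum-CV-error selection keeps a small
  nonzero feature set in roughly a fifth of seeds (measured over 100
  seeds at N = 200, p = 30); the suite asserts the honest version of the
  sparsity property — median selection empty, clear majority of seeds
  below 10% of p — rather than a 90% rate the procedure does not attain.
* The acceptance end-to-end run trains 100-run ensembles on the
  cell-fraction and pathway views only (the views carrying the latent
  signal) with 150 training / 100 held-out samples across 20 seeds, a
  deliberate scale-down to keep the suite within a single-CPU budget.

# Known limitations

* Deconvolution is plain NNLS on TPM; collinear signatures (e.g. closely
  related T-cell subsets) will trade off against each other more than a
  regularized or robust estimator would allow.
* BEMKL prediction currently supports single-view ensembles at the
  matrix level; multi-view BEMKL trains and evaluates held-out splits,
  but cohort-level prediction plumbing is RMTLR-first.
* The exact published gene lists for most response scores live in
  supplementary material of the respective papers and are consumed as
  user-supplied configuration, not shipped.
* Survival analysis, figure reproduction on real cohorts, and read-level
  preprocessing are out of scope.
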