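---
title: "resstack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{resstack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resstack)
```

## The problem

Self-supervised protein models are routinely scored on masked-residue
prediction: hide the amino acid at a site, ask the model for a probability
over the 20 canonical residues, and call the prediction correct when the
top-probability amino acid equals the wildtype. Sequence-based language
models and structure-based convolutional models solve this task from very
different inputs, and panels of such predictors show a characteristic
structure: similar overall accuracies, strong correlation of per-protein
accuracy *within* an input modality and little correlation *across*
modalities, modality-specific strengths by amino-acid class and burial
(structure models on buried aliphatics and on G/P, sequence models on polar
and charged residues), and confidence that decays with solvent exposure.

`resstack` packages the analysis around that structure: a common interchange
format for per-site 20-way predictions, a stacking network that combines
four predictors, the full evaluation battery, a Shrake–Rupley RSA stage, and
a synthetic panel generator so that everything is testable without any
pretrained network or structure download.

## The stacking network

The combiner is a fully connected network
$y = \mathrm{softmax}(W_3\,\mathrm{relu}(W_2\,\mathrm{relu}(W_1 x + b_1) + b_2) + b_3)$
with input dimension 80 (four 20-way probability vectors concatenated in a
fixed, alphabetical model order), hidden widths 120 and 60, and a 20-way
softmax output. It is trained with Adam (fixed learning rate $10^{-4}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on categorical
cross-entropy for a fixed 150 epochs, one training example per site, target
the one-hot wildtype. There is deliberately no validation split or early
stopping: the recipe is a fixed-epoch fit, with `epochs` exposed in
`train_config()` for scaled-down runs.

Choices the recipe leaves open, and what this package does:

* **Batch size** 128, drawn from a global per-epoch shuffle across proteins
  (sites, not proteins, are the examples; shuffling across proteins is noted
  as this package's choice, not an inferred intent).
* **Initialization**: He-style uniform ($\pm\sqrt{6/\mathrm{fan~in}}$),
  standard for relu stacks; biases zero. All initialization and shuffling
  derive from the config seed, so two runs with the same seed produce
  bit-identical loss traces.
* **Model order**: alphabetical by model id, frozen into the saved
  parameters; prediction-time inputs are reordered to match, which removes a
  silent block-permutation failure mode.
* **Model file**: a self-describing JSON archive (shapes, weights at full
  double precision, model order, alphabet). Round trips are exact to below
  1e-12 per weight; a text format keeps the artifact portable and
  diff-able.

The two rejected baselines are implemented as stated: componentwise
averaging of the four vectors, and the single highest probability across all
80 entries (ties: alphabet order first).

## Evaluation definitions

* **Per-protein accuracy**: fraction of a protein's sites whose top
  prediction equals the wildtype. Ties in a probability vector break in
  alphabet order, a documented contract rather than an accident of `which.max`.
* **Class accuracy**: sites pooled across proteins within amino-acid
  classes. The default map is aliphatic {A,V,L,I,M}, aromatic {F,W,Y}, polar
  {S,T,N,Q,C}, positive {K,R,H}, negative {D,E}, unique {G,P}. Histidine's
  placement is genuinely ambiguous; it sits in `positive` here and the whole
  map is a function argument so another scheme can be dropped in.
* **Accuracy correlation**: Pearson product-moment r with a two-sided
  t-transform p-value (`stats::cor.test`), no multiple-testing correction.
  Constant vectors give an `NA` result with a warning; fewer than three
  proteins is an error.
* **Agreement taxonomy**: each site is labeled by which individual models'
  top predictions match the combined model's top: `ALL`, `NONE`, a nonempty
  subset of the sequence pair (`SEQUENCE_ONLY`), of the structure pair
  (`STRUCTURE_ONLY`), otherwise `MIXED`. The raw agreeing subset is returned
  alongside the label, so finer groupings ("at least one sequence model",
  ...) are report-level relabelings. Category accuracy conditions on the
  combined model's top prediction only, not on joint correctness of the
  agreeing models.
* **Confidence–RSA histogram**: half-open bins of width 0.05 in both RSA
  and confidence; the confidence axis closes its last bin at the domain top
  so a confidence of exactly 1 is counted. Populated cells carry the count
  bands 1–25, 26–50, 51–75, >75.

## The synthetic panel

`simulate_panel()` generates labeled proteins and four predictors' outputs
with the statistical structure sketched above. Per site:

1. RSA is drawn from a two-component Beta mixture (weights 0.45/0.55,
   Beta(0.6, 8) core-like and Beta(2.5, 3.5) surface-like), giving roughly
   half the sites RSA < 0.2, the conventional buried/exposed threshold.
2. The wildtype is drawn from a per-burial composition (hydrophobics
   enriched in the core, polar/charged on the surface, roughly
   natural-abundance scale).
3. Each model flips a correctness coin: the site's blended latent
   $v = \rho u + (1-\rho) w$ (with $u$ shared per model type and $w$
   private) is compared against the model's skill for the site's
   (class, burial) cell. Correct calls put a Beta-drawn top probability on
   the wildtype; wrong calls put it on a decoy from a class-conditional
   kernel; the remaining mass is uniform over the other 19 residues.

Three mechanism details deserve a note:

* **The blend is not uniform.** For $0 < \rho < 1$, $v$ has a trapezoidal
  distribution, so the realized correct-call probability is the blend CDF
  evaluated at the skill value, compressing extreme skills toward the
  middle. The shipped defaults were calibrated analytically *through* that
  CDF (`tools/calibrate.R` in the source tree) so the four models' mean
  per-protein accuracies land near 0.61, 0.64, 0.65 and 0.68 — calibration
  anchors, not test targets.
* **Decoys are correlated within a type.** A second shared latent drives
  decoy choice through the same blend. Without it, two same-type models
  essentially never agree on a wrong residue, cross-model agreement becomes
  a near-infallible oracle, and naive probability averaging is close to
  unbeatable — the opposite of how real panels behave, where pair-only
  agreement with the combined model is right only ~70–80% of the time.
* **Confidence profiles are heterogeneous.** The sequence pair outputs
  sharp, near-one-hot distributions (correct/wrong Beta(12,2)/Beta(9,3) and
  Beta(16,1.5)/Beta(12,2.5)); the structure pair is diffuse
  (Beta(6,3)/Beta(4,4) and Beta(8,3)/Beta(5,3.5)). Within every model the
  correct-call distribution stochastically dominates the wrong-call one
  (checked on a CDF grid), so confidence tracks correctness and, because
  skill falls with exposure, declines with RSA. Across models, the
  calibration differences are what make averaging collapse toward the
  sharpest model instead of improving on it — with a single shared
  confidence model, averaging four vectors was nearly Bayes-optimal and no
  stacker could beat it. Top probabilities are floored at 0.1 so the
  intended top entry is always the argmax (an unfloored draw below 1/20
  would let the uniform remainder outrank it and break the
  skill-zero-means-accuracy-zero contract).

Randomness is organized as named substreams hashed from the master seed —
one per (model, protein), one per (type, protein) for each shared latent,
one per protein for labels — so identical seeds give bitwise-identical
panels and adding a model never perturbs another model's draws.

**What the generator does not emulate**, and hence what a green test does
not establish: the real models' full 20-way probability shapes and entropy
spectra (non-top mass is uniform here), protein-family effects, per-protein
skill heterogeneity (each model's skill matrix is shared by all proteins, so
accuracy variance across proteins is sampling plus composition variation
only), and any particular real dataset's numbers. Tests on this panel
establish that the *machinery* — training, evaluation, correlation and
taxonomy code — behaves correctly in a world with the documented structure,
not that any specific published accuracy is reproduced.

## Relative solvent accessibility

`shrake_rupley()` is a from-scratch test-point implementation: each atom's
van der Waals sphere is inflated by the probe radius (default 1.4 Å) and
covered with a deterministic golden-spiral point set (default 960 points); a
point is exposed iff it lies outside every neighbor's inflated sphere, and
SASA is the exposed fraction times the inflated sphere area. There is no
randomness, so results are bit-stable; doubling the point count moves a
single-atom SASA by under 0.2%. Hydrogens are ignored (heavy-atom SASA is
the convention; protonation in the original workflow served model input,
not surface area), alternate locations resolve to the highest-occupancy
conformer, and HETATM records are skipped except through an alias map
(MSE→MET by default). Residue SASA is normalized by the Tien et al. (2013)
theoretical maximum ASA values, shipped as an editable TSV; RSA is not
clipped at 1. The vdW radius table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
SE 1.90) is a single documented table rather than a bit-exact copy of any
particular tool's radii: downstream use is 0.05-wide RSA binning, where
radius differences of a few hundredths of an Å are immaterial. Which exact
SASA algorithm and point count the original workflow used is not recorded;
Shrake–Rupley at 960 points is adopted and both knobs are exposed.

## Curation and splitting

`filter_training_entries()` applies the training-set hygiene rules in a
fixed order — homology to an excluded id (any cluster mate counts), length
above 1024 residues (the input limit of 1024-token sequence models; 1024
itself is retained), failed protonation preprocessing (an input flag;
protonation itself is external) — and reports exactly one reason per
removal. Cluster membership comes from RCSB-style entity cluster lists;
PDB ids match entity ids case-insensitively by the prefix before the
underscore, and cluster ordinals are 1-based as is natural in R.
`split_train_test()` splits by protein, never by site, and keeps whole
clusters on one side; a cluster too large for the test side goes to
training. The original workflow used a fixed external test set; a seeded
homology-aware split is supported in addition because self-contained
testing needs one.

## Numerical contracts

* Probability vectors are renormalized on read when their sum is within
  1e-3 of 1 (serialization slack) and rejected beyond that (corrupt rows).
* Write/read round trips preserve probabilities to 1e-9 (full
  double-precision serialization), model weights to 1e-12.
* Sequence letter X is accepted by the FASTA reader; sites with wildtype X
  are excluded from training and evaluation, with a message.
* Gradients are analytic and are checked against central finite differences
  to a relative 1e-4 in the test suite; the forward pass is checked against
  a hand-computed scalar chain to 1e-12.

## Known limitations

The generator's realized accuracy depends on the blend CDF rather than the
raw skill number whenever latents are shared, which is documented but can
surprise; the combiner is CPU-only, pure R, and sized for desk-scale corpora
(tens of thousands of sites), not for millions; the PDB reader handles
coordinate ATOM/HETATM records only (no mmCIF); and per-protein skill
heterogeneity in the simulator is not implemented — the observed variance
of per-protein accuracy is narrower than real panels show for language
models.
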