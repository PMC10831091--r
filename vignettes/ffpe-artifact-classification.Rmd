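---
title: "Classifying FFPE-induced artifacts in somatic variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying FFPE-induced artifacts in somatic variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Formalin fixation preserves tissue morphology but damages DNA: it
fragments templates and deaminates cytosine to uracil, which sequencing
chemistry reads as thymine. Somatic variant calling on FFPE tumour
material therefore produces, on top of the real mutations, a large load
of artifactual calls with a characteristic profile: low mutation allele
frequency (MAF), a substitution spectrum dominated by C>T and G>A
changes, support concentrated in a single read-pair orientation
(deamination damages one strand, so the F1R2/F2R1 counts of the
alternate allele are skewed), and shorter insert fragments. Hard filters
that remove all low-frequency calls also discard genuine subclonal
variants, which is exactly the signal that matters for tumour burden
estimates, ctDNA panel design, and neoepitope discovery.

`ffpesieve` treats the problem as supervised classification. When a
matched fresh-frozen (FF) sample of the same tumour is available, the
FF call set defines truth: an FFPE call present (same chromosome,
position, reference and alternate allele) in the FF calls is a *true
variant*; an FFPE-private call is an *FFPE artifact*. A small
feed-forward network trained on per-call annotation features then
assigns new calls a probability of being a true variant.

## Truth labeling and data partition

`label_ffpe_calls()` implements the matching rule on full variant keys;
a different alternate allele at a shared site is a different variant,
matching the per-allele semantics of the caller. No left-alignment or
representation normalisation is applied: matched FF and FFPE samples
are assumed to come through one identical calling pipeline, so allele
representations agree by construction. Duplicate keys within one call
set are rejected as ambiguous rather than silently collapsed.

This labeling inherits a known caveat: an FFPE-only call could be a
real subclonal variant missed in the FF sample through regional tumour
heterogeneity. The package makes no attempt to rescue such calls; on
synthetic data the issue does not arise because truth is known by
construction.

`split_train_validation()` partitions each source file independently at
a 7:3 ratio (training size per file is round-half-up of 0.7·n — the
rounding side has to be pinned for reproducibility, and half-up was
chosen), deterministically in the seed. Because technical replicates of
one tumour may be treated as independent samples,
`exclude_training_overlap()` removes from the validation set any
variant key seen anywhere in training before evaluation. The split is
unstratified within each file; with hundreds of calls per file the
label proportions are stable, and stratification would add a degree of
freedom the procedure does not need.

## The 41 predictors

Each called allele is represented by an ordered 41-entry vector
(`default_feature_schema()`, version-tagged so model bundles can detect
drift):

* 22 raw caller annotations: `DP`, `AD_ref`, `AD_alt`, `AF` (computed
  as `AD_alt / (AD_ref + AD_alt)`), the four `F1R2`/`F2R1` orientation
  counts, `MBQ`, `MFRL`, `MMQ` (ref and alt slots), `MPOS`, `TLOD`,
  `ECNT`, `POPAF`, `GERMQ`, `SEQQ`, `STRANDQ`, `ROQ`;
* 4 derived values: the SOB score, the ref-vs-alt orientation cosine,
  and the two allele lengths;
* a 3-way variant-class indicator (SNV/insertion/deletion);
* a 12-way strand-specific substitution-type indicator (`A>C` … `T>G`).

The strand orientation bias score is

$$\mathrm{SOB} = \frac{|F1R2_{alt} - F2R1_{alt}|}{F1R2_{alt} + F2R1_{alt}} \in [0, 1],$$

0 for perfectly balanced orientation support and 1 for single-
orientation support, so orientation-specific damage pushes artifacts
towards 1. The orientation cosine treats the (F1R2, F2R1) counts of the
reference and alternate alleles as 2-vectors and returns their cosine
similarity; reference reads are essentially never biased, so true
variants score near 1. Both are undefined on zero-support vectors and
return `NA` rather than an arbitrary number.

Equal-length multi-base substitutions carry the SNV class flag with all
twelve substitution indicators at zero, keeping the class block an
exact partition while leaving MNVs outside the single-base spectrum.

Missing annotations stay `NA` through `build_feature_matrix()`, with a
parallel missingness mask; imputation is deliberately deferred to the
scaler. `fit_scaler()` learns, per numeric feature and from training
data only, the median (used for imputation) and the post-imputation
mean and standard deviation (used for z-scoring); indicator features
pass through untouched and constant features map to 0. Fitting only on
the training split keeps evaluation leakage-free.

## The classifier

The network is linear(41→32) – batch norm – ReLU – linear(32→16) –
batch norm – ReLU – linear(16→2) – softmax, for 2002 trainable
parameters. Normalising before the activation is the common ordering
and was fixed here; the parameter count is identical either way. The
two-node softmax with cross entropy on the positive (true-variant)
class is algebraically the stated binary cross entropy. Training uses
minibatch Adam; batch-norm layers use batch statistics during training,
accumulate running statistics (momentum 0.1, unbiased variance), and
freeze them afterwards, so inference is a pure function of weights and
input.

Hyperparameters that had to be pinned somewhere are explicit defaults
in `classifier_config()`, all overridable: learning rate 1e-3, batch
size 256, 100 epochs, no class weighting, seed 42. Weight
initialisation is uniform in ±1/√fan_in. Two runs with the same seed
produce bit-identical weights; trailing minibatches of size one are
folded into the previous batch because batch statistics of a single
row are degenerate.

The decision rule is `probability >= threshold`, inclusive, default
threshold 0.5. Inclusivity matters only at exact ties but has to be
fixed for determinism. Thresholding is monotone: lowering the threshold
never removes a true-variant prediction, which is what makes
F1-motivated threshold tuning (see `sweep_threshold()`) a pure
sensitivity/precision trade. Model bundles (`save_model()`) are JSON
with numerics serialised at 17 significant digits, so save–load–predict
is bit-identical; a bundle binds weights, running statistics, the
scaler, the schema fingerprint, and the threshold together, and a
schema mismatch is an error at load or predict time, never a silent
recompute.

## Metrics and reports

With true variants as the positive class: accuracy, specificity
(fraction of artifacts removed), sensitivity (fraction of true variants
retained), precision, and F1 = 2/(sensitivity⁻¹ + precision⁻¹).
Zero-denominator cases are reported as 0 and flagged `undefined`,
matching how published benchmark tables print such cells; F1 is 0
whenever either component is 0. Comparisons against printed tables use
three-decimal half-up rounding (`round_half_up()`), since `round()`'s
banker's rounding differs on exact ties.

`sweep_threshold()` evaluates F1 at every midpoint between consecutive
distinct probabilities plus the 0/1 boundaries — the complete set of
achievable decision boundaries — and breaks ties towards the lowest
threshold, i.e. towards retaining more true variants.

`stratified_report()` evaluates overall, per cancer type, in the
substitution classes C:G>T:A (= C>T and G>A calls, the deamination
transition) and G:C>T:A (= G>T and C>A calls, the oxidation
transversion), and in the low-MAF bin 0.01 < MAF < 0.05 with both
bounds open, as that range is conventionally written.

## The synthetic generator

`generate_paired_dataset()` emulates matched FF/FFPE call sets at the
annotation level the classifier consumes — there is no read-level
simulation, by design. Per call: depth is negative binomial (mean 90,
dispersion 10, floored at 10, a typical exome coverage profile);
alternate support is Binomial(depth, MAF) conditioned on ≥1 read via
the inverse CDF (a called variant must have support); orientation
counts split the allele support binomially at the class bias.
Defaults encode the documented direction and rough magnitude of the
class separation:

* true-variant MAF ~ Beta(2.6, 7) (median ≈ 0.25); artifact MAF ~
  Beta(1.8, 13) (median ≈ 0.10);
* artifact alternate reads are F1R2 with probability 0.9; true-variant
  and reference reads are unbiased (0.5);
* 75% of artifact substitutions are C>T or G>A; true variants are
  uniform over the twelve types;
* fragment lengths centre at 221 bp for FF-derived calls and 147 bp
  for FFPE-derived calls (s.d. 25).

Positions are drawn uniformly over an abstract genome of 22 chromosomes
× 5 Mb without key collisions; no reference FASTA is needed. True
variants appear in both call sets with the same drawn MAF but
independent sampling noise; the FF call set is exactly the true-variant
keys. Everything is deterministic in the seed, including output bytes.

What the generator does *not* model, and hence what passing tests do
not show about real data: read-level error processes and alignment
artifacts; indel artifacts (the artifact spectrum is over the 12 SNV
types); within-sample fragment-length differences between artifact- and
true-supporting reads (fragment length separates preparations, not
classes, here); regional tumour heterogeneity and therefore the
FFPE-only-but-real labeling caveat; per-cancer-type artifact loads; and
covariance between annotations beyond what the sampling scheme induces.
Real-data performance claims require real matched pairs.

At the default problem size — 2,000 true variants plus 2,000 artifacts,
a 7:3 split, 100 epochs — the end-to-end benchmark
(`parameter_recovery_experiment()`) runs in a few seconds on one CPU.
Those sizes give stable held-out metrics (~1,200 evaluation calls)
while keeping the full test suite fast. On this benchmark the trained
network reaches held-out specificity and sensitivity well above a
hand-built two-cutoff (MAF, SOB) rule fitted by exhaustive grid search
(`fit_maf_sob_rule()`), which serves as an independent yardstick; with
the class distributions made identical, held-out accuracy collapses to
the class-proportion baseline, confirming the model finds no phantom
signal.

## Numerical choices and degenerate inputs

* Batch-norm epsilon 1e-5; Adam β₁ = 0.9, β₂ = 0.999, ε = 1e-8.
* Softmax subtracts the row maximum before exponentiation.
* Drawn MAFs are floored at 1e-3 to remain consistent with conditioning
  on non-zero support.
* `compute_maf()` errors on a zero allele-depth sum rather than
  returning `NaN`; SOB/cosine return `NA` on zero-support vectors and
  the scaler imputes them like any other missing value.
* Allele-depth sums exceeding `DP` (a known caller edge case) are
  recorded verbatim with a warning, never clamped.
* Filter semantics follow the VCF spec: `PASS`, `.`, or an empty filter
  set pass; any other label fails `pass_only`. Chromosome names are
  matched verbatim, with a warning when FF and FFPE disagree on the
  `chr` prefix.
* Insert-length summaries require mapping quality strictly greater
  than 20 and count each template once via the mate with positive
  template length; an alignment with no qualifying reads yields an
  `NA` median flagged as undefined.

## Limitations

The classifier is trained per dataset; no pretrained weights ship with
the package, and a model trained on one calling pipeline or capture
design should not be assumed portable to another without revalidation.
Tumour-only FFPE data without a matched FF sample can be scored with an
existing model but cannot be labelled for training. Sequence-context
features (trinucleotide context) are deliberately out of scope.
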