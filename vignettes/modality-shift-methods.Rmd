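---
title: "Integrating nuclear cell types into whole-cell deconvolution references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating nuclear cell types into whole-cell deconvolution references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modshift)
```

## The problem

Bulk RNA-seq deconvolution estimates the fractions of discrete cell types
composing a bulk transcriptome from a reference of per-cell-type expression
profiles. Whole-cell (scRNA-seq) references are the natural choice because
bulk RNA, like whole cells, contains both cytoplasmic and nuclear RNA — but
many cell types (adipocytes, neurons, other fragile or oversized cells) are
only recoverable by single-nucleus (snRNA-seq) protocols. Nuclear profiles
systematically under-represent cytoplasm-enriched transcripts, so dropping
them into a whole-cell reference as-is distorts both that type's estimated
fraction and, through competition in the solver, everyone else's.

`modshift` implements a family of transformations that move nuclear profiles
toward their whole-cell counterparts before they enter a reference, plus the
machinery to benchmark them: a pseudobulk simulator with known ground-truth
proportions, a deconvolution stage, three-scenario accuracy evaluation,
cosine-based robustness analysis across transformations and donors, and
composite accuracy/robustness scoring. Because real paired tissue datasets
are large and access-controlled, a synthetic paired-modality generator with
planted ground truth stands in for them throughout the test suite.

## The synthetic paired-modality generator

`synthetic_design()` / `generate_paired_dataset()` emulate the features of
paired sc/sn data that the analysis actually consumes:

* **Cell-type programs.** A shared log-normal baseline times per-type
  log-normal fold factors (`base_mean_log_sd`, default 1), giving types that
  are distinct but correlated, as real cell types are.
* **Counts.** Negative binomial with a single shared dispersion
  (`nb_dispersion`, default 0.25; size = 4), the same likelihood family the
  VAE assumes. Per-cell relative-abundance vectors are renormalized before
  sampling, so all effects are compositional — exactly what library-size
  normalization later sees.
* **The modality gap.** A planted fraction of genes (`frac_biased_genes`,
  default 10%) receives a multiplicative sn retention factor drawn from
  `depletion_range` (default a fixed 0.125, i.e. 8-fold nuclear depletion).
  Intron content and gene-length effects are deliberately abstracted into
  this single factor: downstream, the gap is handled operationally through
  differential expression, not mechanistically.
* **Donors.** Log-normal multiplicative per-(donor, gene) effects,
  independent across donors and modalities (`donor_effect_sd`, default
  0.03). The value is deliberately modest — about an order of magnitude
  below the planted modality effect on the log scale. Because sc and sn
  donors are disjoint people, any donor variation projects onto the
  modality contrast as a fixed per-gene shift that no per-gene count test
  can separate from a true modality effect; 0.03 keeps that nuisance
  component well below the detection threshold while still giving the
  donor-robustness analysis real between-donor variation to measure. This
  is a known simplification: in tissues where inter-individual expression
  variance rivals the modality gap, per-gene DEG calls between unpaired
  sc and sn cohorts will mix the two sources, and the package's false
  discovery guarantees do not transfer.
* **Asymmetric composition.** Library sizes differ by modality (5,000 vs
  3,000 expected counts per cell), and the default design has one sc-only
  and one sn-only cell type, mirroring the real situation in which some
  types are only observable in nuclei.

What the generator does **not** simulate: ambient RNA, doublets, UMI
saturation, spliced/unspliced fractions, or any mechanistic intron model.
Tests passing on this generator therefore demonstrate that the pipeline's
logic is correct under its stated assumptions, not that any particular
tissue will behave as cleanly.

`generate_synthetic_bulks()` plays the role of an external bulk cohort:
proportion-weighted mixtures of the whole-cell type programs with Poisson
count noise at a configurable bulk library size.

## Differential-expression pruning

For each cell type present in both modalities, cells are summed into
disjoint 10-cell aggregates (`aggregate_cells()`), which de-sparsifies the
counts and avoids pseudo-replication: a cell can contribute to at most one
aggregate, and the operation errors rather than silently resampling. The
aggregates are tested per gene with a negative-binomial GLM Wald test
(DESeq2) with independent filtering and Cook's cutoff disabled so adjusted
p-values are plain Benjamini–Hochberg, thresholded at padj < 0.01. The
number of aggregates per modality per type defaults to
`floor(n_cells / 10)` capped at the smaller modality, minimum 2. A Welch
t-test backend on median-of-ratios-normalized log aggregates is available
behind the same catalog contract for settings where a DESeq2 fit is too
heavy; the median-of-ratios step matters because with a sizeable planted
depletion, plain CPM scaling shifts the apparent level of every unbiased
gene.

Catalog set operations mirror the multi-dataset workflow: per-dataset DEG
unions, their cross-dataset intersection (`intersection_degs()`), the union
over all other datasets (`other_datasets_degs()`), and a size-matched random
control (`sample_random_genes()`) drawn after excluding both the per-dataset
union and the intersection set. Table-style row "-DEG Int." can optionally
also exclude genes DE in the held-out type itself
(`exclude the held-out type from matched_types` when computing the catalog);
the default follows the plain intersection definition.

## Latent transforms

All transforms operate on the gene set left after any pruning (the -DEG
variants train their models on the reduced feature space) and emit
nonnegative matrices rescaled per cell to a target library size — by
default the **median** whole-cell library size; "median (mean count value)"
being ambiguous, the median is implemented and the mean is a switch
(`median_lib_size(stat = "mean")`).

**PCA neighbour shift** (`fit_pca()`, `latent_shift()`, `neighbor_shift()`,
`pca_ls_transform()`). Whole-cell cells plus overlapping nuclear cells are
log1p-transformed, standardized per gene (zero-variance genes dropped with a
recorded mask and restored as zeros on back-projection), and a PCA is kept
to the smallest number of components reaching 75% cumulative variance. Each
overlapping nuclear cell's shift vector is the whole-cell centroid minus its
own latent position — a vector, since it must later be *added* to latent
coordinates; a scalar distance could not be. Each missing-type cell receives
the mean shift vector of its 10 nearest overlapping nuclear neighbours
(Euclidean; ties broken by stable cell index), then is back-projected,
un-standardized, `expm1`-inverted, clipped at zero and rescaled.

**NB-VAE transforms** (`fit_vae()`, `vae_ls_transform()`,
`vae_cond_transform()`). The VAE is a compact negative-binomial-likelihood
model written directly in R: two hidden ReLU layers per side, a
30-dimensional Gaussian latent space, a decoder that emits mean fractions
through a gene softmax scaled by the cell's library size, Adam optimization
of the reparameterized evidence lower bound, a 90/10 train/validation split
stratified by (modality, cell type), and early stopping with patience 10
(best parameters restored). Gradients are derived by hand and verified
against finite differences in the test suite. The conditional variant
appends a one-hot modality label to the encoder input and concatenates it
to the latent vector before the decoder, with per-gene dispersion indexed
by the label (gene-batch dispersion); the unconditional variant ignores
labels entirely and carries a single per-gene dispersion. Held-out cell
types are excluded from training in both modalities, one model per held-out
type. Inference always decodes from the posterior mean, so transforms are
deterministic given a trained model.

The latent-shift transform encodes whole-cell cells (centroid), overlapping
nuclear cells (shift field) and missing cells with an unconditional model
and applies the same neighbour shift as the PCA path before decoding. The
conditional transform re-renders each nuclear cell with the whole-cell
label at encoder and decoder (decode-with-sc-label per the latent-switch
logic; the encoder label is a switch, `encode_label = "sn"`, for the
variant reading).

## References, pseudobulks, deconvolution

`reference_spec()` / `build_reference()` assemble any of the 14 named
variants: two single-modality controls, an all-nuclear pruned variant, and
the mixed variants taking every non-held-out type from the whole-cell side
and the held-out type(s) from the nuclear side, raw, pruned, and/or
transformed. Cells per type are equalized by seeded without-replacement
downsampling (default: the minimum availability across the types involved),
and the per-type sampling seed is derived from the variant seed and the
type name, so every variant of one experiment uses the same sampled cells
and variant differences isolate the transform. Each cell carries its source
modality in the annotation for provenance audits. In the real-setting mode
the "held-out" argument is simply the set of sn-only types.

`generate_pseudobulk_set()` draws, per sample, a proportion vector from a
flat Dirichlet (random scheme) or from the pool's empirical proportions
plus N(0, 0.01) noise clipped and renormalized (realistic scheme), converts
it to integer counts against 1,000 cells by the largest-remainder method,
redraws until every type is represented, sums the sampled cells (without
replacement when possible), adds N(0, 0.05) noise on the summed-count scale
and clips at zero. The recorded truth is the realized cell-count fraction.
The 0.05 noise figure is numerically negligible on raw summed counts; it is
kept on that scale for fidelity and exposed as a knob. Defaults produce
1,000 samples, 500 per scheme.

`deconvolve_nnls()` CPM-normalizes both signature (per-type mean profiles)
and bulks and solves Lawson–Hanson NNLS per sample, normalizing the
solution to sum 1. Proportions are therefore relative to depth-normalized
reference profiles: a reference type's own sequencing depth cannot leak
into its estimated fraction, which is essential when one column of a mixed
reference comes from a shallower nuclear library. External tools
(InstaPrism at 5,000 iterations, Scaden, SCDC as a single batch) are
reachable through `run_external_adapter()`, which owns the marshalling and
validation contract and raises a typed capability error when a tool is not
installed; nothing in the package silently substitutes the built-in solver
for an external one.

## Evaluation and scoring

`scenario_metrics()` computes per-sample Pearson and RMSE across types
(All-Cells), the same after dropping the held-out column with **no**
renormalization (Non-Removed — the exclusion is an evaluation choice, not a
rescaling), and a single across-sample Pearson/RMSE on the held-out column
(Removed-Only), since a per-sample correlation over one type is undefined.
Degenerate constant estimates give NA, dropped pairwise downstream.
Confidence intervals are percentile bootstrap (2.5/97.5) of the mean with
1,000 resamples, no bias correction; reference comparisons use two-tailed
pooled-variance t-tests at the 0.005 level.

Robustness is cosine similarity of flattened proportion tables: across
transformations (off-diagonal entries of `concordance_matrix()`) and across
donor-specific references per transformation. `accuracy_score()` min-max
scales per-sample Pearson and inverted RMSE within each dataset, averages
per transform, then across datasets, and takes the mean of the two;
`robustness_score()` does the same on the two cosine axes. A degenerate
min-max (all values equal) maps to 0.5 — neutral and order-preserving under
perturbation. Self-comparisons are excluded from the transform axis only.

## Problem sizes and benchmark regimes

The test suite and the acceptance script run everything at a miniature of
the full study scale, chosen once as the package's benchmark conditions:

* Default design: 2,000 genes, five types at 200 cells per type and
  modality, 3 sc / 4 sn donors, one type private to each modality. Used for
  the pseudobulk-count, DEG-recovery (sensitivity/FDR against planted
  truth), and NNLS-recovery benchmarks.
* Null calibration: the same design with no biased genes, no donor effects
  and equal library sizes — the two modalities exactly exchangeable — run
  over 10 seeds.
* Direction-of-effect: four fully matched types, 100 pseudobulks of 1,000
  cells, five replicate datasets; compares the whole-cell control, the
  all-nuclear control, and the mixed reference with and without DEG
  pruning.
* VAE benchmark: 800 genes, four matched types at 150 cells, 30% biased
  genes at 20-fold depletion, training capped at 60 epochs (learning rate
  2e-3). The deeper planted gap puts the problem in the regime the
  conditional transform exists for: with the default 10%/8-fold gap the raw
  nuclear profile already sits at cosine ≈ 0.99 to the whole-cell signature
  on log-CPM scale, closer than any decoder reconstruction can land, so a
  before/after comparison would measure reconstruction error, not modality
  correction. At 30%/20-fold the gap (≈ 0.96) dominates reconstruction
  error (≈ 0.985) and the label-switch correction is measurable. The
  trained models visibly learn the planted structure either way: decoding
  the same latent under the two labels lifts biased genes by roughly the
  planted 8–20x while leaving unbiased genes near 1x.

## Numerical and design choices

* All stochastic functions take explicit integer seeds and restore the
  caller's RNG state; reruns are bit-identical.
* Gene intersection preserves the first matrix's ordering; filtering and
  alignment are idempotent.
* The ≥50-cell type filter is applied per matrix (each dataset
  independently).
* Aggregation groups are disjoint or the operation errors.
* k-NN ties resolve by stable cell index; PCA loadings are deterministic up
  to sign.
* `logvar` is clamped to [-6, 6] in the VAE encoder with gradients masked
  at the clamp; decoder means are floored at 1e-10 inside the likelihood.
* The pseudobulk truth is the realized integer composition, not the
  pre-integerization draw.

## Limitations

The retention-factor abstraction ignores the mechanism of the sc/sn gap;
marker genes receive no protection during DEG pruning; the donor model is
exchangeable rather than structured; the built-in solver is NNLS rather
than a probabilistic deconvolution model, and external-tool results will
differ in absolute numbers even where the transform ordering is stable.
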