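---
title: "Methods: clonal tracking of barcoded tumour populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal tracking of barcoded tumour populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

This vignette documents the statistical procedures implemented in
`clonetrace`, the conventions and defaults chosen where the underlying
assay leaves them open, and what validation on synthetic data does and does
not establish.

## From reads to clone profiles

### Counting

Amplicon reads carry a constant region (the 3′ end of the common forward
primer) immediately 5′ of the barcode. `count_barcodes()` assigns each read
to a sample by its index (by default the final colon-separated field of the
read header, as Illumina pipelines write it; alternatively the first bases
of the read), locates the anchor within the first 60 nt allowing up to 2
substitutions, and matches the following fixed-length window against the
reference library.

Two policies here are conventions rather than reproductions, because the
read architecture of any given sequencing run is run-specific:

* **Barcode calls are exact by default.** The assay's libraries are designed
  with well-separated sequences, so exact matching is the conservative
  choice; a Hamming-distance-1 rescue can be enabled, in which case a read
  matching two or more library barcodes equally well is discarded as
  ambiguous rather than guessed — counts are never fabricated.
* **Anchor location is tolerant, barcode calling strict** (2 mismatches in
  the anchor, 0 in the barcode). Anchor errors only cost the read; barcode
  errors would mislabel a clone.

Every read ends in exactly one bin — one (sample, barcode) cell or one of
four discard categories (index / anchor / barcode / ambiguous) — so read
conservation is an invariant the tests assert on every input.

### Filtering and pooling

The pipeline applies, in fixed order:

1. **Read floor**: counts ≤ 10 are set to zero. The floor is inclusive and
   configurable.
2. **Replicate concordance**: within each group of technical replicates
   (same mouse, tissue, piece), a barcode detected — nonzero *after* the
   floor — in fewer than 2 replicates is zeroed across the group. Blood and
   lung samples in quintuplicate designs use the same rule over 5
   replicates. Groups smaller than the required minimum fail loudly; they
   can be explicitly passed through unfiltered, because silently skipping
   the filter would make units incomparable.
3. **Replicate pooling**: counts are summed within each group.
4. **Virtual barcodes**: groups of physically distinct barcodes carried by
   one founder cell (multiple lentiviral integrations) are collapsed by
   summation. `detect_co_integration()` proposes candidates: pairs detected
   together in at least 3 units whose frequency ratio has a coefficient of
   variation ≤ 0.2, merged into connected components. The CV is computed on
   the linear ratio f₁/f₂ (a CV of the *log* ratio is ill-defined when the
   ratio is near 1); exactly proportional pairs give CV = 0 either way. The
   detector is advisory — collapsing is an explicit user decision.
5. **Piece pooling**: tumour pieces are re-assembled into whole tumours.
   The default sums raw counts across pieces before normalising; an
   alternative averages per-piece frequency vectors, weighting each piece
   equally regardless of sequencing depth. Both are exposed because "values
   added and normalised" is ambiguous between the two; the sum-of-counts
   reading is the default and the two agree exactly on single-piece
   tumours.
6. **Normalisation**: each unit's counts become proportions summing to 1.
   Proportions (not counts-per-million) are the single internal scale; every
   downstream statistic here is scale-invariant, and percentages are a
   display transform only. Zero-total units are flagged empty rather than
   producing NaN.

Idempotence of the two filters, conservation of totals under all three
pooling operations, monotone non-increase of richness along the stages, and
invariance of the final profiles to row/column permutations are asserted as
properties over random tables.

## Clonality statistics

* **Shannon diversity** H = −Σ pᵢ ln pᵢ over pᵢ > 0, in nats. The log base
  only rescales H and never reorders samples, so natural log is used
  throughout.
* **Richness log₂ fold change** compares each unit to the arithmetic mean
  richness of the reference-route units *within the same experiment batch*,
  since separately barcoded populations are not comparable across batches.
* **Dominant sets**: `top_fraction_set(p, q)` returns the minimal prefix of
  clones, sorted by descending frequency with ties broken by barcode ID (so
  results are deterministic), whose cumulative frequency reaches q.
  `biomass_capture()` then scores Σ of a target profile's frequencies over
  such a set, summarised across targets by the median (robust to the heavy
  tails of per-tumour capture).
* **Correlation**: Pearson r on untransformed frequencies over the union of
  barcodes, absent barcodes entering as 0. Frequencies (not counts) make
  units of different depth comparable; untransformed values weight dominant
  clones heavily, which matches how composition heatmaps are read. A
  `log1p` option is exposed but off by default. The dendrogram uses average
  linkage on 1 − r, the conventional choice for correlation heatmaps;
  zero-variance profiles yield NA correlations and suppress the dendrogram
  instead of erroring.

## The neutral appearance null

If tumour composition were pure sampling, a clone at initial frequency f
would be present in a tumour of n injected cells with probability
1 − (1 − f)ⁿ (`presence_probability()`, evaluated via `log1p`/`expm1` so
tiny frequencies do not underflow). `simulate_presence()` draws multinomial
injections — multinomial rather than independent binomials, so per-tumour
cell totals are exact — independently per tumour and per replicate, and
summarises each clone's presence count across tumours by its mean and
2.5/97.5 percentiles. The default detection rule is "≥ 1 cell sampled at
injection": this is the *documented null* against which fold changes
(`appearance_fold_change()` = observed/expected) are reported.

Because real detection also loses clones at engraftment, sequencing depth,
the read floor and the concordance filter, a compound `"sequencing"` model
is provided that passes each simulated neutral tumour through those same
stages (engraftment bottleneck, lognormal growth noise, replicate
multinomial sequencing, floor, concordance). Comparing observed appearance
to this compound null isolates *fitness* effects from *detection* effects:
clones with a genuine shared advantage exceed its 97.5th percentile while
neutral clones of the same initial frequency do not. How the original
assay's own simulation handled detection is not recorded; both models are
therefore exposed, with the simple one as default. The number of replicates
(default 10,000; the compound model is typically run at a few hundred) and
the detection threshold in cells are configurable.

Fold-change edge cases: expectation below 10⁻⁹ tumours with a positive
observation is flagged as infinite enrichment; with no observation it is
undefined (NA), never 0/0.

## The synthetic-experiment generator

The generator emulates the data structure the analysis assumes, with ground
truth retained at every stage. Its defaults are the study-scale conditions;
every parameter is a modelling assumption documented here, not a measured
quantity.

| parameter | default | rationale |
|---|---|---|
| `n_barcodes`, `barcode_length` | 2500, 21 nt | reference library scale; sequences drawn uniformly with minimum pairwise Hamming distance 3 (rejection sampling) so exact matching stays unambiguous under single errors |
| `p0_sigma` | 1 | log-normal spread of initial clone abundances; the true distributional shape is unknown, log-normal is a standard stand-in for expansion-generated abundance spectra |
| `n_cells_injected` | 60000 | injection presets 5000 / 60000 / 200000 mirror the assay's PDX and cell-line arms |
| `engraftment_rate` | 0.01 | fraction of injected cells that found the tumour, within the 1/10–1/10⁴ engraftment range reported for fat-pad transplants; founder cells are drawn with probability ∝ injected cells × exp(fitness), i.e. engraftment is fitness-biased survival |
| `fraction_deterministic`, `deterministic_advantage` | 0.02, 200 | a small clone subset shares a multiplicative fitness advantage across mice — the "deterministic phenotype" hypothesis made generative |
| `stochastic_sd` | 1.5 | per-mouse lognormal fitness noise, applied at engraftment and growth; calibrated so that a handful (~5–10, the `dominance_target`) of clones cover 75% of a default tumour's biomass |
| `seeder_fraction`, `organ_bottleneck`, `organ_noise_sd` | 0.25, 2000, 1 | organ colonisation at clone granularity: seeder-flagged clones are resampled from tumour frequencies through a founder bottleneck with growth noise, preserving rank correlation with the tumour |
| `lung_trap_prob` | 0.5 | experimental (IV) regime: circulating clones are partitioned disjointly between lung trapping and liver extravasation — the mechanistic hypothesis for lung–liver decorrelation, not a measured process |
| `n_pieces`, `piece_concentration` | 4, 100 | tumour dissection; per-piece Dirichlet spatial heterogeneity around the whole-tumour composition |
| `tumour_replicates`, `organ_replicates` | 2, 2 (5 for quintuplicate designs) | technical replicate structure |
| `read_depth`, `overdispersion` | 10⁵, 5×10⁻⁴ | Dirichlet-multinomial sequencing counts; the overdispersion (inverse concentration) is set so clones above ~0.1% frequency remain concordant between duplicates at default depth |

Organ colonisation is modelled at clone granularity, not as a single-cell
agent simulation: that is sufficient to reproduce every statistic computed
here and keeps full experiments at desk scale (a 20-mouse default
experiment simulates in seconds).

In vitro passaging seeds flasks from P0, applies clone-intrinsic in vitro
fitness (drawn independently of in vivo fitness and shared across flasks)
plus small per-passage noise, grows deterministically to confluency and
samples the 1:10 split multinomially — the split is the only bottleneck, so
with `split_fraction = 1` and no fitness variance composition is exactly
constant, a degenerate case the tests pin down. The recorded per-passage
profile is the passaged aliquot's composition, mirroring sequencing a fixed
share of cells at each split.

FASTQ emission writes one record per counted read: a random 0–3 nt stagger,
the anchor, the barcode, a downstream constant, with the sample index in the
header and optional per-base substitution errors.

## Numerical conventions and degenerate inputs

* Frequencies must sum to 1 within 10⁻⁶ on input checks and 10⁻⁹ on
  post-normalisation assertions; cumulative-coverage comparisons use a 10⁻⁹
  tolerance so rounding in stored profiles cannot flip set membership.
* Empty profiles: Shannon and correlation are undefined (NA with warning),
  never silently 0; `top_fraction_set()` of an empty profile is the empty
  set.
* Zero reference-route mean richness, unknown samples, overlapping virtual
  groups, and undersized replicate groups are hard errors.
* All simulation entry points are reproducible from a single seed;
  identical inputs give byte-identical outputs, which the orchestration
  test verifies file by file.

## Problem sizes used in validation

The test-suite and the acceptance script run the generator at the study's
default conditions where the check requires them (2,500 barcodes, 60,000
cells, 10 mice per regime, 10⁵ reads per replicate), and at reduced sizes
(hundreds of barcodes, thousands of cells) for unit-level oracles where the
property being checked is size-independent. Monte-Carlo nulls use 10,000
replicates for closed-form comparisons, 2,000 for interval calibration and
200 for the compound detection model; these choices keep the full
validation suite to about a minute on one core.

## What synthetic validation shows — and what it does not

Passing tests establish that the implementation computes its stated
quantities correctly (closed-form oracles, conservation and idempotence
properties, exact FASTQ round trips), that the null is calibrated (neutral
experiments fall inside its intervals), and that the pipeline recovers
planted structure (fitness-advantaged clones, regime-dependent organ
correlations, passaging drift) in the direction and rough magnitude the
generator encodes. They do not establish that the generator's parametric
choices match any real tumour: real data carry PCR chimeras and index
hopping, barcode-level amplification bias, batch effects between
experiments, and spatial sampling artefacts that the generator deliberately
omits (see Non-goals in the help pages). Conclusions about real experiments
should rest on the pipeline's filters and the null comparison, not on
agreement with the simulator.

## Known limitations

* Barcode error correction beyond single-mismatch rescue (e.g. clustering
  sequencing-error neighbours) is out of scope; libraries with minimum
  pairwise distance ≥ 3 make this safe at typical error rates.
* The concordance filter assumes technical replicates are exchangeable;
  depth-imbalanced replicates make the floor effectively stricter in the
  shallower replicate.
* Group-level significance testing (ANOVA, survival) is deliberately not
  included; standard tools apply directly to the exported tidy tables.
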