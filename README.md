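# clonetrace

Clonal tracking of DNA-barcoded tumour populations in spontaneous and
experimental metastasis assays.

## The problem

Cellular DNA barcoding labels every cell of a cancer cell population with a
heritable, sequence-readable tag drawn from a reference library (here ~2,500
barcodes), so that a "clone" — a founder cell and all its progeny — can be
followed through injection into mice, primary tumour growth, circulation and
organ colonisation, or serial in vitro passaging. Amplicon sequencing of each
sample yields barcode read counts; the analysis questions are about clonal
*composition*: How many clones engraft under each injection route (mammary
fat pad, subcutaneous, intraductal, intravenous)? How diverse is each tumour?
Do metastases mirror the clonal make-up of their primary tumour? Are some
clones "deterministically" fit — found in far more tumours than their initial
abundance predicts?

`clonetrace` is aimed at researchers running such experiments. It implements
the complete desk side of the assay: barcode counting from FASTQ, the
replicate-aware filtering/pooling/normalisation pipeline, clonality
statistics, a simulation-based neutral expectation for clone appearance, and
a synthetic-experiment generator with retained ground truth so the whole
workflow can be validated without any sequencing data.

## What it computes

**Counting** (`count_barcodes`): reads are demultiplexed by sample index,
the constant anchor 5′ of the barcode is located (mismatch-tolerant), and
the following window is matched against the library (exact by default, with
an optional single-mismatch rescue that discards ambiguous reads). Assigned
plus discarded reads always equal input reads.

**Pipeline** (`apply_read_floor`, `filter_replicates`, `pool_replicates`,
`collapse_virtual_barcodes`, `pool_pieces`, `normalize_counts`): counts
≤ 10 are zeroed; barcodes detected in fewer than 2 technical replicates of a
sample are discarded; replicates are pooled by summing counts; co-integrated
barcodes (constant frequency ratio across samples, `detect_co_integration`)
can be collapsed into virtual barcodes; tumour pieces are re-assembled into
whole tumours; columns are normalised to clone frequency profiles
*p* = (p_1, ..., p_B), Σp_i = 1.

**Statistics** (`shannon_index`, `richness_log2fc`, `top_fraction_set`,
`biomass_capture`, `pearson_matrix`, `site_scatter`): richness (clones with
p_i > 0); Shannon diversity H = −Σ p_i ln p_i; log₂ fold change in barcode
number against the in-batch reference route mean; the minimal dominant set
reaching a cumulative frequency q (e.g. the top-95% clones) and the share of
another sample's biomass that set captures; pairwise Pearson correlation of
profiles over the barcode union with average-linkage clustering on 1 − r.

**Neutral appearance null** (`presence_probability`, `simulate_presence`,
`observed_presence`, `presence_summary`): under neutral sampling of n
injected cells from initial frequencies f, a clone is present in a tumour
with probability 1 − (1 − f)ⁿ; Monte-Carlo multinomial injections give the
expected number of tumours containing each clone with a 95% interval, and
the observed/expected fold change flags clones whose recurrence across
tumours cannot be explained by their initial abundance. An optional
compound detection model passes simulated tumours through the engraftment
bottleneck, sequencing depth, read floor and replicate-concordance rule, so
the null carries the same detection losses as the data.

**Generator** (`simulation_config`, `simulate_experiment`,
`simulate_passaging`): log-normal initial population, multinomial injection
bottlenecks (5,000 / 60,000 / 200,000-cell presets), fitness-biased
engraftment, deterministic + stochastic clone fitness, tumour dissection
with technical replicates, spontaneous (tumour-seeded, frequency-correlated)
versus experimental (lung/liver split of circulating clones) organ
colonisation, Dirichlet-multinomial sequencing counts, optional FASTQ
emission — with ground truth retained at every stage.

## Worked example

A fully synthetic experiment — 500 barcodes, 4 mice injected in the mammary
fat pad (IMFP) and 4 intravenously (IV), 20,000 cells per mouse — run through
the whole pipeline:

```r
library(clonetrace)

cfg <- simulation_config(n_barcodes = 500, routes = c("IMFP", "IV"),
                         n_mice = 4, n_cells_injected = 20000,
                         read_depth = 50000, seed = 42)
ex  <- simulate_experiment(cfg)
res <- run_pipeline(list(counts = ex$counts, sample_sheet = ex$sheet,
                         seed = 42,
                         determinism = list(p0_unit = "P0.population",
                                            n_cells_injected = 20000,
                                            n_reps = 500)),
                    out_dir = "ct_results")

head(res$diversity[res$diversity$route == "IMFP",
                   c("unit_id", "richness", "shannon")], 4)
#>          unit_id richness   shannon
#> 2 IMFP_m1.tumour       12 1.4356658
#> 3   IMFP_m1.lung        4 0.6286466
#> 4  IMFP_m1.liver        5 0.4911251
#> 5  IMFP_m1.blood       16 0.9931375
```

Each tumour retains only a dozen detectable clones of the 500 injected, and
a Shannon index of ~1.4 nats says a handful dominate. Tumours from different
mice share clones to a varying degree:

```r
tum <- res$sheet$sample_id[res$sheet$tissue == "tumour"]
round(res$correlation$r[tum, tum], 2)
#>                IMFP_m1.tumour IMFP_m2.tumour IMFP_m3.tumour IMFP_m4.tumour
#> IMFP_m1.tumour           1.00           0.76           0.19           0.60
#> IMFP_m2.tumour           0.76           1.00           0.10           0.08
#> IMFP_m3.tumour           0.19           0.10           1.00           0.30
#> IMFP_m4.tumour           0.60           0.08           0.30           1.00

length(top_fraction_set(res$profiles$freq[, tum[1]], q = 0.95))
#> [1] 6
```

Six clones account for 95% of the first tumour's biomass. The neutral-null
comparison flags clones appearing in more tumours than their initial
frequency can explain — including clones below the P0 detection floor that
nonetheless seed several tumours:

```r
ps <- res$presence
enriched <- ps[ps$exceeds_mc_high, ]
head(enriched[order(-enriched$observed),
              c("barcode_id", "p0_frequency", "observed", "expected",
                "mc_high")], 3)
#>     barcode_id p0_frequency observed expected mc_high
#> 492     bc0492            0        4        0       0
#> 302     bc0302            0        2        0       0
#> 420     bc0420            0        1        0       0
```

All tables are also written as TSV to `ct_results/`, together with a
`manifest.json` recording the configuration, input digests, seeds and
per-stage record counts.

## Documentation

The methods vignette (`vignettes/clonal-tracking-methods.Rmd`) describes
the statistical model behind the generator, every tunable parameter with its
default and rationale, the numerical conventions of the pipeline, and the
limitations of synthetic validation. All exported functions carry full help
pages.
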