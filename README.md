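# mrsd

Minimum required sequencing depth (MRSD) prediction for splice-junction
coverage in RNA-seq, with a companion aberrant-splice-event scoring and
ranking pipeline.

## The problem

RNA-seq of patient biosamples can confirm whether a genomic variant
disrupts splicing, but only if the transcript of interest is covered deeply
enough in the sampled tissue. Relative expression (TPM) is a poor guide:
it is blind to uneven coverage along the transcript (e.g. 3' bias of
poly-A-selected libraries) and discards the raw read-count information
that determines whether individual splice junctions can be assessed.

`mrsd` answers the operational question directly: *how many millions of
uniquely mapping reads must a sample be sequenced to, so that a chosen
fraction of a transcript's splice junctions each receive a chosen number
of supporting reads, with that depth holding for a chosen fraction of
control samples from the same tissue?*

## The score

For one transcript in one control sample, let *R* be the ascending-ordered
read counts over the transcript's splice junctions and *R_p* the count at
the largest order-statistic position whose suffix holds at least
proportion *p* of the counts. With the sample's total depth *d* (millions
of uniquely mapping reads), the per-sample minimum required depth for
*r*-read junction coverage is

```
MRSD = r * d / R_p        (millions of reads)
```

i.e. the sample's observed per-million junction coverage *R_p / d* scaled
up to the target *r*. When *R_p* = 0 the transcript is **unfeasible** in
that sample. Across the *n* control samples the reported score is the
⌈*m·n*⌉-th smallest per-sample MRSD (unfeasible = +∞), so the returned
depth holds for at least proportion *m* of controls. Defaults are *r* = 8,
*p* = 0.75, *m* = 0.95; scores below 100 M reads are classed `low_mrsd`,
at or above it `high_mrsd`.

One junction-set transcript model is selected per gene by a three-tier
hierarchy: a curated MANE transcript (if all its junctions are supported in
the base annotation), else the union of the gene's RefSeq transcripts, else
the union of all annotation transcripts.

Case samples are screened for aberrant splicing by comparing each junction
against the control cohort: the **normalized read count** (NRC, reads over
the best adjoining canonical junction), its fold change over the best
control, and singleton status (present in no control) drive filtering and
ranking, with singletons ordered by read count above non-singletons
ordered by fold change.

## Worked example

Everything below runs offline on a synthetic control cohort with known
ground truth (the same generator the test suite uses).

```r
library(mrsd)

cfg    <- generator_config(n_samples = 100, n_genes = 50, seed = 42)
sim    <- generate_reference_set(cfg, tissue_label = "fibroblast-like")
scores <- compute_mrsd_table(sim$reference, sim$models,
                             mrsd_params(r = 8, p = 0.75, m = 0.95))
glance(scores)
#>   n_transcripts n_feasible n_unfeasible median_mrsd     r     p     m n_samples
#> 1            50         48            2        50.4     8  0.75  0.95       100
```

Half the genes in this cohort need about 50 M uniquely mapping reads for
8-read coverage of 75% of their junctions in 95% of samples; two genes are
so weakly covered that no depth can be recommended (`unfeasible`):

```r
dplyr::select(tibble::as_tibble(scores)[1:5, ],
              gene_id, n_junctions, mrsd_millions, class)
#>   gene_id n_junctions mrsd_millions class
#> 1 G0001             4        142.   high_mrsd
#> 2 G0002             8         51.2  low_mrsd
#> 3 G0003             4         25.2  low_mrsd
#> 4 G0004            12          6.83 low_mrsd
#> 5 G0005             7        446.   high_mrsd
```

Inject a known aberrant junction into a held-out case sample and recover
it with the event pipeline:

```r
case <- extract_sample(sim$reference, "S001")
ref  <- drop_samples(sim$reference, "S001")
inj  <- inject_aberrant_event(case, ref, sim$models, "G0007",
                              target_nrc = 0.5, reads = 14, singleton = TRUE)
events <- detect_events(inj$case$counts, inj$reference, sim$models,
                        min_reads = 2, min_nrc = 0.25)
head(dplyr::select(events, key, gene_id, read_count, nrc, singleton, rank), 3)
#>   key                       gene_id read_count  nrc singleton rank
#> 1 chr7:14000500-14003999:+  G0007           14 0.5  TRUE         1
#> 2 chr5:10000500-10001999:-  G0005            9 9    FALSE        2
#> 3 chr12:24004500-24005999:+ G0012           14 2.33 FALSE        3
```

The injected singleton ranks first; the remaining rows are background
events the cohort's count noise produces, which is exactly what the
bootstrap background tooling (`bootstrap_background()`) quantifies.

Real data enter through `read_star_sj()` (STAR `SJ.out.tab`),
`read_reference_set()` (a `sample_id / path / depth_millions` manifest)
and `gtf_to_junctions()` / `build_transcript_models()` (GENCODE-style GTF,
optional MANE list and RefSeq GTF). A command-line wrapper with
`score` / `events` / `evaluate` / `downsample` / `bootstrap` / `panels` /
`vus` / `simulate` subcommands is installed at `inst/scripts/mrsd`.

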