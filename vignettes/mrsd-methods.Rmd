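---
title: "MRSD: model, assumptions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRSD: model, assumptions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsd)
```

## The model

`mrsd` predicts, per transcript and tissue, the sequencing depth at which
RNA-seq becomes informative for splicing analysis. The prediction is built
entirely from order statistics of observed junction read counts in a
control cohort ("reference set") of the same tissue.

For a transcript with junction read counts $R$ (ascending) in a control
sample of total depth $d$ million uniquely mapping reads:

1. **Critical count.** $R_p$ is the count at the largest 1-based position
   $i$ whose suffix proportion $(n - i + 1)/n$ is at least $p$; that is,
   proportion $p$ of the transcript's junction counts are $\ge R_p$. With
   $n$ junctions this is the order statistic at index
   $i = n - \lceil np \rceil + 1$.
2. **Per-sample depth.** The sample's observed critical coverage per
   million reads is $R_p / d$; scaling it to the target $r$ gives the
   per-sample minimum required depth $r\,d / R_p$ (millions of reads).
   $R_p = 0$ means no finite depth extrapolates to $r$ reads:
   the transcript is *unfeasible* in that sample.
3. **Cohort aggregation.** Across the $n_s$ control samples the reported
   MRSD is the $\lceil m\,n_s \rceil$-th smallest per-sample value, with
   unfeasible as $+\infty$: the smallest depth that "holds" for at least
   proportion $m$ of controls. If that order statistic is $+\infty$ the
   transcript is unfeasible in the tissue.

The score is therefore *exactly* proportional to $r$, non-decreasing in
$p$ (the critical index moves toward smaller counts), and non-decreasing
in $m$ (a larger order-statistic index). These three properties are
asserted as tests, not assumed.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `r` | desired reads per junction | 8 | scores scale linearly in `r` |
| `p` | proportion of a transcript's junctions at `r` reads | 0.75 | satisfied with `>=` |
| `m` | proportion of control samples for which the depth holds | 0.95 | 0.99 for a stricter model |
| `threshold` | low/high MRSD bracket boundary (millions of reads) | 100 | boundary value is high-MRSD |
| `min_reads` | event filter: minimum supporting reads | 2 | |
| `min_nrc` | event filter: NRC threshold for non-singletons | 0.25 | strict `>` |

The underlying depth unit is millions of *uniquely mapping* reads: only
the unique-read column of STAR `SJ.out.tab` is counted and multimappers
are discarded. Per-sample depth `d` is taken from the manifest, not
inferred from junction counts, because junction counts cannot recover a
run's total depth. Junction counts are taken as the input file reports
them; whether PCR-duplicate-marked reads were excluded upstream is the
caller's pipeline choice and is deliberately not second-guessed here.

## Transcript models

One junction set per gene, selected hierarchically:

1. the gene's MANE transcript, **provided** every one of its junctions
   coordinate-matches a junction derivable from some transcript of the
   base (GENCODE-style) annotation — "supported" is implemented as exact
   coordinate identity, the strictest testable reading;
2. otherwise a RefSeq composite: the union of junctions over all RefSeq
   transcripts of the gene (no restriction to curated `NM_` accessions:
   the input table defines the universe);
3. otherwise the union over all base-annotation transcripts.

A MANE transcript that fails the support check falls through to the next
tier rather than being excluded. Junctions are 1-based fully-closed intron
intervals (`start` = exon end + 1, `end` = next exon start − 1), matching
STAR's `SJ.out.tab` so that format needs no coordinate conversion. Strand
`*` (unknown) matches only `*`; there is no strand-relaxed joining, which
keeps the join semantics deterministic.

Inter-transcript variability is summarised by `cv_mrsd_report()`: the
coefficient of variation uses the population (n-denominator) standard
deviation, since the transcript set of a gene is complete rather than a
sample; unfeasible transcripts are excluded from the CV but counted, so
feasibility discordance between transcripts remains visible.

## Event metrics

For a case sample scored against the reference cohort, each junction
assignable to a modelled gene gets:

* **read count** — supporting split reads in the case;
* **NRC** — read count divided by the highest-count *adjoining* canonical
  junction of the gene's model, in the same sample. Adjoining means
  sharing the event's donor or acceptor coordinate; if no model junction
  shares a site, the nearest flanking model junction on each side is
  used; if those carry no reads, the gene-wide canonical maximum stands
  in; only when no canonical junction of the gene carries reads is the
  NRC undefined and the event flagged. The fallback chain keeps the
  normalisation local where possible but defined whenever the gene is
  expressed. NRC may exceed 1.
* **NRC fold change** — case NRC over the highest control NRC for the
  junction; control NRCs are computed against each control's *own*
  canonical counts (a control's usage is its own property, not the
  case's). Controls carrying the junction with undefined NRC contribute
  nothing.
* **n samples / singleton** — presence counts across case plus controls.

Filtering retains singletons and non-singletons whose NRC strictly
exceeds every control's; the threshold filter additionally requires
`min_reads` supporting reads and, for non-singletons, NRC strictly above
`min_nrc`. Ranking places singletons (by decreasing read count) above all
non-singletons (by decreasing fold change); ties break by decreasing read
count, then lexicographic junction key — the tie-break keys beyond the
primary ordering are this package's own convention, chosen so ranking is
a total order invariant to input order. Ranks are assigned after
filtering.

## Evaluation tools

* **PPV/NPV** (`evaluate_ppv_npv()`): a prediction is positive when the
  test sample's depth meets the MRSD (unfeasible always predicts
  insufficient, so unfeasible transcripts sit in the NPV denominator);
  coverage is "achieved" by the same $\lceil p\,n\rceil$-junction rule
  the score itself uses, making self-evaluation exactly consistent.
* **Calibration** (`calibration_experiment()`): held-out samples from the
  same generative model are scaled to exactly the predicted depth
  (counts multiplied by MRSD$/d$) and checked for achieving coverage.
  Deterministic scaling — rather than stochastic resampling — isolates
  the order-statistic calibration that the score promises; stochastic
  thinning is a separate tool (below). The reported Monte-Carlo standard
  error is the standard deviation of per-transcript achieved proportions
  over $\sqrt{T}$, which captures both the binomial noise over held-out
  samples and the sampling noise of each transcript's estimated MRSD.
  With 150 reference samples the $\lceil 0.95 \cdot 150\rceil = 143$rd
  order statistic has true coverage $143/151 \approx 0.947$; the
  discreteness of the order-statistic index is an inherent property of
  the estimator, visible at any finite cohort size.
* **Downsampling** (`downsample_gene()`): binomial thinning with
  retention probability $1 - f$, the exact count-marginal of removing
  reads uniformly at random — the package's data model is count-based,
  so read-level removal would add bookkeeping without changing any
  distribution. `rank_stability_experiment()` re-runs detection across
  thinning levels to show when events fall out of reach.
* **Bootstrap background** (`bootstrap_background()`): resamples control
  cohorts of 30/60/90 with replacement (2,000 replicates by default) and
  reports median retained singleton / non-singleton event counts. Raw
  medians only; no multiple-testing machinery is layered on top.
* **TPM comparison** (`compare_tpm()`): least-squares fit of log10 MRSD
  on log10 TPM over genes with finite MRSD and TPM > 0 (zeros and
  unfeasible genes cannot be log-transformed and are excluded from the
  fit), plus per-bracket TPM summaries that expose high-expression genes
  with poor junction-level coverage.
* **Panels / variants** (`panel_report()`, `vus_feasibility()`): per-panel
  per-tissue proportions of low-MRSD genes with joint-best ties reported
  as such, and annotation of candidate splice-impacting variants
  (significance-filtered, splice-impact score ≥ 0.5 inclusive) with
  per-tissue feasibility classes.

## The synthetic-data generator

`generate_reference_set()` emulates the statistical structure of a real
control cohort: gamma-distributed sample depths (default mean 80 M,
sd 20 M uniquely mapping reads — a realistic clinical bulk RNA-seq
depth), log-normal per-gene junction coverage rates (default
`meanlog = log(0.2)`, `sdlog = 1.5` reads per million per junction,
spanning deeply covered genes down to genes that are unfeasible at any
practical depth), and negative-binomial count noise
(`size = 20` by default; `Inf` gives the Poisson limit). An optional 3'
bias multiplies junction means by a monotone ramp along the transcript
($\exp(-s)$ at the 5' end up to 1 at the 3' end, per-gene strength drawn
uniformly up to the configured maximum), reproducing the mechanism by
which TPM overstates the coverage of biased genes. Gene-level properties
(structure, rates, bias) are seeded separately from sample-level noise,
so independent cohorts — reference, held-out, case — can be drawn from
one generative model.

What the generator does *not* emulate: correlated junction usage within a
transcript, alternative isoform structure, sample-level expression
covariates (batch, eQTL/sQTL), or sequence-level realism. Passing tests
therefore demonstrate the correctness and internal calibration of the
scoring machinery under its own assumptions, not the field performance of
any particular reference cohort.

`inject_aberrant_event()` plants ground-truth events: a novel
exon-skipping junction with a requested read count, with the adjoining
canonical maximum pinned so the NRC hits the target as nearly as integer
counts allow (the attained value is recorded); non-singleton events add
carrier controls at a strictly lower NRC computed against each carrier's
own canonical counts, which requires the carrier's canonical denominator
to exceed $1/\mathrm{NRC}$ — carriers are therefore drawn from controls
expressing the gene deeply enough.

## Numerical choices

* Pure order statistics throughout — no quantile interpolation. Junction
  counts are integers; interpolation would report depths implied by no
  observed sample.
* Index computations guard against floating-point edge cases with a
  $10^{-9}$ slack before `ceiling()`; boundary conventions are `>=` for
  both $p$ and $m$, the bracket boundary (100 M) classifies as high-MRSD,
  the event NRC threshold is strict `>`, and the variant score threshold
  is inclusive `>=`.
* Unfeasible scores are carried as `Inf` in memory (safe ordering,
  explicit arithmetic) and serialised as the literal string
  `"unfeasible"`, never a numeric sentinel.
* A transcript model with zero junctions yields a per-row error record in
  the score table rather than failing the whole run; single-exon genes
  have no junctions and no MRSD by construction.
* Problem sizes in the test suite (150-sample reference cohorts, 200
  genes, 500 held-out samples, 2,000 bootstrap replicates) were chosen to
  match a realistically sized tissue cohort while keeping the full suite
  comfortably reproducible on a laptop.

## Known limitations

* Scores describe control-cohort coverage; disease states with global
  transcriptome shifts, eQTL/sQTL effects, or allele-specific expression
  are outside the model.
* The event pipeline scores junctions against the selected transcript
  model per gene; intergenic junctions and statistical outlier p-values
  are out of scope.
* MRSD transfers across library designs (read length, enrichment) only to
  the extent that per-million junction coverage transfers; reference sets
  should match the intended assay where possible.
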