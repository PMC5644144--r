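---
title: "Detecting historical DNA methylation from CpG observed/expected ratios"
author: "cpgoe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting historical DNA methylation from CpG observed/expected ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgoe)
```

## The biological signal

In many animals, DNA methylation targets cytosines in CpG dinucleotides,
predominantly within gene bodies. Methylated cytosines deaminate to
thymine at an elevated rate, so genes that have been methylated in the
germ line over evolutionary time slowly lose CpG sites. The footprint of
that history is measurable from sequence alone through the normalised CpG
content of a region,

$$\mathrm{CpG}_{o/e} = \frac{N \cdot \mathrm{CpG}}{C \cdot G},$$

where $N$ is the number of (unambiguous) bases in the region,
$\mathrm{CpG}$ the number of CpG dinucleotides, and $C$ and $G$ the
cytosine and guanine counts. Under independence of adjacent bases the
expected per-position CpG frequency is $(C/N)(G/N)$, so the ratio is
close to 1 for sequence with no depletion and well below 1 where CpG
sites have decayed.

Surveyed across all genes of a species, the distribution of per-gene
$\mathrm{CpG}_{o/e}$ is diagnostic. Species with an intact germ-line
methylation system (honeybee is the canonical example) show a *bimodal*
distribution: a low mode of historically methylated genes and a high mode
of unmethylated ones. Species without such a system (*Drosophila*, and
collembolans such as the giant springtail analysed with these methods)
show a single mode. `cpgoe` turns that qualitative picture into an
explicit, reproducible call.

## From sequences to a verdict

The pipeline has four stages, each exposed as an ordinary function:

1. **Sequence universes** (`read_fasta()`, `read_gff_genes()`,
   `extract_gene_bodies()`, `tile_genome()`). Gene bodies are spliced
   exonic sequence by default (`mode = "spliced"`), matching a
   transcript-level survey; `mode = "span"` includes introns for
   comparison. Minus-strand genes are reverse-complemented —
   $\mathrm{CpG}_{o/e}$ is exactly strand-symmetric (CpG is its own
   reverse complement and $C$/$G$ swap), so this is interface hygiene,
   not a modelling choice. Genome fragments are non-overlapping windows
   (default 1 kb) from position 0 of each scaffold, trailing partial
   windows dropped, windows with more than 20 % ambiguous bases
   discarded and counted. An optional `truncate_to = 1000` reproduces a
   uniform 1-kb truncation of gene bodies; truncation is 5′-anchored and
   shorter genes are kept.

2. **The statistic** (`cpg_oe()`, `cpg_oe_table()`). $N$ counts only
   unambiguous bases: assembly gaps and Ns would otherwise inflate the
   numerator but not the counts, biasing the ratio upward. The CpG scan
   is overlapping (``"CGCG"`` contains two CpGs) and any window touching
   an ambiguous base is skipped. Ratios are undefined when $C = 0$ or
   $G = 0$; these propagate as `NA` and are excluded (and counted) at
   the table level rather than raising errors mid-batch. Sequences with
   fewer than `min_length = 200` unambiguous bases are excluded because
   the small-$N$ variance of a ratio statistic is extreme (the 4-mer
   `"ACGT"` scores 4.0).

3. **Mixture modelling** (`fit_gmm()`, `select_model()`). Univariate
   Gaussian mixtures are fitted by EM, best of `n_starts = 10`
   initialisations (first: means at evenly spaced sample quantiles;
   rest: random responsibilities). Both one-dimensional variance
   families are fitted — shared ("equal", the E family of model-based
   clustering) and per-component ("unequal", V) — for every
   $K = 1 \dots k_{\max} = 4$, and ranked by BIC in the minimised
   convention $-2\log L + p\ln n$ (some clustering software maximises
   the opposite sign; rank order is identical). Ties break toward
   smaller $K$, then the equal family. Numerical safeguards: component
   variances floored at $\max(10^{-6},\,10^{-4}\hat\sigma^2)$;
   convergence when the log-likelihood improves by less than $10^{-8}$;
   values are sorted internally so the fit is exactly invariant to input
   order; for $K = 1$ the EM reduces to the closed-form mean/variance
   MLE and restarts are skipped.

4. **The call** (`call_methylation_signature()`). A bimodal verdict
   requires three things at once: the BIC winner has $K \ge 2$; it beats
   the best single-Gaussian fit by at least `delta_bic_min = 6` (strong
   evidence on the conventional BIC scale); and the best *two-component*
   candidate has modes separated by at least `separation_min = 2` pooled
   standard deviations. The separation is deliberately measured on the
   $K = 2$ candidate rather than the BIC winner: with realistic
   length-heterogeneous data the winner is often $K = 3$, where a broad,
   low-weight component absorbs skew and heavy tails, and the spacing of
   those sub-components says nothing about whether two gene classes
   exist. Both thresholds are explicit stand-ins for a judgement the
   qualitative literature leaves implicit; they are parameters, echoed
   into every report.

```{r example}
spec <- genome_sim_spec(default_gene_classes("bimodal"),
                        n_genes = 500, seed = 42)
tx <- generate_gene_set(spec)$sequences
report <- run_gene_body_analysis(transcripts = tx, seed = 1)
report
```

## What the simulator emulates — and what it does not

`generate_gene_set()` and `generate_annotated_genome()` exist so the
whole pipeline, including its decision thresholds, can be exercised and
calibrated with no external data. Sequences are drawn from a first-order
Markov chain whose baseline transition rows equal the base composition;
CpG depletion is imposed by multiplying the C$\to$G transition
probability by a factor $d \in (0, 1.5]$ and renormalising the C row.
This reproduces the *end state* of germ-line methylation plus
CpG$\to$TpG decay — a depleted dinucleotide in an otherwise
composition-matched sequence — without simulating mutation through time.

Because of the renormalisation, the realised $\mathrm{CpG}_{o/e}$ is not
$d$ itself. The analytic mapping is available as `expected_cpg_oe()`
(stationary distribution of the chain; the asymptotic ratio is
$p(G\mid C)/\pi_G$) and its inverse as `depletion_for_cpg_oe()`, so
classes are specified by the ratio they should realise. Defaults are
chosen once to mirror the canonical study conditions:

* GC fraction 0.35 for gene classes, 0.33 intergenic — an AT-rich
  arthropod genome;
* single-class ("unimodal") preset: target $\mathrm{CpG}_{o/e}$ 0.7, the
  collembolan-like gene-body mean;
* two-class ("bimodal") preset: 50/50 at targets 0.35 and 0.85, the
  honeybee-like pattern;
* genome-wide background: target 0.79, a genome slightly depleted
  relative to expectation;
* transcript lengths: normal with mean 1500 bp, sd 700 bp, floored at
  200 bp (a floor rather than resampling keeps the length draw simple
  and reproducible).

`generate_annotated_genome()` additionally splits each transcript into
1–3 exons, inserts introns and intergenic spacers drawn from the
intergenic composition, assigns strands at random, and emits
FASTA + GFF3 + a truth table. Scaffold lengths are derived from their
content, so no placement can overflow a scaffold. By construction,
spliced extraction from the written files reproduces every generated
transcript byte-exactly — the round trip the test suite asserts.

The simulator is honest about what it is not. Real gene sets have
intragenic composition heterogeneity, isochores, exon-biased GC,
selection on synonymous sites, and annotation error; none of these are
modelled. Passing the simulation-based tests therefore shows that the
*method* behaves as designed under its own assumptions (calibrated
depletion, Gaussian-ish class distributions, known truth), not that any
particular real genome will produce clean verdicts. The sampling noise
of the ratio does mimic one important real feature: per-gene variance
grows as genes get shorter, which is exactly what makes the
heavy-tail/K=3 issue above appear in practice.

## Problem sizes and determinism

The simulation studies in the test suite use the sizes at which the
method is intended to operate: transcriptomes of 2 000 genes for the
end-to-end verdicts (about 3 Mb of simulated sequence per replicate),
100-kb sequences for generator calibration against the analytic
expectation (agreement within ±0.05 over a grid of depletion factors),
and 20 replicate seeds per scenario. The false-bimodality control is 40
replicates of 2 000 single-Gaussian values, with the bimodal verdict
required in at most 5 %.

Every stochastic step takes an explicit seed and restores the caller's
RNG state; the simulator consumes R's own RNG inside compiled code, so
`(spec, seed)` determines outputs bit-for-bit, and written reports are
byte-identical across reruns (a wall-clock timestamp is off by default
and opt-in via `write_report(timestamp = TRUE)`).

## Known limitations

* Components are Gaussian; strongly skewed class distributions are
  accommodated only indirectly (extra components), which is why the
  verdict never reads mode structure off the BIC winner alone.
* The modality call is binary by design. Intermediate states — partial
  methylation systems, mosaic methylation — will land on whichever side
  of the thresholds the data support, and the `delta_bic` and
  `separation` evidence in the report should be read alongside the
  verdict.
* $\mathrm{CpG}_{o/e}$ is an indirect, historical signal. It cannot see
  recent gains or losses of methylation, and low-complexity or
  repeat-dense inputs can distort it; the package does no masking.
* GFF3 parsing resolves exons through `Parent` chains up to depth 10 and
  treats an undefined parent id as the gene id itself; exotic annotation
  conventions beyond that are out of scope.
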