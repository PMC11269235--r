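---
title: "Methods: upstream motif scanning and gene-set statistics for neuronal transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream motif scanning and gene-set statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlmotif)
```

## The analysis this package implements

Early-life stress leaves a transcriptional memory in *C. elegans*.
Animals that transit the dauer diapause ("postdauer" adults) show
genome-wide expression changes in specific neurons, among them the ADL
nociceptive chemosensory pair, and much of this reprogramming runs
through the somatic nuclear RNAi Argonaute NRDE-3. The computational
backbone of such a study is not the sequencing itself but a chain of
small, exacting analyses:

1. extract the regulatory sequence upstream of every gene's
   translational start;
2. scan those regions for degenerate, gapped DNA motifs — the
   DAF-3/SMAD binding site `GTCTA`, a ~30-bp conserved element (the
   "MSP motif") with two bounded spacers, their conjunction (the
   composite "PD motif"), and E-box variants (`CASCTG`, `CACGTG`);
3. call expressed genes from RPKM-normalized counts at a fixed cutoff;
4. compare gene lists: overlap counts and percentages, Jaccard
   similarities, hypergeometric enrichment with astronomically small
   p-values, and the wild-type-minus-mutant partition that quantifies
   how much differential expression depends on a factor;
5. reduce behavioral plate assays to dimensionless indices.

`adlmotif` implements each stage as a separately testable module, adds
a synthetic-data generator that emits truth labels for every stage, and
composes everything in `run_pipeline()`.

## Upstream regions

`extract_upstream()` takes the `window` (default 500 bp) immediately 5'
of the first base of the start codon, on the gene's own strand, so the
returned sequence always reads in transcription direction and never
includes the ATG. Coordinates are 0-based half-open internally; GFF3 is
converted from 1-based inclusive on read and BED is written 0-based
half-open, so each dialect keeps its native convention. Genes closer
than `window` to a contig edge yield a truncated region with a flag;
zero available bases is an error rather than an empty region, because
an empty string would silently drop the gene from every downstream
tally. Overlapping neighbours are not masked from one another's
windows, and no isoform resolution is attempted: one ATG per gene id is
the contract. Bases outside `ACGT` are preserved as `N`.

The original analysis built a BLAST database of upstream sequences and
searched patterns against it; this package scans the extracted regions
directly instead. Direct scanning evaluates the pattern grammar
exactly, with no heuristic seeding, and makes the per-start semantics
below enforceable.

## The motif grammar and its matcher

`compile_pattern()` parses patterns written as literal bases, bracketed
choice sets (`[AT]`, `[A/T]`), the IUPAC letters `S/W/Y/R`, and bounded
spacers in both common spellings, `N(0,3)` and `N_0-3`; a bare `N` is a
length-1 spacer. A pattern compiles to an ordered block list with
derived length bounds; the MSP motif compiles to 25 fixed positions and
spacers of 0–3 and 0–2 bases, hence match lengths 25–30 — the "~30 bp"
element.

Matching semantics, chosen for deterministic counts:

* a hit exists at a start position iff *some* spacer-length assignment
  makes every fixed position agree;
* per start, exactly one hit is reported, with the lexicographically
  smallest (leftmost-shortest) assignment — so "1 to 3 copies" style
  statements count start positions, never spacer variants;
* overlapping starts are all reported;
* `N` in the subject matches nothing, spacer positions included.
  Assembly gaps therefore cannot fabricate motifs, at the cost of
  missing genuine instances that span an ambiguous base — the
  conservative direction for enrichment claims.

Upstream regions are already strand-resolved, so scanning defaults to
the forward strand of the region; `both_strands = TRUE` additionally
scans the reverse complement and reports those hits in
reverse-complement coordinates (palindromes such as `CACGTG` then
appear once per strand; deduplication is the caller's choice).

Full-PD classification (`classify_pd_status()`) is the intersection of
the DAF-3-site gene list and the conserved-sequence gene list —
presence of both elements anywhere in the region, with no spacing or
order constraint. The composite is deliberately *not* modelled as one
spaced motif, because the defining analysis was a list intersection.

The matcher is verified against an independent oracle that enumerates
every spacer assignment at every start (`tests/testthat/helper-oracles.R`),
on random patterns (≤ 4 blocks, spacers ≤ 3) over random sequences
(≤ 60 bp, 3% `N`): 10,000 cases in the acceptance suite. The oracle
shares no code with the scanner.

## Expression calls

RPKM is `counts * 1e9 / (length_nt * total_reads)` per sample, with
column sums as totals unless explicit totals are given. A gene is
called expressed in a condition when the *mean* RPKM across that
condition's replicates meets the cutoff, `>= 10` by default. The source
material writes both "cutoff of 10 RPKM" and "RPKM > 10"; with
continuous data the boundary choice is immaterial in practice, so the
rule is a surfaced parameter (`rule = ">="` or `">"`) rather than a
hidden constant, and the replicate summarizer (mean, the convention for
expression calls) is likewise explicit. DE tables are consumed, not
computed: differential-expression testing belongs to dedicated tools
(edgeR and kin), and this package only thresholds their output at
`fdr < 0.05` (strict) and routes genes by direction.

## Set statistics

All reported percentages round half away from zero at the stated
decimals. That convention is not cosmetic: it is the one that
reproduces every published figure of this analysis from its published
counts (62, 81, 24.6, 43, 77.7, 87.5, 90, 32.7, 14.9), which the
acceptance suite asserts.

"Similarity" between two expressed transcriptomes is Jaccard,
`100·k/(a + b − k)` — back-computing the published 77.7% from
5206/(5908 + 6001 − 5206) and 87.5% from 5951/(6375 + 6377 − 5951)
identifies the formula exactly. Overlaps "compared to" a named list use
that list's size as the denominator (`percent_of_query()`).

The hypergeometric tail is computed in log space from `lgamma` with a
log-sum-exp over the support, so log10 p-values of order −1200 (as
printed in the motivating analysis) are finite and accurate; nothing is
ever exponentiated on the way to the report, and `p_display()` renders
scientific notation directly from `log10_p`. Correctness is pinned
three ways: exact rational enumeration over the complete grid `N <= 25`
(binomials there are exact in doubles), log-space pmf normalization up
to `N = 10^4`, and an elementary telescoping-product cross-check plus
`phyper(log.p = TRUE)` at magnitude ~1e-1400. `phyper` is used only as
an independent oracle in tests, never as the implementation.

Conventions that the source material leaves open, decided here and
recorded in output metadata:

* **Population `N` is a required explicit input.** The published
  p-values do not state their population, and tail probabilities are
  exquisitely sensitive to it, so no default is supplied.
* **Ties count as enriched** (`k >= expected`), and enrichment uses the
  upper tail `P[X >= k]`; depletion uses the lower tail and reports
  "x-fold under enriched" as `fold = expected / observed` (so 2.3-fold
  under enriched means observed ≈ expected/2.3), infinite at zero
  observed. No two-sided option is offered: the statements being
  reproduced are one-sided.
* No multiple-testing correction across reference lists; the
  reproduced reports are raw hypergeometric p-values.

`dependence_partition()` is pure set algebra: dependent genes are the
wild-type DE genes absent from the mutant's corresponding list, and the
headline percentage is `100 · (dep_up + dep_down) / (wt_up + wt_down)`,
rounded to integer.

## Behavioral indices

The six-sector octanol avoidance formula is typeset ambiguously in the
defining protocol ("(A + B)-(E + F)/N"). It is implemented as
`((A + B) − (E + F)) / N`: only that reading is bounded and
dimensionless, and only it makes a negative index mean avoidance, as
the accompanying text requires. Worms in the central sectors C and D
count toward `N` ("total number of animals in all the six sectors") but
not toward either pole. Chemotaxis is
`(n_attractant − n_control)/n_total`, reversal is a simple fraction.
Per-trial indices are first-class; `summarize_assays()` aggregates as
mean ± SD with the trial as the unit. Significance testing on indices
is out of scope by design (routine named tests).

## The synthetic-data generator

The generator exists so that every stage has an exact oracle without
any sequencing download; its defaults encode the study design it
emulates.

* `gen_genome()` builds upstream windows by **rejection sampling**: a
  region is resampled (cap 1000 attempts) until the scanner finds
  exactly the planted instances, so recovery tests are equality, not
  approximation. Instances are placed non-overlapping at uniform
  offsets; genes alternate strands; DAF-3/MSP planting overlaps in
  exactly `n_full_pd` genes and is otherwise disjoint, making the
  full-PD truth set unambiguous. Background composition defaults to
  uniform 25% per base; an AT-rich setting stresses specificity of the
  AT-heavy MSP pattern. Rejection sampling is what real promoters do
  *not* do — real backgrounds contain chance motif instances — so
  passing recovery tests demonstrates scanner exactness, not
  genome-scale motif counts.
* `gen_counts()` draws negative-binomial counts (default dispersion
  0.1, log-normal baselines around 200) for a 2 genotypes × 2
  conditions × 4 replicates design, the library design of the
  motivating experiment, with 116 up / 595 down planted DE genes by
  default and a 0.9 dependent fraction, mirroring the published DE-set
  sizes and the ~90% NRDE-3 dependence. Truth FDR values are drawn
  below 0.05 for planted genes and above for the rest, so `de_sets()`
  recovers the planted sets exactly. Fold change defaults to 4.
* `gen_association()` plants a motif/DE-down association by solving the
  two Bernoulli rates whose odds ratio and expected marginal match the
  configuration, then sampling; the realized 2×2 table is emitted as
  truth.
* `gen_assay()` places worms multinomially with pole masses
  `(1 ± θ)/2`, zero central mass in the canonical model (expected index
  exactly θ); a `lingering` parameter diverts mass to C/D, shrinking
  the expectation to `θ(1 − lingering)`, to probe index robustness.

Everything is seed-deterministic: the same seed and parameters
regenerate byte-identical files.

What the generator does *not* emulate: read-level errors, FACS
contamination or ambient RNA, realistic promoter base composition and
motif clustering, isoform structure, or correlated replicates. Green
tests on synthetic data therefore certify the arithmetic and the
matcher, not biological discovery performance on real genomes.

## Problem sizes and numerical choices

The test and acceptance workloads use: 10,000 random oracle-equivalence
cases (patterns ≤ 4 blocks, sequences ≤ 60 bp), a 500-gene genome with
500-bp windows for planted recovery (37 conserved-sequence carriers at
the 0.074 planting fraction, 10 full-PD genes), the complete
hypergeometric grid `N ≤ 25` plus normalization at `N = 10^4` and an
extreme tail at `N = 2·10^4`, 20 seeds at universe 5000 for association
detection (odds ratio 4) and null calibration (odds ratio 1), and
10^4-worm assays for index recovery within 0.03 (binomial SD ≈ 0.01).
These sizes were chosen as the smallest at which each property is
sharp: exact recovery is scale-free, and the stochastic checks sit at
least three standard errors from their thresholds.

Degenerate inputs are errors, not silent answers: zero-worm plates,
zero-total samples, empty replicate subsets, zero-length upstream
regions, unknown contigs, duplicate gene ids, malformed motif tokens,
and infeasible association marginals all fail with named messages, and
`validate_config()` collects every configuration error in one pass.

## Limitations

* Gene-level only: one translational start per gene id; alternative
  isoforms must be collapsed upstream.
* The scanner is exact but exponential in the number of spacers in the
  worst case; the motifs of interest have ≤ 2 spacers, where it is
  effectively linear per start.
* Published genome-scale tallies (e.g. how many genes carry the
  conserved sequence genome-wide) depend on the exact genome build and
  isoform collapsing of the original analysis and are not reproduced
  here; the package reproduces the *method* and the printed set
  arithmetic.
* Under-enrichment folds follow this package's explicit
  `expected/observed` definition; other tools may differ.
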