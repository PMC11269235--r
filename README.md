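# adlmotif

Regulatory-genomics toolkit for cell-type transcriptome studies in
*C. elegans*, built around the analysis of postdauer reprogramming in
the ADL chemosensory neurons. It is for researchers who have gene
lists, count matrices and a genome, and need the exacting small
analyses between them done reproducibly:

* **Upstream regions** — strand-aware extraction of the window
  (default 500 bp) 5′ of each gene's translational start, from FASTA +
  GFF3/gene-table, written back as FASTA/BED6.
* **Degenerate gapped motifs** — a compiled grammar of literals, choice
  sets (`[AT]`, IUPAC `S/W/Y/R`) and bounded spacers (`N(0,3)` /
  `N_0-3`), scanned exactly. Built-ins: the DAF-3/SMAD site `GTCTA`,
  the ~30-bp conserved "MSP motif"
  `CT[AT]TAA[AT]TTN(0,3)[AC]AN(0,2)TTTTG[CT]CATAA[TA]C[TC]`, the
  composite PD motif (presence of both), and E-boxes `CASCTG` /
  `CACGTG`.
* **Expression** — RPKM (`counts·10⁹ / (length_nt · total_reads)`),
  expressed-gene calls at a cutoff (mean over replicates ≥ 10 RPKM by
  default), and DE-table ingestion at FDR < 0.05.
* **Set statistics** — overlaps, query percentages, Jaccard
  similarity, log-space hypergeometric enrichment
  `P[X ≥ k | n, K, N]` accurate down to p ~ 10⁻¹²⁰⁰ and beyond, and
  the wild-type-vs-mutant dependence partition
  `dependent = wt \ mut`.
* **Behavior** — avoidance index `((A+B)−(E+F))/N` over six plate
  sectors, chemotaxis index `(n_at − n_ctrl)/n_total`, reversal
  fractions.
* **Synthetic data** — seed-deterministic generators with truth
  labels: genomes with rejection-sampled motif-free backgrounds and
  planted instances, negative-binomial counts for a 2×2×4 design with
  planted DE, associations with a configured odds ratio, and
  multinomial assay plates with known attraction parameter θ.
* **Pipeline** — `run_pipeline()` composes everything from a validated
  YAML/list config and writes TSV/FASTA/BED reports plus a manifest of
  input hashes.

## Worked example

Compile the MSP motif, scan a sequence, and reproduce the dependence
arithmetic of a two-genotype DE comparison:

```r
library(adlmotif)

msp <- compile_pattern(msp_motif_spec(), name = "msp")
msp
#> <motif_pattern 'msp'>  CT [AT] TAA [AT] TT N(0,3) [AC] A N(0,2) TTTTG [CT] CATAA [TA] C [TC]  (match length 25-30)

scan_region(msp, paste0(strrep("A", 12),
                        "CTTTAATTTGGGCAGGTTTTGTCATAAACC",
                        strrep("A", 8)))[, 1:3]
#>   offset length strand
#> 1     12     30      +
```

The hit starts at 0-based offset 12 and spans 30 bp: the two spacers
took lengths 3 and 2 on top of the 25 fixed positions.

```r
ids <- sprintf("g%04d", 1:1500)
part <- dependence_partition(
  gene_set("wt_up",   ids[1:116]),
  gene_set("wt_down", ids[117:711]),
  gene_set("mut_up",   c(ids[1:15],    ids[801:881])),   # 15 shared
  gene_set("mut_down", c(ids[117:169], ids[901:952])))   # 53 shared
part
#> <dependence_partition>
#>   up:   116 wild-type, 15 shared -> 101 dependent
#>   down: 595 wild-type, 53 shared -> 542 dependent
#>   90% of wild-type DE genes are genotype-dependent
```

Of 116 + 595 wild-type DE genes, 101 + 542 lose their differential
expression in the mutant — 90%, the headline dependence figure. An
enrichment test against an explicit population reports fold and a
log-space p-value:

```r
pop <- gene_set("population", ids)
enrichment_test(gene_set("msp_motif", ids[180:250]), part$dependent_down, pop)
#> <enrichment_result> msp_motif vs dependent_down: k=71 (n=71, K=542, N=1500)
#>   expected 25.65, 2.77-fold enriched, p = 1.8e-33

jaccard_percent(5908, 6001, 5206, 1)
#> [1] 77.7
```

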