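# capiso

Analysis toolkit for **targeted full-length isoform sequencing by ORF-probe
capture**, driven by a ground-truthed synthetic experiment generator.

## The problem

Isoform abundances in a transcriptome span six or more orders of magnitude,
so untargeted long-read cDNA sequencing spends almost all of its depth on the
most abundant transcripts and misses low-abundance isoforms of the genes one
actually cares about (transcription factors, kinases, disease genes).
Hybridization capture with biotinylated probes synthesized from a single
cloned ORF per gene enriches full-length cDNA of the targeted genes before
sequencing; because isoforms of a gene share most of their exonic sequence,
one probe template captures the whole isoform family whenever the exonic
overlap between template and isoform is sufficient (empirically, ≥ 50 bp).

`capiso` implements the computational side of such an experiment:

* **Capture coverage** — for a one-ORF-per-gene design, the fraction of
  annotated isoforms with exonic overlap ≥ *m* nt against their gene's
  representative (APPRIS-principal, random, or specified), in both the
  exon-union and genomic-span overlap readings.
* **Capture model** — piecewise-linear retention in overlap *v*:
  background `p_bg` below 35 nt, full `p_on` at ≥ 45 nt, linear between;
  post-capture abundance ∝ pre-capture × efficiency, renormalized to 10⁶.
* **Full-length read processing** — a read is full-length iff it has the 5′
  primer, the 3′ primer and the polyA tail; demultiplexing by sample
  barcode; PCR-chimera detection from dual inner barcodes (concordant /
  discordant / unresolved), with per-isoform strict-majority calls.
* **Structural classification** — junction-chain based, in decision order:
  FSM (identical chain), ISM (consecutive sub-chain), NIC (all junctions or
  all sites annotated), NNC (novel splice site); mono-exon and intergenic
  handling; intron-retention flags; novelty summaries counting distinct
  sites and junctions once.
* **Feature annotation** — CAGE peak support of 5′ ends, canonical polyA
  motif (AATAAA/ATTAAA) fully inside the 5–25 nt window upstream of the 3′
  end, splice-site trinucleotide conservation from a bedGraph track.
* **Orthogonal validation** — novel isoforms survive only if every novel
  junction has ≥ 3 supporting short reads.
* **Enrichment & saturation** — on-target rates (TPM- or FL-read-weighted),
  fold enrichment (capturant rate / input rate), per-isoform capture
  efficiency vs overlap, rank-abundance tables, and saturation-discovery
  curves by without-replacement subsampling (100 iterations per depth)
  with a hypergeometric closed-form oracle.
* **Synthetic experiment generator** — genome + multi-isoform annotation
  with canonical GT..AG splice sites, log-uniform six-decade expression,
  overlap-dependent capture, barcoded reads with controllable chimera and
  full-length rates, and Poisson short-read junction counts — all
  deterministic under a seed, with every truth value recorded.

Formats go through Bioconductor infrastructure (`rtracklayer`, `Biostrings`,
`GenomicRanges`): GTF (GENCODE dialect, repeated `tag` attributes handled),
BED12, BED, bedGraph, FASTA, TSV.

## Worked example

```r
library(capiso)
bundle <- run_pipeline(run_config(seed = 1))
writeLines(make_report(bundle))
```

```
== capiso run report ==

[enrichment]
  on-target rate (TPM): input 0.04% -> capturant 3.38%
  on-target rate (FL reads): 3.45%
  fold enrichment: 96.6

[classification]
  82 isoforms: FSM=65, ISM=1, NIC=3, NNC=13
  novelty: sites 5.75%, junctions 10.34%, isoforms 19.51%
  validated novel isoforms: 14 / 16

[chimeras]
  non-chimeric isoform rate: all 98.78%, novel 100.00%

[features]
  5' within CAGE peak: 100.00%
  polyA motif found: 97.56%

[capture coverage]
  appris/exonic: 100.00%; appris/span: 100.00%; random/exonic: 100.00%

[saturation]
  depth 795: 13.7 genes, 37.1 isoforms
  ...
  depth 15909: 20.0 genes, 82.0 isoforms
```

Reading this: the eight targeted genes carried 0.04% of input abundance and
3.38% after capture — a 96.6-fold enrichment, close to the 100-fold ceiling
set by the default `p_on/p_bg = 0.5/0.005` contrast.  Of 82 collapsed
isoforms, 16 are novel relative to the (deliberately incomplete) reference
annotation; novelty amplifies from 5.75% of distinct splice sites through
10.34% of junctions to 19.51% of isoforms, because one novel local element
makes an entire transcript novel.  14 of the 16 novel isoforms pass the
3-short-read junction validation; 98.78% of isoforms are called non-chimeric
by the dual-barcode majority vote (2% of reads are simulated chimeras).
Passing `outdir =` to `run_pipeline()` writes every input and result
(GTF/FASTA/BED/bedGraph/TSV/JSON + manifest) and is byte-identical across
runs with the same config.

A thin CLI wrapper for shell use ships in `inst/cli/capiso`
(`capiso run --config run.yaml --out DIR`, `capiso coverage --gtf FILE ...`).

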