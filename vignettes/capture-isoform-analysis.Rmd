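---
title: "Targeted full-length isoform capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted full-length isoform capture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capiso)
```

## The problem

Most human protein-coding genes express several isoforms, but isoform
abundances span many orders of magnitude, so untargeted long-read cDNA
sequencing spends nearly all of its depth on the most abundant transcripts.
Hybridization capture with probes synthesized from a single cloned ORF per
gene concentrates sequencing on genes of interest; because isoforms of one
gene share most of their exonic sequence, one probe template is expected to
pull down the whole isoform family.  `capiso` implements the computational
side of such an experiment at desk scale: a fully synthetic, ground-truthed
capture experiment plus the analyses one would run on the real thing —
capture-coverage estimation, full-length (FL) read processing with
dual-barcode PCR-chimera detection, SQANTI-style structural classification,
functional feature annotation, orthogonal junction validation, and
enrichment/saturation statistics.

## Core models

### Capture efficiency

Spike-in experiments show capture efficiency is flat for probe/target
overlaps from about 45 nt up to several kb, and collapses to background at
35 nt.  We encode this as a piecewise-linear retention curve: a transcript
$t$ of a targeted gene with exonic overlap $v$ (nt) against the gene's probe
template retains with efficiency

$$
e(t) \;=\;
\begin{cases}
p_{bg} & v < 35\\
p_{bg} + (p_{on}-p_{bg})\,\frac{v-35}{45-35} & 35 \le v < 45\\
p_{on} & v \ge 45,
\end{cases}
$$

and untargeted transcripts retain at $p_{bg}$.  Post-capture abundance is
pre-capture abundance times $e(t)$, renormalized to $10^6$ (TPM scale).  The
defaults $p_{on} = 0.5$, $p_{bg} = 0.005$ give a 100-fold on/off contrast;
no functional form beyond "flat above 45, floor at 35" is empirically
constrained, and the linear ramp is the simplest interpolation between the
two observed knee points.  The baseline model is deterministic, which gives
the pipeline an exact closed form to check against: the capturant on-target
rate must equal $\sum_{t \in T} a_t e_t / \sum_t a_t e_t$ to machine
precision.

Overlap $v$ is the *exonic* overlap — the intersection of the two
transcripts' exon-interval unions — because probes derive from spliced ORF
sequence.  Since published descriptions of the genomic-range intersection
are ambiguous between exon records and whole-transcript spans,
`coverage_estimate()` computes both readings (`span = TRUE/FALSE`) and the
pipeline reports both.

### Structural classification

Isoform identity is the junction chain: the ordered intron coordinates,
stored in ascending genomic order on both strands (strand is metadata), so
chain equality is strand-safe.  Multi-exon categories are decided in order:

1. **FSM** — chain identical to a reference transcript's chain;
2. **ISM** — chain equal to a *consecutive* run of introns of a reference
   chain (the SQANTI convention; "consecutive" is our choice, adopted for
   interoperability);
3. **NIC/combination** — every junction annotated, but the chain is not a
   sub-chain of any reference transcript;
4. **NIC/novel_junction** — at least one junction novel but every splice
   site annotated;
5. **NNC** — at least one novel splice site.

Splice-site novelty is position-, side- and strand-specific: a donor at a
coordinate annotated only as an acceptor is novel.  Mono-exon isoforms are
contained-in-a-reference-exon (`mono-exon-known`), overlapping a gene
footprint (`mono-exon-novel`), or `intergenic`.  Gene assignment uses most
shared junctions, then most exonic overlap, then lexicographic gene id —
fully deterministic.  Intron retention is flagged when an isoform exon
strictly contains an annotated intron of the matched gene (strict
containment guarantees both flanking reference exons are overlapped).  The
flag is computed for every category but is interpreted, as in the field's
convention, for novel isoforms.

### Chimera detection

Each simulated cDNA molecule carries a matched pair of inner 5′/3′ barcodes
(96 pairs by default).  PCR chimeras join the 5′ portion of one molecule to
the 3′ portion of another, so their inner barcodes mismatch.  A read is
*concordant* (matching pair), *discordant* (both present, mismatched) or
*unresolved* (either barcode missing; such reads are excluded from all
denominators).  An isoform is called non-chimeric iff **strictly more than
half** of its resolved member reads are concordant; published wording
("a majority") does not resolve ties, and we call ties chimeric — the
conservative choice when the isoforms at stake are novel-isoform claims.
Note the read-level discordance estimator is blind to chimeras whose two
parents happen to carry the same barcode pair, a $1/96$ collision, so its
expectation is $r(1-1/96)$ for true rate $r$; tests account for this.

### Saturation-discovery curves

FL reads are subsampled **without replacement** (a finite pool is
subsampled, not resampled); the number of unique genes/isoforms is averaged
over 100 iterations per depth.  Within an iteration a single random
permutation is truncated at each depth: each depth's marginal draw is still
uniform without replacement, per-iteration curves are monotone by
construction, and the cost is one permutation per iteration.  The analytic
oracle is the hypergeometric closed form
$E[\text{unique}] = \sum_i \left(1 - \binom{N-n_i}{d}/\binom{N}{d}\right)$,
which the curves must match within 3 standard errors.

## The synthetic-data generator

`simulate_annotation()` builds a genome and multi-isoform annotation with
known truth.  Each gene gets a principal transcript (tagged
`appris_principal` + `basic`, TSL 1) and alternatives derived by exon
skipping, alternative donors/acceptors (3–30 nt shifts), intron retention,
and alternative first/last exons; all splice sites are canonical GT..AG in
the transcribed sense by construction (planted into the genome, with
conflicting plants rejected), and a canonical AATAAA polyA motif is planted
5–20 nt upstream of the 3′ end for 70% of transcripts (best-effort; plants
that clash with splice-site constraints are skipped).  Alternative isoforms
receive random TSL 1–5, which exercises the TSL-confirmation summary.

Default study conditions, chosen once as a realistic desk-scale rendering of
a targeted capture experiment and not revisited:

| knob | default | rationale |
|---|---|---|
| genes / isoforms per gene | 20 / 1–8 | small but multi-isoform-rich |
| exons per transcript | 3–9 | typical mammalian span at reduced scale |
| expression dynamic range | 6 decades, log-uniform per gene | the transcriptome-wide range; isoform split Dirichlet(1), uninformative |
| capture | $p_{on}=0.5$, $p_{bg}=0.005$, knees 35/45 nt | see above |
| reads / FL rate / chimera rate | 20,000 / 0.8 / 0.02 | Sequel-era FL yields; low single-digit chimera rates |
| samples / barcode pairs | 7 / 96 | seven-tissue multiplex; plate-format dual barcodes |
| withheld novel isoforms | 20% of alternatives | so classification meets genuine novelty |
| short-read junction depth | $5\times10^5$ expected reads per unit mass | a deep orthogonal Illumina run; at this depth moderately expressed junctions clear the 3-read validation bar |

Targets (8 genes by default) are drawn from the lower-abundance half of
genes because capture is the tool one reaches for precisely when targets are
low to moderate abundance; `target_bias = "uniform"` disables this.  Probe
representation per target is log-uniform over $10^{-1}$–$10^2$ TPM, so the
1-TPM probe-representation stratum in the recovery report is non-trivial.

Non-FL reads drop exactly one of {5′ primer, 3′ primer, polyA} uniformly —
the minimal model that exercises the FL filter.  A read missing its 3′
primer also loses its sample barcode (which lives inside that primer).
Chimeric reads take their alignment blocks from the 5′ parent molecule (a
single-contig block list cannot represent both parents); both parent ids are
recorded as truth.

What the generator does **not** emulate: sequencing errors and quality
scores, consensus-accuracy filtering, 5′/3′ truncation continua, abundance-
dependent off-target binding (exposed nowhere; off-target retention is a
constant $p_{bg}$), fragment-length loading bias, and genuinely intergenic
transcription.  Passing tests therefore demonstrate correctness of the
analysis logic under a clean structural model, not robustness to the error
modes of real long reads.

## Numerical and convention choices

* Internal coordinates are 0-based half-open everywhere; GTF converts at the
  boundary.  bedGraph boundaries resolve to the right-hand interval.
* The polyA window "5–25 nt upstream" is read as: the motif lies entirely
  within that window, offsets measured to the motif's 3′-most base (so a
  found motif has end-offset in [5, 20]); both end- and start-offsets are
  emitted so either reading can be consumed downstream.
* CAGE distance is signed in transcript orientation, negative when the 5′
  end is upstream of the nearest peak center; membership uses the half-open
  peak interval.  Ties in |distance| resolve to the first peak in file order.
* Missing conservation scores stay `NA` (0 is a meaningful phyloP value).
* Alignment-quality thresholds (≥ 0.99 coverage, ≥ 0.95 identity) are
  inclusive.  Junction validation (≥ 3 short reads per novel junction) is
  inclusive, vacuous for isoforms without novel junctions, and junctions
  absent from the count table count as 0.
* Representatives shorter than the 50 bp coverage threshold still cover
  themselves (a probe trivially captures its own template); genes without an
  APPRIS tag are skipped with a warning by default (configurable to
  `longest` or `error`), keeping the estimate well-defined.
* The pipeline expands one global seed into independent per-stage seeds via
  a seeded `sample.int`, so stages are individually reproducible; all
  randomness flows from the config seed, and two runs of one config are
  byte-identical.

## Problem sizes

The test suite runs the full pipeline at 2,000–20,000 reads, oracle
comparisons on ~1,600 random micro-fixtures, saturation analysis on a
10,000-read pool, and chimera-rate recovery at 50,000 reads; these sizes
make every distributional check decisive at 3-standard-error tolerances
while keeping a complete run in the low minutes on one core.

## Limitations

The capture model is transcript-level: probes are not tiled, GC content and
melting temperature are ignored, and enrichment does not depend on probe
representation (observed to be a weak effect).  Classification consumes
aligned exon structures; alignment itself (and hence alignment error) is out
of scope, as are ORF prediction, RT-switching artifact detection, and
TSS/TES end clustering (5′/3′ variation within a junction chain is collapsed).
The published coverage figures for the full human annotation (99.7% with
APPRIS representatives) require the complete reference annotation as input;
with `read_gtf()` + `coverage_estimate()` the same analysis runs on any GTF,
and the package's own reports quote only what it computes on its synthetic
conditions.
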