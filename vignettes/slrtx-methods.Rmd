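---
title: "Methods: UMI-based synthetic long-read assembly and isoform analysis"
author: "slrtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UMI-based synthetic long-read assembly and isoform analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrtx)
```

## The measurement model

Synthetic long-read (SLR) transcriptome sequencing reconstructs
single-molecule transcript sequences from ordinary short reads. Each
first-strand cDNA molecule is tagged with a unique molecular identifier
(UMI) and flanked by known synthetic 5' and 3' adapters; after
amplification the UMI is transposed to random internal positions, so each
short read carries the UMI of its molecule of origin plus a fragment of its
sequence. Reads sharing a `(sample index, UMI)` pair therefore tile one
molecule and can be de novo assembled into a single long read with a
consensus-corrected, per-base-quality-scored sequence. A reconstructed
contig is *full length* when both synthetic adapters are found at its
termini; otherwise the adapters tell which end is missing.

slrtx implements that computational core end to end — simulation, binning,
assembly, quality scoring, completeness classification — plus the
validation analyses a control experiment needs (error profiling against
reference transcripts, terminus-offset histograms, chimera detection by
split end-mapping, abundance recovery, on-target rates) and the downstream
biology (isoform assignment and counting, differential expression,
isoform-resolved SNV statistics, fusion-junction detection).

## The simulator and what it emulates

`sim_config()` + `simulate_dataset()` generate a toy annotation (multi-exon
genes on two chromosomes; alternative isoforms by single internal-exon
skipping), barcoded molecules, and error-bearing short reads, with
truth sidecars for every stage. The artefact model covers the phenomena the
QC stages are built to detect:

* **Premature reverse-transcription termination** (default fraction 0.13)
  removes a 5' segment of at least 100 nt, uniform up to half the
  transcript, while leaving the 5' adapter attached — the
  "false full length" phenomenon in which a contig classifies as full
  length yet starts well downstream of the annotated TSS. The 100 nt floor
  matches the observation that essentially all non-canonical start sites
  sit more than 100 bp downstream; the fraction itself is a free parameter
  of the simulator, not a published value.
* **Poly-T mispriming** at the TTS (default fraction 0.16): a signed offset
  drawn from a discrete normal (SD 2 nt) truncated to ±5 nt and excluding
  0, since a zero offset would be no event; negative offsets truncate the
  3' end, positive offsets append templated-slippage A's.
* **Inter-molecular PCR chimeras** (default rate 0.018): a molecule keeps
  its 5' part up to a junction drawn uniformly from the middle 50% of its
  insert and continues with the 3' part of another molecule.
* **Short-read errors**: independent per-base substitutions, insertions and
  deletions (defaults 4.15e-3 / 3.84e-4 / 4.8e-4, the magnitudes typical of
  Illumina RNA data). Fragment starts are near-uniform with overhang
  clipping (minimum 50 nt overlap), so termini are covered at depths
  comparable to the interior — coverage uniformity is the mechanism that
  makes consensus correction work.

UMIs are 16 nt, drawn uniformly from the 4^16 space; collisions are allowed
and recorded in truth rather than prevented, keeping the collision pathway
testable. Adapters are fixed 22 nt package constants (`ADAPTER_5P`,
`ADAPTER_3P`) and configurable everywhere they are consumed.

What the simulator does **not** model: cycle-dependent Illumina error
spectra, PCR duplication beyond chimeras, poly-A-tail length, and
expression structure beyond a static abundance ladder (default: a geometric
ladder spanning three decades). Tests passing on this generator demonstrate
the pipeline's correctness on its stated error model, not performance on
real libraries.

## Assembly and the quality model

Each bin is assembled with a per-bin de Bruijn graph (default k = 25, both
read orientations), k-mers below multiplicity 2 dropped, and the
highest-multiplicity path extracted greedily with deterministic tie-breaks
(higher count first, then the lexicographically smaller base). Bins with
fewer than 3 reads are rejected — below three reads a consensus is
statistically meaningless. Member reads are then overlaid on the path by
majority k-mer offset, giving the per-column pileup from which the final
consensus sequence, depth and agreement profiles are computed. Because each
bin holds a single molecule, no scaffolding, bubble popping at scale, or
repeat resolution is needed; this is deliberately not a general-purpose
assembler.

The multiplicity-2 filter implies a practical coverage floor: a k-mer must
be fully contained in at least two reads, so per-molecule coverage below
roughly 15x leaves occasional singleton k-mers and truncates paths. The
package's defaults (coverage 30, read length 150) sit comfortably above
that; the test suite's exactness checks use coverage 20.

Per-base quality integrates the three available signals — depth, agreement,
and the member reads' own quality scores:

\[ p_\mathrm{err} = \max\left(\frac{d - c + 1}{d + 2},\; \bar e \right),
\qquad Q = \min\big(\mathrm{round}(-10 \log_{10} p_\mathrm{err}),\; Q_\mathrm{cap}\big) \]

with `d` the column depth, `c` the plurality count (Laplace-smoothed
dissent), and `ē` the depth-weighted mean per-read error probability at the
column, which floors the estimate: a consensus cannot claim less error than
its evidence. The cap defaults to Q60. The closed form is this package's
own choice; published SLR quality models are not public, and no result here
depends on exact Q values.

Adapters are located by best semi-global match (edit distance ≤ 2 by
default) within a terminal window of 1.5 adapter lengths, in both contig
orientations; the contig is reported in the orientation matching the 5'
adapter. Classes follow directly from the two flags: `full_length`,
`missing_5p`, `missing_3p`, `fragment`.

## Alignment carriers

Transcript-space validation (`align_to_reference()`) selects candidate
references by exact k-mer anchoring and resolves near-ties with a full
overlap alignment (match +1, mismatch −2, gap open −4, gap extend −1,
through `Biostrings::pairwiseAlignment`). The two-stage design matters for
exon-skipping siblings: a reference-side gap does not reduce the anchored
query span, so anchor counts tie and only the gap-penalizing alignment
score separates the isoforms. Operations are re-derived by walking the
aligned strings, giving per-reference-position substitution, insertion and
deletion counts.

Genome-space spliced alignment (`genome_align()`) chains exact k-mer
anchors (k = 21) colinearly per chromosome and strand; genomic gaps of at
least 20 nt between chained blocks are introns, shorter gaps are indels and
merge. Block edges are refined by exact extension, so junction coordinates
are base-accurate on clean contigs. The 20 nt threshold separates splice
gaps from indel errors at this scale.

## QC conventions

* **Error-rate summary**: every rate shares one denominator, the total
  aligned assembled bases (alignment columns), so
  `match = 1 − (sub + ins + del)` holds identically. This is the convention
  under which the published summary rows are internally consistent.
* **Positional bias**: ratio of the position's per-coverage rate to the
  overall rate of that error type; positions inside homopolymer runs ≥ 4 nt
  are flagged (reported error hotspots range from four to seven identical
  bases).
* **Terminus offsets** come from overlap-alignment end-gap bookkeeping:
  TSS offset = uncovered reference head − unaligned query head; TTS offset
  = unaligned query tail − uncovered reference tail. Both signs are
  recoverable, including appended poly-A slippage. Buckets: exact, within
  5 nt, more than 100 nt downstream.
* **Chimera detection** maps the two terminal 100 nt windows independently.
  Every reference within a small margin of the window's best anchor score
  is a candidate — shared terminal exons make the best hit a tie, not a
  unique call. A contig is clean when some common candidate is consistent
  in order, strand and separation (≤ 1.5 contig lengths); disjoint
  candidate sets mean an inter-molecular chimera; a common reference with
  inconsistent geometry is intra-molecular; unmappable windows are flagged.
  Sibling-isoform chimeras (5' of one isoform joined to 3' of its
  exon-skipping sibling) are invisible to end-mapping by construction —
  both windows lie in shared exons — so the chimera acceptance experiment
  uses a spike-in-like panel of distinct single-isoform references, the
  setting in which the published chimera rate was measured.
* **Abundance**: Pearson r of log2(expected) vs log2(observed + 0.5) over
  full-length contigs, with and without the ≥ 700 bp length filter.

## Isoform quantification and differential expression

A contig's junction chain must match a consecutive run of an isoform's
annotated chain, within ±5 nt at each junction end (the tolerance mirrors
the 5 nt granularity used for terminus buckets). Consecutive-subchain
matching, rather than whole-chain equality, lets prematurely terminated
molecules still be assigned; full-length error-free contigs match uniquely
because the sibling isoforms differ in at least one junction. Ties resolve
to the longest compatible chain, then the lexicographically smallest id;
mono-exonic contigs assign by exon containment.

The differential test is intentionally minimal: median-of-ratios size
factors; method-of-moments negative-binomial dispersion per feature,
moderated towards the across-feature median (a handful of replicates cannot
support per-feature dispersions alone) and floored at 0.01; a Wald test on
the log fold change with a delta-method standard error; BH adjustment.
The *selection rule* is the contractual part: significant means adjusted
p ≤ 0.05 and |fold change| > 2. This engine is not a DESeq2 reproduction
and is validated only for calibration (null type-I error near nominal) and
the selection rule.

DEG/DEI categorization is set algebra on gene identifiers: DEG-only,
DEG∩DEI, and DEI-only (genes owning at least one differential isoform but
no gene-level change), with the two headline fractions. Sample similarity
uses row Z-scores, average-linkage clustering on 1 − Pearson, and PCA by
eigendecomposition of the sample covariance — all deterministic.

## SNV-isoform statistics

Wild-type and alternate contigs are counted per (variant, isoform, sample)
from spliced genome alignments; third bases and non-covering contigs are
excluded, and the SNV rate is `alt / (alt + wt)`.

* **Uneven distribution**: variants on ≥ 2 isoforms with ≥ 5 covering
  contigs are tested by chi-squared goodness of fit of ALT counts against
  each isoform's share of the variant's total (WT + ALT) contigs. The null
  is each isoform's overall usage — the question is whether the allele is
  placed differently from how the gene's transcripts are used, not whether
  usage is uniform. (The source analysis does not state its null; this is
  the package's documented choice.)
* **Distribution shift**: a 2×k Fisher exact test comparing the WT and ALT
  isoform profiles, by full enumeration of tables with the observed margins
  when the total is ≤ 200, else Monte-Carlo with 10^5 draws at a fixed
  default seed (20210427). The p-value is the total probability of tables
  no more probable than the observed one.
* **Switching**: a (variant, isoform) pair switches when its rate is
  ≥ 0.5 in every sample of one group and < 0.5 in every sample of the
  other. The published thresholds ("≥ 0.5" high, "≤ 0.5" low) overlap at
  exactly 0.5; the package resolves the boundary as high ≥ 0.5, low < 0.5,
  deterministically and configurably. No additional significance test is
  layered on the threshold rule.

BH adjustment is applied within each screen family at FDR 5%.

## Fusion detection

Known junctions are searched as exact 30-mers (the center of the 100 nt
junction flank: 15 nt each side of the breakpoint), in both orientations —
cDNA strandedness is not guaranteed after assembly. Candidates are verified
by split alignment: each arm must align to its partner reference with
≥ 90% identity over ≥ 50 nt (configurable stand-ins for a BLAST
confirmation step). Novel candidates are contigs whose aligned blocks span
two annotated genes; trans candidates additionally go through a split
second pass because the spliced aligner assigns one chromosome per contig.

The filter implements the two published criteria: (i) partners in trans, or
in cis separated by more than 40 kb with at least one gene wholly in
between; and (ii) both breakpoints at annotated exon edges, within a ±2 nt
jitter tolerance. Separation is measured between the nearest gene-span
boundaries (the published text does not say whether it is junction-to-
junction or gene-to-gene; gene boundaries are the package's configurable
choice).

## Determinism and problem sizes

Every stochastic stage is seed-deterministic: identical configurations give
byte-identical FASTQ, GTF, BED and truth files, and the pipeline manifest
checksums are reproducible. Ties are always broken lexicographically.

The test and acceptance workloads are sized for a desk-scale run: 500
molecules at coverage 20 for the consensus-error measurement, 2,000 molecules
for chimera detection, 600 for terminus buckets, 1,000 simulated variants
for screen calibration. These sizes give binomial standard errors small
enough for three-sigma checks while keeping the full suite in minutes.

## Known limitations

* The assembler assumes one molecule per bin; UMI collisions produce mixed
  bins that typically assemble to the dominant molecule. Collisions are
  truth-recorded but not corrected (no UMI error-merging).
* End-mapping cannot see sibling-isoform chimeras (shared terminal exons)
  or junctions outside the terminal windows.
* The DE engine's dispersion moderation is a single global prior, not a
  mean-dispersion trend; it is adequate for calibration at toy scale.
* Premature termination makes truncated contigs' junction chains ambiguous
  between isoforms sharing a junction suffix; assignment then falls back to
  the deterministic tie-break, which can undercount skipped isoforms.
* The quality model is a defensible closed form, not a reproduction of any
  published score; downstream analyses use sequences, not Q values.
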