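# slrtx — synthetic long-read transcriptome assembly and isoform analysis

Characterizing full-length transcript isoforms with short-read sequencers
is hard: a 150 nt read rarely spans enough junctions to identify which
splice variant it came from. Synthetic long-read (SLR) protocols solve this
by tagging every first-strand cDNA molecule with a unique molecular
identifier (UMI) and flanking it with known synthetic adapters; after
amplification, the UMI ends up attached to random internal fragments of the
molecule, so short reads sharing a `(sample index, UMI)` pair tile one
molecule and can be de novo assembled back into it.

slrtx is an R implementation of the computational side of that approach,
aimed at bioinformaticians who want to reconstruct, validate and analyse
SLR transcriptome data — or to study the method itself on fully
truth-annotated simulations:

* **Simulator** — toy gene models, barcoded molecules and error-bearing
  short reads with truth sidecars, including the library artefacts the QC
  is designed to catch (premature RT termination, poly-T mispriming at the
  TTS, inter-molecular PCR chimeras).
* **Assembly** — per-UMI de Bruijn assembly with a consensus quality model
  `Q = round(−10·log10 max((d−c+1)/(d+2), ē))` (depth `d`, plurality count
  `c`, mean read error `ē`, capped at Q60), adapter detection and
  completeness classes (`full_length`, `missing_5p`, `missing_3p`,
  `fragment`).
* **QC against references** — per-position substitution/insertion/deletion
  profiles with a single-denominator summary (`match = 1 − sum error`),
  positional bias ratios with homopolymer flags, TSS/TTS offset buckets
  (exact / within 5 nt / >100 nt downstream), chimera detection by split
  end-mapping of the terminal 100 nt windows, observed-vs-expected
  abundance (log2 Pearson, with the ≥700 bp filter) and BED on-target
  rates.
* **Isoform analysis** — splice-junction-chain assignment (±5 nt
  tolerance), gene/isoform count matrices, a minimal negative-binomial
  Wald test with the FDR 5% + >2-fold selection rule, and DEG/DEI
  categorization (DEG-only / both / DEI-only).
* **SNV-isoform statistics** — per (variant, isoform, sample) WT/ALT
  counts and SNV rate = alt/(alt+wt); chi-squared uneven-distribution
  screen, 2×k Fisher exact test (full enumeration ≤ 200 total, Monte-Carlo
  beyond), and the uniform high(≥0.5)/low(<0.5) isoform-switching screen.
* **Fusion detection** — exact 30-mer junction search (15 nt either side
  of the breakpoint, both strands), split-alignment verification (≥90%
  identity, ≥50 nt arms), and the trans-or-cis(>40 kb, ≥1 intervening
  gene) + exon-boundary filter.

## Worked example

Simulate a small library, assemble it, and validate the contigs:

```r
library(slrtx)

cfg <- sim_config(n_genes = 4, n_molecules = 60, coverage = 25, seed = 11)
ann <- build_toy_annotation(cfg)
mols <- inject_chimeras(sample_molecules(ann, cfg), cfg)
reads <- fragment_to_short_reads(mols, cfg)

bins <- bin_reads(reads[, c("id", "seq", "qual", "sample_index", "umi")])
asm  <- assemble_bins(bins)
table(vapply(asm$contigs, `[[`, "", "completeness"))
#> full_length  missing_3p  missing_5p
#>          54           1           5

fl  <- Filter(function(x) x$completeness == "full_length", asm$contigs)
aln <- align_to_reference(fl, reference_seqs(ann))
profile_errors(aln)
#> error_profile over 62109 aligned bases: match 1, sub 0, ins 0, del 0 (sum 0)
terminus_offsets(aln)
#> terminus_offsets over 54 full-length contigs
#>   TSS: exact 85.2%, within 5 nt 0.0%, >100 nt downstream 14.8%
#>   TTS: exact 77.8%, within 5 nt 22.2%
```

Reading the output: all 60 bins assembled; 54 contigs carry both adapters
and are full length, and the others report which adapter is missing.
Consensus over ~25x per-molecule coverage removed every injected
short-read error across 62,109 aligned bases. The 14.8% of start sites
shifted more than 100 nt downstream are the simulated prematurely
terminated molecules (configured fraction 0.13) — they still carry the 5'
adapter, which is exactly why terminus QC is needed on top of adapter
classification — and the 22.2% of termination sites within ±5 nt are the
simulated poly-T mispriming events (configured fraction 0.16).

A one-command version of the same flow, with a manifest of checksummed
outputs:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 11,
                             sim = list(n_genes = 4, n_molecules = 60)))
```

A thin CLI wrapper lives at `inst/cli/slrtx`
(`slrtx simulate|assemble|run`).

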