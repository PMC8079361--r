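#' Fragment molecules into UMI-tagged short reads
#'
#' Emulates random transposition of the UMI to internal positions of each
#' barcoded molecule: fragment start positions are approximately uniform
#' along the molecule (the coverage-uniformity property that drives
#' consensus error reduction), every read carries the molecule's sample
#' index and UMI, and per-base substitution/insertion/deletion errors are
#' injected at the configured rates. Reads overhanging a molecule end are
#' clipped, with a minimum overlap of 50 nt, so termini are covered at
#' depths comparable to the interior.
#'
#' @param mols Molecule table from [sample_molecules()] (after optional
#'   [inject_chimeras()]).
#' @param config A [sim_config()]; `config$coverage` must be positive.
#' @return data.frame of simulated reads: `id`, `molecule_id`, `umi`,
#'   `sample_index`, `seq`, `qual`, `offset` (0-based truth offset of the
#'   clipped fragment on the molecule), `strand`.
#' @export
fragment_to_short_reads <- function(mols, config) {
  if (config$coverage <= 0) stop("coverage depth must be positive")
  set.seed(config$seed + 3000L)
  rl <- config$read_length
  min_ov <- 50L
  lens <- nchar(mols$seq)
  if (nrow(mols) > 0 && min(lens) < rl)
    stop("read length ", rl, " exceeds shortest molecule length ", min(lens))

  out <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    len <- lens[i]
    target <- config$coverage * len
    # expected clipped read length under the uniform start model
    n_exp <- ceiling(target / (rl - min_ov / 2)) + 4L
    starts <- integer(0); got <- 0
    while (got < target) {
      s <- sample.int(len + rl - 2L * min_ov, n_exp) - (rl - min_ov) - 1L
      from <- pmax(s, 0L); to <- pmin(s + rl, len)
      starts <- c(starts, s)
      got <- sum(pmin(starts + rl, len) - pmax(starts, 0L))
    }
    # trim overshoot deterministically
    csum <- cumsum(pmin(starts + rl, len) - pmax(starts, 0L))
    keep <- seq_len(which(csum >= target)[1])
    starts <- starts[keep]
    from <- pmax(starts, 0L) + 1L
    to <- pmin(starts + rl, len)
    seqs <- substring(mols$seq[i], from, to)
    strand <- sample(c("+", "-"), length(seqs), replace = TRUE)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    out[[i]] <- data.frame(molecule_id = mols$molecule_id[i],
                           umi = mols$umi[i],
                           sample_index = mols$sample_index[i],
                           seq = seqs, offset = from - 1L, strand = strand,
                           stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  if (is.null(reads)) {
    reads <- data.frame(molecule_id = character(), umi = character(),
                        sample_index = character(), seq = character(),
                        offset = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  reads$seq <- inject_read_errors(reads$seq, config)
  reads$id <- sprintf("r%07d", seq_len(nrow(reads)))
  reads$qual <- strrep(phred_to_char(config$base_quality), nchar(reads$seq))
  reads[, c("id", "molecule_id", "umi", "sample_index", "seq", "qual",
            "offset", "strand")]
}

# independent per-base substitutions, insertions and deletions
inject_read_errors <- function(seqs, config) {
  if (length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nsub <- rbinom(length(seqs), lens, config$sub_rate)
  nins <- rbinom(length(seqs), lens, config$ins_rate)
  ndel <- rbinom(length(seqs), lens, config$del_rate)
  touch <- which(nsub + nins + ndel > 0)
  bases <- c("A", "C", "G", "T")
  for (i in touch) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (nsub[i] > 0) {
      pos <- sample.int(length(s), min(nsub[i], length(s)))
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    if (ndel[i] > 0 && length(s) > ndel[i]) {
      pos <- sample.int(length(s), ndel[i])
      s <- s[-pos]
    }
    if (nins[i] > 0) {
      pos <- sort(sample.int(length(s), min(nins[i], length(s))))
      for (j in rev(seq_along(pos))) {
        s <- append(s, sample(bases, 1), after = pos[j])
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Write simulated reads as FASTQ with the package header dialect
#'
#' Headers follow `@<readid> BX:<sampleindex>:<UMI> MI:<moleculeid>`.
#' @param reads Read table from [fragment_to_short_reads()].
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  ids <- sprintf("%s BX:%s:%s MI:%s", reads$id, reads$sample_index,
                 reads$umi, reads$molecule_id)
  write_fastq(ids, reads$seq, reads$qual, path)
}

#' Run the full simulator and write a dataset to disk
#'
#' Generates annotation, molecules, chimeras and short reads, and writes:
#' `reads.fastq`, `references.fasta` (spliced transcripts), `genome.fasta`,
#' `annotation.gtf`, `targets.bed`, `molecules.tsv` (truth),
#' `reads_truth.tsv`, and `fusions.tsv` (designed junction flanks) when
#' fusions are enabled. Identical configs (including seed) give
#' byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param sample_index Sample index for the generated library.
#' @return Invisibly, a list with the in-memory `annotation`, `molecules`
#'   and `reads` plus the file `paths`.
#' @export
simulate_dataset <- function(config, out_dir, sample_index = "S1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- build_toy_annotation(config)
  mols <- sample_molecules(ann, config, sample_index = sample_index)
  if (config$fusions && !is.null(ann$fusions)) {
    mols <- add_fusion_molecules(mols, ann, config)
  }
  mols <- inject_chimeras(mols, config)
  reads <- fragment_to_short_reads(mols, config)

  paths <- list(reads = file.path(out_dir, "reads.fastq"),
                references = file.path(out_dir, "references.fasta"),
                genome = file.path(out_dir, "genome.fasta"),
                annotation = file.path(out_dir, "annotation.gtf"),
                targets = file.path(out_dir, "targets.bed"),
                molecules = file.path(out_dir, "molecules.tsv"),
                reads_truth = file.path(out_dir, "reads_truth.tsv"))
  write_reads_fastq(reads, paths$reads)
  write_fasta(reference_seqs(ann), paths$references)
  write_fasta(ann$genome, paths$genome)
  write_annotation_gtf(ann, paths$annotation)
  write_targets_bed(ann, paths$targets)
  write_molecule_truth(mols, paths$molecules)
  write.table(reads[, c("id", "molecule_id", "offset", "strand")],
              paths$reads_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  if (config$fusions && !is.null(ann$fusions)) {
    paths$fusions <- file.path(out_dir, "fusions.tsv")
    write.table(ann$fusions, paths$fusions, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(annotation = ann, molecules = mols, reads = reads,
                 paths = paths))
}

# append designed fusion molecules (full fused transcripts, both adapters)
add_fusion_molecules <- function(mols, ann, config) {
  set.seed(config$seed + 4000L)
  rows <- list()
  for (i in seq_len(nrow(ann$fusions))) {
    fid <- ann$fusions$fusion_id[i]
    seq <- fusion_transcript_seq(ann, fid)
    for (j in seq_len(config$n_fusion_molecules)) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = sprintf("f%s_%02d", sub("FUS_", "", fid), j),
        umi = random_dna(config$umi_length),
        sample_index = if (nrow(mols)) mols$sample_index[1] else "S1",
        isoform_id = fid, insert = seq, adapter_5p = TRUE, adapter_3p = TRUE,
        premature_offset = 0L, tts_offset = 0L, chimera = "none",
        partner_isoform = NA_character_, partner_molecule = NA_character_,
        junction_pos = NA_integer_, partner_junction = NA_integer_,
        seq = NA_character_, stringsAsFactors = FALSE)
    }
  }
  extra <- do.call(rbind, rows)
  extra$seq <- molecule_sequence(extra, config)
  out <- rbind(mols, extra)
  structure(out, class = c("barcoded_molecules", "data.frame"))
}
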