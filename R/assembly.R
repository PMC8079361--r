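# SLR assembly: bin short reads by (sample index, UMI), assemble each bin
# with a per-bin de Bruijn graph, compute consensus quality, locate the
# synthetic adapters and classify completeness.

#' Assembly parameters
#'
#' @param k De Bruijn k-mer size; odd, between 15 and 63 (at most 32 in this
#'   implementation's 2-bit encoding).
#' @param min_reads Minimum reads per bin; smaller bins are rejected.
#' @param min_mult Minimum k-mer multiplicity retained in the graph.
#' @param quality_cap Phred cap for consensus qualities.
#' @param adapter_max_edit Maximum edit distance for adapter detection.
#' @return Object of class `assembly_params`.
#' @export
assembly_params <- function(k = 25L, min_reads = 3L, min_mult = 2L,
                            quality_cap = 60L, adapter_max_edit = 2L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 63L) stop("k must be odd in [15, 63]")
  if (k > 32L) stop("k above 32 is not supported by the 2-bit encoding")
  if (min_reads < 1L) stop("min_reads must be at least 1")
  structure(list(k = k, min_reads = as.integer(min_reads),
                 min_mult = as.integer(min_mult),
                 quality_cap = as.integer(quality_cap),
                 adapter_max_edit = as.integer(adapter_max_edit)),
            class = "assembly_params")
}

#' Bin short reads by (sample index, UMI)
#'
#' @param reads Either a read table with columns `id`, `seq`, `qual`,
#'   `sample_index`, `umi` (as produced by [fragment_to_short_reads()]) or a
#'   path to a FASTQ file whose headers carry the UMI tag.
#' @param umi_regex Regex with two capture groups (sample index, UMI) applied
#'   to FASTQ headers; default matches `BX:<sampleindex>:<UMI>`.
#' @return List of bins; each bin is a list with `sample_index`, `umi` and a
#'   `reads` data.frame. Bins partition the input read multiset.
#' @export
bin_reads <- function(reads, umi_regex = "BX:([^: ]+):([ACGTN]+)") {
  if (is.character(reads) && length(reads) == 1) {
    fq <- read_fastq(reads)
    m <- regmatches(fq$id, regexec(umi_regex, fq$id))
    bad <- which(vapply(m, length, integer(1)) != 3L)
    if (length(bad))
      stop("read header missing UMI tag: ",
           sub(" .*", "", fq$id[bad[1]]))
    reads <- data.frame(id = sub(" .*", "", fq$id),
                        sample_index = vapply(m, `[`, "", 2L),
                        umi = vapply(m, `[`, "", 3L),
                        seq = fq$seq, qual = fq$qual,
                        stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0) return(list())
  if (anyNA(reads$umi) || any(!nzchar(reads$umi)))
    stop("read header missing UMI tag: ", reads$id[which(!nzchar(reads$umi))[1]])
  key <- paste(reads$sample_index, reads$umi, sep = ":")
  idx <- split(seq_len(nrow(reads)), key)
  lapply(idx, function(i) {
    list(sample_index = reads$sample_index[i[1]], umi = reads$umi[i[1]],
         reads = reads[i, c("id", "seq", "qual")])
  })
}

#' Assemble one UMI bin into an SLR contig
#'
#' Builds a de Bruijn graph (both read orientations), drops k-mers below the
#' multiplicity threshold, extracts the highest-multiplicity path with
#' deterministic tie-breaks, then re-overlays the member reads on the path to
#' obtain the per-base pileup from which the consensus sequence, depth and
#' agreement profiles and Phred qualities are computed.
#'
#' @param bin One bin from [bin_reads()].
#' @param params [assembly_params()].
#' @return An `slr_contig`, or an `slr_rejection` (with a `reason`) for bins
#'   below the read threshold or without surviving k-mers.
#' @export
assemble_bin <- function(bin, params = assembly_params()) {
  n <- nrow(bin$reads)
  id <- paste(bin$sample_index, bin$umi, sep = ":")
  if (n < params$min_reads) {
    return(structure(list(id = id, reason = "too few reads", n_reads = n),
                     class = "slr_rejection"))
  }
  path <- .dbg_assemble(bin$reads$seq, params$k, params$min_mult)
  if (!nzchar(path) || nchar(path) < params$k + 1L) {
    return(structure(list(id = id, reason = "insufficient coverage",
                          n_reads = n), class = "slr_rejection"))
  }
  prof <- .consensus_profile(path, bin$reads$seq, bin$reads$qual, params$k)
  seq <- prof$sequence
  depth <- prof$depth
  agree <- prof$agree
  # trim zero-depth termini (interior zero depth cannot occur on a path
  # built from the same reads)
  covered <- which(depth > 0)
  if (length(covered) == 0) {
    return(structure(list(id = id, reason = "insufficient coverage",
                          n_reads = n), class = "slr_rejection"))
  }
  span <- covered[1]:covered[length(covered)]
  if (any(depth[span] == 0)) span <- span[depth[span] > 0]
  seq <- paste(strsplit(seq, "", fixed = TRUE)[[1]][span], collapse = "")
  depth <- depth[span]; agree <- agree[span]
  mean_err <- prof$mean_read_err[span]
  qual <- score_quality(depth, agree, mean_err, cap = params$quality_cap)
  structure(list(id = id, sample_index = bin$sample_index, umi = bin$umi,
                 sequence = seq, quality = qual, depth = depth,
                 agreement = agree / depth, n_reads = prof$reads_used,
                 completeness = NA_character_, insert = NA_character_,
                 insert_quality = NULL,
                 adapter_5p = list(found = NA, pos = NA_integer_),
                 adapter_3p = list(found = NA, pos = NA_integer_)),
            class = "slr_contig")
}

#' Per-base consensus quality scores
#'
#' Implements the three-ingredient quality model: per column the error
#' probability is the Laplace-smoothed dissent estimate
#' `p_err = (d - c + 1) / (d + 2)` (d = depth, c = plurality count), floored
#' by the depth-weighted mean per-read error probability derived from the
#' short-read Phred scores, and `Q = round(-10 log10 p_err)` capped.
#'
#' @param depth Integer vector of per-column depths (all positive).
#' @param agree Integer vector of plurality counts.
#' @param mean_read_err Per-column mean short-read error probability
#'   (default 0, i.e. no floor).
#' @param cap Phred cap.
#' @return Integer vector of Phred scores.
#' @export
score_quality <- function(depth, agree, mean_read_err = 0, cap = 60L) {
  if (any(depth <= 0)) stop("zero depth at a retained position")
  p_err <- pmax((depth - agree + 1) / (depth + 2), mean_read_err)
  as.integer(pmin(round(-10 * log10(p_err)), cap))
}

#' Locate terminal adapters and classify completeness
#'
#' Adapters are searched by best semi-global match (edit distance up to
#' `max_edit`) within the terminal window of 1.5 adapter lengths, in both
#' contig orientations; the contig is reported in the orientation matching
#' the 5' adapter when found. Classes: `full_length` (both adapters at the
#' termini), `missing_5p`, `missing_3p`, `fragment`.
#'
#' @param contig An `slr_contig` (or plain character sequence).
#' @param adapter_5p,adapter_3p Adapter sequences.
#' @param max_edit Maximum edit distance.
#' @return The contig with `completeness`, `insert`, `insert_quality` and
#'   adapter fields filled (for character input, a list with the same
#'   fields).
#' @export
classify_completeness <- function(contig, adapter_5p = ADAPTER_5P,
                                  adapter_3p = ADAPTER_3P, max_edit = 2L) {
  plain <- is.character(contig)
  seq <- if (plain) contig else contig$sequence
  qual <- if (plain) rep(30L, nchar(seq)) else contig$quality

  cand <- orient_and_find(seq, qual, adapter_5p, adapter_3p, max_edit)
  cls <- if (cand$f5 && cand$f3) "full_length"
  else if (cand$f3) "missing_5p"
  else if (cand$f5) "missing_3p"
  else "fragment"

  ins_from <- if (cand$f5) cand$e5 + 1L else 1L
  ins_to <- if (cand$f3) cand$s3 - 1L else nchar(cand$seq)
  insert <- if (ins_from <= ins_to) substring(cand$seq, ins_from, ins_to) else ""
  iq <- if (ins_from <= ins_to) cand$qual[ins_from:ins_to] else integer(0)

  if (plain) {
    return(list(completeness = cls, insert = insert,
                sequence = cand$seq,
                adapter_5p = list(found = cand$f5, pos = cand$p5),
                adapter_3p = list(found = cand$f3, pos = cand$s3)))
  }
  contig$sequence <- cand$seq
  contig$quality <- cand$qual
  contig$depth <- cand$flip_vec(contig$depth)
  contig$agreement <- cand$flip_vec(contig$agreement)
  contig$completeness <- cls
  contig$insert <- insert
  contig$insert_quality <- iq
  contig$adapter_5p <- list(found = cand$f5, pos = cand$p5)
  contig$adapter_3p <- list(found = cand$f3, pos = cand$s3)
  contig
}

# try both orientations; prefer the one with more adapters found, then the
# one whose 5' adapter is found, then the lexicographically smaller sequence
orient_and_find <- function(seq, qual, a5, a3, max_edit) {
  eval_ori <- function(s, q, flip) {
    win <- ceiling(1.5 * nchar(a5))
    n <- nchar(s)
    head_win <- substring(s, 1L, min(win, n))
    m5 <- adapter_match(a5, head_win, max_edit)
    win3 <- ceiling(1.5 * nchar(a3))
    tail_start <- max(1L, n - win3 + 1L)
    tail_win <- substring(s, tail_start, n)
    m3 <- adapter_match(a3, tail_win, max_edit)
    list(seq = s, qual = q, flip = flip,
         f5 = !is.null(m5), p5 = if (!is.null(m5)) m5$start else NA_integer_,
         e5 = if (!is.null(m5)) m5$end else NA_integer_,
         f3 = !is.null(m3),
         s3 = if (!is.null(m3)) tail_start + m3$start - 1L else NA_integer_,
         flip_vec = if (flip) rev else identity)
  }
  fwd <- eval_ori(seq, qual, FALSE)
  rseq <- revcomp(seq)
  rc <- eval_ori(rseq, rev(qual), TRUE)
  sf <- fwd$f5 + fwd$f3; sr <- rc$f5 + rc$f3
  if (sf > sr) return(fwd)
  if (sr > sf) return(rc)
  if (fwd$f5 && !rc$f5) return(fwd)
  if (rc$f5 && !fwd$f5) return(rc)
  if (seq <= rseq) fwd else rc
}

# best match of an adapter inside a window at edit distance <= max_edit;
# NULL when absent
adapter_match <- function(adapter, window, max_edit) {
  if (nchar(window) < nchar(adapter) - max_edit) return(NULL)
  hits <- Biostrings::matchPattern(adapter, Biostrings::DNAString(window),
                                   max.mismatch = max_edit,
                                   with.indels = TRUE)
  if (length(hits) == 0) return(NULL)
  # choose the hit with the smallest edit distance, then leftmost
  ed <- vapply(seq_along(hits), function(i) {
    s <- as.character(hits[[i]])
    as.integer(utils::adist(adapter, s))
  }, integer(1))
  best <- which(ed == min(ed))[1]
  list(start = BiocGenerics::start(hits)[best],
       end = BiocGenerics::end(hits)[best], edits = min(ed))
}

#' Assemble all bins of a read set
#'
#' @param bins Output of [bin_reads()].
#' @param params [assembly_params()].
#' @param adapter_5p,adapter_3p Adapter sequences for completeness
#'   classification.
#' @return List with `contigs` (list of classified `slr_contig`s) and
#'   `rejected` (data.frame of bin id, reason, read count).
#' @export
assemble_bins <- function(bins, params = assembly_params(),
                          adapter_5p = ADAPTER_5P, adapter_3p = ADAPTER_3P) {
  contigs <- list(); rej <- list()
  for (b in bins) {
    r <- assemble_bin(b, params)
    if (inherits(r, "slr_rejection")) {
      rej[[length(rej) + 1L]] <- data.frame(id = r$id, reason = r$reason,
                                           n_reads = r$n_reads,
                                           stringsAsFactors = FALSE)
    } else {
      r <- classify_completeness(r, adapter_5p, adapter_3p,
                                 params$adapter_max_edit)
      contigs[[length(contigs) + 1L]] <- r
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(id = character(), reason = character(), n_reads = integer(),
               stringsAsFactors = FALSE)
  list(contigs = contigs, rejected = rejected)
}

#' @export
print.slr_contig <- function(x, ...) {
  cat(sprintf("slr_contig %s: %d nt, %s, %d reads, mean depth %.1f, mean Q %.1f\n",
              x$id, nchar(x$sequence), x$completeness, x$n_reads,
              mean(x$depth), mean(x$quality)))
  invisible(x)
}

#' Write SLR contigs as FASTQ (Phred+33)
#'
#' Header tags carry the completeness class and supporting read count:
#' `@<id> CL:<class> RN:<n>`.
#' @param contigs List of classified `slr_contig`s.
#' @param path Output path.
#' @export
write_slr_fastq <- function(contigs, path) {
  ids <- vapply(contigs, function(x)
    sprintf("%s CL:%s RN:%d", x$id, x$completeness, x$n_reads), character(1))
  seqs <- vapply(contigs, `[[`, "", "sequence")
  quals <- vapply(contigs, function(x) phred_to_char(x$quality), character(1))
  write_fastq(ids, seqs, quals, path)
}

#' Read an SLR FASTQ written by [write_slr_fastq()]
#' @param path FASTQ path.
#' @return List of `slr_contig`-shaped records (sequence and qualities exact).
#' @export
read_slr_fastq <- function(path) {
  fq <- read_fastq(path)
  lapply(seq_len(nrow(fq)), function(i) {
    parts <- strsplit(fq$id[i], " ", fixed = TRUE)[[1]]
    cls <- sub("^CL:", "", parts[grepl("^CL:", parts)])
    rn <- as.integer(sub("^RN:", "", parts[grepl("^RN:", parts)]))
    structure(list(id = parts[1], sequence = fq$seq[i],
                   quality = char_to_phred(fq$qual[i]),
                   completeness = if (length(cls)) cls else NA_character_,
                   n_reads = if (length(rn)) rn else NA_integer_),
              class = "slr_contig")
  })
}
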