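# Alignment carriers for the QC and downstream modules: transcript-space
# pairwise alignment (best reference per contig, operation-resolved) and
# genome-space spliced alignment by exact k-mer anchoring.

# anchored query bases of `query` against `ref` (exact k-mer chains);
# cheap best-reference / strand scoring. min_intron = 1 keeps blocks from
# merging across gaps, so only genuinely matching spans are counted.
anchor_score <- function(query, ref, k = 15L) {
  m <- .anchor_chain(query, ref, k, 1L)
  if (nrow(m) == 0) return(0L)
  sum(m[, 2] - m[, 1] + 1L)
}

contig_seqs <- function(contigs, use_insert = TRUE) {
  if (is.character(contigs)) {
    if (is.null(names(contigs))) names(contigs) <- sprintf("contig%04d",
                                                           seq_along(contigs))
    return(contigs)
  }
  seqs <- vapply(contigs, function(x) {
    if (use_insert && !is.null(x$insert) && !is.na(x$insert) &&
        nzchar(x$insert)) x$insert else x$sequence
  }, character(1))
  names(seqs) <- vapply(contigs, `[[`, "", "id")
  seqs
}

#' Align contigs to a reference transcript set
#'
#' Each contig is assigned to its best-scoring reference and strand: exact
#' k-mer anchoring picks the candidate reference, then an overlap (free end
#' gap) alignment with affine gap penalties (match +1, mismatch -2, gap open
#' -4, gap extend -1) resolves the operation string. Contigs without any
#' anchored reference are reported separately.
#'
#' @param contigs List of classified `slr_contig`s (their adapter-trimmed
#'   inserts are aligned) or a named character vector of sequences.
#' @param references Named character vector of reference sequences.
#' @param min_anchor Minimum anchored bases to accept a reference.
#' @return Object of class `slr_alignments`: list with `records` (one
#'   alignment record per aligned contig) and `unaligned` (contig ids).
#' @export
align_to_reference <- function(contigs, references, min_anchor = 30L) {
  if (length(references) == 0) stop("non-empty reference set required")
  seqs <- contig_seqs(contigs)
  refs <- toupper(references)
  records <- list(); unaligned <- character(0)
  for (i in seq_along(seqs)) {
    q <- seqs[[i]]
    if (!nzchar(q)) { warning("empty contig skipped: ", names(seqs)[i])
      unaligned <- c(unaligned, names(seqs)[i]); next }
    qr <- revcomp(q)
    sc_f <- vapply(refs, function(r) anchor_score(q, r), numeric(1))
    sc_r <- vapply(refs, function(r) anchor_score(qr, r), numeric(1))
    sc <- pmax(sc_f, sc_r)
    if (max(sc) < min_anchor) { unaligned <- c(unaligned, names(seqs)[i]); next }
    # near-tied references (e.g. exon-skipping siblings, where a reference-
    # side gap does not reduce the anchored query span) are resolved by the
    # full alignment score, which penalizes the gap; only the anchor-
    # supported strand is aligned unless the strands are themselves close
    cand <- names(refs)[sc >= max(sc) - 30]
    best <- NULL
    for (ref_id in sort(cand)) {
      alns <- list()
      if (sc_f[ref_id] >= sc_r[ref_id] - 30)
        alns[["+"]] <- pairwise_ops(q, refs[[ref_id]])
      if (sc_r[ref_id] >= sc_f[ref_id] - 30)
        alns[["-"]] <- pairwise_ops(qr, refs[[ref_id]])
      for (strand in names(alns)) {
        b <- alns[[strand]]
        b$ref_id <- ref_id; b$strand <- strand
        b$ref_len <- nchar(refs[[ref_id]])
        if (is.null(best) || b$score > best$score) best <- b
      }
    }
    best$contig_id <- names(seqs)[i]
    records[[length(records) + 1L]] <- best
  }
  structure(list(records = records, unaligned = unaligned),
            class = "slr_alignments")
}

# overlap alignment + operation walk; coordinates are 1-based on the subject
pairwise_ops <- function(query, ref) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = ref, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  r_start <- BiocGenerics::start(Biostrings::subject(aln))
  r_end <- BiocGenerics::end(Biostrings::subject(aln))
  q_start <- BiocGenerics::start(Biostrings::pattern(aln))
  q_end <- BiocGenerics::end(Biostrings::pattern(aln))

  sub_cols <- which(p != "-" & s != "-" & p != s)
  ins_cols <- which(s == "-")
  del_cols <- which(p == "-")
  rpos <- cumsum(s != "-") + r_start - 1L
  list(score = Biostrings::score(aln),
       ref_start = r_start, ref_end = r_end,
       q_start = q_start, q_end = q_end, q_len = nchar(query),
       n_match = sum(p == s & p != "-"),
       n_mismatch = length(sub_cols),
       n_ins = length(ins_cols), n_del = length(del_cols),
       sub_pos = rpos[sub_cols], ins_pos = rpos[ins_cols],
       del_pos = rpos[del_cols],
       covered = c(r_start, r_end))
}

#' @export
print.slr_alignments <- function(x, ...) {
  cat("slr_alignments:", length(x$records), "aligned,",
      length(x$unaligned), "unaligned\n")
  invisible(x)
}

#' Spliced alignment of contigs to a genome
#'
#' Anchors exact k-mers on every chromosome and strand, chains colinear
#' anchors, and reports aligned blocks; genomic gaps of at least
#' `min_intron` nt between consecutive blocks are interpreted as introns
#' (shorter gaps are indels and merge into one block).
#'
#' @param contigs Contigs as in [align_to_reference()].
#' @param genome Named character vector of chromosome sequences.
#' @param k Anchor k-mer size.
#' @param min_intron Minimum intron length (nt); alignment deletion runs of
#'   at least this length are introns.
#' @param min_anchor Minimum anchored bases to report an alignment.
#' @return Object of class `genome_alignments`: per contig a record with
#'   `chrom`, `strand`, `blocks` (matrix qstart/qend/rstart/rend, 1-based
#'   inclusive, query coordinates on the aligned orientation) and
#'   `oriented_query`.
#' @export
genome_align <- function(contigs, genome, k = 21L, min_intron = 20L,
                         min_anchor = 50L) {
  seqs <- contig_seqs(contigs)
  records <- list(); unaligned <- character(0)
  for (i in seq_along(seqs)) {
    q <- toupper(seqs[[i]]); qr <- revcomp(q)
    best <- NULL; best_sc <- 0
    for (ch in names(genome)) {
      for (strand in c("+", "-")) {
        qq <- if (strand == "+") q else qr
        m <- .anchor_chain(qq, genome[[ch]], k, min_intron)
        if (nrow(m) == 0) next
        sc <- sum(m[, 2] - m[, 1] + 1L)
        if (sc > best_sc) {
          best_sc <- sc
          best <- list(contig_id = names(seqs)[i], chrom = ch,
                       strand = strand, blocks = m, oriented_query = qq)
        }
      }
    }
    if (is.null(best) || best_sc < min_anchor) {
      unaligned <- c(unaligned, names(seqs)[i])
    } else {
      colnames(best$blocks) <- c("qstart", "qend", "rstart", "rend")
      records[[length(records) + 1L]] <- best
    }
  }
  structure(list(records = records, unaligned = unaligned),
            class = "genome_alignments")
}

# intron intervals implied by a block matrix (0 rows when mono-block)
blocks_to_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = blocks[-n, "rend"] + 1L,
             end = blocks[-1, "rstart"] - 1L)
}
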