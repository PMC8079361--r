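# Reference-based validation of SLR contigs: per-position error profiling
# with summary rates, positional bias, terminus (TSS/TTS) offsets, chimera
# detection by split end-mapping, abundance recovery and on-target rates.

#' Accumulate a per-reference-position error profile
#'
#' Counts substitution, insertion and deletion bases per reference position
#' across a set of alignments and summarises the rates with a single
#' denominator, the total aligned assembled bases (matches + mismatches +
#' insertions + deletions), so that `match = 1 - sum_error`.
#'
#' @param alignments An `slr_alignments` object.
#' @return Object of class `error_profile`: `positional` (data.frame ref_id,
#'   pos, coverage, sub, ins, del), `totals`, and `rates` (match,
#'   substitution, insertion, deletion, sum_error).
#' @export
profile_errors <- function(alignments) {
  recs <- alignments$records
  by_ref <- split(recs, vapply(recs, `[[`, "", "ref_id"))
  pos_rows <- list()
  tot <- c(match = 0, sub = 0, ins = 0, del = 0)
  for (ref_id in names(by_ref)) {
    rl <- by_ref[[ref_id]][[1]]$ref_len
    cov <- integer(rl); sub <- integer(rl); ins <- integer(rl); del <- integer(rl)
    for (r in by_ref[[ref_id]]) {
      cov[r$ref_start:r$ref_end] <- cov[r$ref_start:r$ref_end] + 1L
      if (length(r$sub_pos)) {
        t <- tabulate(r$sub_pos, rl); sub <- sub + t
      }
      if (length(r$ins_pos)) {
        t <- tabulate(r$ins_pos, rl); ins <- ins + t
      }
      if (length(r$del_pos)) {
        t <- tabulate(r$del_pos, rl); del <- del + t
      }
      tot["match"] <- tot["match"] + r$n_match
      tot["sub"] <- tot["sub"] + r$n_mismatch
      tot["ins"] <- tot["ins"] + r$n_ins
      tot["del"] <- tot["del"] + r$n_del
    }
    pos_rows[[ref_id]] <- data.frame(ref_id = ref_id, pos = seq_len(rl),
                                     coverage = cov, sub = sub, ins = ins,
                                     del = del, stringsAsFactors = FALSE)
  }
  positional <- if (length(pos_rows)) do.call(rbind, pos_rows) else
    data.frame(ref_id = character(), pos = integer(), coverage = integer(),
               sub = integer(), ins = integer(), del = integer())
  rownames(positional) <- NULL
  denom <- sum(tot)
  rates <- if (denom > 0) {
    s <- tot[["sub"]] / denom; i <- tot[["ins"]] / denom; d <- tot[["del"]] / denom
    list(substitution = s, insertion = i, deletion = d,
         sum_error = s + i + d, match = 1 - (s + i + d))
  } else list(substitution = NA_real_, insertion = NA_real_,
              deletion = NA_real_, sum_error = NA_real_, match = NA_real_)
  structure(list(positional = positional, totals = tot,
                 aligned_bases = denom, rates = rates),
            class = "error_profile")
}

#' Summary error rates from component rates
#'
#' The summary convention used throughout: all rates share one denominator,
#' so the sum error is the plain sum of the substitution, insertion and
#' deletion rates and the match rate is its complement.
#'
#' @param substitution,insertion,deletion Component error rates.
#' @return Named list with `sum_error` and `match`.
#' @export
error_rate_summary <- function(substitution, insertion, deletion) {
  s <- substitution + insertion + deletion
  list(sum_error = s, match = 1 - s)
}

#' @export
print.error_profile <- function(x, ...) {
  r <- x$rates
  cat(sprintf(paste0("error_profile over %.0f aligned bases: match %.4g, ",
                     "sub %.4g, ins %.4g, del %.4g (sum %.4g)\n"),
              x$aligned_bases, r$match, r$substitution, r$insertion,
              r$deletion, r$sum_error))
  invisible(x)
}

#' Positional error-bias ratios with homopolymer annotation
#'
#' For one reference, the ratio of each error type at each position,
#' normalized by the overall rate of that error type (positional rate =
#' count / coverage at the position; overall rate from the profile summary).
#' Positions inside homopolymer runs of at least `min_run` nt are flagged.
#'
#' @param profile An `error_profile`.
#' @param ref_id Reference to report.
#' @param ref_seq Reference sequence (for the homopolymer annotation).
#' @param min_run Homopolymer run length threshold (default 4).
#' @return data.frame pos, ratio_sub, ratio_ins, ratio_del, homopolymer.
#' @export
positional_bias <- function(profile, ref_id, ref_seq, min_run = 4L) {
  d <- profile$positional[profile$positional$ref_id == ref_id, ]
  if (nrow(d) == 0) stop("reference not present in profile: ", ref_id)
  overall <- profile$rates
  ratio <- function(cnt, rate) {
    if (is.na(rate) || rate == 0) return(rep(0, nrow(d)))
    pr <- ifelse(d$coverage > 0, cnt / d$coverage, 0)
    pr / rate
  }
  zero_flag <- c(sub = is.na(overall$substitution) || overall$substitution == 0,
                 ins = is.na(overall$insertion) || overall$insertion == 0,
                 del = is.na(overall$deletion) || overall$deletion == 0)
  bases <- strsplit(toupper(ref_seq), "", fixed = TRUE)[[1]]
  r <- rle(bases)
  run_len <- rep(r$lengths, r$lengths)
  out <- data.frame(pos = d$pos,
                    ratio_sub = ratio(d$sub, overall$substitution),
                    ratio_ins = ratio(d$ins, overall$insertion),
                    ratio_del = ratio(d$del, overall$deletion),
                    homopolymer = run_len[d$pos] >= min_run)
  attr(out, "zero_rate_types") <- names(zero_flag)[zero_flag]
  out
}

#' Transcript start/termination site offsets of full-length contigs
#'
#' Offsets are signed (positive = downstream of the annotated site) and
#' derived from overlap-alignment end-gap bookkeeping: the TSS offset is the
#' uncovered reference head minus the unaligned query head, the TTS offset
#' is the unaligned query tail minus the uncovered reference tail. Bucket
#' fractions (exact; within 5 nt; more than 100 nt downstream) are computed
#' over the full-length contigs supplied.
#'
#' @param alignments An `slr_alignments` over full-length contigs.
#' @return Object of class `terminus_offsets`: per-contig data.frame and
#'   `tss_buckets` / `tts_buckets` fraction vectors.
#' @export
terminus_offsets <- function(alignments) {
  recs <- alignments$records
  rows <- lapply(recs, function(r) {
    data.frame(contig_id = r$contig_id, ref_id = r$ref_id,
               tss_offset = (r$ref_start - 1L) - (r$q_start - 1L),
               tts_offset = (r$q_len - r$q_end) - (r$ref_len - r$ref_end),
               stringsAsFactors = FALSE)
  })
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), ref_id = character(),
               tss_offset = integer(), tts_offset = integer())
  n <- nrow(d)
  frac <- function(x) if (n > 0) x / n else NA_real_
  tss <- c(exact = frac(sum(d$tss_offset == 0)),
           within5 = frac(sum(d$tss_offset != 0 & abs(d$tss_offset) <= 5)),
           over100_downstream = frac(sum(d$tss_offset > 100)))
  tts <- c(exact = frac(sum(d$tts_offset == 0)),
           within5 = frac(sum(d$tts_offset != 0 & abs(d$tts_offset) <= 5)),
           over100_downstream = frac(sum(d$tts_offset > 100)))
  structure(list(offsets = d, tss_buckets = tss, tts_buckets = tts, n = n),
            class = "terminus_offsets")
}

#' @export
print.terminus_offsets <- function(x, ...) {
  cat(sprintf("terminus_offsets over %d full-length contigs\n", x$n))
  cat(sprintf("  TSS: exact %.1f%%, within 5 nt %.1f%%, >100 nt downstream %.1f%%\n",
              100 * x$tss_buckets["exact"], 100 * x$tss_buckets["within5"],
              100 * x$tss_buckets["over100_downstream"]))
  cat(sprintf("  TTS: exact %.1f%%, within 5 nt %.1f%%\n",
              100 * x$tts_buckets["exact"], 100 * x$tts_buckets["within5"]))
  invisible(x)
}

#' Detect chimeric contigs by split end-mapping
#'
#' The two terminal windows of each contig are mapped independently to the
#' reference database. Different best references make the contig an
#' inter-molecular chimera; the same reference with inconsistent
#' order/strand or a separation beyond 1.5 contig lengths makes it
#' intra-molecular; an unmappable window is counted as flagged
#' (`unmapped_end`). The chimera rate is flagged / classified contigs.
#'
#' @param contigs Full-length contigs (list of `slr_contig` or named
#'   character vector of inserts).
#' @param references Named character vector of reference transcripts.
#' @param end_window Terminal window length (nt, default 100); shrunk with a
#'   warning when longer than half the contig.
#' @param min_anchor Minimum anchored bases for a window to count as mapped.
#' @return Object of class `chimera_report`: per-contig verdict table and
#'   the overall `rate`.
#' @export
detect_chimeras <- function(contigs, references, end_window = 100L,
                            min_anchor = 30L) {
  seqs <- contig_seqs(contigs)
  refs <- toupper(references)
  rows <- list()
  for (i in seq_along(seqs)) {
    q <- seqs[[i]]; n <- nchar(q)
    w <- end_window
    if (w > n / 2) {
      w <- floor(n / 2)
      warning("end window shrunk to ", w, " for contig ", names(seqs)[i])
    }
    w5 <- substring(q, 1L, w)
    w3 <- substring(q, n - w + 1L, n)
    # all references within a small margin of the window's best anchor
    # score are candidates: terminal exons shared between isoforms of one
    # gene make the best reference a tie, not a unique call
    map_window <- function(win) {
      hits <- list()
      for (rid in names(refs)) {
        for (strand in c("+", "-")) {
          ww <- if (strand == "+") win else revcomp(win)
          m <- .anchor_chain(ww, refs[[rid]], 15L, 1L)
          if (nrow(m) == 0) next
          sc <- sum(m[, 2] - m[, 1] + 1L)
          key <- rid
          if (is.null(hits[[key]]) || sc > hits[[key]]$score)
            hits[[key]] <- list(id = rid, pos = m[1, 3], strand = strand,
                                score = sc)
        }
      }
      if (length(hits) == 0) return(list())
      best_sc <- max(vapply(hits, `[[`, 0, "score"))
      if (best_sc < min_anchor) return(list())
      Filter(function(h) h$score >= best_sc - 10, hits)
    }
    c5 <- map_window(w5); c3 <- map_window(w3)
    best_of <- function(cands) {
      if (length(cands) == 0) return(NA_character_)
      sc <- vapply(cands, `[[`, 0, "score")
      names(cands)[order(-sc, names(cands))[1]]
    }
    consistent <- function(h5, h3) {
      h5$strand == h3$strand &&
        !(h5$strand == "+" && h3$pos < h5$pos) &&
        !(h5$strand == "-" && h3$pos > h5$pos) &&
        abs(h3$pos - h5$pos) <= 1.5 * n
    }
    common <- intersect(names(c5), names(c3))
    clean_ref <- NA_character_
    for (rid in sort(common)) {
      if (consistent(c5[[rid]], c3[[rid]])) { clean_ref <- rid; break }
    }
    verdict <- if (length(c5) == 0 || length(c3) == 0) "unmapped_end"
    else if (!is.na(clean_ref)) "clean"
    else if (length(common) == 0) "inter_molecular"
    else "intra_molecular"
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = names(seqs)[i], verdict = verdict,
      ref_5p = if (!is.na(clean_ref)) clean_ref else best_of(c5),
      ref_3p = if (!is.na(clean_ref)) clean_ref else best_of(c3),
      stringsAsFactors = FALSE)
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), verdict = character(),
               ref_5p = character(), ref_3p = character())
  flagged <- sum(d$verdict != "clean")
  structure(list(verdicts = d, flagged = flagged, total = nrow(d),
                 rate = if (nrow(d) > 0) flagged / nrow(d) else NA_real_),
            class = "chimera_report")
}

#' Chimera rate from flagged and total counts
#'
#' @param flagged Number of flagged contigs.
#' @param total Number of classified full-length contigs.
#' @param digits Decimal places of the percentage (default 1).
#' @return Percentage, rounded.
#' @export
chimera_rate_pct <- function(flagged, total, digits = 1) {
  round(100 * flagged / total, digits)
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf("chimera_report: %d/%d flagged (%.1f%%)\n", x$flagged,
              x$total, 100 * x$rate))
  print(table(x$verdicts$verdict))
  invisible(x)
}

#' Compare observed contig counts with expected abundances
#'
#' Pearson correlation of log2(expected) against log2(observed + 0.5),
#' reported for all references and for those with length at least
#' `min_length` (the length-bias filter).
#'
#' @param observed Named vector of observed full-length contig counts per
#'   reference (missing references count 0).
#' @param expected data.frame with columns `id`, `expected` (positive),
#'   `length`.
#' @param min_length Minimum reference length for the filtered correlation.
#' @return Object of class `abundance_comparison` with `table`, `r_all`,
#'   `r_filtered` and `dropouts`.
#' @export
compare_abundance <- function(observed, expected, min_length = 700L) {
  if (any(expected$expected <= 0) || any(expected$length <= 0))
    stop("expected table must have positive abundances and lengths")
  obs <- observed[match(expected$id, names(observed))]
  obs[is.na(obs)] <- 0
  d <- data.frame(id = expected$id, expected = expected$expected,
                  length = expected$length, observed = as.numeric(obs),
                  stringsAsFactors = FALSE)
  pear <- function(x) {
    if (nrow(x) < 3) return(NA_real_)
    cor(log2(x$expected), log2(x$observed + 0.5))
  }
  keep <- d$length >= min_length
  structure(list(table = d, r_all = pear(d), r_filtered = pear(d[keep, ]),
                 n_filtered = sum(keep),
                 dropouts = d$id[d$observed == 0]),
            class = "abundance_comparison")
}

#' @export
print.abundance_comparison <- function(x, ...) {
  cat(sprintf("abundance_comparison: r = %.3f (all %d refs), r = %.3f (%d refs after length filter), %d dropouts\n",
              x$r_all, nrow(x$table), x$r_filtered, x$n_filtered,
              length(x$dropouts)))
  invisible(x)
}

#' Read a BED file (0-based, half-open)
#' @param path BED path.
#' @return data.frame chrom, start, end, name.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(f)) {
    x <- f[[i]]
    if (length(x) < 3 || is.na(suppressWarnings(as.integer(x[2]))) ||
        is.na(suppressWarnings(as.integer(x[3]))))
      stop("malformed BED line ", i, " in ", path)
  }
  data.frame(chrom = vapply(f, `[`, "", 1),
             start = as.integer(vapply(f, `[`, "", 2)),
             end = as.integer(vapply(f, `[`, "", 3)),
             name = vapply(f, function(x) if (length(x) >= 4) x[4] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' Read- and base-level on-target fractions
#'
#' @param genome_alignments A `genome_alignments` object.
#' @param targets data.frame from [read_bed()] (0-based, half-open) or a BED
#'   path.
#' @return List with `read_level` and `base_level` fractions (in \[0, 1\]),
#'   plus the underlying counts.
#' @export
compute_on_target <- function(genome_alignments, targets) {
  if (is.character(targets)) targets <- read_bed(targets)
  recs <- genome_alignments$records
  if (length(recs) == 0 || nrow(targets) == 0) {
    return(list(read_level = 0, base_level = 0, n_aligned = length(recs),
                aligned_bases = 0))
  }
  tg <- GenomicRanges::GRanges(targets$chrom,
                               IRanges::IRanges(targets$start + 1L,
                                                targets$end))
  on_reads <- 0; on_bases <- 0; all_bases <- 0
  for (r in recs) {
    gr <- GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$blocks[, "rstart"],
                                                  r$blocks[, "rend"]))
    all_bases <- all_bases + sum(BiocGenerics::width(gr))
    ov <- GenomicRanges::intersect(gr, tg)
    w <- sum(BiocGenerics::width(ov))
    on_bases <- on_bases + w
    if (w > 0) on_reads <- on_reads + 1
  }
  list(read_level = on_reads / length(recs),
       base_level = if (all_bases > 0) on_bases / all_bases else 0,
       n_aligned = length(recs), aligned_bases = all_bases)
}
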