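# Fusion transcript detection: junction 30-mer text search over contigs,
# split-alignment verification of candidates, discovery of novel fusion
# candidates from genome alignments spanning two genes, and the two-part
# geometry/exon-boundary filter.

#' Build a junction k-mer library from a fusion table
#'
#' Each fusion contributes the 30-mer centered on its junction (15 nt before
#' and 15 nt after the breakpoint), extracted from the 100 nt flank (50 nt
#' either side). Duplicate 30-mers across fusions are flagged ambiguous;
#' rows with non-ACGT flanks are rejected with a reason.
#'
#' @param fusion_table data.frame (or TSV path) with columns `fusion_id`,
#'   `gene_5p`, `gene_3p`, `flank` (100 nt) or `flank_5p`/`flank_3p`
#'   (50 nt each), plus optional breakpoint columns `chrom_5p`, `pos_5p`,
#'   `chrom_3p`, `pos_3p`.
#' @return Object of class `junction_library`: data.frame with `kmer30`,
#'   `ambiguous` and the breakpoint metadata; rejected rows in
#'   `attr(, "rejected")`.
#' @export
build_junction_library <- function(fusion_table) {
  if (is.character(fusion_table)) fusion_table <-
      read.delim(fusion_table, stringsAsFactors = FALSE)
  d <- fusion_table
  if (!"flank" %in% names(d) && all(c("flank_5p", "flank_3p") %in% names(d)))
    d$flank <- paste0(d$flank_5p, d$flank_3p)
  if (!"flank" %in% names(d)) stop("fusion table needs flank sequences")
  d$flank <- toupper(d$flank)
  ok <- nchar(d$flank) == 100L & !grepl("[^ACGT]", d$flank)
  rejected <- d[!ok, , drop = FALSE]
  d <- d[ok, , drop = FALSE]
  d$kmer30 <- substring(d$flank, 36L, 65L)
  d$ambiguous <- d$kmer30 %in% d$kmer30[duplicated(d$kmer30)]
  out <- structure(d, class = c("junction_library", "data.frame"))
  attr(out, "rejected") <- rejected
  out
}

#' Exact 30-mer search of a junction library over contigs
#'
#' Each 30-mer and its reverse complement is searched as an exact substring
#' of every contig.
#'
#' @param contigs Contigs (list of `slr_contig` or named character vector).
#' @param library A `junction_library`.
#' @return data.frame of raw hits: contig_id, fusion_id, offset (1-based
#'   position of the 30-mer on the contig), strand.
#' @export
search_junctions <- function(contigs, library) {
  if (nrow(library) == 0) stop("junction library is empty")
  seqs <- contig_seqs(contigs)
  rows <- list()
  for (i in seq_len(nrow(library))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") library$kmer30[i] else revcomp(library$kmer30[i])
      hit <- which(vapply(seqs, function(s)
        grepl(pat, s, fixed = TRUE), logical(1)))
      for (h in hit) {
        off <- as.integer(regexpr(pat, seqs[[h]], fixed = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = names(seqs)[h], fusion_id = library$fusion_id[i],
          offset = off, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), fusion_id = character(),
               offset = integer(), strand = character())
}

#' Verify a junction hit by split alignment of the two contig arms
#'
#' The contig segment 5' of the hit must align to the 5' partner reference
#' and the 3' segment to the 3' partner, each with at least `min_identity`
#' over at least `min_arm` nt; the breakpoint is refined to the alignment
#' boundary. Arms shorter than `min_arm` are unverifiable (`short_arm`).
#'
#' @param contig Contig sequence (character) or `slr_contig`.
#' @param hit One row of [search_junctions()] output.
#' @param partner_refs Named character vector with the two partner reference
#'   sequences (names = partner gene/reference ids).
#' @param gene_5p,gene_3p Names in `partner_refs` for the two partners.
#' @param min_identity Minimum arm identity (default 0.9).
#' @param min_arm Minimum arm length in nt (default 50).
#' @return List: `status` ("verified", "unverified", "short_arm"),
#'   `breakpoint` (contig coordinate of the junction), per-arm identities.
#' @export
verify_candidate <- function(contig, hit, partner_refs, gene_5p, gene_3p,
                             min_identity = 0.9, min_arm = 50L) {
  seq <- if (is.character(contig)) contig else contig_seqs(list(contig))[[1]]
  if (hit$strand == "-") seq <- revcomp(seq)
  off <- if (hit$strand == "-") nchar(seq) - (hit$offset + 30L - 1L) + 1L else
    hit$offset
  junction <- off + 14L  # last base of the 5' half of the 30-mer
  arm5 <- substring(seq, 1L, junction)
  arm3 <- substring(seq, junction + 1L, nchar(seq))
  if (nchar(arm5) < min_arm || nchar(arm3) < min_arm)
    return(list(status = "short_arm", breakpoint = junction,
                identity_5p = NA_real_, identity_3p = NA_real_))
  arm_identity <- function(arm, ref) {
    best <- 0
    for (s in c(ref, revcomp(ref))) {
      ops <- pairwise_ops(arm, s)
      denom <- ops$n_match + ops$n_mismatch + ops$n_ins + ops$n_del
      aligned_q <- ops$q_end - ops$q_start + 1L
      id <- if (denom > 0 && aligned_q >= min_arm) ops$n_match / denom else 0
      if (id > best) best <- id
    }
    best
  }
  id5 <- arm_identity(arm5, partner_refs[[gene_5p]])
  id3 <- arm_identity(arm3, partner_refs[[gene_3p]])
  status <- if (id5 >= min_identity && id3 >= min_identity) "verified" else
    "unverified"
  list(status = status, breakpoint = junction, identity_5p = id5,
       identity_3p = id3)
}

#' Detect novel fusion candidates from genome alignments
#'
#' Contigs whose aligned blocks map to two distinct annotated genes become
#' candidates, with the breakpoint at the inter-gene block junction.
#'
#' @param genome_alignments A `genome_alignments` object.
#' @param ann Annotation.
#' @return data.frame of `fusion_candidate` rows: contig_id, gene_5p,
#'   gene_3p, breakpoints on both partners (genomic), orientation class.
#' @export
detect_novel_fusions <- function(genome_alignments, ann) {
  rows <- list()
  for (r in genome_alignments$records) {
    b <- r$blocks
    gene_hit <- vapply(seq_len(nrow(b)), function(i) {
      g <- ann$genes[ann$genes$chrom == r$chrom &
                       ann$genes$start <= b[i, "rend"] &
                       ann$genes$end >= b[i, "rstart"], "gene_id"]
      if (length(g)) g[1] else NA_character_
    }, character(1))
    genes <- unique(gene_hit[!is.na(gene_hit)])
    if (length(genes) != 2) next
    # breakpoint: block junction where the gene changes
    switch_at <- which(gene_hit[-length(gene_hit)] != gene_hit[-1] &
                         !is.na(gene_hit[-length(gene_hit)]) &
                         !is.na(gene_hit[-1]))[1]
    if (is.na(switch_at)) next
    g5 <- gene_hit[switch_at]; g3 <- gene_hit[switch_at + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = r$contig_id, gene_5p = g5, gene_3p = g3,
      chrom_5p = r$chrom, pos_5p = b[switch_at, "rend"],
      chrom_3p = r$chrom, pos_3p = b[switch_at + 1L, "rstart"],
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), gene_5p = character(),
               gene_3p = character(), chrom_5p = character(),
               pos_5p = integer(), chrom_3p = character(),
               pos_3p = integer())
}

#' Multi-chromosome novel-fusion candidates
#'
#' [genome_align()] assigns each contig to a single chromosome, so trans
#' (different-chromosome) candidates are found by splitting the contig at
#' its unaligned boundary and mapping the remainder separately. This helper
#' runs that second pass for contigs whose best alignment covers less than
#' `min_cover` of the contig.
#'
#' @param contigs Contigs as elsewhere.
#' @param genome Named chromosome sequences.
#' @param ann Annotation.
#' @param min_cover Fraction of a contig that must be covered before the
#'   split pass is skipped.
#' @return data.frame as [detect_novel_fusions()], with possibly different
#'   chromosomes for the two partners.
#' @export
detect_novel_fusions_split <- function(contigs, genome, ann,
                                       min_cover = 0.9) {
  seqs <- contig_seqs(contigs)
  ga <- genome_align(seqs, genome)
  same <- detect_novel_fusions(ga, ann)
  rows <- if (nrow(same)) list(same) else list()
  covered <- setNames(rep(0, length(seqs)), names(seqs))
  rec_of <- list()
  for (r in ga$records) {
    covered[r$contig_id] <- sum(r$blocks[, "qend"] - r$blocks[, "qstart"] + 1L) /
      nchar(seqs[[r$contig_id]])
    rec_of[[r$contig_id]] <- r
  }
  for (cid in names(seqs)[covered > 0 & covered < min_cover]) {
    r <- rec_of[[cid]]
    qcov <- c(min(r$blocks[, "qstart"]), max(r$blocks[, "qend"]))
    n <- nchar(seqs[[cid]])
    # leftover arm, on the aligned orientation
    left <- substring(r$oriented_query, 1L, qcov[1] - 1L)
    right <- substring(r$oriented_query, qcov[2] + 1L, n)
    arm <- if (nchar(left) >= nchar(right)) left else right
    arm_is_left <- nchar(left) >= nchar(right)
    if (nchar(arm) < 50L) next
    ga2 <- genome_align(setNames(arm, "arm"), genome)
    if (length(ga2$records) == 0) next
    r2 <- ga2$records[[1]]
    gene_at <- function(chrom, lo, hi) {
      g <- ann$genes[ann$genes$chrom == chrom & ann$genes$start <= hi &
                       ann$genes$end >= lo, "gene_id"]
      if (length(g)) g[1] else NA_character_
    }
    g_main <- gene_at(r$chrom, min(r$blocks[, "rstart"]),
                      max(r$blocks[, "rend"]))
    g_arm <- gene_at(r2$chrom, min(r2$blocks[, "rstart"]),
                     max(r2$blocks[, "rend"]))
    if (is.na(g_main) || is.na(g_arm) || g_main == g_arm) next
    g5 <- if (arm_is_left) g_arm else g_main
    g3 <- if (arm_is_left) g_main else g_arm
    b5 <- if (arm_is_left) c(r2$chrom, max(r2$blocks[, "rend"])) else
      c(r$chrom, max(r$blocks[, "rend"]))
    b3 <- if (arm_is_left) c(r$chrom, min(r$blocks[, "rstart"])) else
      c(r2$chrom, min(r2$blocks[, "rstart"]))
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = cid, gene_5p = g5, gene_3p = g3,
      chrom_5p = b5[1], pos_5p = as.integer(b5[2]),
      chrom_3p = b3[1], pos_3p = as.integer(b3[2]),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else same
}

#' Apply the fusion geometry and exon-boundary filters
#'
#' A candidate passes when (i) its partners are in trans (different
#' chromosomes) or in cis separated by more than `min_separation` bp with at
#' least one gene wholly in between, and (ii) both breakpoints fall within
#' `exon_tol` nt of an annotated exon edge of the respective partner, and
#' (iii) it is verified (when a verification status is supplied; `NA`
#' statuses count as verified so the filter can be used on geometry alone).
#'
#' @param candidates data.frame with gene_5p, gene_3p, chrom_5p, pos_5p,
#'   chrom_3p, pos_3p, and optionally `verified` (logical).
#' @param ann Annotation with gene intervals and exon boundaries.
#' @param min_separation Minimum cis separation in bp (default 40000).
#' @param exon_tol Exon-edge tolerance in nt (default 2).
#' @return The candidate table with columns `orientation` ("trans"/"cis"),
#'   `separation`, `intervening`, `exon_edge_5p`, `exon_edge_3p`, `pass`,
#'   `fail_reason`.
#' @export
filter_novel_fusions <- function(candidates, ann, min_separation = 40000L,
                                 exon_tol = 2L) {
  d <- candidates
  n <- nrow(d)
  d$orientation <- NA_character_
  d$separation <- NA_integer_; d$intervening <- NA_integer_
  d$exon_edge_5p <- NA; d$exon_edge_3p <- NA
  d$pass <- FALSE; d$fail_reason <- NA_character_
  if (n == 0) return(d)
  at_exon_edge <- function(gene, chrom, pos) {
    ex <- ann$exons[ann$exons$gene_id == gene, ]
    if (nrow(ex) == 0) return(NA)
    any(abs(ex$start - pos) <= exon_tol | abs(ex$end - pos) <= exon_tol)
  }
  for (i in seq_len(n)) {
    if (!all(c(d$gene_5p[i], d$gene_3p[i]) %in% ann$genes$gene_id)) {
      d$fail_reason[i] <- "unannotated gene"
      next
    }
    trans <- d$chrom_5p[i] != d$chrom_3p[i]
    d$orientation[i] <- if (trans) "trans" else "cis"
    geom_ok <- trans
    if (!trans) {
      d$separation[i] <- gene_separation(ann, d$gene_5p[i], d$gene_3p[i])
      d$intervening[i] <- intervening_genes(ann, d$gene_5p[i], d$gene_3p[i])
      geom_ok <- d$separation[i] > min_separation && d$intervening[i] >= 1L
    }
    d$exon_edge_5p[i] <- at_exon_edge(d$gene_5p[i], d$chrom_5p[i], d$pos_5p[i])
    d$exon_edge_3p[i] <- at_exon_edge(d$gene_3p[i], d$chrom_3p[i], d$pos_3p[i])
    verified <- if ("verified" %in% names(d)) isTRUE(d$verified[i]) ||
      is.na(d$verified[i]) else TRUE
    d$pass[i] <- geom_ok && isTRUE(d$exon_edge_5p[i]) &&
      isTRUE(d$exon_edge_3p[i]) && verified
    if (!d$pass[i]) {
      d$fail_reason[i] <- if (!geom_ok) "geometry" else
        if (!isTRUE(d$exon_edge_5p[i]) || !isTRUE(d$exon_edge_3p[i]))
          "not at exon boundary" else "unverified"
    }
  }
  d
}
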