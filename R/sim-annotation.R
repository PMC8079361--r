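#' Build a truth-annotated toy gene annotation
#'
#' Lays out genes with multi-exon isoforms on one or two toy chromosomes and,
#' when `config$fusions` is `TRUE`, reproduces the designed fusion-pair
#' geometry exactly: one cis pair separated by `fusion_cis_far_sep` bp with an
#' intervening gene, one cis pair at `fusion_cis_near_sep` bp with none, and
#' one trans pair on different chromosomes. Alternative isoforms are generated
#' by single internal-exon skipping, so every isoform of a gene has a distinct
#' splice-junction chain.
#'
#' @param config A [sim_config()].
#' @return An object of class `toy_annotation`: data frames `genes`,
#'   `isoforms`, `exons`, `fusions`, and the named `genome` sequence vector.
#' @export
build_toy_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  if (config$fusions && ng < 6L)
    stop("configuration error: fusion scenarios require at least 6 genes")

  # per-gene structures in gene-relative coordinates
  structs <- lapply(seq_len(ng), function(i) {
    ne <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
    # exon skipping needs an internal exon; mono/di-exonic layouts are only
    # allowed when a single isoform per gene is requested
    if (config$isoforms_per_gene > 1L) ne <- max(ne, 3L)
    el <- sample(seq(config$exon_length[1], config$exon_length[2]), ne,
                 replace = TRUE)
    il <- sample(seq(config$intron_length[1], config$intron_length[2]),
                 ne - 1L, replace = TRUE)
    starts <- cumsum(c(1L, head(el, -1) + il))
    ends <- starts + el - 1L
    list(n_exons = ne, starts = starts, ends = ends, len = max(ends))
  })

  chrom <- character(ng); offset <- integer(ng); strand <- character(ng)
  if (config$fusions) {
    # G1 (cis-far 5'), G2 (intervening), G3 (cis-far 3'), G4/G5 (cis-near),
    # G6 first gene on chr2 (trans partner)
    chrom[1:5] <- "chr1"; chrom[6] <- "chr2"
    strand[1:6] <- "+"
    offset[1] <- 1000L
    e1 <- offset[1] + structs[[1]]$len - 1L
    offset[3] <- e1 + config$fusion_cis_far_sep + 1L
    offset[2] <- e1 + 2000L
    if (offset[2] + structs[[2]]$len >= offset[3])
      stop("intervening gene does not fit; increase fusion_cis_far_sep")
    e3 <- offset[3] + structs[[3]]$len - 1L
    offset[4] <- e3 + 5000L
    e4 <- offset[4] + structs[[4]]$len - 1L
    offset[5] <- e4 + config$fusion_cis_near_sep + 1L
    offset[6] <- 1000L
    extra <- setdiff(seq_len(ng), 1:6)
  } else {
    extra <- seq_len(ng)
  }
  cur <- c(chr1 = if (config$fusions) offset[5] + structs[[5]]$len + 5000L else 1000L,
           chr2 = if (config$fusions) offset[6] + structs[[6]]$len + 5000L else 1000L)
  for (i in extra) {
    ch <- if (i %% 2 == 0) "chr2" else "chr1"
    chrom[i] <- ch
    offset[i] <- cur[[ch]]
    cur[[ch]] <- cur[[ch]] + structs[[i]]$len + 5000L
    strand[i] <- sample(c("+", "-"), 1, prob = c(0.7, 0.3))
  }

  gene_id <- sprintf("G%02d", seq_len(ng))
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = offset,
                      end = offset + vapply(structs, `[[`, 1L, "len") - 1L,
                      stringsAsFactors = FALSE)

  iso_rows <- list(); exon_rows <- list()
  for (i in seq_len(ng)) {
    st <- structs[[i]]
    abs_s <- st$starts + offset[i] - 1L
    abs_e <- st$ends + offset[i] - 1L
    internal <- seq(2L, st$n_exons - 1L)
    for (j in seq_len(config$isoforms_per_gene)) {
      iso <- sprintf("%s.%d", gene_id[i], j)
      keep <- seq_len(st$n_exons)
      if (j > 1L) {
        skip <- internal[(j - 2L) %% length(internal) + 1L]
        keep <- setdiff(keep, skip)
      }
      iso_rows[[length(iso_rows) + 1L]] <-
        data.frame(isoform_id = iso, gene_id = gene_id[i],
                   stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(isoform_id = iso, gene_id = gene_id[i],
                   rank = seq_along(keep), start = abs_s[keep],
                   end = abs_e[keep], stringsAsFactors = FALSE)
    }
  }
  isoforms <- do.call(rbind, iso_rows)
  exons <- do.call(rbind, exon_rows)

  # genome sequences
  genome <- vapply(unique(genes$chrom), function(ch) {
    random_dna(max(genes$end[genes$chrom == ch]) + 1000L)
  }, character(1))

  ann <- structure(list(genes = genes, isoforms = isoforms, exons = exons,
                        fusions = NULL, genome = genome, config = config),
                   class = "toy_annotation")

  if (config$fusions) {
    mk <- function(id, g5, g3, type, sep, interv, pass) {
      b5 <- fusion_breakpoint(ann, g5, side = "5p")
      b3 <- fusion_breakpoint(ann, g3, side = "3p")
      data.frame(fusion_id = id, gene_5p = g5, gene_3p = g3, type = type,
                 separation = sep, intervening = interv,
                 chrom_5p = b5$chrom, pos_5p = b5$pos,
                 chrom_3p = b3$chrom, pos_3p = b3$pos,
                 expected_pass = pass, stringsAsFactors = FALSE)
    }
    fus <- rbind(
      mk("FUS_CIS_FAR", "G01", "G03", "cis", config$fusion_cis_far_sep, 1L, TRUE),
      mk("FUS_CIS_NEAR", "G04", "G05", "cis", config$fusion_cis_near_sep, 0L, FALSE),
      mk("FUS_TRANS", "G06", "G02", "trans", NA_integer_, NA_integer_, TRUE))
    fus$flank <- vapply(seq_len(nrow(fus)), function(i) {
      fusion_flank(ann, fus$gene_5p[i], fus$gene_3p[i], 50L)
    }, character(1))
    ann$fusions <- fus
  }
  ann
}

# breakpoint at an annotated exon boundary: 5' partner donates exons 1-2
# (break at the genomic end of exon 2), 3' partner accepts from exon 2 on
# (break at the genomic start of its exon 2); fusion genes are laid out "+"
fusion_breakpoint <- function(ann, gene, side) {
  iso <- ann$isoforms$isoform_id[ann$isoforms$gene_id == gene][1]
  ex <- ann$exons[ann$exons$isoform_id == iso, ]
  ex <- ex[order(ex$rank), ]
  ch <- ann$genes$chrom[ann$genes$gene_id == gene]
  if (side == "5p") list(chrom = ch, pos = ex$end[2]) else
    list(chrom = ch, pos = ex$start[2])
}

fusion_arm_seq <- function(ann, gene, side) {
  iso <- ann$isoforms$isoform_id[ann$isoforms$gene_id == gene][1]
  ex <- ann$exons[ann$exons$isoform_id == iso, ]
  ex <- ex[order(ex$rank), ]
  ch <- ann$genes$chrom[ann$genes$gene_id == gene]
  g <- ann$genome[[ch]]
  if (side == "5p") {
    paste(substring(g, ex$start[1:2], ex$end[1:2]), collapse = "")
  } else {
    n <- nrow(ex)
    paste(substring(g, ex$start[2:n], ex$end[2:n]), collapse = "")
  }
}

fusion_flank <- function(ann, g5, g3, half = 50L) {
  up <- fusion_arm_seq(ann, g5, "5p")
  dn <- fusion_arm_seq(ann, g3, "3p")
  paste0(substring(up, nchar(up) - half + 1L, nchar(up)),
         substring(dn, 1L, half))
}

#' Full transcript (fusion) sequence for a designed fusion
#' @param ann A `toy_annotation` with fusions.
#' @param fusion_id Designed fusion id.
#' @return Character scalar; the fused transcript sequence.
#' @export
fusion_transcript_seq <- function(ann, fusion_id) {
  f <- ann$fusions[ann$fusions$fusion_id == fusion_id, ]
  if (nrow(f) != 1) stop("unknown fusion id: ", fusion_id)
  paste0(fusion_arm_seq(ann, f$gene_5p, "5p"),
         fusion_arm_seq(ann, f$gene_3p, "3p"))
}

#' Spliced transcript sequence of an annotated isoform
#' @param ann A `toy_annotation`.
#' @param isoform_id Isoform id.
#' @return Character scalar (reverse-complemented for minus-strand genes, so
#'   the sequence reads 5' to 3' on the transcript).
#' @export
transcript_seq <- function(ann, isoform_id) {
  ex <- ann$exons[ann$exons$isoform_id == isoform_id, ]
  if (nrow(ex) == 0) stop("unknown isoform id: ", isoform_id)
  ex <- ex[order(ex$rank), ]
  gene <- ex$gene_id[1]
  ch <- ann$genes$chrom[ann$genes$gene_id == gene]
  strand <- ann$genes$strand[ann$genes$gene_id == gene]
  s <- paste(substring(ann$genome[[ch]], ex$start, ex$end), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Reference transcript set of a toy annotation
#' @param ann A `toy_annotation`.
#' @return Named character vector of spliced transcript sequences.
#' @export
reference_seqs <- function(ann) {
  ids <- ann$isoforms$isoform_id
  setNames(vapply(ids, function(i) transcript_seq(ann, i), character(1)), ids)
}

#' Genomic splice-junction chain (intron intervals) of an isoform
#' @param ann A `toy_annotation`.
#' @param isoform_id Isoform id.
#' @return data.frame with columns `start`, `end`: 1-based inclusive intron
#'   intervals in genomic coordinates (zero rows for mono-exonic isoforms).
#' @export
junction_chain <- function(ann, isoform_id) {
  ex <- ann$exons[ann$exons$isoform_id == isoform_id, ]
  ex <- ex[order(ex$start), ]
  n <- nrow(ex)
  if (n < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-n] + 1L, end = ex$start[-1] - 1L)
}

# bases strictly between two gene spans on the same chromosome (NA if
# different chromosomes or overlapping)
gene_separation <- function(ann, g1, g2) {
  a <- ann$genes[ann$genes$gene_id == g1, ]
  b <- ann$genes[ann$genes$gene_id == g2, ]
  if (a$chrom != b$chrom) return(NA_integer_)
  gap <- max(b$start - a$end, a$start - b$end) - 1L
  max(gap, 0L)
}

intervening_genes <- function(ann, g1, g2) {
  a <- ann$genes[ann$genes$gene_id == g1, ]
  b <- ann$genes[ann$genes$gene_id == g2, ]
  if (a$chrom != b$chrom) return(NA_integer_)
  lo <- min(a$end, b$end); hi <- max(a$start, b$start)
  others <- ann$genes[ann$genes$chrom == a$chrom &
                        !(ann$genes$gene_id %in% c(g1, g2)), ]
  sum(others$start > lo & others$end < hi)
}

#' @export
print.toy_annotation <- function(x, ...) {
  cat("toy_annotation:", nrow(x$genes), "genes,", nrow(x$isoforms),
      "isoforms on", length(x$genome), "chromosome(s)")
  if (!is.null(x$fusions)) cat(";", nrow(x$fusions), "designed fusions")
  cat("\n")
  invisible(x)
}

#' Write the toy annotation as GTF (1-based, inclusive)
#' @param ann A `toy_annotation`.
#' @param path Output path.
#' @export
write_annotation_gtf <- function(ann, path) {
  ex <- merge(ann$exons, ann$genes[, c("gene_id", "chrom", "strand")],
              by = "gene_id", sort = FALSE)
  ex <- ex[order(ex$chrom, ex$isoform_id, ex$rank), ]
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                      ex$gene_id, ex$isoform_id, ex$rank)
  lines <- sprintf("%s\tslrtx\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, ex$start, ex$end, ex$strand, attr_str)
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read a GTF exon annotation into the package's annotation tables
#'
#' Minimal GTF reader for exon features carrying `gene_id` and
#' `transcript_id` attributes; returns a `toy_annotation`-shaped object
#' without genome sequences.
#' @param path GTF path.
#' @export
read_annotation_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "exon", logical(1))
  f <- f[keep]
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(sprintf('%s "[^"]+"', key), a))
    if (length(m) == 0) return(NA_character_)
    sub(sprintf('%s "([^"]+)"', key), "\\1", m)
  }
  rows <- lapply(f, function(x) {
    data.frame(isoform_id = get_attr(x[9], "transcript_id"),
               gene_id = get_attr(x[9], "gene_id"),
               chrom = x[1], strand = x[7],
               start = as.integer(x[4]), end = as.integer(x[5]),
               stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, rows)
  ex <- ex[order(ex$isoform_id, ex$start), ]
  ex$rank <- stats::ave(ex$start, ex$isoform_id, FUN = seq_along)
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  isoforms <- unique(ex[, c("isoform_id", "gene_id")])
  rownames(isoforms) <- NULL
  structure(list(genes = genes, isoforms = isoforms,
                 exons = ex[, c("isoform_id", "gene_id", "rank", "start", "end")],
                 fusions = NULL, genome = NULL, config = NULL),
            class = "toy_annotation")
}

#' Write target regions (gene spans) as BED (0-based, half-open)
#' @param ann A `toy_annotation`.
#' @param path Output path.
#' @export
write_targets_bed <- function(ann, path) {
  g <- ann$genes
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$start - 1L, g$end,
                   g$gene_id, g$strand)
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
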