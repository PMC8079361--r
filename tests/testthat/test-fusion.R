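# Junction 30-mer search, split-alignment verification, novel-fusion
# discovery and the geometry/exon-boundary filter.

fusion_fixture <- function() {
  if (is.null(.sim_cache[["fusion_ann"]])) {
    cfg <- sim_config(n_genes = 8, fusions = TRUE, seed = 19)
    .sim_cache[["fusion_ann"]] <- build_toy_annotation(cfg)
  }
  .sim_cache[["fusion_ann"]]
}

test_that("junction library extracts the central 30-mer and flags duplicates", {
  flank <- random_seq(100, seed = 61)
  tab <- data.frame(fusion_id = c("F1", "F2", "F3"),
                    gene_5p = "A", gene_3p = "B",
                    flank = c(flank, flank, random_seq(100, seed = 62)),
                    stringsAsFactors = FALSE)
  lib <- build_junction_library(tab)
  expect_equal(lib$kmer30[1], substring(flank, 36, 65))
  expect_equal(lib$ambiguous, c(TRUE, TRUE, FALSE))

  # non-ACGT flank rejected with the row preserved in the rejection set
  tab$flank[3] <- paste0(substring(tab$flank[3], 1, 99), "N")
  lib2 <- build_junction_library(tab)
  expect_equal(nrow(lib2), 2)
  expect_equal(attr(lib2, "rejected")$fusion_id, "F3")

  # two 50 nt halves are concatenated
  tab3 <- data.frame(fusion_id = "F1", gene_5p = "A", gene_3p = "B",
                     flank_5p = substring(flank, 1, 50),
                     flank_3p = substring(flank, 51, 100),
                     stringsAsFactors = FALSE)
  expect_equal(build_junction_library(tab3)$kmer30,
               substring(flank, 36, 65))

  empty <- build_junction_library(tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("30-mer text search finds verbatim and reverse-complement hits", {
  flank <- random_seq(100, seed = 63)
  lib <- build_junction_library(data.frame(fusion_id = "F1", gene_5p = "A",
                                           gene_3p = "B", flank = flank,
                                           stringsAsFactors = FALSE))
  kmer <- lib$kmer30[1]
  ctg_fwd <- paste0(random_seq(200, seed = 64), kmer,
                    random_seq(200, seed = 65))
  ctg_rc <- revcomp(ctg_fwd)
  hits <- search_junctions(c(fwd = ctg_fwd, rc = ctg_rc), lib)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$offset[hits$contig_id == "fwd"], 201L)
  expect_equal(hits$strand[hits$contig_id == "fwd"], "+")
  expect_equal(hits$strand[hits$contig_id == "rc"], "-")

  # random contigs produce no false hits (2,000 x 200 x 4^-30 expected)
  set.seed(66)
  lib100 <- build_junction_library(data.frame(
    fusion_id = sprintf("F%03d", 1:100), gene_5p = "A", gene_3p = "B",
    flank = vapply(1:100, function(i) random_seq(100, seed = 600 + i),
                   character(1)), stringsAsFactors = FALSE))
  rnd <- setNames(random_seq(2000, seed = 67), "rnd")
  expect_equal(nrow(search_junctions(rnd, lib100)), 0)
})

test_that("split alignment verifies true fusion contigs and rejects fakes", {
  ann <- fusion_fixture()
  fus <- ann$fusions[ann$fusions$fusion_id == "FUS_CIS_FAR", ]
  contig <- fusion_transcript_seq(ann, "FUS_CIS_FAR")
  lib <- build_junction_library(ann$fusions)
  hits <- search_junctions(setNames(contig, "fc"), lib)
  hit <- hits[hits$fusion_id == "FUS_CIS_FAR", ]
  expect_equal(nrow(hit), 1)

  arms <- c(slrtx:::fusion_arm_seq(ann, fus$gene_5p, "5p"),
            slrtx:::fusion_arm_seq(ann, fus$gene_3p, "3p"))
  names(arms) <- c(fus$gene_5p, fus$gene_3p)
  v <- verify_candidate(contig, hit, arms, fus$gene_5p, fus$gene_3p)
  expect_equal(v$status, "verified")
  expect_lte(abs(v$breakpoint - nchar(arms[[1]])), 2)

  # the same 30-mer inside an unrelated sequence: arms fail identity
  fake <- paste0(random_seq(300, seed = 71),
                 lib$kmer30[lib$fusion_id == "FUS_CIS_FAR"],
                 random_seq(300, seed = 72))
  hf <- search_junctions(setNames(fake, "fake"), lib)
  hf <- hf[hf$fusion_id == "FUS_CIS_FAR", ]
  vf <- verify_candidate(fake, hf, arms, fus$gene_5p, fus$gene_3p)
  expect_equal(vf$status, "unverified")

  # pure 5' partner sequence with a coincidental hit: 3' arm maps to the
  # wrong partner
  pureA <- paste0(arms[[1]],
                  substring(lib$kmer30[lib$fusion_id == "FUS_CIS_FAR"], 16, 30),
                  arms[[1]])
  hp <- data.frame(contig_id = "pureA", fusion_id = "FUS_CIS_FAR",
                   offset = nchar(arms[[1]]) - 14L, strand = "+",
                   stringsAsFactors = FALSE)
  vp <- verify_candidate(pureA, hp, arms, fus$gene_5p, fus$gene_3p)
  expect_equal(vp$status, "unverified")

  # arm shorter than 50 nt is unverifiable
  short <- substring(contig, nchar(arms[[1]]) - 20, nchar(contig))
  hs <- search_junctions(setNames(short, "s"), lib)
  hs <- hs[hs$fusion_id == "FUS_CIS_FAR", ]
  vs <- verify_candidate(short, hs, arms, fus$gene_5p, fus$gene_3p)
  expect_equal(vs$status, "short_arm")
})

test_that("novel-fusion discovery spans two genes, not one", {
  ann <- fusion_fixture()
  iso <- ann$isoforms$isoform_id[1]
  single <- genome_align(setNames(transcript_seq(ann, iso), "one"),
                         ann$genome)
  expect_equal(nrow(detect_novel_fusions(single, ann)), 0)

  cis <- fusion_transcript_seq(ann, "FUS_CIS_FAR")
  ga <- genome_align(setNames(cis, "fc"), ann$genome)
  cand <- detect_novel_fusions(ga, ann)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gene_5p, "G01")
  expect_equal(cand$gene_3p, "G03")

  # trans fusion requires the split second pass
  tr <- fusion_transcript_seq(ann, "FUS_TRANS")
  cand_tr <- detect_novel_fusions_split(setNames(tr, "ft"), ann$genome, ann)
  expect_true(any(cand_tr$gene_5p == "G06" & cand_tr$gene_3p == "G02"))
})

test_that("the geometry/exon-boundary filter truth table holds", {
  # hand-specified layout with every geometry class:
  #   A-B   cis, 47,000 bp apart, 0 intervening genes
  #   C-D   cis, 48,000 bp apart, E wholly in between
  #   F-G   cis, 8,000 bp apart
  #   A-H   trans (H on chr2)
  gene <- function(id, chrom, start) {
    ex <- data.frame(isoform_id = paste0(id, ".1"), gene_id = id,
                     rank = 1:3,
                     start = start + c(0L, 500L, 1500L),
                     end = start + c(199L, 799L, 1999L))
    list(gene = data.frame(gene_id = id, chrom = chrom, strand = "+",
                           start = start, end = start + 1999L,
                           stringsAsFactors = FALSE),
         exons = ex)
  }
  gs <- list(gene("A", "chr1", 1000L), gene("B", "chr1", 50000L),
             gene("C", "chr1", 60000L), gene("E", "chr1", 70000L),
             gene("D", "chr1", 110000L), gene("F", "chr1", 120000L),
             gene("G", "chr1", 130000L), gene("H", "chr2", 1000L))
  ann <- structure(list(
    genes = do.call(rbind, lapply(gs, `[[`, "gene")),
    isoforms = data.frame(isoform_id = paste0(c("A", "B", "C", "E", "D",
                                                "F", "G", "H"), ".1"),
                          gene_id = c("A", "B", "C", "E", "D", "F", "G", "H"),
                          stringsAsFactors = FALSE),
    exons = do.call(rbind, lapply(gs, `[[`, "exons")),
    fusions = NULL, genome = NULL, config = NULL),
    class = "toy_annotation")

  expect_equal(slrtx:::gene_separation(ann, "A", "B"), 47000L)
  expect_equal(slrtx:::intervening_genes(ann, "A", "B"), 0L)
  expect_equal(slrtx:::gene_separation(ann, "C", "D"), 48000L)
  expect_equal(slrtx:::intervening_genes(ann, "C", "D"), 1L)
  expect_equal(slrtx:::gene_separation(ann, "F", "G"), 8000L)

  edge_of <- function(g, which) {
    ex <- ann$exons[ann$exons$gene_id == g, ]
    if (which == "end2") ex$end[2] else ex$start[2]
  }
  ch <- function(g) ann$genes$chrom[ann$genes$gene_id == g]
  mk <- function(g5, g3, edge = TRUE) {
    p5 <- edge_of(g5, "end2"); p3 <- edge_of(g3, "start2")
    if (!edge) { p5 <- p5 + 10L; p3 <- p3 + 10L }
    data.frame(contig_id = "x", gene_5p = g5, gene_3p = g3,
               chrom_5p = ch(g5), pos_5p = p5,
               chrom_3p = ch(g3), pos_3p = p3, stringsAsFactors = FALSE)
  }
  cases <- rbind(mk("A", "H"), mk("A", "H", edge = FALSE),     # trans
                 mk("C", "D"), mk("C", "D", edge = FALSE),     # cis >40k, 1
                 mk("A", "B"), mk("A", "B", edge = FALSE),     # cis >40k, 0
                 mk("F", "G"), mk("F", "G", edge = FALSE))     # cis <=40k
  out <- filter_novel_fusions(cases, ann)
  expect_equal(out$pass,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$orientation, c("trans", "trans", rep("cis", 6)))

  # breakpoints within the +/-2 nt jitter tolerance still count
  jit <- mk("C", "D")
  jit$pos_5p <- jit$pos_5p + 2L
  expect_true(filter_novel_fusions(jit, ann)$pass)

  # unannotated partner fails with a reason
  bad <- mk("C", "D"); bad$gene_3p <- "ZZ"
  expect_match(filter_novel_fusions(bad, ann)$fail_reason, "unannotated")
})

test_that("end-to-end: designed pass fusions verified, fail fusions rejected", {
  ann <- fusion_fixture()
  lib <- build_junction_library(ann$fusions)
  contigs <- setNames(
    vapply(ann$fusions$fusion_id, function(f) fusion_transcript_seq(ann, f),
           character(1)),
    ann$fusions$fusion_id)
  hits <- search_junctions(contigs, lib)
  hits <- hits[hits$contig_id == hits$fusion_id, ]
  expect_equal(sort(hits$fusion_id), sort(ann$fusions$fusion_id))
  cand <- merge(hits[, c("contig_id", "fusion_id")], ann$fusions,
                by = "fusion_id")
  cand <- cand[, c("contig_id", "gene_5p", "gene_3p", "chrom_5p", "pos_5p",
                   "chrom_3p", "pos_3p")]
  out <- filter_novel_fusions(cand, ann)
  expect_equal(setNames(out$pass, out$contig_id)[ann$fusions$fusion_id],
               setNames(ann$fusions$expected_pass, ann$fusions$fusion_id))
})
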