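# Reference QC: alignment operations, error profiling, positional bias,
# terminus offsets, chimera detection, abundance and on-target rates.

test_that("alignment records recover exact, substituted and RC contigs", {
  ref <- c(R1 = random_seq(800, seed = 1), R2 = random_seq(900, seed = 2))
  aln <- align_to_reference(c(q1 = ref[["R1"]]), ref)
  r <- aln$records[[1]]
  expect_equal(r$ref_id, "R1")
  expect_equal(r$strand, "+")
  expect_equal(c(r$ref_start, r$ref_end), c(1, 800))
  expect_equal(r$n_mismatch + r$n_ins + r$n_del, 0)
  expect_equal(r$n_match, 800)

  one_sub <- ref[["R1"]]
  substring(one_sub, 400, 400) <- if (substring(one_sub, 400, 400) == "A")
    "C" else "A"
  r2 <- align_to_reference(c(q = one_sub), ref)$records[[1]]
  expect_equal(r2$n_mismatch, 1)
  expect_equal(r2$sub_pos, 400)

  r3 <- align_to_reference(c(q = revcomp(ref[["R2"]])), ref)$records[[1]]
  expect_equal(r3$ref_id, "R2")
  expect_equal(r3$strand, "-")
  expect_equal(r3$n_match, 900)
})

test_that("error profile counts and the Table-style summary convention hold", {
  ref <- c(R1 = random_seq(1000, seed = 5))
  aln <- align_to_reference(setNames(ref, "q0"), ref)
  p0 <- profile_errors(aln)
  expect_equal(p0$rates$substitution, 0)
  expect_equal(p0$rates$match, 1)

  one_sub <- ref[["R1"]]
  substring(one_sub, 123, 123) <- if (substring(one_sub, 123, 123) == "G")
    "T" else "G"
  p1 <- profile_errors(align_to_reference(c(q = one_sub), ref))
  expect_equal(p1$rates$substitution, 1e-3)
  expect_equal(p1$positional$sub[p1$positional$pos == 123], 1)

  # identity: match + sub + ins + del = 1 for every report
  s <- p1$rates
  expect_equal(s$match + s$substitution + s$insertion + s$deletion, 1)
  expect_equal(s$sum_error, s$substitution + s$insertion + s$deletion)
})

test_that("positional bias normalizes by the overall rate", {
  # all insertions at one position: ratio there = reference length
  ref_seq <- random_seq(200, seed = 9)
  prof <- structure(list(
    positional = data.frame(ref_id = "R", pos = 1:200,
                            coverage = rep(10L, 200),
                            sub = 0L, ins = c(rep(0L, 99), 50L, rep(0L, 100)),
                            del = 0L),
    totals = c(match = 10 * 200 - 50, sub = 0, ins = 50, del = 0),
    aligned_bases = 2000,
    rates = list(substitution = 0, insertion = 50 / 2000, deletion = 0,
                 sum_error = 50 / 2000, match = 1 - 50 / 2000)),
    class = "error_profile")
  pb <- positional_bias(prof, "R", ref_seq)
  expect_equal(pb$ratio_ins[pb$pos == 100], 200)
  expect_true(all(pb$ratio_ins[pb$pos != 100] == 0))
  # zero overall rate reports ratios 0 with a flag
  expect_true(all(pb$ratio_sub == 0))
  expect_true("sub" %in% attr(pb, "zero_rate_types"))
})

test_that("uniform random errors give positional ratios near 1", {
  set.seed(31)
  ref <- c(R1 = random_seq(500, seed = 7))
  contigs <- character(120)
  for (i in 1:120) {
    s <- ref[["R1"]]
    pos <- sample.int(500, 3)
    for (p in pos) {
      substring(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substring(s, p, p)), 1)
    }
    contigs[i] <- s
  }
  names(contigs) <- sprintf("c%03d", 1:120)
  prof <- profile_errors(align_to_reference(contigs, ref))
  pb <- positional_bias(prof, "R1", ref[["R1"]])
  expect_lt(abs(mean(pb$ratio_sub) - 1), 0.15)
})

test_that("homopolymer runs of at least 4 nt are flagged", {
  ref_seq <- paste0(random_seq(141, seed = 3), strrep("A", 7),
                    random_seq(100, seed = 4))
  prof <- structure(list(
    positional = data.frame(ref_id = "R", pos = seq_len(nchar(ref_seq)),
                            coverage = 1L, sub = 0L, ins = 0L, del = 0L),
    totals = c(match = nchar(ref_seq), sub = 0, ins = 0, del = 0),
    aligned_bases = nchar(ref_seq),
    rates = list(substitution = 0, insertion = 0, deletion = 0,
                 sum_error = 0, match = 1)), class = "error_profile")
  pb <- positional_bias(prof, "R", ref_seq)
  expect_true(all(pb$homopolymer[142:148]))
  expect_false(pb$homopolymer[1])
})

test_that("terminus offsets recover truncation and mispriming by sign", {
  ref <- c(R1 = random_seq(1200, seed = 11))
  perfect <- setNames(ref[["R1"]], "p")
  prem <- setNames(substring(ref[["R1"]], 151), "t")   # 150 nt 5' truncation
  mis <- setNames(substring(ref[["R1"]], 1, 1197), "m") # TTS -3
  to <- terminus_offsets(align_to_reference(c(perfect, prem, mis), ref))
  d <- to$offsets
  expect_equal(d$tss_offset[d$contig_id == "p"], 0)
  expect_equal(d$tts_offset[d$contig_id == "p"], 0)
  expect_equal(d$tss_offset[d$contig_id == "t"], 150)
  expect_equal(d$tts_offset[d$contig_id == "m"], -3)
  expect_equal(unname(to$tss_buckets["over100_downstream"]), 1 / 3)
  expect_equal(unname(to$tts_buckets["within5"]), 1 / 3)
})

test_that("split end-mapping classifies clean and chimeric contigs", {
  refs <- c(A = random_seq(900, seed = 21), B = random_seq(1000, seed = 22))
  clean <- setNames(refs[["A"]], "clean")
  chim <- setNames(paste0(substring(refs[["A"]], 1, 450),
                          substring(refs[["B"]], 501)), "chim")
  rep <- detect_chimeras(c(clean, chim), refs)
  v <- rep$verdicts
  expect_equal(v$verdict[v$contig_id == "clean"], "clean")
  expect_equal(v$verdict[v$contig_id == "chim"], "inter_molecular")
  expect_equal(v$ref_5p[v$contig_id == "chim"], "A")
  expect_equal(v$ref_3p[v$contig_id == "chim"], "B")
  expect_equal(rep$rate, 0.5)
})

test_that("chimera rate arithmetic reproduces one-decimal rounding", {
  expect_equal(chimera_rate_pct(120, 6803), 1.8)
})

test_that("abundance comparison applies the log scale and length filter", {
  expected <- data.frame(id = sprintf("R%02d", 1:10),
                         expected = 2 ^ (1:10),
                         length = c(rep(400, 4), rep(900, 6)),
                         stringsAsFactors = FALSE)
  obs <- setNames(5 * expected$expected, expected$id)
  cmp <- compare_abundance(obs, expected)
  expect_equal(cmp$r_all, 1, tolerance = 1e-4)
  expect_equal(cmp$n_filtered, 6)
  expect_equal(cmp$r_filtered, 1, tolerance = 1e-4)
  expect_length(cmp$dropouts, 0)

  # dropouts listed; too few references after filtering -> NA
  obs2 <- obs; obs2[1] <- 0
  cmp2 <- compare_abundance(obs2, expected)
  expect_equal(cmp2$dropouts, "R01")
  cmp3 <- compare_abundance(obs, expected, min_length = 2000)
  expect_true(is.na(cmp3$r_filtered))
})

test_that("abundance recovery on a simulated mixture matches the resampling oracle", {
  set.seed(99)
  n_ref <- 20
  ab <- 10 ^ seq(0, 3, length.out = n_ref)
  prob <- ab / sum(ab)
  n_mol <- 3000
  counts <- tabulate(sample.int(n_ref, n_mol, replace = TRUE, prob = prob),
                     n_ref)
  expected <- data.frame(id = sprintf("R%02d", 1:n_ref), expected = ab,
                         length = rep(800, n_ref), stringsAsFactors = FALSE)
  cmp <- compare_abundance(setNames(counts, expected$id), expected)
  # oracle: distribution of r under repeated multinomial sampling
  r_oracle <- replicate(200, {
    cnt <- tabulate(sample.int(n_ref, n_mol, replace = TRUE, prob = prob),
                    n_ref)
    cor(log2(ab), log2(cnt + 0.5))
  })
  expect_lt(abs(cmp$r_all - mean(r_oracle)), 0.02)
})

test_that("on-target fractions follow interval arithmetic", {
  genome <- c(chr1 = random_seq(4000, seed = 41))
  contig_in <- substring(genome[["chr1"]], 1001, 1600)
  contig_half <- substring(genome[["chr1"]], 2001, 2600)
  ga <- genome_align(c(inside = contig_in, half = contig_half), genome)

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1600\tT1\t0\t+", "chr1\t2000\t2300\tT2\t0\t+"),
             bed)
  ot <- compute_on_target(ga, bed)
  expect_equal(ot$read_level, 1.0)
  expect_equal(ot$base_level, (600 + 300) / 1200)

  empty_bed <- tempfile(fileext = ".bed")
  writeLines(character(0), empty_bed)
  ot0 <- compute_on_target(ga, empty_bed)
  expect_equal(ot0$read_level, 0)
  expect_equal(ot0$base_level, 0)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\tx\t200"), bad)
  expect_error(read_bed(bad), "line 2")
})
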