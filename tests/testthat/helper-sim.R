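# Shared in-code fixtures for the suite. Everything is generated at test
# time from seeds; nothing is read from disk.

# small end-to-end dataset: annotation + molecules + reads + contigs,
# memoised per parameter set within a test run
.sim_cache <- new.env(parent = emptyenv())

sim_fixture <- function(..., key = NULL) {
  args <- list(...)
  key <- if (is.null(key)) paste(deparse(args), collapse = "") else key
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- do.call(sim_config, args)
  ann <- build_toy_annotation(cfg)
  mols <- inject_chimeras(sample_molecules(ann, cfg), cfg)
  reads <- fragment_to_short_reads(mols, cfg)
  bins <- bin_reads(reads[, c("id", "seq", "qual", "sample_index", "umi")])
  asm <- assemble_bins(bins)
  fl <- Filter(function(x) x$completeness == "full_length", asm$contigs)
  out <- list(config = cfg, annotation = ann, molecules = mols,
              reads = reads, bins = bins, contigs = asm$contigs,
              rejected = asm$rejected, full_length = fl)
  .sim_cache[[key]] <- out
  out
}

# truth lookup: molecule row for a contig (bins are keyed by UMI)
truth_of <- function(contig, mols) {
  mols[mols$umi == contig$umi, ]
}

# tiling error-free reads over a known sequence (deterministic layout);
# terminal reads are duplicated so end k-mers survive the multiplicity
# filter, as they do under the simulator's overhanging fragmentation
tile_reads <- function(seq, read_len = 150L, step = 20L, qual = 30L) {
  n <- nchar(seq)
  starts <- unique(c(seq(1L, max(n - read_len + 1L, 1L), by = step),
                     n - read_len + 1L))
  starts <- c(starts, 1L, n - read_len + 1L)
  data.frame(id = sprintf("t%03d", seq_along(starts)),
             seq = substring(seq, starts, starts + read_len - 1L),
             qual = strrep(phred_to_char(qual), read_len),
             start = starts,
             stringsAsFactors = FALSE)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# inject substitutions at a given per-base rate (test-side, independent of
# the package's error injector)
mutate_seq <- function(seq, rate, seed) {
  set.seed(seed)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  for (p in hit) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}
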