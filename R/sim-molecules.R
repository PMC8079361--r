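#' Sample truth-annotated barcoded cDNA molecules
#'
#' Draws molecules from the annotated isoforms at the configured abundances,
#' assigns each a UMI drawn uniformly from the 4^L space (collisions allowed
#' and truth-recorded), and applies the library artefact model: premature
#' reverse-transcription termination (5' truncation of at least 100 nt while
#' the 5' adapter is still attached, the false-full-length phenomenon),
#' poly-T mispriming offsets at the TTS, and adapter dropout.
#'
#' @param ann A `toy_annotation`.
#' @param config A [sim_config()]. `config$abundance` must be `NULL` or have
#'   one entry per isoform.
#' @param sample_index Sample index tag carried by every molecule.
#' @param n Number of molecules (default `config$n_molecules`).
#' @return data.frame of class `barcoded_molecules`, one row per molecule:
#'   truth labels plus `insert` (adapterless sequence) and `seq` (emitted
#'   sequence including any adapters).
#' @export
sample_molecules <- function(ann, config, sample_index = "S1",
                             n = config$n_molecules) {
  validate_sim_config(config)
  set.seed(config$seed + 1000L)
  ids <- ann$isoforms$isoform_id
  ab <- config$abundance
  if (is.null(ab)) {
    ab <- 2 ^ seq(0, log2(1000), length.out = length(ids))
  }
  if (length(ab) != length(ids))
    stop("abundance vector length (", length(ab),
         ") does not match isoform count (", length(ids), ")")
  ab <- ab / sum(ab)

  empty <- data.frame(molecule_id = character(), umi = character(),
                      sample_index = character(), isoform_id = character(),
                      insert = character(), adapter_5p = logical(),
                      adapter_3p = logical(), premature_offset = integer(),
                      tts_offset = integer(), chimera = character(),
                      partner_isoform = character(),
                      partner_molecule = character(),
                      junction_pos = integer(), partner_junction = integer(),
                      seq = character(), stringsAsFactors = FALSE)
  if (n == 0) return(structure(empty, class = c("barcoded_molecules",
                                                "data.frame")))

  iso_idx <- sample_index_vec <- NULL
  iso_idx <- sample.int(length(ids), n, replace = TRUE, prob = ab)
  tx <- reference_seqs(ann)
  insert <- unname(tx[ids[iso_idx]])

  umi <- vapply(seq_len(n), function(i) random_dna(config$umi_length),
                character(1))

  premature <- integer(n)
  sel <- runif(n) < config$p_premature
  for (i in which(sel)) {
    len <- nchar(insert[i])
    hi <- floor(0.5 * len)
    if (hi >= 100L) {
      premature[i] <- sample(seq(100L, hi), 1)
      insert[i] <- substring(insert[i], premature[i] + 1L)
    }
  }

  tts <- integer(n)
  selm <- runif(n) < config$p_mispriming
  if (any(selm)) {
    off_support <- setdiff(-5:5, 0L)
    w <- stats::dnorm(off_support, 0, 2)
    draws <- sample(off_support, sum(selm), replace = TRUE, prob = w / sum(w))
    tts[selm] <- draws
    for (j in seq_along(draws)) {
      i <- which(selm)[j]
      d <- draws[j]
      if (d < 0) {
        insert[i] <- substring(insert[i], 1L, nchar(insert[i]) + d)
      } else {
        insert[i] <- paste0(insert[i], strrep("A", d))
      }
    }
  }

  ad5 <- runif(n) >= config$p_missing_5p
  ad3 <- runif(n) >= config$p_missing_3p

  out <- data.frame(molecule_id = sprintf("m%05d", seq_len(n)), umi = umi,
                    sample_index = sample_index, isoform_id = ids[iso_idx],
                    insert = insert, adapter_5p = ad5, adapter_3p = ad3,
                    premature_offset = premature, tts_offset = tts,
                    chimera = "none", partner_isoform = NA_character_,
                    partner_molecule = NA_character_,
                    junction_pos = NA_integer_,
                    partner_junction = NA_integer_, seq = NA_character_,
                    stringsAsFactors = FALSE)
  out$seq <- molecule_sequence(out, config)
  structure(out, class = c("barcoded_molecules", "data.frame"))
}

molecule_sequence <- function(mols, config) {
  paste0(ifelse(mols$adapter_5p, config$adapter_5p, ""), mols$insert,
         ifelse(mols$adapter_3p, config$adapter_3p, ""))
}

#' Convert a fraction of molecules into inter-molecular PCR chimeras
#'
#' Each molecule is independently selected with probability
#' `config$chimera_rate`; a selected molecule keeps its 5' part up to a
#' junction drawn uniformly from the middle 50% of its insert and acquires
#' the 3' part of a partner molecule from a different isoform (so the contig
#' carries the 5' terminus of molecule A and the 3' terminus of molecule B).
#' Truth labels record partner and junction; unselected molecules are
#' untouched.
#'
#' @param mols Output of [sample_molecules()].
#' @param config A [sim_config()].
#' @return The molecule table with chimera truth labels updated.
#' @export
inject_chimeras <- function(mols, config) {
  r <- config$chimera_rate
  if (r < 0 || r > 1) stop("chimera rate must lie in [0, 1]")
  if (r == 0 || nrow(mols) == 0) return(mols)
  if (length(unique(mols$isoform_id)) < 2)
    stop("chimera injection requires at least 2 distinct source isoforms")
  set.seed(config$seed + 2000L)
  if (is.null(mols$partner_molecule)) mols$partner_molecule <- NA_character_
  if (is.null(mols$partner_junction)) mols$partner_junction <- NA_integer_
  sel <- which(runif(nrow(mols)) < r)
  orig <- mols$insert  # junctions are cut from the pre-chimera inserts
  for (i in sel) {
    others <- which(mols$isoform_id != mols$isoform_id[i])
    p <- others[sample.int(length(others), 1)]
    lenA <- nchar(orig[i]); lenB <- nchar(orig[p])
    jA <- sample(seq(floor(0.25 * lenA), ceiling(0.75 * lenA)), 1)
    jB <- sample(seq(floor(0.25 * lenB), ceiling(0.75 * lenB)), 1)
    mols$insert[i] <- paste0(substring(orig[i], 1L, jA),
                             substring(orig[p], jB + 1L))
    mols$chimera[i] <- "inter"
    mols$partner_isoform[i] <- mols$isoform_id[p]
    mols$partner_molecule[i] <- mols$molecule_id[p]
    mols$junction_pos[i] <- jA
    mols$partner_junction[i] <- jB
    mols$adapter_3p[i] <- mols$adapter_3p[p]
    mols$tts_offset[i] <- mols$tts_offset[p]
  }
  mols$seq <- molecule_sequence(mols, config)
  mols
}

#' Write the molecule truth table as TSV
#' @param mols Molecule table.
#' @param path Output path.
#' @export
write_molecule_truth <- function(mols, path) {
  cols <- setdiff(colnames(mols), c("insert", "seq"))
  write.table(mols[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
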