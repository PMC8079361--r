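#' Simulation configuration
#'
#' Parameter container for the library model behind the simulator: gene/isoform
#' layout, molecule sampling, short-read fragmentation and the artefact
#' processes (premature termination, TTS mispriming, PCR chimeras) that the
#' downstream QC stages are designed to detect.
#'
#' @param n_genes Number of genes in the toy annotation.
#' @param isoforms_per_gene Isoforms per gene (first isoform uses all exons,
#'   later ones skip one internal exon each).
#' @param exons_per_gene Integer range (length 2) of exon counts per gene.
#' @param exon_length Integer range of exon lengths (nt).
#' @param intron_length Integer range of intron lengths (nt).
#' @param n_molecules Number of barcoded cDNA molecules to sample.
#' @param abundance Abundance vector over isoforms (recycled/normalized to sum
#'   to 1), or `NULL` for a geometric ladder spanning roughly three decades.
#' @param read_length Short-read length (nt).
#' @param coverage Target per-molecule short-read coverage depth.
#' @param sub_rate,ins_rate,del_rate Per-base short-read error rates.
#' @param base_quality Phred quality written for simulated short-read bases.
#' @param p_premature Fraction of molecules prematurely terminated during
#'   reverse transcription (5' truncation of at least 100 nt; the molecule
#'   still receives the 5' adapter, the false-full-length phenomenon).
#' @param p_mispriming Fraction of molecules with a poly-T mispriming offset
#'   at the TTS (discrete normal, SD 2 nt, truncated to \[-5, +5\], never 0).
#' @param chimera_rate Fraction of molecules converted to inter-molecular
#'   PCR chimeras.
#' @param p_missing_5p,p_missing_3p Fractions of molecules lacking the 5'/3'
#'   synthetic adapter.
#' @param umi_length UMI length (nt); 16 by default.
#' @param adapter_5p,adapter_3p Synthetic terminal adapter sequences.
#' @param fusions Logical; lay out designed fusion-pair geometry (one cis pair
#'   separated by more than 40 kb with an intervening gene, one cis pair
#'   closer than 40 kb, one trans pair) and emit fusion molecules.
#' @param fusion_cis_far_sep,fusion_cis_near_sep Exact emitted separations
#'   (bp between gene spans) for the designed cis pairs.
#' @param n_fusion_molecules Fusion molecules emitted per designed fusion.
#' @param seed Random seed; fully determines the simulator output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 12,
                       isoforms_per_gene = 2,
                       exons_per_gene = c(3L, 6L),
                       exon_length = c(150L, 400L),
                       intron_length = c(200L, 800L),
                       n_molecules = 500,
                       abundance = NULL,
                       read_length = 150,
                       coverage = 30,
                       sub_rate = 4.15e-3,
                       ins_rate = 3.84e-4,
                       del_rate = 4.80e-4,
                       base_quality = 30L,
                       p_premature = 0.13,
                       p_mispriming = 0.16,
                       chimera_rate = 0.018,
                       p_missing_5p = 0.03,
                       p_missing_3p = 0.03,
                       umi_length = 16L,
                       adapter_5p = ADAPTER_5P,
                       adapter_3p = ADAPTER_3P,
                       fusions = FALSE,
                       fusion_cis_far_sep = 45000L,
                       fusion_cis_near_sep = 10000L,
                       n_fusion_molecules = 5L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              n_molecules = as.integer(n_molecules),
              abundance = abundance,
              read_length = as.integer(read_length),
              coverage = coverage,
              sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
              base_quality = as.integer(base_quality),
              p_premature = p_premature, p_mispriming = p_mispriming,
              chimera_rate = chimera_rate,
              p_missing_5p = p_missing_5p, p_missing_3p = p_missing_3p,
              umi_length = as.integer(umi_length),
              adapter_5p = toupper(adapter_5p), adapter_3p = toupper(adapter_3p),
              fusions = isTRUE(fusions),
              fusion_cis_far_sep = as.integer(fusion_cis_far_sep),
              fusion_cis_near_sep = as.integer(fusion_cis_near_sep),
              n_fusion_molecules = as.integer(n_fusion_molecules),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("configuration error: at least one gene required")
  rates <- c(cfg$sub_rate, cfg$ins_rate, cfg$del_rate, cfg$p_premature,
             cfg$p_mispriming, cfg$chimera_rate, cfg$p_missing_5p,
             cfg$p_missing_3p)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (!is.null(cfg$abundance)) {
    if (any(cfg$abundance < 0)) stop("abundance must be non-negative")
  }
  if (cfg$umi_length < 4L) stop("UMI too short")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("slrtx simulation config:", x$n_genes, "genes x",
      x$isoforms_per_gene, "isoforms,", x$n_molecules, "molecules,",
      "coverage", x$coverage, "at read length", x$read_length, "\n")
  cat("  error rates sub/ins/del:",
      format(c(x$sub_rate, x$ins_rate, x$del_rate), digits = 3), "\n")
  cat("  artefacts: premature", x$p_premature, "| mispriming", x$p_mispriming,
      "| chimera", x$chimera_rate, "| seed", x$seed, "\n")
  invisible(x)
}
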