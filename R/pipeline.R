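# End-to-end orchestration: simulate -> assemble -> qc -> quant -> fusion,
# driven by a single config, with per-stage logging and a checksum manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed, propagated to every stochastic stage.
#' @param stages Character vector of stages to run, in dependency order.
#' @param sim Simulation parameter overrides (passed to [sim_config()]).
#' @param assembly Assembly parameter overrides ([assembly_params()]).
#' @param reads Optional path to an existing FASTQ (skips the simulate
#'   stage inputs).
#' @param variants Optional variant TSV path; enables the snv stage.
#' @param log_level "info" or "quiet".
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "slrtx_out", seed = 1L,
                            stages = c("simulate", "assemble", "qc",
                                       "quant", "fusion"),
                            sim = list(), assembly = list(),
                            reads = NULL, variants = NULL,
                            log_level = "info") {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, sim = sim, assembly = assembly,
                 reads = reads, variants = variants,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

plog <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [slrtx] ", ...)
}

#' Run the pipeline
#'
#' Stages run in dependency order; a failing stage stops the run with a
#' non-zero status and preserved upstream outputs. Status codes: 0 success,
#' 1 invalid configuration, 2 missing input file.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return List with `status` and `manifest` (data.frame path, md5) —
#'   identical config and seed give identical checksums.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    return(list(status = 1L, manifest = NULL,
                error = "invalid config: not a pipeline_config"))
  if (!is.null(config$reads) && !file.exists(config$reads))
    return(list(status = 2L, manifest = NULL,
                error = paste("missing input file:", config$reads)))
  if (!is.null(config$variants) && !file.exists(config$variants))
    return(list(status = 2L, manifest = NULL,
                error = paste("missing input file:", config$variants)))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name) {
    plog(config, "stage ", name)
    switch(name,
      simulate = {
        sim_args <- config$sim
        sim_args$seed <- config$seed
        scfg <- do.call(sim_config, sim_args)
        state$sim <- simulate_dataset(scfg, config$out_dir)
        state$config_sim <- scfg
        outputs <<- c(outputs, unlist(state$sim$paths))
      },
      assemble = {
        reads_path <- if (!is.null(config$reads)) config$reads else
          file.path(config$out_dir, "reads.fastq")
        if (!file.exists(reads_path))
          stop("missing input file: ", reads_path, call. = FALSE)
        params <- do.call(assembly_params, config$assembly)
        bins <- bin_reads(reads_path)
        asm <- assemble_bins(bins, params)
        state$contigs <- asm$contigs
        slr_path <- file.path(config$out_dir, "slr.fastq")
        rej_path <- file.path(config$out_dir, "rejected_bins.tsv")
        write_slr_fastq(asm$contigs, slr_path)
        write.table(asm$rejected, rej_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <<- c(outputs, slr_path, rej_path)
      },
      qc = {
        refs <- read_fasta(file.path(config$out_dir, "references.fasta"))
        fl <- Filter(function(x) x$completeness == "full_length",
                     state$contigs)
        aln <- align_to_reference(fl, refs)
        prof <- profile_errors(aln)
        summ_path <- file.path(config$out_dir, "error_summary.tsv")
        write.table(data.frame(metric = names(prof$rates),
                               rate = unlist(prof$rates)),
                    summ_path, sep = "\t", quote = FALSE, row.names = FALSE)
        chim <- detect_chimeras(fl, refs)
        chim_path <- file.path(config$out_dir, "chimera_report.tsv")
        write.table(chim$verdicts, chim_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        term <- terminus_offsets(aln)
        term_path <- file.path(config$out_dir, "terminus_offsets.tsv")
        write.table(term$offsets, term_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        state$alignments <- aln
        outputs <<- c(outputs, summ_path, chim_path, term_path)
      },
      quant = {
        ann <- state$sim$annotation
        fl <- Filter(function(x) x$completeness == "full_length",
                     state$contigs)
        ga <- genome_align(fl, ann$genome)
        asg <- assign_isoforms(ga, ann)
        state$genome_alignments <- ga
        state$assignments <- asg
        cm <- build_count_matrices(setNames(list(asg), "S1"), ann)
        iso_path <- file.path(config$out_dir, "isoform_counts.tsv")
        write.table(data.frame(isoform_id = rownames(cm$isoform),
                               cm$isoform, check.names = FALSE),
                    iso_path, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <<- c(outputs, iso_path)
      },
      snv = {
        if (is.null(config$variants)) {
          plog(config, "no variant table supplied; snv stage skipped")
          return(invisible())
        }
        vars <- read_variants(config$variants)
        mat <- pileup_by_isoform(state$genome_alignments,
                                 state$assignments, vars)
        snv_path <- file.path(config$out_dir, "snv_isoform_matrix.tsv")
        write.table(mat, snv_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <<- c(outputs, snv_path)
      },
      fusion = {
        ann <- state$sim$annotation
        if (is.null(ann$fusions)) {
          plog(config, "no designed fusions in annotation; stage skipped")
          return(invisible())
        }
        lib <- build_junction_library(ann$fusions)
        fl <- Filter(function(x) x$completeness == "full_length",
                     state$contigs)
        hits <- search_junctions(fl, lib)
        fus_path <- file.path(config$out_dir, "fusion_hits.tsv")
        write.table(hits, fus_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <<- c(outputs, fus_path)
      },
      stop("unknown stage: ", name, call. = FALSE))
    invisible()
  }

  for (st in config$stages) {
    res <- tryCatch({ run_stage(st); NULL }, error = function(e) e)
    if (!is.null(res)) {
      status <- if (grepl("missing input file", conditionMessage(res)))
        2L else 1L
      return(list(status = status, manifest = manifest_of(outputs),
                  error = conditionMessage(res), failed_stage = st))
    }
  }
  plog(config, "done; ", length(outputs), " outputs")
  list(status = 0L, manifest = manifest_of(outputs))
}

manifest_of <- function(paths) {
  paths <- unique(paths[file.exists(paths)])
  data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
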