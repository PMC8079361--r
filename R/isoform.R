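# Isoform-resolved quantification: splice-chain matching of genome-aligned
# contigs against the annotation, count matrices, a minimal
# negative-binomial differential test with the FDR 5% / >2-fold selection
# rule, DEG/DEI categorization, and sample-similarity summaries.

#' Assign a genome-aligned contig to an annotated isoform
#'
#' The contig's splice-junction chain (genomic intron intervals implied by
#' alignment gaps of at least the intron threshold) must match a consecutive
#' run of an isoform's annotated junction chain, with both ends of every
#' junction within `tolerance` nt. Multiple consistent isoforms resolve by
#' the longest compatible chain, then the lexicographically smallest isoform
#' id. Mono-exonic contigs are assigned by containment in an annotated
#' exon. Contigs matching no isoform are `novel`; contigs on chromosomes
#' missing from the annotation are `unassigned`.
#'
#' @param record One record of a `genome_alignments` object.
#' @param ann A `toy_annotation` (or [read_annotation_gtf()] output).
#' @param tolerance Junction end tolerance in nt (default 5).
#' @return List: `contig_id`, `isoform_id` (or `"novel"` / `"unassigned"`),
#'   `gene_id`, `n_junctions`, `reason`.
#' @export
assign_isoform <- function(record, ann, tolerance = 5L) {
  out <- list(contig_id = record$contig_id, isoform_id = "unassigned",
              gene_id = NA_character_, n_junctions = NA_integer_,
              reason = NA_character_)
  if (!record$chrom %in% ann$genes$chrom) {
    out$reason <- paste0("chromosome not annotated: ", record$chrom)
    return(out)
  }
  cj <- blocks_to_junctions(record$blocks)
  out$n_junctions <- nrow(cj)
  iso_ids <- ann$isoforms$isoform_id[
    ann$isoforms$gene_id %in% ann$genes$gene_id[ann$genes$chrom == record$chrom]]

  if (nrow(cj) == 0) {
    span <- c(min(record$blocks[, "rstart"]), max(record$blocks[, "rend"]))
    cands <- character(0)
    for (iso in iso_ids) {
      ex <- ann$exons[ann$exons$isoform_id == iso, ]
      if (any(ex$start - tolerance <= span[1] & ex$end + tolerance >= span[2]))
        cands <- c(cands, iso)
    }
    if (length(cands) == 0) { out$isoform_id <- "novel"; return(out) }
    iso <- sort(cands)[1]
    out$isoform_id <- iso
    out$gene_id <- ann$isoforms$gene_id[ann$isoforms$isoform_id == iso]
    return(out)
  }

  best <- character(0); best_len <- -1L
  for (iso in iso_ids) {
    aj <- junction_chain(ann, iso)
    m <- match_subchain(cj, aj, tolerance)
    if (m) {
      # all contig junctions matched; compatible chain length = nrow(cj)
      if (nrow(cj) > best_len) { best_len <- nrow(cj); best <- iso }
      else if (nrow(cj) == best_len) best <- c(best, iso)
    }
  }
  if (length(best) == 0) { out$isoform_id <- "novel"; return(out) }
  iso <- sort(best)[1]
  out$isoform_id <- iso
  out$gene_id <- ann$isoforms$gene_id[ann$isoforms$isoform_id == iso]
  out
}

# TRUE when contig junctions cj form a consecutive run of annotated chain aj
# within tolerance at both junction ends
match_subchain <- function(cj, aj, tol) {
  k <- nrow(cj); n <- nrow(aj)
  if (k > n) return(FALSE)
  for (s in seq_len(n - k + 1L)) {
    idx <- s:(s + k - 1L)
    if (all(abs(aj$start[idx] - cj$start) <= tol) &&
        all(abs(aj$end[idx] - cj$end) <= tol)) return(TRUE)
  }
  FALSE
}

#' Assign all contigs of a genome alignment set
#' @param genome_alignments A `genome_alignments` object.
#' @param ann Annotation.
#' @param tolerance Junction tolerance (nt).
#' @return data.frame contig_id, isoform_id, gene_id, n_junctions.
#' @export
assign_isoforms <- function(genome_alignments, ann, tolerance = 5L) {
  rows <- lapply(genome_alignments$records, function(r) {
    a <- assign_isoform(r, ann, tolerance)
    data.frame(contig_id = a$contig_id, isoform_id = a$isoform_id,
               gene_id = if (is.null(a$gene_id)) NA_character_ else a$gene_id,
               n_junctions = a$n_junctions, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), isoform_id = character(),
               gene_id = character(), n_junctions = integer())
}

#' Build isoform and gene count matrices
#'
#' @param assignments Named list of assignment data.frames (one per sample,
#'   names = sample ids), as from [assign_isoforms()]; rows with isoform_id
#'   `novel`/`unassigned` are ignored.
#' @param ann Annotation providing the isoform-to-gene map.
#' @return List with integer matrices `isoform` and `gene` (features x
#'   samples); gene counts are sums of constituent isoform counts.
#' @export
build_count_matrices <- function(assignments, ann) {
  samples <- names(assignments)
  iso_ids <- sort(ann$isoforms$isoform_id)
  iso <- matrix(0L, length(iso_ids), length(samples),
                dimnames = list(iso_ids, samples))
  for (s in samples) {
    a <- assignments[[s]]
    a <- a[a$isoform_id %in% iso_ids, ]
    if (nrow(a)) {
      t <- table(a$isoform_id)
      iso[names(t), s] <- iso[names(t), s] + as.integer(t)
    }
  }
  gene_of <- setNames(ann$isoforms$gene_id, ann$isoforms$isoform_id)
  g <- rowsum(iso, gene_of[rownames(iso)])
  storage.mode(g) <- "integer"
  list(isoform = iso, gene = g[sort(rownames(g)), , drop = FALSE])
}

#' Two-group negative-binomial differential test
#'
#' Median-of-ratios size factors, method-of-moments dispersion (floored at
#' 0.01), per-feature Wald test on the log fold change, BH adjustment.
#' Significance requires adjusted p <= 0.05 and |fold change| > 2. Features
#' with all-zero counts get p = 1 and are excluded from the BH denominator.
#'
#' @param counts Integer matrix (features x samples).
#' @param groups Factor/character of length ncol(counts) with two levels;
#'   the fold change is level 2 over level 1.
#' @param alpha FDR level (default 0.05).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1, i.e. 2-fold).
#' @return data.frame feature, base_mean, log2fc, p, padj, significant.
#' @export
differential_expression <- function(counts, groups, alpha = 0.05,
                                    lfc_cut = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 1)) stop("at least one sample per group required")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  g1 <- groups == levels(groups)[1]; g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)

  base_mean <- rowMeans(norm)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  # method-of-moments dispersion pooled across groups, floored
  v1 <- apply(norm[, g1, drop = FALSE], 1, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, var)
  if (n1 < 2) v1 <- rep(NA_real_, nrow(norm))
  if (n2 < 2) v2 <- rep(NA_real_, nrow(norm))
  disp_est <- function(m, v) ifelse(!is.na(v) & m > 0, (v - m) / m^2, NA_real_)
  disp <- rowMeans(cbind(disp_est(mu1, v1), disp_est(mu2, v2)), na.rm = TRUE)
  disp[is.nan(disp)] <- NA_real_
  # moderate towards the across-feature median: per-feature MoM estimates
  # from a handful of replicates are too noisy to use alone
  prior <- stats::median(disp[!is.na(disp) & disp > 0])
  if (!length(prior) || is.na(prior)) prior <- 0.01
  disp <- pmax(ifelse(is.na(disp), prior, disp), prior, 0.01)

  eps <- 0.5
  lfc <- log2((mu2 + eps) / (mu1 + eps))
  # delta-method SE of log(mu) for an NB mean over n samples
  se2 <- (1 / n1) * (1 / (mu1 + eps) + disp) +
    (1 / n2) * (1 / (mu2 + eps) + disp)
  z <- log((mu2 + eps) / (mu1 + eps)) / sqrt(se2)
  p <- 2 * pnorm(-abs(z))

  allzero <- rowSums(counts) == 0
  p[allzero] <- 1
  padj <- rep(NA_real_, length(p))
  padj[!allzero] <- p.adjust(p[!allzero], method = "BH")
  padj[allzero] <- 1
  sig <- !is.na(padj) & padj <= alpha & abs(lfc) > lfc_cut
  data.frame(feature = rownames(counts), base_mean = base_mean,
             log2fc = lfc, p = p, padj = padj, significant = sig,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-of-ratios size factors
#' @param counts Count matrix (features x samples).
#' @return Numeric vector of size factors (geometric-mean normalized).
#' @export
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  sf <- apply(counts, 2, function(x) exp(stats::median((log(x) - lg)[use])))
  sf / exp(mean(log(sf)))
}

#' Categorize differentially expressed genes and isoforms
#'
#' Splits genes into three disjoint sets: DEG-only (differential at gene
#' level with no differential isoform), DEG-and-DEI, and DEI-only (genes
#' owning at least one differential isoform but no gene-level change), with
#' the two headline fractions.
#'
#' @param deg DE result on genes (from [differential_expression()]).
#' @param dei DE result on isoforms.
#' @param ann Annotation providing the isoform-to-gene map.
#' @return Object of class `de_categorization`: sets and fractions.
#' @export
categorize_deg_dei <- function(deg, dei, ann) {
  gene_of <- setNames(ann$isoforms$gene_id, ann$isoforms$isoform_id)
  deg_genes <- deg$feature[deg$significant]
  dei_iso <- dei$feature[dei$significant]
  if (any(!dei_iso %in% names(gene_of)))
    stop("isoform with unknown parent gene: ",
         dei_iso[!dei_iso %in% names(gene_of)][1])
  dei_genes <- unique(unname(gene_of[dei_iso]))
  sets <- list(deg_only = setdiff(deg_genes, dei_genes),
               both = intersect(deg_genes, dei_genes),
               dei_only = setdiff(dei_genes, deg_genes))
  frac_deg_only <- if (length(deg_genes) > 0)
    length(sets$deg_only) / length(deg_genes) else NA_real_
  frac_dei_only <- if (length(dei_genes) > 0)
    length(sets$dei_only) / length(dei_genes) else NA_real_
  structure(list(sets = sets, n_deg = length(deg_genes),
                 n_dei_genes = length(dei_genes),
                 frac_deg_only = frac_deg_only,
                 frac_dei_only = frac_dei_only,
                 defined = length(deg_genes) > 0 || length(dei_genes) > 0),
            class = "de_categorization")
}

#' DEI-only fraction from printed counts
#' @param dei_only Number of DEI-only genes.
#' @param dei_genes Number of genes owning at least one DEI.
#' @param digits Decimal places of the percentage.
#' @return Percentage, rounded.
#' @export
dei_only_fraction_pct <- function(dei_only, dei_genes, digits = 1) {
  round(100 * dei_only / dei_genes, digits)
}

#' @export
print.de_categorization <- function(x, ...) {
  cat(sprintf("DEG-only %d | DEG&DEI %d | DEI-only %d genes\n",
              length(x$sets$deg_only), length(x$sets$both),
              length(x$sets$dei_only)))
  if (!is.na(x$frac_dei_only))
    cat(sprintf("  DEI-only fraction: %.1f%% (%d/%d)\n",
                100 * x$frac_dei_only, length(x$sets$dei_only), x$n_dei_genes))
  invisible(x)
}

#' Sample similarity: clustering, PCA, Pearson matrix
#'
#' Features are row-standardized (Z score; constant rows dropped), samples
#' are clustered by average linkage on 1 - Pearson distance, and PCA is the
#' eigendecomposition of the sample covariance of the standardized matrix.
#'
#' @param mat Numeric matrix (features x samples), counts or rates.
#' @return List with `hclust` (stats::hclust object), `pca` (sample
#'   coordinates, features `sdev`), `pearson` (sample correlation matrix).
#' @export
sample_similarity <- function(mat) {
  if (ncol(mat) < 2) stop("at least 2 samples required")
  sds <- apply(mat, 1, sd)
  keep <- !is.na(sds) & sds > 0
  z <- (mat[keep, , drop = FALSE] - rowMeans(mat[keep, , drop = FALSE])) /
    sds[keep]
  pear <- cor(z)
  hc <- hclust(as.dist(1 - pear), method = "average")
  cv <- cov(z)
  eg <- eigen(cv, symmetric = TRUE)
  # sample coordinates: eigenvectors scaled by the component sdev
  pcs <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow = ncol(cv))
  rownames(pcs) <- colnames(mat)
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  list(hclust = hc, pca = list(coords = pcs,
                               sdev = sqrt(pmax(eg$values, 0))),
       pearson = pear)
}
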