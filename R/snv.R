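# Isoform-resolved SNV statistics: wild-type/alternate contig counting per
# (variant, isoform, sample), the chi-squared uneven-distribution screen,
# the Fisher exact distribution-shift screen, the tumor-vs-metastasis
# switching screen, and catalogue cross-referencing.

#' Read a variant table (VCF-like TSV)
#'
#' Expected columns: CHROM, POS, REF, ALT plus optional GENE, EFFECT,
#' VALIDATED. Only single-nucleotide variants with REF != ALT are accepted.
#' @param path TSV path.
#' @return data.frame chrom, pos, ref, alt, gene, effect, validated.
#' @export
read_variants <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d))) stop("variant table needs columns CHROM, POS, REF, ALT")
  bad <- nchar(d$ref) != 1 | nchar(d$alt) != 1 | d$ref == d$alt
  if (any(bad)) stop("non-SNV or degenerate variant rows: ", sum(bad))
  d$gene <- if ("gene" %in% names(d)) d$gene else NA_character_
  d$effect <- if ("effect" %in% names(d)) d$effect else NA_character_
  d$validated <- if ("validated" %in% names(d)) d$validated else NA
  d[, c("chrom", "pos", "ref", "alt", "gene", "effect", "validated")]
}

#' Pile up wild-type/alternate contig counts per (variant, isoform, sample)
#'
#' For each variant site, a contig whose aligned blocks cover the site
#' contributes its base at the site (extracted strand-aware from the aligned
#' orientation of the contig): the reference base counts as wild type, the
#' alternate base as alternate; any third base, and contigs not covering the
#' site, are ignored.
#'
#' @param genome_alignments A `genome_alignments` object (one sample).
#' @param assignments Assignment data.frame from [assign_isoforms()] for the
#'   same contigs.
#' @param variants Variant data.frame (see [read_variants()]).
#' @param sample_id Sample label for the output rows.
#' @return data.frame of class `snv_isoform_matrix` rows: variant_id,
#'   chrom, pos, isoform_id, sample, wt, alt, rate (NA when wt + alt = 0).
#' @export
pileup_by_isoform <- function(genome_alignments, assignments, variants,
                              sample_id = "S1") {
  iso_of <- setNames(assignments$isoform_id, assignments$contig_id)
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    chrom <- variants$chrom[v]; pos <- variants$pos[v]
    refb <- toupper(variants$ref[v]); altb <- toupper(variants$alt[v])
    vid <- sprintf("%s:%d:%s>%s", chrom, pos, refb, altb)
    counts <- list()
    covered_chrom <- FALSE
    for (r in genome_alignments$records) {
      if (r$chrom != chrom) next
      covered_chrom <- TRUE
      b <- r$blocks
      hit <- which(b[, "rstart"] <= pos & b[, "rend"] >= pos)
      if (length(hit) == 0) next
      qpos <- b[hit[1], "qstart"] + (pos - b[hit[1], "rstart"])
      base <- substring(r$oriented_query, qpos, qpos)
      iso <- iso_of[r$contig_id]
      if (is.na(iso) || iso %in% c("novel", "unassigned")) next
      key <- iso
      if (is.null(counts[[key]])) counts[[key]] <- c(wt = 0L, alt = 0L)
      if (base == refb) counts[[key]]["wt"] <- counts[[key]]["wt"] + 1L
      else if (base == altb) counts[[key]]["alt"] <- counts[[key]]["alt"] + 1L
    }
    if (length(counts) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = vid, chrom = chrom, pos = pos,
        isoform_id = NA_character_, sample = sample_id, wt = 0L, alt = 0L,
        rate = NA_real_, flag = if (covered_chrom) NA_character_ else
          "chromosome absent from alignments", stringsAsFactors = FALSE)
    } else {
      for (iso in names(counts)) {
        wt <- counts[[iso]][["wt"]]; alt <- counts[[iso]][["alt"]]
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = vid, chrom = chrom, pos = pos, isoform_id = iso,
          sample = sample_id, wt = wt, alt = alt,
          rate = if (wt + alt > 0) alt / (wt + alt) else NA_real_,
          flag = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), chrom = character(),
               pos = integer(), isoform_id = character(),
               sample = character(), wt = integer(), alt = integer(),
               rate = numeric(), flag = character())
  class(out) <- c("snv_isoform_matrix", "data.frame")
  out
}

#' SNV rate from counts
#' @param alt,wt Alternate and wild-type contig counts.
#' @return alt / (alt + wt); NA when both are zero.
#' @export
snv_rate <- function(alt, wt) {
  ifelse(alt + wt > 0, alt / (alt + wt), NA_real_)
}

#' Chi-squared screen for unevenly distributed SNVs across isoforms
#'
#' Variants observed on more than one isoform and covered by at least
#' `min_contigs` contigs are tested by a chi-squared goodness-of-fit of the
#' ALT counts across isoforms against each isoform's share of the total
#' (WT + ALT) contigs for that variant; other variants are excluded, not
#' tested. p-values are BH-adjusted within the tested family.
#'
#' @param matrix An `snv_isoform_matrix` (one sample or pooled).
#' @param min_isoforms Minimum isoforms involved (default 2).
#' @param min_contigs Minimum covering contigs (default 5).
#' @param alpha FDR level.
#' @return data.frame variant_id, n_isoforms, n_contigs, statistic, df, p,
#'   padj, significant; one row per tested variant.
#' @export
test_uneven_distribution <- function(matrix, min_isoforms = 2L,
                                     min_contigs = 5L, alpha = 0.05) {
  d <- matrix[!is.na(matrix$isoform_id), ]
  rows <- list()
  for (vid in unique(d$variant_id)) {
    dv <- d[d$variant_id == vid & (d$wt + d$alt) > 0, ]
    if (nrow(dv) == 0) next
    tot <- sum(dv$wt + dv$alt)
    if (nrow(dv) < min_isoforms || tot < min_contigs) next
    A <- sum(dv$alt)
    if (A == 0) next
    p_exp <- (dv$wt + dv$alt) / tot
    # pool cells whose expected ALT count is 0 into the nearest neighbour
    # by count (cannot occur here since p_exp > 0 by construction)
    exp_alt <- A * p_exp
    stat <- sum((dv$alt - exp_alt)^2 / exp_alt)
    df <- nrow(dv) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = vid, n_isoforms = nrow(dv), n_contigs = tot,
      statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), n_isoforms = integer(),
               n_contigs = integer(), statistic = numeric(), df = integer(),
               p = numeric())
  out$padj <- if (nrow(out)) p.adjust(out$p, "BH") else numeric(0)
  out$significant <- !is.na(out$padj) & out$padj <= alpha
  out
}

#' Exact p-value for a 2 x k table (distribution shift between WT and ALT)
#'
#' Two-sided Fisher exact test by full enumeration of all tables with the
#' observed margins when the total is at most `enum_cutoff`, otherwise by
#' Monte-Carlo sampling from the null (`mc_draws` draws at a fixed seed).
#' The p-value is the total probability of tables no more probable than the
#' observed one.
#'
#' @param wt,alt Integer vectors of WT and ALT counts across isoforms.
#' @param enum_cutoff Maximum table total for full enumeration (default 200).
#' @param mc_draws Monte-Carlo draws beyond the cutoff.
#' @param mc_seed Seed for the Monte-Carlo path.
#' @return List with `p` and `method` ("enumeration" or "monte_carlo").
#' @export
fisher_2xk <- function(wt, alt, enum_cutoff = 200L, mc_draws = 1e5L,
                       mc_seed = 20210427L) {
  stopifnot(length(wt) == length(alt))
  tab <- rbind(wt = as.integer(wt), alt = as.integer(alt))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  k <- ncol(tab)
  if (k < 2 || any(rowSums(tab) == 0)) return(list(p = 1, method = "degenerate"))
  row_tot <- rowSums(tab); col_tot <- colSums(tab); N <- sum(tab)

  log_prob <- function(r1) {
    # table probability given row margins and column margins; r1 = first row
    sum(lchoose(col_tot, r1)) - lchoose(N, row_tot[1])
  }
  obs <- log_prob(tab[1, ])
  if (N <= enum_cutoff) {
    # enumerate first-row allocations with sum row_tot[1], 0 <= r1_j <= col_tot_j
    p_total <- 0
    rec <- function(j, remaining, r1) {
      if (j == k) {
        if (remaining > col_tot[k]) return()
        r1[k] <- remaining
        lp <- log_prob(r1)
        if (lp <= obs + 1e-9) p_total <<- p_total + exp(lp)
        return()
      }
      for (x in 0:min(col_tot[j], remaining)) {
        r1[j] <- x
        rec(j + 1L, remaining - x, r1)
      }
    }
    rec(1L, row_tot[1], integer(k))
    return(list(p = min(p_total, 1), method = "enumeration"))
  }
  # Monte-Carlo: sample first rows from the multivariate hypergeometric null
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(mc_seed)
  hits <- 0L
  urn <- rep(seq_len(k), col_tot)
  for (b in seq_len(ceiling(mc_draws / 1000))) {
    nb <- min(1000L, mc_draws - (b - 1L) * 1000L)
    for (s in seq_len(nb)) {
      draw <- tabulate(sample(urn, row_tot[1]), k)
      if (log_prob(draw) <= obs + 1e-9) hits <- hits + 1L
    }
  }
  list(p = (hits + 1) / (mc_draws + 1), method = "monte_carlo")
}

#' Fisher distribution-shift screen across variants
#'
#' Applies [fisher_2xk()] to each variant's WT/ALT-by-isoform table (at
#' least two isoforms with wt + alt > 0) and BH-adjusts within the family.
#'
#' @param matrix An `snv_isoform_matrix`.
#' @param alpha FDR level.
#' @param ... Passed to [fisher_2xk()].
#' @return data.frame variant_id, p, padj, significant, method.
#' @export
test_distribution_shift <- function(matrix, alpha = 0.05, ...) {
  d <- matrix[!is.na(matrix$isoform_id), ]
  rows <- list()
  for (vid in unique(d$variant_id)) {
    dv <- d[d$variant_id == vid & (d$wt + d$alt) > 0, ]
    if (nrow(dv) < 2) next
    f <- fisher_2xk(dv$wt, dv$alt, ...)
    rows[[length(rows) + 1L]] <- data.frame(variant_id = vid, p = f$p,
                                           method = f$method,
                                           stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), p = numeric(), method = character())
  out$padj <- if (nrow(out)) p.adjust(out$p, "BH") else numeric(0)
  out$significant <- !is.na(out$padj) & out$padj <= alpha
  out
}

#' Screen for SNV-isoform switching between sample groups
#'
#' A (variant, isoform) pair switches when its SNV rate is at least
#' `threshold` in every sample of one group and strictly below `threshold`
#' in every sample of the other. Pairs with an undefined rate in any sample
#' are excluded with a reason.
#'
#' @param matrix An `snv_isoform_matrix` over all samples.
#' @param groups Named vector mapping sample id to group (two groups, e.g.
#'   primary vs metastasis).
#' @param threshold Rate threshold (default 0.5; high is >= threshold, low
#'   is < threshold).
#' @return data.frame variant_id, isoform_id, switching, direction,
#'   excluded_reason.
#' @export
screen_switching <- function(matrix, groups, threshold = 0.5) {
  if (any(!matrix$sample %in% names(groups)))
    stop("every sample must be labelled with a group")
  glev <- unique(groups)
  if (length(glev) != 2) stop("exactly two groups required")
  d <- matrix[!is.na(matrix$isoform_id), ]
  rows <- list()
  for (key in unique(paste(d$variant_id, d$isoform_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    dv <- d[d$variant_id == parts[1] & d$isoform_id == parts[2], ]
    res <- data.frame(variant_id = parts[1], isoform_id = parts[2],
                      switching = FALSE, direction = NA_character_,
                      excluded_reason = NA_character_,
                      stringsAsFactors = FALSE)
    expect <- names(groups)
    have <- dv$sample[!is.na(dv$rate)]
    if (!all(expect %in% have)) {
      res$excluded_reason <- "undefined rate in at least one sample"
    } else {
      rate_of <- setNames(dv$rate, dv$sample)
      r1 <- rate_of[names(groups)[groups == glev[1]]]
      r2 <- rate_of[names(groups)[groups == glev[2]]]
      if (all(r1 >= threshold) && all(r2 < threshold)) {
        res$switching <- TRUE; res$direction <- paste0("high_in_", glev[1])
      } else if (all(r2 >= threshold) && all(r1 < threshold)) {
        res$switching <- TRUE; res$direction <- paste0("high_in_", glev[2])
      }
    }
    rows[[length(rows) + 1L]] <- res
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), isoform_id = character(),
               switching = logical(), direction = character(),
               excluded_reason = character())
}

#' Cross-reference variants against an external catalogue
#'
#' Exact-key intersection on (chrom, pos, ref, alt); duplicate catalogue
#' rows are collapsed, malformed rows skipped with a warning.
#'
#' @param variants Variant data.frame (see [read_variants()]).
#' @param catalogue data.frame or TSV path with columns chrom, pos, ref, alt.
#' @return The variant table with a logical `in_catalogue` column; the
#'   flagged count is in `attr(, "n_flagged")`.
#' @export
crossref_catalogue <- function(variants, catalogue) {
  if (is.character(catalogue)) catalogue <- read.delim(catalogue,
                                                       stringsAsFactors = FALSE)
  names(catalogue) <- tolower(names(catalogue))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(catalogue)))
    stop("catalogue needs columns chrom, pos, ref, alt")
  ok <- !is.na(catalogue$pos) & nchar(catalogue$ref) == 1 &
    nchar(catalogue$alt) == 1
  if (any(!ok)) warning(sum(!ok), " malformed catalogue rows skipped")
  catalogue <- catalogue[ok, ]
  key <- function(d) paste(d$chrom, d$pos, toupper(d$ref), toupper(d$alt),
                           sep = ":")
  cat_keys <- unique(key(catalogue))
  variants$in_catalogue <- key(variants) %in% cat_keys
  attr(variants, "n_flagged") <- sum(variants$in_catalogue)
  variants
}
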