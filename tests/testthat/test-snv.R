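# Isoform-resolved SNV counting and the three statistical screens.

# construct a toy pileup scene: one gene, one exon region, contigs carrying
# REF or ALT at a genomic site
make_scene <- function(n_wt, n_alt, n_other = 0, iso = "I1", pos = 500L,
                       refb = "A", altb = "G", sample_id = "S1",
                       start_id = 1L) {
  recs <- list(); asg <- list(); i <- start_id - 1L
  add <- function(base) {
    i <<- i + 1L
    q <- strrep("T", 101)
    substring(q, 51, 51) <- base
    recs[[length(recs) + 1L]] <<- list(
      contig_id = sprintf("c%03d", i), chrom = "chr1", strand = "+",
      blocks = cbind(qstart = 1L, qend = 101L,
                     rstart = pos - 50L, rend = pos + 50L),
      oriented_query = q)
    asg[[length(asg) + 1L]] <<- data.frame(
      contig_id = sprintf("c%03d", i), isoform_id = iso, gene_id = "G1",
      n_junctions = 0L, stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_wt)) add(refb)
  for (j in seq_len(n_alt)) add(altb)
  for (j in seq_len(n_other)) add("C")
  list(ga = structure(list(records = recs, unaligned = character(0)),
                      class = "genome_alignments"),
       asg = do.call(rbind, asg))
}

test_that("pileup counts WT/ALT per isoform and ignores third bases", {
  sc <- make_scene(7, 3, n_other = 2)
  vars <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  m <- pileup_by_isoform(sc$ga, sc$asg, vars)
  expect_equal(m$wt, 7L)
  expect_equal(m$alt, 3L)
  expect_equal(m$rate, 0.3)
  # count conservation: wt + alt <= covering contigs
  expect_lte(m$wt + m$alt, 12)

  # site nobody covers
  vars2 <- data.frame(chrom = "chr1", pos = 10000L, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  m2 <- pileup_by_isoform(sc$ga, sc$asg, vars2)
  expect_equal(m2$wt + m2$alt, 0L)
  expect_true(is.na(m2$rate))

  # chromosome absent from alignments is flagged
  vars3 <- data.frame(chrom = "chr9", pos = 500L, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  m3 <- pileup_by_isoform(sc$ga, sc$asg, vars3)
  expect_match(m3$flag, "absent")
})

test_that("strand-aware base extraction counts minus-strand contigs", {
  sc <- make_scene(2, 1)
  # a minus-strand record: oriented_query is already the aligned orientation,
  # so extraction is positional regardless of strand label
  sc$ga$records[[1]]$strand <- "-"
  vars <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  m <- pileup_by_isoform(sc$ga, sc$asg, vars)
  expect_equal(m$wt + m$alt, 3L)
})

test_that("uneven-distribution screen applies the contig and isoform filters", {
  # single isoform -> excluded
  m1 <- make_scene(5, 5)$ga
  mat1 <- pileup_by_isoform(m1, make_scene(5, 5)$asg,
                            data.frame(chrom = "chr1", pos = 500L,
                                       ref = "A", alt = "G"))
  expect_equal(nrow(test_uneven_distribution(mat1)), 0)

  # two isoforms but only 4 contigs -> excluded
  a <- make_scene(1, 1, iso = "I1")
  b <- make_scene(1, 1, iso = "I2", start_id = 50L)
  ga <- structure(list(records = c(a$ga$records, b$ga$records),
                       unaligned = character(0)),
                  class = "genome_alignments")
  asg <- rbind(a$asg, b$asg)
  mat2 <- pileup_by_isoform(ga, asg, data.frame(chrom = "chr1", pos = 500L,
                                                ref = "A", alt = "G"))
  expect_equal(nrow(test_uneven_distribution(mat2)), 0)

  # balanced ALT across equal-usage isoforms: statistic 0, p = 1
  a <- make_scene(5, 5, iso = "I1")
  b <- make_scene(5, 5, iso = "I2", start_id = 50L)
  ga <- structure(list(records = c(a$ga$records, b$ga$records),
                       unaligned = character(0)),
                  class = "genome_alignments")
  mat3 <- pileup_by_isoform(ga, rbind(a$asg, b$asg),
                            data.frame(chrom = "chr1", pos = 500L,
                                       ref = "A", alt = "G"))
  res <- test_uneven_distribution(mat3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("chi-squared screen type-I error is nominal under the null", {
  set.seed(101)
  n_var <- 1000
  rows <- list()
  for (v in seq_len(n_var)) {
    usage <- c(0.6, 0.4)
    tot <- rbinom(2, 30, 0.8) + 5L
    alt_tot <- rbinom(1, sum(tot), 0.3)
    alt <- stats::rmultinom(1, alt_tot, tot / sum(tot))[, 1]
    wt <- pmax(tot - alt, 0L)
    rows[[v]] <- data.frame(variant_id = sprintf("v%04d", v),
                            chrom = "chr1", pos = v, isoform_id = c("I1", "I2"),
                            sample = "S1", wt = wt, alt = alt,
                            rate = alt / (alt + wt), flag = NA_character_,
                            stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, rows)
  class(mat) <- c("snv_isoform_matrix", "data.frame")
  res <- test_uneven_distribution(mat)
  rate <- mean(res$p <= 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), 3 * se + 0.02)
  # BH false discoveries controlled
  expect_lte(sum(res$significant) / max(nrow(res), 1), 0.05)
})

test_that("Fisher exact p-values match the enumeration oracle exactly", {
  # extreme 2x2: only the two extreme tables are as or more extreme
  f <- fisher_2xk(c(10, 0), c(0, 10))
  expect_equal(f$method, "enumeration")
  expect_equal(f$p, 2 / choose(20, 10))

  # proportional rows -> p = 1
  expect_equal(fisher_2xk(c(4, 8), c(2, 4))$p, 1)

  # degenerate table
  expect_equal(fisher_2xk(c(5, 5), c(0, 0))$p, 1)

  # 2x3 table against the reference implementation
  p_ref <- stats::fisher.test(rbind(c(4, 4, 4), c(1, 1, 10)))$p.value
  expect_equal(fisher_2xk(c(4, 4, 4), c(1, 1, 10))$p, p_ref,
               tolerance = 1e-10)
})

test_that("Fisher enumeration agrees with fisher.test on random small tables", {
  set.seed(7)
  for (rep in 1:40) {
    k <- sample(2:3, 1)
    tab <- matrix(rpois(2 * k, 3), 2, k)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 30)
      next
    p_mine <- fisher_2xk(tab[1, ], tab[2, ])$p
    p_ref <- stats::fisher.test(tab)$p.value
    expect_equal(p_mine, p_ref, tolerance = 1e-8,
                 label = paste("table", paste(tab, collapse = ",")))
  }
})

test_that("Monte-Carlo Fisher approximates enumeration on larger tables", {
  wt <- c(60, 80, 50); alt <- c(20, 10, 40)   # total 260 > cutoff
  f <- fisher_2xk(wt, alt, mc_draws = 2e4)
  expect_equal(f$method, "monte_carlo")
  p_ref <- stats::fisher.test(rbind(wt, alt),
                              simulate.p.value = TRUE, B = 2e4)$p.value
  expect_lt(abs(f$p - p_ref), 0.02)
})

test_that("distribution-shift screen BH-adjusts within the family", {
  rows <- rbind(
    data.frame(variant_id = "v1", chrom = "chr1", pos = 1,
               isoform_id = c("I1", "I2"), sample = "S1",
               wt = c(10, 0), alt = c(0, 10), rate = c(0, 1),
               flag = NA_character_),
    data.frame(variant_id = "v2", chrom = "chr1", pos = 2,
               isoform_id = c("I1", "I2"), sample = "S1",
               wt = c(4, 8), alt = c(2, 4), rate = c(1/3, 1/3),
               flag = NA_character_))
  class(rows) <- c("snv_isoform_matrix", "data.frame")
  res <- test_distribution_shift(rows)
  expect_equal(nrow(res), 2)
  expect_true(res$significant[res$variant_id == "v1"])
  expect_false(res$significant[res$variant_id == "v2"])
})

test_that("switching screen requires uniform high/low rates with a strict low side", {
  mk <- function(rates, samples) {
    data.frame(variant_id = "v1", chrom = "chr1", pos = 1,
               isoform_id = "I1", sample = samples, wt = 10,
               alt = round(10 * rates / (1 - pmin(rates, 0.99))),
               rate = rates, flag = NA_character_,
               stringsAsFactors = FALSE)
  }
  groups <- setNames(rep(c("M", "T"), each = 3),
                     c("M1", "M2", "M3", "T1", "T2", "T3"))
  sw <- screen_switching(mk(c(0.8, 0.7, 0.9, 0.1, 0.0, 0.2), names(groups)),
                         groups)
  expect_true(sw$switching)
  expect_equal(sw$direction, "high_in_M")

  not_uniform <- screen_switching(
    mk(c(0.8, 0.3, 0.9, 0.1, 0.0, 0.2), names(groups)), groups)
  expect_false(not_uniform$switching)

  # rate exactly at the threshold on the low side breaks the call
  boundary <- screen_switching(
    mk(c(0.8, 0.7, 0.9, 0.1, 0.5, 0.2), names(groups)), groups)
  expect_false(boundary$switching)

  # undefined rate in one sample excludes the pair
  m <- mk(c(0.8, 0.7, 0.9, 0.1, 0.0, 0.2), names(groups))
  m$rate[2] <- NA
  excl <- screen_switching(m, groups)
  expect_false(excl$switching)
  expect_match(excl$excluded_reason, "undefined")
})

test_that("switching screen recovers simulated rate flips with high recall", {
  set.seed(2024)
  groups <- setNames(rep(c("M", "T"), each = 3),
                     c("M1", "M2", "M3", "T1", "T2", "T3"))
  n_pair <- 60
  rows <- list(); truth <- logical(n_pair)
  for (i in seq_len(n_pair)) {
    flip <- i <= 40   # 40 true switchers, 20 mid-rate non-switchers
    truth[i] <- flip
    p <- if (flip) c(rep(0.9, 3), rep(0.1, 3)) else rep(0.45, 6)
    alt <- rbinom(6, 20, p)
    rows[[i]] <- data.frame(variant_id = sprintf("v%02d", i),
                            chrom = "chr1", pos = i, isoform_id = "I1",
                            sample = names(groups), wt = 20 - alt,
                            alt = alt, rate = alt / 20,
                            flag = NA_character_, stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, rows)
  class(mat) <- c("snv_isoform_matrix", "data.frame")
  sw <- screen_switching(mat, groups)
  key <- sprintf("v%02d", seq_len(n_pair))
  called <- setNames(sw$switching, sw$variant_id)[key]
  recall <- sum(called & truth) / sum(truth)
  expect_gte(recall, 0.9)
})

test_that("catalogue cross-reference is an exact set intersection", {
  vars <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
                     pos = 1:5, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  cat_tab <- data.frame(chrom = c("chr1", "chr2", "chr3", "chr3", "chr9"),
                        pos = c(1, 4, 5, 5, 1), ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
  out <- crossref_catalogue(vars, cat_tab)
  expect_equal(attr(out, "n_flagged"), 3)
  expect_equal(out$in_catalogue, c(TRUE, FALSE, FALSE, TRUE, TRUE))

  none <- crossref_catalogue(vars, cat_tab[0, ])
  expect_equal(attr(none, "n_flagged"), 0)
})
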