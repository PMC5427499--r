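test_that("genic classification follows the one-nucleotide half-open overlap rule", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(1499L, 1500L), end = c(2000L, 2000L))
  cnvr <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                     class = "dup")
  expect_equal(classify_cnvrs(cnvr, genes[1, ])$genic_class, "genic")
  expect_equal(classify_cnvrs(cnvr, genes[2, ])$genic_class, "nongenic")
})

test_that("genic labels match the all-pairs brute-force oracle", {
  set.seed(31)
  for (rep in 1:10) {
    cnvrs <- data.frame(chrom = sample(c("c1", "c2"), 40, TRUE),
                        start = sample(0:5000, 40))
    cnvrs$end <- cnvrs$start + sample(50:800, 40, TRUE)
    genes <- data.frame(gene_id = sprintf("g%d", 1:25),
                        chrom = sample(c("c1", "c2"), 25, TRUE),
                        start = sample(0:5000, 25))
    genes$end <- genes$start + sample(100:1500, 25, TRUE)
    got <- classify_cnvrs(cnvrs, genes)$genic_class
    expect_identical(got, bf_genic_labels(cnvrs, genes))
    # order invariance
    perm <- sample(nrow(genes))
    expect_identical(classify_cnvrs(cnvrs, genes[perm, ])$genic_class, got)
  }
  # genic + nongenic = total
  expect_equal(sum(table(bf_genic_labels(cnvrs, genes))), nrow(cnvrs))
})

test_that("genic CN is the unweighted mean of overlapping window states", {
  tr <- toy_track(c(1, 2, 2, 3, 1), ratios = c(1, 2, 2, 3, 1))
  gene <- data.frame(gene_id = "g1", chrom = "chr1", start = 300L, end = 900L)
  res <- genic_cn(tr, gene)
  expect_equal(res$cn, mean(c(2, 2, 3)))
  expect_equal(res$cn_int, 2L)

  del <- toy_track(rep(0, 4), ratios = rep(0.02, 4))
  gdel <- data.frame(gene_id = "g2", chrom = "chr1", start = 100L, end = 800L)
  expect_equal(genic_cn(del, gdel)$cn, 0)

  expect_error(genic_cn(tr, data.frame(gene_id = "gX", chrom = "chrZ",
                                       start = 0L, end = 100L)), "chromosome")
})

test_that("genic CN equals the per-base brute-force oracle on random genes", {
  set.seed(33)
  states <- sample(0:4, 300, replace = TRUE, prob = c(0.1, 0.5, 0.2, 0.1, 0.1))
  tr <- toy_track(states, ratios = states)
  for (rep in 1:250) {
    start <- sample(0:(300 * 250 - 200), 1)
    gene <- data.frame(gene_id = "g", chrom = "chr1", start = start,
                       end = start + sample(30:3000, 1))
    gene$end <- min(gene$end, 300 * 250)
    expect_equal(genic_cn(tr, gene)$cn, bf_genic_cn(tr, gene))
  }
})

test_that("genic CN is strand invariant and matches the containing CNVR", {
  tr <- toy_track(c(1, 1, 3, 3, 3, 3, 1), ratios = c(1, 1, 3, 3, 3, 3, 1))
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 600L, end = 1400L,
                     strand = "+")
  gene_minus <- gene; gene_minus$strand <- "-"
  expect_equal(genic_cn(tr, gene)$cn, genic_cn(tr, gene_minus)$cn)
  # gene fully inside one CNVR takes that CNVR's CN
  seg <- segment_track(tr, min_windows = 1)
  expect_equal(genic_cn(tr, gene)$cn, seg$cn[1])
})

test_that("genic_cn_matrix agrees with per-gene genic_cn", {
  set.seed(34)
  states1 <- sample(0:3, 200, replace = TRUE)
  states2 <- sample(0:3, 200, replace = TRUE)
  tracks <- list(s1 = toy_track(states1, ratios = states1),
                 s2 = toy_track(states2, ratios = states2))
  genes <- data.frame(gene_id = sprintf("g%d", 1:30), chrom = "chr1",
                      start = sort(sample(0:(200 * 250 - 2000), 30)))
  genes$end <- genes$start + sample(200:1800, 30, TRUE)
  gcm <- genic_cn_matrix(tracks, genes)
  for (i in sample(30, 8)) {
    for (s in c("s1", "s2")) {
      expect_equal(gcm$cn[i, s],
                   genic_cn(tracks[[s]], genes[i, ])$cn)
    }
  }
  expect_identical(gcm$cn_int, matrix(as.integer(round_half_up(gcm$cn)),
                                      nrow = 30, dimnames = dimnames(gcm$cn)))
})

test_that("dup/del comparison reports direction and p-values", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L, end = 100000L)
  mk <- function(n_dup, n_del) {
    start <- c(seq_len(n_dup) * 10L, 50000L + seq_len(n_del) * 10L)
    data.frame(chrom = "chr1", start = start, end = start + 5L,
               class = c(rep("dup", n_dup), rep("del", n_del)))
  }
  cohort <- replicate(6, mk(3, 9), simplify = FALSE)
  names(cohort) <- sprintf("s%d", 1:6)
  res <- dup_del_comparison(cohort, genes)
  expect_equal(res$genic$direction, "del > dup")
  expect_gt(res$genic$median_del, res$genic$median_dup)
  expect_true(res$genic$p_value > 0 && res$genic$p_value <= 1)

  same <- replicate(5, mk(4, 4), simplify = FALSE)
  names(same) <- sprintf("s%d", 1:5)
  res2 <- dup_del_comparison(same, genes)
  expect_gt(res2$genic$p_value, 0.9)
  expect_equal(res2$genic$direction, "no difference")
})

test_that("a deletion-skewed cohort shows a significant deletion excess", {
  g <- build_genome(4, 750000, 0.4, seed = 35)
  cfg <- sim_config(n_strains = 50, n_loci = 100, p_duplication = 0.2,
                    seed = 36)
  sim <- simulate_population(g, cfg)
  genes <- simulate_genes(g, seed = 37)
  cnvrs <- truth_to_cnvrs(sim$truth)
  res <- dup_del_comparison(cnvrs, genes)
  expect_lt(res$genic$p_value, 0.05)
  expect_lt(res$nongenic$p_value, 0.05)
  expect_equal(res$genic$direction, "del > dup")
  expect_equal(res$nongenic$direction, "del > dup")
})

test_that("in-frame fraction follows length arithmetic", {
  x <- data.frame(chrom = "c", start = c(0L, 0L, 0L),
                  end = c(750L, 500L, 300L), class = "dup")
  expect_equal(inframe_fraction(x), 2 / 3)
  expect_warning(f0 <- inframe_fraction(x[0, ]), "undefined")
  expect_true(is.na(f0))

  # window-multiple lengths: 250 = 1 mod 3, so length mod 3 cycles with the
  # window count; fraction equals the fraction of window counts divisible by 3
  set.seed(38)
  wcount <- sample(1:40, 200, replace = TRUE)
  y <- data.frame(chrom = "c", start = 0L, end = wcount * 250L, class = "dup")
  expect_equal(inframe_fraction(y), mean(wcount %% 3 == 0))
})

test_that("gene annotations read identically from BED and GFF3", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chrI",
                      start = c(100L, 2000L, 5000L),
                      end = c(1000L, 3500L, 6200L),
                      strand = c("+", "-", "+"))
  bed <- tempfile(fileext = ".bed")
  write.table(data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                         0L, genes$strand),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chrI\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$start + 1L, genes$end, genes$strand,
                       genes$gene_id)), gff)
  from_bed <- read_genes(bed)
  from_gff <- read_genes(gff)
  expect_equal(from_bed[, c("gene_id", "chrom", "start", "end", "strand")],
               from_gff[, c("gene_id", "chrom", "start", "end", "strand")])
  expect_equal(from_bed$start, genes$start)
  expect_equal(from_gff$end, genes$end)
})
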