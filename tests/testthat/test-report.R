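test_that("cohort summary arithmetic matches hand computation", {
  g <- build_genome(16, 750000, 0.4, seed = 61)  # 12 Mb genome
  mk <- function(n, len = 1000L) {
    start <- seq(30000L, by = 5000L, length.out = n)
    data.frame(chrom = "chrI", start = start, end = start + len,
               cn = 2L, class = rep(c("dup", "del"), length.out = n))
  }
  calls <- list(s1 = mk(3), s2 = mk(5))
  cs <- cohort_summary(calls, g)
  expect_equal(cs$aggregate$mean_cnvrs, 4)
  expect_equal(cs$aggregate$median_cnvrs, 4)
  expect_equal(cs$aggregate$se_cnvrs, sd(c(3, 5)) / sqrt(2))
  # 480 kb on a 12 Mb genome = 4%
  calls2 <- list(s1 = mk(1, len = 480000L))
  cs2 <- cohort_summary(calls2, g)
  expect_equal(cs2$strains$genome_affected_fraction, 0.04)
  # per-strain dup + del = total
  expect_equal(cs$strains$n_dup + cs$strains$n_del, cs$strains$n_cnvrs)
})

test_that("cohort summary equals a brute-force recount from written BED files", {
  g <- build_genome(2, 400000, 0.4, seed = 62)
  sim <- simulate_population(g, sim_config(n_strains = 4, n_loci = 15, seed = 63))
  calls <- call_cohort(sim$tracks, g)
  cs <- cohort_summary(calls, g)
  d <- tempfile(); dir.create(d)
  reread <- list()
  for (s in names(calls)) {
    p <- file.path(d, paste0(s, ".bed"))
    write_cnvrs(calls[[s]], p)
    reread[[s]] <- read_cnvrs(p)
  }
  for (i in seq_along(reread)) {
    x <- reread[[i]]
    expect_equal(nrow(x), cs$strains$n_cnvrs[i])
    expect_equal(sum(x$end - x$start), cs$strains$genome_affected_bp[i])
    expect_equal(sum(x$class == "dup"), cs$strains$n_dup[i])
  }
})

test_that("size distribution bins fractions per series", {
  x <- data.frame(chrom = "c", start = 0L, end = c(500L, 750L, 6000L),
                  class = c("dup", "dup", "del"))
  sd_ <- size_distribution(x, bin_edges = c(0, 1000, 5000, 10000))
  all_row <- sd_[sd_$series == "all", ]
  expect_equal(all_row$fraction, c(2 / 3, 0, 1 / 3))
  expect_equal(sum(all_row$n), 3)
  for (s in unique(sd_$series)) {
    expect_equal(sum(sd_$fraction[sd_$series == s]), 1)
  }
  expect_warning(e <- size_distribution(x[0, ]), "empty")
  expect_equal(nrow(e), 0)
})

test_that("simulated dup and del size modes land in the documented bins", {
  g <- build_genome(16, 750000, 0.4, seed = 64)
  sim <- simulate_population(g, sim_config(n_strains = 1, n_loci = 400,
                                           p_duplication = 0.5, seed = 65))
  ev <- sim$truth$events
  x <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                  class = ev$class)
  sd_ <- size_distribution(x)
  dup <- sd_[sd_$series == "dup", ]
  del <- sd_[sd_$series == "del", ]
  expect_equal(dup$bin[which.max(dup$fraction)], "(0,1e+03]")
  expect_equal(del$bin[which.max(del$fraction)], "(5e+03,7e+03]")
})

test_that("gene family view reproduces per-gene strain proportions", {
  set.seed(66)
  n <- 132
  cn_int <- rbind(
    THI5_like = c(rep(0L, 121), rep(1L, 11)),
    MAL31_like = c(rep(2L, 100), rep(1L, 32)),
    flat = rep(1L, n))
  colnames(cn_int) <- sprintf("s%03d", seq_len(n))
  gcm <- structure(list(
    genes = data.frame(gene_id = rownames(cn_int), chrom = "chr1",
                       start = c(0L, 2000L, 4000L),
                       end = c(1000L, 3000L, 5000L)),
    cn = cn_int + 0, cn_int = cn_int), class = "genic_cn_matrix")
  fv <- gene_family_view(gcm, c("THI5_like", "MAL31_like", "flat"))
  p <- fv$proportions
  expect_equal(p$pct_del[1], 91.67)
  expect_equal(round(100 * p$prop_dup[2], 1), 75.8)
  expect_equal(p$prop_unchanged[3], 1)
  expect_equal(p$prop_dup + p$prop_del + p$prop_unchanged, rep(1, 3))
  # brute-force recount
  for (i in 1:3) {
    expect_equal(p$n_dup[i], sum(cn_int[i, ] > 1))
    expect_equal(p$n_del[i], sum(cn_int[i, ] < 1))
  }
  expect_error(gene_family_view(gcm, "missing_gene"), "absent")
})

test_that("intragenic profiles label intact, partial and block structure", {
  n <- 2400  # 60 kb at 25 bp
  g <- toy_genome(len = 25 * n, cen = c(29500, 30500))
  base <- data.frame(chrom = "chr1", start = 25L * (seq_len(n) - 1L),
                     depth = 40L, gc = 0.45)
  gene <- data.frame(gene_id = "FLO_like", chrom = "chr1", start = 10000L,
                     end = 14000L)
  p0 <- intragenic_profile(base, g, gene, fine_window = 25)
  expect_equal(p0$label, "intact")
  expect_equal(nrow(p0$blocks), 0)

  # 3' half duplicated
  half <- base
  sel <- half$start >= 12000 & half$start < 14000
  half$depth[sel] <- 80L
  p1 <- intragenic_profile(half, g, gene, fine_window = 25)
  expect_equal(p1$label, "partial_duplication")
  expect_gt(p1$frac_dup, 0.4)
  expect_lt(p1$frac_dup, 0.6)

  # localized noisy 2x block: boundaries recovered within 2 fine windows
  set.seed(67)
  noisy <- base
  noisy$depth <- rnbinom(n, size = 400, mu = 40)
  block <- noisy$start >= 10500 & noisy$start < 11500
  noisy$depth[block] <- rnbinom(sum(block), size = 400, mu = 80)
  p2 <- intragenic_profile(noisy, g, gene, fine_window = 25)
  dup_blocks <- p2$blocks[p2$blocks$class == "dup", ]
  main <- dup_blocks[which.max(dup_blocks$end - dup_blocks$start), ]
  expect_lte(abs(main$start - 10500), 2 * 25)
  expect_lte(abs(main$end - 11500), 2 * 25)
})

test_that("the demo pipeline runs, manifests its outputs and fails loudly", {
  out <- tempfile("pipe")
  res <- run_pipeline(pipeline_config(out, seed = 11))
  expect_gte(nrow(res$manifest), 6)
  expect_true(all(file.exists(file.path(out, res$manifest$file))))
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  # per-strain dup + del = total in the written summary
  ss <- read.delim(file.path(out, "strain_summary.tsv"))
  expect_equal(ss$n_dup + ss$n_del, ss$n_cnvrs)

  # missing depth directory: the error names the stage and the path
  bad <- pipeline_config(tempfile("bad"), seed = 1, simulate = FALSE,
                         depth_dir = "/nonexistent/depth_dir")
  expect_error(run_pipeline(bad), "load_depth.*nonexistent|nonexistent.*not found")
})

test_that("heat-map matrix round-trips through TSV export", {
  out <- tempfile("pipe2")
  res <- run_pipeline(pipeline_config(out, seed = 12))
  tab <- read.delim(file.path(out, "cn_matrix.tsv"), check.names = FALSE)
  m <- as.matrix(tab[, colnames(res$cn_matrix$cn), drop = FALSE])
  rownames(m) <- tab$locus_id
  storage.mode(m) <- "integer"
  expect_identical(m, res$cn_matrix$cn)
  expect_equal(rowSums(m), rowSums(res$cn_matrix$cn))
})
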