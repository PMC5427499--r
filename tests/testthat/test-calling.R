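test_that("normalization maps uniform depth to ratio 1 and a step region to its CN", {
  g <- toy_genome(len = 250 * 400)
  tr <- normalize_track(flat_depth(400), g)
  expect_equal(tr$ratio, rep(1, 400))
  expect_equal(tr$cn_state, rep(1L, 400))

  d <- flat_depth(400)
  d$depth[101:110] <- 60
  tr2 <- normalize_track(d, g)
  expect_equal(tr2$ratio[101:110], rep(2, 110 - 101 + 1))
  expect_equal(tr2$cn_state[101:110], rep(2L, 10))
  expect_equal(tr2$cn_state[-(101:110)], rep(1L, 390))
})

test_that("binned-median GC correction removes an injected GC bias", {
  set.seed(42)
  n <- 2500
  g <- toy_genome(len = 250 * n)
  gc <- pmin(pmax(0.45 + 0.1 * sin(seq_len(n) / 60) + rnorm(n, 0, 0.02),
                  0.3), 0.6)
  bias <- 1 - 1.5 * (gc - 0.45)  # strong linear GC effect
  depth <- rnbinom(n, size = 200, mu = 30 * bias)
  d <- data.frame(chrom = "chr1", start = 250 * (seq_len(n) - 1L),
                  depth = depth, gc = gc)
  raw_r <- suppressWarnings(cor(depth, gc))
  expect_lt(raw_r, -0.3)
  tr <- normalize_track(d, g)
  expect_lt(abs(cor(tr$ratio, tr$gc)), 0.05)
})

test_that("normalization is scale invariant and deterministic", {
  set.seed(7)
  n <- 800
  g <- toy_genome(len = 250 * n)
  d <- data.frame(chrom = "chr1", start = 250 * (seq_len(n) - 1L),
                  depth = rnbinom(n, size = 100, mu = 30),
                  gc = round(runif(n, 0.35, 0.55), 3))
  d$depth[201:220] <- d$depth[201:220] * 3
  tr1 <- normalize_track(d, g)
  d3 <- d; d3$depth <- d3$depth * 7L
  tr3 <- normalize_track(d3, g)
  expect_equal(tr3$ratio, tr1$ratio)
  expect_identical(tr3$cn_state, tr1$cn_state)
  c1 <- call_strain(d, g)
  c3 <- call_strain(d3, g)
  expect_equal(as.data.frame(c1), as.data.frame(c3))
  expect_equal(as.data.frame(call_strain(d, g)), as.data.frame(c1))
})

test_that("normalization rejects corrupt input", {
  g <- toy_genome(len = 250 * 200)
  d <- flat_depth(200)
  d$depth[1:150] <- 0
  expect_error(normalize_track(d, g), "zero depth")
  d2 <- flat_depth(200)
  d2$start[5] <- 9999L
  expect_error(normalize_track(d2, g), "tile")
})

test_that("segmentation turns state runs into CNVRs", {
  tr <- toy_track(c(1, 1, 2, 2, 2, 1), ratios = c(1, 1, 2.1, 1.9, 2, 1))
  seg <- segment_track(tr, min_windows = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 500)
  expect_equal(seg$end, 1250)
  expect_equal(seg$cn, 2L)
  expect_equal(seg$class, "dup")

  tr2 <- toy_track(c(0, 0, 1, 0, 0), ratios = c(0.1, 0, 1, 0.2, 0))
  seg2 <- segment_track(tr2, min_windows = 2)
  expect_equal(nrow(seg2), 2)
  expect_equal(seg2$cn, c(0L, 0L))
  expect_equal(seg2$n_windows, c(2L, 2L))

  expect_equal(nrow(segment_track(toy_track(rep(1, 20)))), 0)
})

test_that("every window belongs to at most one candidate CNVR", {
  set.seed(11)
  for (rep in 1:20) {
    states <- sample(0:3, 60, replace = TRUE, prob = c(0.1, 0.6, 0.2, 0.1))
    tr <- toy_track(states, ratios = states + runif(60, -0.2, 0.2))
    seg <- segment_track(tr, min_windows = 1)
    covered <- integer(0)
    if (nrow(seg)) {
      for (i in seq_len(nrow(seg))) {
        covered <- c(covered, seq(seg$start[i], seg$end[i] - 250, by = 250))
      }
    }
    expect_false(any(duplicated(covered)))
    expect_true(all(seg$end > seg$start))
    expect_true(all((seg$end - seg$start) %% 250 == 0))
    expect_true(all(seg$cn != 1L))
  }
})

test_that("rank-sum significance matches exact enumeration on small samples", {
  tr <- toy_track(c(2, 2, 1, 1, 1, 1, 1),
                  ratios = c(2.05, 1.95, 1.02, 0.98, 1.01, 0.99, 1.03))
  cand <- data.frame(chrom = "chr1", start = 0L, end = 500L)
  res <- test_significance(cand, tr)
  oracle <- bf_ranksum_p(c(2.05, 1.95), c(1.02, 0.98, 1.01, 0.99, 1.03))
  expect_equal(res$p_value, oracle)

  # smallest admissible case: 1 candidate window vs 3 neutral windows
  tr1 <- toy_track(c(3, 1, 1, 1), ratios = c(3, 1.01, 0.99, 1.02))
  r1 <- test_significance(data.frame(chrom = "chr1", start = 0L, end = 250L), tr1)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_equal(r1$p_value, bf_ranksum_p(3, c(1.01, 0.99, 1.02)))
})

test_that("a strong candidate is retained with a tiny p-value", {
  set.seed(13)
  ratios <- c(rnorm(20, 2, 0.1), rnorm(500, 1, 0.1))
  states <- c(rep(2, 20), rep(1, 500))
  tr <- toy_track(states, ratios = ratios)
  cand <- data.frame(chrom = "chr1", start = 0L, end = 20L * 250L)
  res <- test_significance(cand, tr)
  expect_lt(res$p_value, 1e-10)
  expect_true(res$retained)
})

test_that("embedded events are recovered with high reciprocal overlap", {
  g <- build_genome(2, 500000, 0.4, seed = 21)
  cfg <- sim_config(n_strains = 3, n_loci = 10, carrier_freq = 1,
                    min_event_windows = 4, base_depth = 30, seed = 22)
  sim <- simulate_population(g, cfg)
  calls <- call_cohort(sim$tracks, g)
  ev <- evaluate_calls(calls, sim$truth, reciprocal = 0.8)
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$precision, 0.85)
})

test_that("an event-free strain yields at most sporadic false calls", {
  g <- build_genome(2, 400000, 0.4, seed = 23)
  sim <- simulate_population(g, sim_config(n_strains = 1, n_loci = 0, seed = 24))
  calls <- call_strain(sim$tracks[[1]], g)
  expect_lte(nrow(calls), 2)
})

test_that("called CN tracks the simulated dose for CN 0 and 2-4", {
  g <- build_genome(4, 750000, 0.4, seed = 25)
  cfg <- sim_config(n_strains = 4, n_loci = 90, p_duplication = 0.6,
                    carrier_freq = 1, max_extra_copies = 3,
                    min_event_windows = 4, seed = 26)
  sim <- simulate_population(g, cfg)
  calls <- call_cohort(sim$tracks, g)
  hits <- list()
  for (s in names(calls)) {
    cs <- calls[[s]]
    ev <- sim$truth$events
    kvec <- sim$truth$cn[, s]
    for (i in seq_len(nrow(ev))) {
      k <- unname(kvec[i])
      if (k == 1L) next
      ov <- cs$chrom == ev$chrom[i] & cs$start < ev$end[i] & cs$end > ev$start[i]
      called <- if (any(ov)) cs$cn[which(ov)[which.max(
        pmin(cs$end[ov], ev$end[i]) - pmax(cs$start[ov], ev$start[i]))]]
      else NA_integer_
      key <- as.character(k)
      hits[[key]] <- c(hits[[key]], identical(called, k))
    }
  }
  for (k in c("0", "2", "3")) {
    expect_gte(mean(hits[[k]]), 0.9)
  }
  if (length(hits[["4"]]) >= 5) expect_gte(mean(hits[["4"]]), 0.9)
})

test_that("falls back to genome-wide neutral windows when a chromosome has none", {
  tr2 <- rbind(toy_track(rep(2, 6), chrom = "chrA"),
               toy_track(rep(1, 50), chrom = "chrB"))
  tr2 <- cnvdiv:::keep_track_attrs(tr2, toy_track(rep(1, 2)))
  cand <- data.frame(chrom = "chrA", start = 0L, end = 1500L)
  expect_message(res <- test_significance(cand, tr2), "genome-wide")
  expect_lt(res$p_value, 0.05)
})
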