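# Independent brute-force oracles and small fixture builders.
# Oracles deliberately use naive enumeration (double loops, per-base scans,
# union-find) so they share no code path with the package implementation.

# --- fixtures -----------------------------------------------------------

# a one-chromosome genome without randomness
toy_genome <- function(len = 200000, chrom = "chr1",
                       cen = c(round(len / 2) - 500, round(len / 2) + 500)) {
  genome_model(chromosomes = data.frame(name = chrom, length = len),
               centromeres = data.frame(chrom = chrom, start = cen[1],
                                        end = cen[2]))
}

# a normalized window_track built directly from states/ratios
toy_track <- function(states, ratios = states, window = 250, chrom = "chr1",
                      strain = "toy") {
  n <- length(states)
  tr <- data.frame(chrom = chrom, start = as.integer(window * (seq_len(n) - 1L)),
                   depth = ratios * 30, gc = 0.45, ratio = ratios,
                   cn_state = as.integer(states), masked = FALSE)
  attr(tr, "window") <- as.integer(window)
  attr(tr, "strain_id") <- strain
  attr(tr, "normalized") <- TRUE
  class(tr) <- c("window_track", "data.frame")
  tr
}

# flat-GC depth track at uniform depth with an optional elevated region
flat_depth <- function(n_windows, depth = 30, window = 250, chrom = "chr1") {
  data.frame(chrom = chrom,
             start = as.integer(window * (seq_len(n_windows) - 1L)),
             depth = depth, gc = 0.45)
}

# --- oracles ------------------------------------------------------------

# PIC by explicit frequency-table counting
bf_pic <- function(v) {
  tot <- 0
  for (a in unique(v)) tot <- tot + (sum(v == a) / length(v))^2
  1 - tot
}

# genic/nongenic labels by all-pairs half-open overlap
bf_genic_labels <- function(cnvrs, genes) {
  lab <- character(nrow(cnvrs))
  for (i in seq_len(nrow(cnvrs))) {
    hit <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (cnvrs$chrom[i] == genes$chrom[j] &&
          cnvrs$start[i] < genes$end[j] && cnvrs$end[i] > genes$start[j]) {
        hit <- TRUE
        break
      }
    }
    lab[i] <- if (hit) "genic" else "nongenic"
  }
  lab
}

# genic CN by per-base scan: collect the windows containing each gene base,
# average their states once each
bf_genic_cn <- function(track, gene) {
  w <- attr(track, "window")
  t <- track[track$chrom == gene$chrom, ]
  wins <- integer(0)
  for (b in gene$start:(gene$end - 1L)) {
    i <- which(t$start <= b & b < t$start + w)
    if (length(i)) wins <- c(wins, i)
  }
  mean(t$cn_state[sort(unique(wins))])
}

# connected components of interval overlap by union-find
bf_union_components <- function(iv) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && iv$chrom[i] == iv$chrom[j] &&
        iv$start[i] < iv$end[j] && iv$end[i] > iv$start[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# context label by per-base zone membership
bf_context_label <- function(locus, zones, definition = "A") {
  zdf <- if (definition == "A") zones$definition_a else zones$definition_b
  in_zone <- function(df) {
    any(vapply(seq_len(nrow(df)), function(k) {
      df$chrom[k] == locus$chrom &&
        any(seq(locus$start, locus$end - 1L) >= df$start[k] &
              seq(locus$start, locus$end - 1L) < df$end[k])
    }, logical(1)))
  }
  if (in_zone(zdf)) "subtelomeric"
  else if (in_zone(zones$pericentromeric)) "pericentromeric"
  else "interstitial"
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
bf_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  w_all <- apply(combs, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
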