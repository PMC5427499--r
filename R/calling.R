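#' Caller configuration
#'
#' Parameters of the windowed read-depth CN caller. Defaults follow common
#' yeast practice: 250 bp windows, 25 GC bins for the binned-median bias
#' correction, a 7 kb telomere/centromere mask excluded from the normalization
#' reference, candidate regions of at least 2 windows, and retention at
#' rank-sum p < 0.05.
#'
#' @param window window size in bp.
#' @param gc_bins number of equal-width GC bins for the bias correction.
#' @param mask_telocentromeric bp around chromosome ends and centromeres whose
#'   windows are excluded when estimating the per-bin reference medians.
#' @param min_windows minimum number of windows in a candidate CNVR.
#' @param alpha significance level for candidate retention.
#' @return an object of class \code{calling_config}.
#' @export
calling_config <- function(window = 250, gc_bins = 25,
                           mask_telocentromeric = 7000,
                           min_windows = 2, alpha = 0.05) {
  stopifnot(window > 0, gc_bins >= 1, mask_telocentromeric >= 0,
            min_windows >= 1, alpha > 0, alpha < 1)
  structure(list(window = as.integer(window), gc_bins = as.integer(gc_bins),
                 mask_telocentromeric = as.integer(mask_telocentromeric),
                 min_windows = as.integer(min_windows), alpha = alpha),
            class = "calling_config")
}

#' Normalize a windowed depth track to copy-number ratios
#'
#' Corrects GC bias and depth-of-coverage differences by binned-median
#' normalization: each window's depth is divided by the median depth of all
#' windows in the same GC bin (equal-width bins across the observed GC range),
#' where the reference medians are computed excluding windows within
#' \code{mask_telocentromeric} bp of chromosome ends or centromeres. Ratios
#' are then rescaled so the genome-wide median ratio is 1, and integer CN
#' states are assigned by round-half-up (so ratios in [0.5, 1.5) are the
#' neutral state 1). The result is invariant to multiplying all depths by a
#' constant.
#'
#' @param track depth data.frame (\code{chrom}, \code{start}, \code{depth},
#'   \code{gc}) or a path readable by [read_depth()]. Windows must tile each
#'   chromosome in steps of \code{window} bp.
#' @param genome a [genome_model()].
#' @param window window size in bp.
#' @param gc_bins number of GC bins.
#' @param mask_telocentromeric mask span in bp.
#' @return the track with added columns \code{ratio}, \code{cn_state},
#'   \code{masked}; class \code{window_track}.
#' @export
normalize_track <- function(track, genome, window = 250, gc_bins = 25,
                            mask_telocentromeric = 7000) {
  if (is.character(track)) track <- read_depth(track)
  stopifnot(is.data.frame(track),
            all(c("chrom", "start", "depth", "gc") %in% names(track)),
            inherits(genome, "genome_model"))
  strain <- attr(track, "strain_id") %||% "strain"
  if (any(track$gc < 0 | track$gc > 1)) stop_fmt("gc values must be in [0, 1]")
  chroms <- genome$chromosomes$name
  if (!all(track$chrom %in% chroms))
    stop_fmt("track chromosome absent from genome: %s",
             paste(setdiff(unique(track$chrom), chroms), collapse = ", "))
  track <- track[order(match(track$chrom, chroms), track$start), , drop = FALSE]
  rownames(track) <- NULL
  # windows must tile each chromosome in fixed steps
  for (ch in unique(track$chrom)) {
    st <- track$start[track$chrom == ch]
    if (!identical(as.integer(st), as.integer(seq(0L, by = window, length.out = length(st)))))
      stop_fmt("windows on %s do not tile the chromosome at %d bp", ch, window)
  }
  if (mean(track$depth == 0) > 0.5)
    stop_fmt("more than 50%% of windows have zero depth; input looks corrupt")

  clen <- stats::setNames(genome$chromosomes$length, chroms)
  cen <- genome$centromeres
  m <- mask_telocentromeric
  L <- clen[track$chrom]
  cs <- cen$start[match(track$chrom, cen$chrom)]
  ce <- cen$end[match(track$chrom, cen$chrom)]
  wend <- track$start + window
  masked <- track$start < m | wend > L - m |
    (track$start < ce + m & wend > cs - m)

  gcr <- range(track$gc)
  if (diff(gcr) < 1e-8) {
    bin <- rep(1L, nrow(track))
    nb <- 1L
  } else {
    breaks <- seq(gcr[1], gcr[2], length.out = gc_bins + 1)
    bin <- findInterval(track$gc, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    nb <- gc_bins
  }
  ref <- !masked
  if (!any(ref)) ref <- rep(TRUE, nrow(track))  # degenerate tiny genome
  med <- tapply(track$depth[ref], factor(bin[ref], levels = seq_len(nb)),
                stats::median)
  glob <- stats::median(track$depth[ref])
  if (!is.finite(glob) || glob <= 0)
    stop_fmt("median reference depth is zero; cannot normalize")
  empty <- !is.finite(med) | med <= 0
  if (any(empty[sort(unique(bin))]))
    warning(sprintf("strain %s: %d empty GC bin(s); falling back to global median",
                    strain, sum(empty[sort(unique(bin))])))
  med[empty] <- glob
  ratio <- track$depth / as.numeric(med[bin])
  scale <- stats::median(ratio)
  if (!is.finite(scale) || scale <= 0)
    stop_fmt("genome-wide median ratio is zero; cannot rescale")
  track$ratio <- ratio / scale
  track$cn_state <- as.integer(pmax(0, round_half_up(track$ratio)))
  track$masked <- masked
  attr(track, "window") <- as.integer(window)
  attr(track, "strain_id") <- strain
  attr(track, "normalized") <- TRUE
  class(track) <- c("window_track", "data.frame")
  track
}

#' Segment a normalized track into candidate CNVRs
#'
#' Groups maximal runs of consecutive windows on the same side of the neutral
#' state (all duplicated, state > 1, or all deleted, state < 1) into candidate
#' regions, discards runs shorter than \code{min_windows}, and assigns each
#' region the integer CN obtained by round-half-up of the mean window ratio
#' over the run. Candidate intervals are disjoint and sorted by position.
#'
#' @param track a normalized \code{window_track}.
#' @param min_windows minimum run length in windows.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{cn}, \code{class}, \code{n_windows}, \code{p_value} (NA until
#'   tested).
#' @export
segment_track <- function(track, min_windows = 2) {
  stopifnot(inherits(track, "window_track"), !is.null(track$cn_state))
  w <- attr(track, "window")
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    side <- sign(t$cn_state - 1L)
    r <- rle(side)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != 0 & r$lengths >= min_windows)
    for (k in keep) {
      i <- starts[k]:ends[k]
      cn <- as.integer(round_half_up(mean(t$ratio[i])))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = t$start[starts[k]],
        end = t$start[ends[k]] + w,
        cn = cn,
        class = if (r$values[k] > 0) "dup" else "del",
        n_windows = length(i))
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      cn = integer(), class = character(),
                      n_windows = integer())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(match(res$chrom, unique(track$chrom)), res$start), ,
               drop = FALSE]
  }
  res$p_value <- rep(NA_real_, nrow(res))
  rownames(res) <- NULL
  res
}

#' Rank-sum significance test for a candidate CNVR
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test of the candidate's
#' window ratios against the neutral windows (CN state 1) of the same
#' chromosome, excluding windows inside the candidate. If the chromosome has
#' no neutral windows the comparison falls back to genome-wide neutral
#' windows (with a message). Small samples use the exact null distribution;
#' larger ones the normal approximation with continuity correction (the
#' default behaviour of [stats::wilcox.test()]).
#'
#' @param candidate one-row data.frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @param track the normalized \code{window_track} the candidate came from.
#' @param alpha retention threshold.
#' @return the candidate row with \code{p_value} and logical \code{retained}
#'   columns.
#' @export
test_significance <- function(candidate, track, alpha = 0.05) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1,
            inherits(track, "window_track"))
  w <- attr(track, "window")
  on_ch <- track$chrom == candidate$chrom
  in_cand <- on_ch & track$start < candidate$end &
    (track$start + w) > candidate$start
  cand <- track$ratio[in_cand]
  neutral <- track$ratio[on_ch & track$cn_state == 1L & !in_cand]
  if (!length(neutral)) {
    message("no neutral windows on ", candidate$chrom,
            "; comparing against genome-wide neutral windows")
    neutral <- track$ratio[track$cn_state == 1L & !in_cand]
  }
  if (!length(cand) || !length(neutral))
    stop_fmt("cannot test candidate %s:%d-%d: no windows available",
             candidate$chrom, candidate$start, candidate$end)
  p <- suppressWarnings(stats::wilcox.test(cand, neutral,
                                           alternative = "two.sided",
                                           correct = TRUE)$p.value)
  candidate$p_value <- p
  candidate$retained <- is.finite(p) && p < alpha
  candidate
}

#' Call CNVRs for one strain
#'
#' Composition of the three caller stages: [normalize_track()] (skipped if
#' the input is already a normalized track), [segment_track()], and
#' [test_significance()] on every candidate; only candidates with
#' p < \code{alpha} are retained. Deterministic: the same input always yields
#' the same calls.
#'
#' @param depth depth data.frame, file path, or normalized
#'   \code{window_track}.
#' @param genome a [genome_model()].
#' @param config a [calling_config()].
#' @return data.frame of significant CNVRs (class \code{cnvr_set}) with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{cn}, \code{class},
#'   \code{n_windows}, \code{p_value}; attributes \code{strain_id},
#'   \code{alpha}.
#' @examples
#' g <- build_genome(1, 200000, 0.5, seed = 1)
#' sim <- simulate_population(g, sim_config(n_strains = 1, n_loci = 3,
#'                                          carrier_freq = 1, seed = 3))
#' call_strain(sim$tracks[[1]], g)
#' @export
call_strain <- function(depth, genome, config = calling_config()) {
  track <- if (inherits(depth, "window_track") && isTRUE(attr(depth, "normalized")))
    depth
  else normalize_track(depth, genome, window = config$window,
                       gc_bins = config$gc_bins,
                       mask_telocentromeric = config$mask_telocentromeric)
  cand <- segment_track(track, min_windows = config$min_windows)
  if (nrow(cand)) {
    p <- vapply(seq_len(nrow(cand)), function(i) {
      test_significance(cand[i, , drop = FALSE], track,
                        alpha = config$alpha)$p_value
    }, numeric(1))
    cand$p_value <- p
    cand <- cand[is.finite(p) & p < config$alpha, , drop = FALSE]
    rownames(cand) <- NULL
  }
  attr(cand, "strain_id") <- attr(track, "strain_id")
  attr(cand, "alpha") <- config$alpha
  class(cand) <- c("cnvr_set", "data.frame")
  cand
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set (%s): %d CNVRs (%d dup / %d del)\n",
              attr(x, "strain_id") %||% "strain", nrow(x),
              sum(x$class == "dup"), sum(x$class == "del")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Call CNVRs for a cohort of strains
#'
#' @param depths named list of depth tracks (or file paths).
#' @param genome a [genome_model()].
#' @param config a [calling_config()].
#' @return named list of \code{cnvr_set} data.frames.
#' @export
call_cohort <- function(depths, genome, config = calling_config()) {
  stopifnot(is.list(depths), !is.null(names(depths)))
  out <- lapply(names(depths), function(s) {
    tr <- depths[[s]]
    if (is.data.frame(tr) && is.null(attr(tr, "strain_id")))
      attr(tr, "strain_id") <- s
    tryCatch(call_strain(tr, genome, config),
             error = function(e) stop_fmt("strain %s: %s", s,
                                          conditionMessage(e)))
  })
  stats::setNames(out, names(depths))
}

#' Plot a normalized track
#'
#' Copy-number ratio along one chromosome with windows colored by CN state;
#' a quick visual check of normalization and segmentation.
#'
#' @param x a \code{window_track}.
#' @param chrom chromosome to plot (default: first in the track).
#' @param ... passed to [plot()].
#' @export
plot.window_track <- function(x, chrom = NULL, ...) {
  chrom <- chrom %||% x$chrom[1]
  t <- x[x$chrom == chrom, ]
  col <- ifelse(t$cn_state == 1L, "grey60",
                ifelse(t$cn_state > 1L, "firebrick", "navy"))
  graphics::plot(t$start / 1000, t$ratio, col = col, pch = 16, cex = 0.4,
                 xlab = sprintf("%s position (kb)", chrom),
                 ylab = "CN ratio", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Compare calls with ground truth
#'
#' Matches per-strain calls against the simulator's truth at a reciprocal
#' overlap threshold: a truth event of a strain counts as recovered if some
#' call of that strain overlaps it by at least \code{reciprocal} of both
#' interval lengths, and vice versa for precision.
#'
#' @param calls named list of per-strain CNVR data.frames.
#' @param truth truth list (\code{events} + \code{cn} matrix).
#' @param reciprocal reciprocal overlap threshold in (0, 1].
#' @return list with \code{precision}, \code{recall}, \code{n_truth},
#'   \code{n_calls}, and a per-strain data.frame; class
#'   \code{cnv_evaluation}.
#' @export
evaluate_calls <- function(calls, truth, reciprocal = 0.8) {
  stopifnot(reciprocal > 0, reciprocal <= 1)
  strains <- names(calls)
  stopifnot(all(strains %in% colnames(truth$cn)))
  rows <- lapply(strains, function(s) {
    tev <- truth$events[truth$cn[, s] != 1L, , drop = FALSE]
    cs <- calls[[s]]
    nt <- nrow(tev); nc <- nrow(cs)
    th <- ch <- 0L
    if (nt > 0 && nc > 0) {
      lev <- unique(c(tev$chrom, cs$chrom))
      gt <- as_granges0(tev$chrom, tev$start, tev$end, seqlevels = lev)
      gc_ <- as_granges0(cs$chrom, cs$start, cs$end, seqlevels = lev)
      h <- GenomicRanges::findOverlaps(gt, gc_)
      if (length(h)) {
        qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
        ov <- GenomicRanges::width(GenomicRanges::pintersect(gt[qi], gc_[si]))
        ok <- ov >= reciprocal * GenomicRanges::width(gt[qi]) &
          ov >= reciprocal * GenomicRanges::width(gc_[si])
        th <- length(unique(qi[ok]))
        ch <- length(unique(si[ok]))
      }
    }
    data.frame(strain_id = s, n_truth = nt, n_calls = nc,
               truth_recovered = th, calls_matched = ch)
  })
  per <- do.call(rbind, rows)
  res <- list(precision = sum(per$calls_matched) / max(1L, sum(per$n_calls)),
              recall = sum(per$truth_recovered) / max(1L, sum(per$n_truth)),
              n_truth = sum(per$n_truth), n_calls = sum(per$n_calls),
              per_strain = per, reciprocal = reciprocal)
  class(res) <- "cnv_evaluation"
  res
}

#' @export
print.cnv_evaluation <- function(x, ...) {
  cat(sprintf("cnv_evaluation: precision %.3f, recall %.3f (%d calls vs %d truth events, reciprocal >= %.2f)\n",
              x$precision, x$recall, x$n_calls, x$n_truth, x$reciprocal))
  invisible(x)
}
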