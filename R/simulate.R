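#' Simulation configuration for a multi-strain CN cohort
#'
#' Defines the statistical structure of a simulated wine-yeast-like cohort:
#' how many strains and CN-variable loci, the duplication/deletion balance and
#' size distributions, how often events sit in subtelomeric zones, the
#' population frequency of each CN allele, and the depth-emission model
#' (negative-binomial counts with a GC-dependent mean). Defaults emulate the
#' cohort structure of a 132-strain wine-yeast population sequenced at ~30x:
#' duplications mostly below 1 kb, deletions concentrated between 5 and 7 kb,
#' a deletion excess, and a substantial subtelomeric share of events.
#'
#' @param n_strains number of strains in the cohort.
#' @param n_loci number of CN-variable loci (ground-truth events) to place.
#' @param p_duplication probability that a locus is a duplication (otherwise a
#'   deletion with carrier CN 0).
#' @param p_subtelomeric probability that a locus is placed entirely within
#'   \code{subtel_span} bp of a chromosome end.
#' @param subtel_span subtelomeric zone span in bp (25 kb by convention).
#' @param dup_size_dist named vector \code{c(meanlog=, sdlog=)} of the
#'   log-normal duplication size distribution in bp.
#' @param del_size_short,del_size_long bp ranges of the short and long
#'   deletion size components (uniform within each range).
#' @param del_long_weight mixture weight of the long deletion component.
#' @param allele_freq_dist named vector \code{c(alpha=, beta=)} of the Beta
#'   distribution from which each locus draws its carrier frequency; the
#'   default Beta(0.8, 0.8) produces both rare and common CN alleles.
#' @param carrier_freq optional fixed carrier frequency overriding
#'   \code{allele_freq_dist} (useful for controlled experiments).
#' @param max_extra_copies maximum number of extra copies a duplication
#'   carrier may gain; carrier CN is 1 + a truncated-geometric draw.
#' @param base_depth mean reads per window at CN 1.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson); variance per window is \code{mu + mu^2/dispersion}.
#' @param residual_depth fraction of \code{base_depth} still emitted inside
#'   CN 0 deletions (mismapping background).
#' @param gc_amplitude relative depth modulation at the extremes of the GC
#'   range (see Details).
#' @param window window size in bp.
#' @param min_event_windows minimum event size in windows; event sizes are
#'   snapped to the window grid.
#' @param seed integer seed for the whole simulation.
#'
#' @details Window GC content is a smooth random field in [0.30, 0.60]. The
#' GC factor applied to the emission mean is unimodal and centered at GC 0.45,
#' and is normalized to mean 1 across the genome so that genome-average depth
#' equals \code{base_depth} at CN 1 while individual windows are biased, which
#' is what the caller's GC correction has to undo.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_strains = 132, n_loci = 2820,
                       p_duplication = 0.4, p_subtelomeric = 0.45,
                       subtel_span = 25000,
                       dup_size_dist = c(meanlog = log(700), sdlog = 0.8),
                       del_size_short = c(500, 1000),
                       del_size_long = c(5000, 7000),
                       del_long_weight = 0.65,
                       allele_freq_dist = c(alpha = 0.8, beta = 0.8),
                       carrier_freq = NULL,
                       max_extra_copies = 6,
                       base_depth = 30, dispersion = 100,
                       residual_depth = 0.02, gc_amplitude = 0.3,
                       window = 250, min_event_windows = 2, seed = 1) {
  probs <- c(p_duplication, p_subtelomeric, del_long_weight)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must be in [0, 1]")
  if (!is.null(carrier_freq) && (carrier_freq < 0 || carrier_freq > 1))
    stop_fmt("carrier_freq must be in [0, 1]")
  stopifnot(n_strains >= 1, n_loci >= 0, base_depth > 0, dispersion > 0,
            window > 0, max_extra_copies >= 1, min_event_windows >= 1,
            residual_depth >= 0, all(allele_freq_dist > 0))
  structure(list(n_strains = as.integer(n_strains), n_loci = as.integer(n_loci),
                 p_duplication = p_duplication, p_subtelomeric = p_subtelomeric,
                 subtel_span = subtel_span, dup_size_dist = dup_size_dist,
                 del_size_short = del_size_short, del_size_long = del_size_long,
                 del_long_weight = del_long_weight,
                 allele_freq_dist = allele_freq_dist, carrier_freq = carrier_freq,
                 max_extra_copies = as.integer(max_extra_copies),
                 base_depth = base_depth, dispersion = dispersion,
                 residual_depth = residual_depth, gc_amplitude = gc_amplitude,
                 window = as.integer(window),
                 min_event_windows = as.integer(min_event_windows),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d strains, %d loci, P(dup)=%.2f, ",
                     "P(subtel)=%.2f, depth %gx (NB size %g), window %d bp, seed %d\n"),
              x$n_strains, x$n_loci, x$p_duplication, x$p_subtelomeric,
              x$base_depth, x$dispersion, x$window, x$seed))
  invisible(x)
}

# smooth GC field in [0.30, 0.60] for one chromosome of n windows
gc_field <- function(n) {
  i <- seq_len(n)
  p1 <- stats::runif(1, 50, 200)
  p2 <- stats::runif(1, 15, 60)
  ph <- stats::runif(2, 0, 2 * pi)
  g <- 0.45 + 0.07 * sin(2 * pi * i / p1 + ph[1]) +
    0.04 * sin(2 * pi * i / p2 + ph[2]) + stats::rnorm(n, 0, 0.004)
  round(pmin(pmax(g, 0.30), 0.60), 4)
}

# unimodal GC response centered at 0.45, floor 0.2 (un-normalized)
gc_response <- function(gc, amplitude) {
  pmax(1 - amplitude * ((gc - 0.45) / 0.15)^2, 0.2)
}

# truncated-geometric extra copies for duplication carriers
draw_extra_copies <- function(n, max_extra) {
  pmin(stats::rgeom(n, 0.5) + 1L, max_extra)
}

#' Simulate a multi-strain copy-number cohort
#'
#' Places non-overlapping ground-truth CN events on the genome (subtelomeric
#' with probability \code{p_subtelomeric}, otherwise uniformly in interstitial
#' space; events never touch the centromere), draws a carrier frequency per
#' locus, assigns per-strain copy numbers (baseline 1 for non-carriers,
#' CN 0 for deletion carriers, 1 + extra copies for duplication carriers), and
#' emits per-strain windowed depth tracks from a negative-binomial model whose
#' mean is \code{base_depth * CN * gc_factor}.
#'
#' @param genome a [genome_model()].
#' @param cfg a [sim_config()].
#' @return an object of class \code{cn_simulation}: a list with
#'   \describe{
#'     \item{truth}{list with \code{events} (data.frame: locus_id, chrom,
#'       start, end, class, carrier_freq) and \code{cn} (integer matrix,
#'       loci x strains, baseline 1).}
#'     \item{tracks}{named list of per-strain depth data.frames with columns
#'       \code{chrom}, \code{start}, \code{depth}, \code{gc}.}
#'     \item{genome, config}{the inputs.}
#'   }
#' @examples
#' g <- build_genome(1, 200000, 0.5, seed = 1)
#' sim <- simulate_population(g, sim_config(n_strains = 3, n_loci = 4, seed = 2))
#' sim$truth$events
#' @export
simulate_population <- function(genome, cfg) {
  stopifnot(inherits(genome, "genome_model"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  w <- cfg$window
  chroms <- genome$chromosomes$name
  clen <- stats::setNames(genome$chromosomes$length, chroms)
  nwin <- clen %/% w
  if (any(nwin < 4)) stop_fmt("chromosomes too short for window %d", w)

  gc <- lapply(nwin, gc_field)
  fac <- lapply(gc, gc_response, amplitude = cfg$gc_amplitude)
  fac_mean <- mean(unlist(fac))
  fac <- lapply(fac, function(f) f / fac_mean)

  events <- place_events(genome, cfg)
  n_ev <- nrow(events)

  strains <- sprintf("strain_%03d", seq_len(cfg$n_strains))
  cn <- matrix(1L, nrow = n_ev, ncol = cfg$n_strains,
               dimnames = list(events$locus_id, strains))
  if (n_ev > 0) {
    for (j in seq_len(n_ev)) {
      q <- events$carrier_freq[j]
      carrier <- stats::rbinom(cfg$n_strains, 1L, q) == 1L
      tries <- 0L
      while (!any(carrier) && tries < 50L) {
        carrier <- stats::rbinom(cfg$n_strains, 1L, q) == 1L
        tries <- tries + 1L
      }
      if (!any(carrier)) carrier[sample.int(cfg$n_strains, 1L)] <- TRUE
      if (events$class[j] == "dup") {
        cn[j, carrier] <- 1L + draw_extra_copies(sum(carrier), cfg$max_extra_copies)
      } else {
        cn[j, carrier] <- 0L
      }
    }
  }

  # per-strain emission
  tracks <- vector("list", cfg$n_strains)
  names(tracks) <- strains
  ev_by_chrom <- split(seq_len(n_ev), factor(events$chrom, levels = chroms))
  for (s in seq_len(cfg$n_strains)) {
    per_chrom <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      n <- nwin[[ci]]
      wcn <- rep(1L, n)
      for (j in ev_by_chrom[[ci]]) {
        if (cn[j, s] != 1L) {
          i0 <- events$start[j] %/% w + 1L
          i1 <- (events$end[j] - 1L) %/% w + 1L
          wcn[i0:i1] <- cn[j, s]
        }
      }
      mu <- cfg$base_depth * ifelse(wcn == 0L, cfg$residual_depth, wcn) * fac[[ci]]
      per_chrom[[ci]] <- data.frame(
        chrom = ch,
        start = as.integer(w * (seq_len(n) - 1L)),
        depth = stats::rnbinom(n, size = cfg$dispersion, mu = mu),
        gc = gc[[ci]])
    }
    tr <- do.call(rbind, per_chrom)
    rownames(tr) <- NULL
    attr(tr, "strain_id") <- strains[s]
    tracks[[s]] <- tr
  }

  structure(list(truth = list(events = events, cn = cn),
                 tracks = tracks, genome = genome, config = cfg),
            class = "cn_simulation")
}

# event placement: subtelomeric vs interstitial, window-aligned, no overlaps,
# never touching a centromere, interstitial events fully outside subtel zones
place_events <- function(genome, cfg) {
  w <- cfg$window
  span <- cfg$subtel_span
  chroms <- genome$chromosomes$name
  clen <- stats::setNames(genome$chromosomes$length, chroms)
  cen <- genome$centromeres
  placed <- stats::setNames(vector("list", length(chroms)), chroms)
  out <- vector("list", cfg$n_loci)
  if (cfg$n_loci == 0L) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), class = character(),
                      carrier_freq = numeric()))
  }
  # The subtelomeric/interstitial decision is drawn once per event and kept
  # through placement retries, so the realized subtelomeric fraction is an
  # unbiased Binomial(n_loci, p_subtelomeric) draw whenever placement is
  # feasible; infeasible configurations error out instead of silently
  # shifting events elsewhere.
  max_attempts <- 500L
  for (k in seq_len(cfg$n_loci)) {
    is_dup <- stats::runif(1) < cfg$p_duplication
    subtel <- stats::runif(1) < cfg$p_subtelomeric
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      size <- if (is_dup) {
        stats::rlnorm(1, cfg$dup_size_dist[["meanlog"]], cfg$dup_size_dist[["sdlog"]])
      } else if (stats::runif(1) < cfg$del_long_weight) {
        stats::runif(1, cfg$del_size_long[1], cfg$del_size_long[2])
      } else {
        stats::runif(1, cfg$del_size_short[1], cfg$del_size_short[2])
      }
      size_w <- max(cfg$min_event_windows, round_half_up(size / w))
      size <- size_w * w
      ch <- sample(chroms, 1, prob = clen[chroms])
      L <- clen[[ch]]
      if (size >= span || size >= L / 4) next
      if (subtel) {
        left <- stats::runif(1) < 0.5
        lo_w <- if (left) 0L else as.integer(ceiling((L - span) / w))
        hi_w <- if (left) (span - size) %/% w else (L - size) %/% w
        if (hi_w < lo_w) next
        start <- w * (lo_w + sample.int(hi_w - lo_w + 1L, 1L) - 1L)
      } else {
        start <- w * sample.int(L %/% w - size_w + 1L, 1L) - w
        # fully outside both subtelomeric zones
        if (start < span || start + size > L - span) next
      }
      end <- start + size
      cc <- cen[cen$chrom == ch, ]
      if (start < cc$end && end > cc$start) next
      prev <- placed[[ch]]
      if (!is.null(prev) && any(start < prev$end & end > prev$start)) next
      row <- data.frame(chrom = ch, start = as.integer(start),
                        end = as.integer(end),
                        class = if (is_dup) "dup" else "del")
      placed[[ch]] <- rbind(prev, row[, c("start", "end")])
      out[[k]] <- row
      done <- TRUE
      break
    }
    if (!done)
      stop_fmt("could not place event %d (%s) without overlap after %d attempts",
               k, if (subtel) "subtelomeric" else "interstitial", max_attempts)
  }
  events <- do.call(rbind, out)
  events <- events[order(match(events$chrom, chroms), events$start), , drop = FALSE]
  events$locus_id <- sprintf("locus_%d", seq_len(nrow(events)))
  events$carrier_freq <- if (is.null(cfg$carrier_freq)) {
    stats::rbeta(nrow(events), cfg$allele_freq_dist[["alpha"]],
                 cfg$allele_freq_dist[["beta"]])
  } else rep(cfg$carrier_freq, nrow(events))
  rownames(events) <- NULL
  events[, c("locus_id", "chrom", "start", "end", "class", "carrier_freq")]
}

#' @export
print.cn_simulation <- function(x, ...) {
  ev <- x$truth$events
  cat(sprintf("cn_simulation: %d strains, %d truth events (%d dup / %d del)\n",
              length(x$tracks), nrow(ev), sum(ev$class == "dup"),
              sum(ev$class == "del")))
  invisible(x)
}

#' Convert ground-truth events to per-strain CNVR tables
#'
#' Views the simulator's truth as if it were a perfect caller's output: for
#' each strain, the events at which that strain's CN differs from baseline.
#' Useful for testing downstream stages independently of the caller.
#'
#' @param truth the \code{truth} element of a [simulate_population()] result.
#' @param strain_ids strains to include (default: all columns of the CN matrix).
#' @return named list of per-strain data.frames with columns \code{chrom},
#'   \code{start}, \code{end}, \code{cn}, \code{class}, \code{n_windows},
#'   \code{p_value}.
#' @export
truth_to_cnvrs <- function(truth, strain_ids = colnames(truth$cn)) {
  ev <- truth$events
  out <- lapply(strain_ids, function(s) {
    v <- truth$cn[, s]
    sel <- v != 1L
    data.frame(chrom = ev$chrom[sel], start = ev$start[sel], end = ev$end[sel],
               cn = as.integer(v[sel]),
               class = ifelse(v[sel] > 1L, "dup", "del"),
               n_windows = NA_integer_, p_value = NA_real_)
  })
  stats::setNames(out, strain_ids)
}
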