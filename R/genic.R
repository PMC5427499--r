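#' Label CNVRs as genic or nongenic
#'
#' A CNVR is genic if it overlaps any gene by at least one nucleotide under
#' half-open interval intersection (abutting intervals do not overlap). The
#' result is independent of the input ordering.
#'
#' @param cnvrs data.frame of CNVRs (\code{chrom}, \code{start}, \code{end}).
#' @param genes gene annotation data.frame (\code{chrom}, \code{start},
#'   \code{end}).
#' @return the CNVR data.frame with an added \code{genic_class} column
#'   (\code{"genic"} or \code{"nongenic"}).
#' @export
classify_cnvrs <- function(cnvrs, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(cnvrs)),
            all(c("chrom", "start", "end") %in% names(genes)))
  if (!nrow(cnvrs)) {
    cnvrs$genic_class <- character()
    return(cnvrs)
  }
  lev <- unique(c(cnvrs$chrom, genes$chrom))
  gc_ <- as_granges0(cnvrs$chrom, cnvrs$start, cnvrs$end, seqlevels = lev)
  gg <- as_granges0(genes$chrom, genes$start, genes$end, seqlevels = lev)
  hit <- GenomicRanges::countOverlaps(gc_, gg, minoverlap = 1L) > 0
  cnvrs$genic_class <- ifelse(hit, "genic", "nongenic")
  cnvrs
}

#' Genic copy number of one gene in one strain
#'
#' Mean CN state of all windows overlapping the gene by at least one
#' nucleotide; partially overlapping windows count fully (unweighted mean,
#' following the convention that genic CN is the average CN of the windows
#' that overlap the gene's coordinates). A base-weighted mean is available
#' for sensitivity analysis.
#'
#' @param track a normalized \code{window_track}.
#' @param gene one-row data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param weighted if TRUE, weight windows by their bp overlap with the gene.
#' @return data.frame with \code{gene_id}, \code{strain_id}, \code{cn}
#'   (mean, non-negative real) and \code{cn_int} (round-half-up).
#' @export
genic_cn <- function(track, gene, weighted = FALSE) {
  stopifnot(inherits(track, "window_track"), nrow(gene) == 1)
  w <- attr(track, "window")
  sel <- track$chrom == gene$chrom & track$start < gene$end &
    (track$start + w) > gene$start
  if (!any(track$chrom == gene$chrom))
    stop_fmt("gene %s: chromosome %s absent from track",
             gene$gene_id, gene$chrom)
  if (!any(sel))
    stop_fmt("gene %s: no windows overlap %s:%d-%d",
             gene$gene_id, gene$chrom, gene$start, gene$end)
  st <- track$cn_state[sel]
  if (weighted) {
    ws <- track$start[sel]
    ov <- pmin(ws + w, gene$end) - pmax(ws, gene$start)
    cn <- sum(st * ov) / sum(ov)
  } else {
    cn <- mean(st)
  }
  data.frame(gene_id = gene$gene_id,
             strain_id = attr(track, "strain_id") %||% "strain",
             cn = cn, cn_int = as.integer(round_half_up(cn)))
}

#' Genic CN matrix across a cohort
#'
#' Computes the genic CN of every gene in every strain from the strains'
#' normalized window tracks (unweighted mean of overlapping window states),
#' plus the integer-binned matrix used for discrete-allele diversity
#' measures.
#'
#' @param tracks named list of normalized \code{window_track}s.
#' @param genes gene annotation data.frame.
#' @return object of class \code{genic_cn_matrix}: list with \code{genes},
#'   \code{cn} (real matrix, genes x strains) and \code{cn_int} (integer).
#' @export
genic_cn_matrix <- function(tracks, genes) {
  stopifnot(is.list(tracks), length(tracks) >= 1, !is.null(names(tracks)))
  strains <- names(tracks)
  ng <- nrow(genes)
  cn <- matrix(NA_real_, ng, length(strains),
               dimnames = list(genes$gene_id, strains))
  for (s in strains) {
    track <- tracks[[s]]
    stopifnot(inherits(track, "window_track"))
    w <- attr(track, "window")
    for (ch in unique(genes$chrom)) {
      t <- track[track$chrom == ch, , drop = FALSE]
      gi <- which(genes$chrom == ch)
      if (!nrow(t)) stop_fmt("chromosome %s absent from track of %s", ch, s)
      cs <- cumsum(c(0, t$cn_state))
      n <- nrow(t)
      i0 <- pmin(pmax(genes$start[gi] %/% w, 0L), n - 1L)
      i1 <- pmin(pmax((genes$end[gi] - 1L) %/% w, 0L), n - 1L)
      cn[gi, s] <- (cs[i1 + 2L] - cs[i0 + 1L]) / (i1 - i0 + 1L)
    }
  }
  cni <- matrix(as.integer(round_half_up(cn)), nrow = ng,
                dimnames = dimnames(cn))
  structure(list(genes = genes, cn = cn, cn_int = cni),
            class = "genic_cn_matrix")
}

#' @export
print.genic_cn_matrix <- function(x, ...) {
  cat(sprintf("genic_cn_matrix: %d genes x %d strains\n",
              nrow(x$cn), ncol(x$cn)))
  invisible(x)
}

#' Compare duplicated vs deleted CNVR counts across strains
#'
#' Counts genic/nongenic duplicated and deleted CNVRs per strain and compares
#' the duplication and deletion count vectors with a two-sided Mann-Whitney U
#' test (Wilcoxon rank-sum with continuity correction), separately for genic
#' and nongenic CNVRs.
#'
#' @param cnvrs_by_strain named list of per-strain CNVR data.frames (with
#'   \code{class} column).
#' @param genes gene annotation used to split genic vs nongenic.
#' @return list with the per-strain \code{counts} data.frame and, for each of
#'   \code{genic} and \code{nongenic}, the test statistic \code{U}, the
#'   p-value, both medians, and the direction; class \code{dup_del_test}.
#' @export
dup_del_comparison <- function(cnvrs_by_strain, genes) {
  stopifnot(is.list(cnvrs_by_strain), length(cnvrs_by_strain) >= 2)
  rows <- lapply(names(cnvrs_by_strain), function(s) {
    x <- classify_cnvrs(as.data.frame(cnvrs_by_strain[[s]]), genes)
    data.frame(strain_id = s,
               genic_dup = sum(x$genic_class == "genic" & x$class == "dup"),
               genic_del = sum(x$genic_class == "genic" & x$class == "del"),
               nongenic_dup = sum(x$genic_class == "nongenic" & x$class == "dup"),
               nongenic_del = sum(x$genic_class == "nongenic" & x$class == "del"))
  })
  counts <- do.call(rbind, rows)
  one <- function(dup, del) {
    ht <- suppressWarnings(stats::wilcox.test(dup, del, correct = TRUE,
                                              alternative = "two.sided"))
    p <- ht$p.value
    if (!is.finite(p)) p <- 1  # fully tied samples carry no evidence
    md <- stats::median(dup); me <- stats::median(del)
    list(U = unname(ht$statistic), p_value = p,
         median_dup = md, median_del = me,
         direction = if (me > md) "del > dup" else if (md > me) "dup > del"
         else "no difference")
  }
  res <- list(counts = counts,
              genic = one(counts$genic_dup, counts$genic_del),
              nongenic = one(counts$nongenic_dup, counts$nongenic_del))
  class(res) <- "dup_del_test"
  res
}

#' @export
print.dup_del_test <- function(x, ...) {
  for (k in c("genic", "nongenic")) {
    t <- x[[k]]
    cat(sprintf("%s: median dup %.1f vs del %.1f (%s), U = %.1f, p = %.3g\n",
                k, t$median_dup, t$median_del, t$direction, t$U, t$p_value))
  }
  invisible(x)
}

#' Fraction of genic duplications with length a multiple of three
#'
#' Among genic duplications, the fraction whose length (end - start) is
#' divisible by 3 -- duplications that preserve reading frame if in coding
#' sequence.
#'
#' @param cnvrs CNVR data.frame; if \code{genes} is supplied, rows are first
#'   restricted to genic duplications, otherwise the input is assumed to be
#'   genic duplications already.
#' @param genes optional gene annotation.
#' @return a single fraction in [0, 1], or NA (with a warning) if there are
#'   no genic duplications.
#' @export
inframe_fraction <- function(cnvrs, genes = NULL) {
  x <- as.data.frame(cnvrs)
  if (!is.null(genes)) {
    x <- classify_cnvrs(x, genes)
    x <- x[x$genic_class == "genic" & x$class == "dup", , drop = FALSE]
  }
  if (!nrow(x)) {
    warning("no genic duplications; in-frame fraction undefined")
    return(NA_real_)
  }
  mean((x$end - x$start) %% 3 == 0)
}
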