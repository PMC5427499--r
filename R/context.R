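#' Build genomic-context zones
#'
#' Materializes the zones used for context classification: subtelomeres under
#' definition A (a fixed span from each chromosome end, 25 kb by convention),
#' subtelomeres under definition B (from each end to the first essential
#' gene, available only when the genome carries essential-gene anchors), and
#' pericentromeres (centromere plus a flank on each side, 7 kb by default).
#' All zones are clipped to chromosome bounds.
#'
#' @param genome a [genome_model()].
#' @param subtel_span definition-A span in bp from each end.
#' @param peri_flank pericentromeric flank in bp.
#' @param essential_genes optional data.frame (\code{chrom}, \code{start},
#'   \code{end}) overriding \code{genome$essential_genes}.
#' @return object of class \code{context_zones}: list with
#'   \code{definition_a}, \code{definition_b} (NULL without essential genes),
#'   \code{pericentromeric} interval tables and the spans used.
#' @export
build_zones <- function(genome, subtel_span = 25000, peri_flank = 7000,
                        essential_genes = NULL) {
  stopifnot(inherits(genome, "genome_model"), subtel_span > 0, peri_flank > 0)
  chroms <- genome$chromosomes$name
  clen <- stats::setNames(genome$chromosomes$length, chroms)
  ess <- essential_genes %||% genome$essential_genes

  half_warned <- clen[subtel_span > clen / 2]
  if (length(half_warned))
    warning(sprintf("subtelomeric span %d exceeds half the length of %d chromosome(s); whole chromosome(s) subtelomeric",
                    subtel_span, length(half_warned)))
  def_a <- do.call(rbind, lapply(chroms, function(ch) {
    L <- clen[[ch]]
    data.frame(chrom = ch,
               start = c(0L, as.integer(max(L - subtel_span, 0))),
               end = c(as.integer(min(subtel_span, L)), as.integer(L)),
               side = c("left", "right"))
  }))

  def_b <- NULL
  if (!is.null(ess)) {
    def_b <- do.call(rbind, lapply(chroms, function(ch) {
      L <- clen[[ch]]
      e <- ess[ess$chrom == ch, , drop = FALSE]
      if (!nrow(e)) {
        warning(sprintf("no essential gene on %s; whole chromosome subtelomeric under definition B", ch))
        return(data.frame(chrom = ch, start = 0L, end = as.integer(L),
                          side = "both"))
      }
      data.frame(chrom = ch,
                 start = c(0L, as.integer(max(e$end))),
                 end = c(as.integer(min(e$start)), as.integer(L)),
                 side = c("left", "right"))
    }))
    def_b <- def_b[def_b$end > def_b$start, , drop = FALSE]
    rownames(def_b) <- NULL
  }

  cen <- genome$centromeres
  peri <- data.frame(chrom = cen$chrom,
                     start = as.integer(pmax(cen$start - peri_flank, 0)),
                     end = as.integer(pmin(cen$end + peri_flank,
                                           clen[cen$chrom])))
  structure(list(definition_a = def_a, definition_b = def_b,
                 pericentromeric = peri, subtel_span = subtel_span,
                 peri_flank = peri_flank),
            class = "context_zones")
}

#' @export
print.context_zones <- function(x, ...) {
  cat(sprintf("context_zones: subtelomere span %d bp (definition A)%s, pericentromeric flank %d bp\n",
              x$subtel_span,
              if (!is.null(x$definition_b)) " + essential-gene definition B" else "",
              x$peri_flank))
  invisible(x)
}

#' Classify intervals by genomic context
#'
#' A locus is subtelomeric if it overlaps a subtelomeric zone by at least one
#' nucleotide under the chosen definition; otherwise pericentromeric if it
#' overlaps the centromere flank; otherwise interstitial. Subtelomeric takes
#' precedence when a locus overlaps both zone types.
#'
#' @param x data.frame of intervals (\code{chrom}, \code{start}, \code{end}).
#' @param zones a [build_zones()] result.
#' @param definition \code{"A"} (fixed span) or \code{"B"} (essential-gene).
#' @return factor with levels \code{subtelomeric}, \code{pericentromeric},
#'   \code{interstitial}, one per row of \code{x}.
#' @export
classify_context <- function(x, zones, definition = c("A", "B")) {
  definition <- match.arg(definition)
  stopifnot(inherits(zones, "context_zones"),
            all(c("chrom", "start", "end") %in% names(x)))
  zdf <- if (definition == "A") zones$definition_a else zones$definition_b
  if (is.null(zdf))
    stop_fmt("definition B requires an essential-gene list in the genome model")
  lev <- unique(c(x$chrom, zdf$chrom, zones$pericentromeric$chrom))
  gx <- as_granges0(x$chrom, x$start, x$end, seqlevels = lev)
  gs <- as_granges0(zdf$chrom, zdf$start, zdf$end, seqlevels = lev)
  gp <- as_granges0(zones$pericentromeric$chrom, zones$pericentromeric$start,
                    zones$pericentromeric$end, seqlevels = lev)
  sub <- GenomicRanges::countOverlaps(gx, gs, minoverlap = 1L) > 0
  peri <- GenomicRanges::countOverlaps(gx, gp, minoverlap = 1L) > 0
  factor(ifelse(sub, "subtelomeric",
                ifelse(peri, "pericentromeric", "interstitial")),
         levels = c("subtelomeric", "pericentromeric", "interstitial"))
}

#' Context summary of CN-diverse loci and genes
#'
#' For each available subtelomere definition, counts how many of the supplied
#' loci (and optionally genes) are subtelomeric, pericentromeric, or
#' interstitial, with fractions reported to 0.1%.
#'
#' @param loci data.frame of (typically CN-diverse) locus intervals.
#' @param genes optional data.frame of (typically CN-diverse) gene intervals.
#' @param zones a [build_zones()] result.
#' @param definitions definitions to report; default A plus B when available.
#' @return nested list (definition -> loci/genes -> counts and percentages);
#'   class \code{context_summary}.
#' @export
context_summary <- function(loci, genes = NULL, zones,
                            definitions = NULL) {
  stopifnot(inherits(zones, "context_zones"))
  definitions <- definitions %||%
    c("A", if (!is.null(zones$definition_b)) "B")
  one <- function(df, what, def) {
    n <- nrow(df)
    if (n == 0) {
      warning(sprintf("no %s supplied; fractions undefined", what))
      return(list(n = 0L, n_subtelomeric = 0L, pct_subtelomeric = NA_real_,
                  n_pericentromeric = 0L, pct_pericentromeric = NA_real_,
                  n_interstitial = 0L))
    }
    ctx <- classify_context(df, zones, def)
    ns <- sum(ctx == "subtelomeric")
    np <- sum(ctx == "pericentromeric")
    list(n = n, n_subtelomeric = ns,
         pct_subtelomeric = round(100 * ns / n, 1),
         n_pericentromeric = np,
         pct_pericentromeric = round(100 * np / n, 1),
         n_interstitial = n - ns - np)
  }
  out <- lapply(definitions, function(def) {
    res <- list(loci = one(loci, "loci", def))
    if (!is.null(genes)) res$genes <- one(genes, "genes", def)
    res
  })
  names(out) <- paste0("definition_", definitions)
  class(out) <- "context_summary"
  out
}

#' @export
print.context_summary <- function(x, ...) {
  for (def in names(x)) {
    for (what in names(x[[def]])) {
      s <- x[[def]][[what]]
      if (s$n == 0) next
      cat(sprintf("%s %s: %d/%d (%.1f%%) subtelomeric, %d (%.1f%%) pericentromeric\n",
                  sub("_", " ", def), what, s$n_subtelomeric, s$n,
                  s$pct_subtelomeric, s$n_pericentromeric,
                  s$pct_pericentromeric))
    }
  }
  invisible(x)
}

#' Per-chromosome CN-diversity map
#'
#' Projects locus diversity scores onto the genome's window grid: each window
#' gets the maximum score of any overlapping locus (NA where none overlaps)
#' and its genomic-context label -- a plain-text track suitable for plotting
#' chromosome diversity maps.
#'
#' @param diversity scored locus table with coordinates (e.g. a
#'   \code{cn_diversity} table, typically filtered to the CN-diverse rows).
#' @param genome a [genome_model()].
#' @param zones a [build_zones()] result.
#' @param window window size in bp.
#' @param score which score column to project.
#' @param definition subtelomere definition for the context label.
#' @return data.frame with \code{chrom}, \code{start}, \code{score},
#'   \code{context}.
#' @export
chromosome_map <- function(diversity, genome, zones, window = 250,
                           score = c("pic", "log10_s2"), definition = "A") {
  score <- match.arg(score)
  win <- genome_windows(genome, window)
  win$score <- NA_real_
  if (nrow(diversity)) {
    lev <- unique(c(win$chrom, diversity$chrom))
    gw <- as_granges0(win$chrom, win$start, win$start + window, seqlevels = lev)
    gl <- as_granges0(diversity$chrom, diversity$start, diversity$end,
                      seqlevels = lev)
    h <- GenomicRanges::findOverlaps(gw, gl)
    if (length(h)) {
      sc <- tapply(diversity[[score]][S4Vectors::subjectHits(h)],
                   S4Vectors::queryHits(h), max, na.rm = TRUE)
      win$score[as.integer(names(sc))] <- as.numeric(sc)
    }
  }
  win$context <- classify_context(
    data.frame(chrom = win$chrom, start = win$start, end = win$start + window),
    zones, definition)
  win
}
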