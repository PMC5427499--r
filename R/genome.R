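#' Construct a genome model
#'
#' A genome model is the coordinate backbone of the analysis: an ordered set
#' of chromosomes with lengths, one centromere interval per chromosome, and
#' (optionally) essential-gene anchors used by the essential-gene subtelomere
#' definition. All coordinates in the package are 0-based, half-open.
#'
#' @param chromosomes data.frame with columns \code{name} (unique) and
#'   \code{length} (bp, > 0).
#' @param centromeres data.frame with columns \code{chrom}, \code{start},
#'   \code{end}; each interval must lie strictly inside its chromosome.
#' @param essential_genes optional data.frame with columns \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end}; coordinates must lie inside the
#'   chromosome. Stored sorted by position within each chromosome.
#' @return an object of class \code{genome_model}.
#' @seealso [build_genome()] to simulate one, [build_zones()] for the
#'   genomic-context zones derived from it.
#' @export
genome_model <- function(chromosomes, centromeres, essential_genes = NULL) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  stopifnot(is.data.frame(centromeres), all(c("chrom", "start", "end") %in% names(centromeres)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop_fmt("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop_fmt("chromosome lengths must be positive")
  len <- stats::setNames(chromosomes$length, chromosomes$name)
  centromeres$chrom <- as.character(centromeres$chrom)
  if (!all(centromeres$chrom %in% chromosomes$name))
    stop_fmt("centromere on unknown chromosome: %s",
             paste(setdiff(centromeres$chrom, chromosomes$name), collapse = ", "))
  bad <- centromeres$start <= 0 | centromeres$end >= len[centromeres$chrom] |
    centromeres$end <= centromeres$start
  if (any(bad))
    stop_fmt("centromere interval not strictly inside chromosome: %s",
             paste(centromeres$chrom[bad], collapse = ", "))
  if (!is.null(essential_genes)) {
    stopifnot(is.data.frame(essential_genes),
              all(c("gene_id", "chrom", "start", "end") %in% names(essential_genes)))
    essential_genes$chrom <- as.character(essential_genes$chrom)
    if (!all(essential_genes$chrom %in% chromosomes$name))
      stop_fmt("essential gene on unknown chromosome")
    bad <- essential_genes$start < 0 | essential_genes$end > len[essential_genes$chrom] |
      essential_genes$end <= essential_genes$start
    if (any(bad))
      stop_fmt("essential gene coordinates outside chromosome: %s",
               paste(essential_genes$gene_id[bad], collapse = ", "))
    ord <- order(match(essential_genes$chrom, chromosomes$name), essential_genes$start)
    essential_genes <- essential_genes[ord, , drop = FALSE]
    rownames(essential_genes) <- NULL
  }
  structure(list(chromosomes = chromosomes[, c("name", "length")],
                 centromeres = centromeres[, c("chrom", "start", "end")],
                 essential_genes = essential_genes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.2f Mb total\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  if (!is.null(x$essential_genes))
    cat(sprintf("  essential-gene anchors: %d\n", nrow(x$essential_genes)))
  invisible(x)
}

#' Simulate a genome model
#'
#' Builds a multi-chromosome genome with a centromere placed at a stated
#' fractional position of each chromosome (with a small random jitter). The
#' default layout mimics the 16-chromosome budding-yeast genome at the
#' 12 Mb order of magnitude.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp; a single value or a vector
#'   recycled across chromosomes. Must be at least 100 windows (25 kb at the
#'   default 250 bp window) and at least 50 kb so that both 25 kb subtelomeric
#'   zones fit.
#' @param centromere_fraction fractional position of the centromere midpoint
#'   along each chromosome, in (0, 1).
#' @param seed integer seed; the model is deterministic given the seed.
#' @param window window size in bp used only for the minimum-length check.
#' @param centromere_width width of the centromere interval in bp.
#' @param jitter relative jitter (fraction of chromosome length) applied to
#'   the centromere midpoint.
#' @return a [genome_model()].
#' @examples
#' g <- build_genome(2, 200000, 0.5, seed = 7)
#' g$centromeres
#' @export
build_genome <- function(n_chrom = 16, chrom_length = 750000,
                         centromere_fraction = 0.4, seed = 1,
                         window = 250, centromere_width = 1000,
                         jitter = 0.02) {
  stopifnot(n_chrom >= 1, centromere_fraction > 0, centromere_fraction < 1)
  chrom_length <- rep_len(as.integer(chrom_length), n_chrom)
  if (any(chrom_length < 100L * window))
    stop_fmt("chrom_length must be at least 100 windows (%d bp)", 100L * window)
  if (any(chrom_length < 2L * 25000L))
    stop_fmt("chrom_length %d too small to host two 25 kb subtelomeric zones",
             min(chrom_length))
  set.seed(seed)
  name <- paste0("chr", as.character(utils::as.roman(seq_len(n_chrom))))
  mid <- round(chrom_length * (centromere_fraction +
                                 stats::runif(n_chrom, -jitter, jitter)))
  half <- centromere_width %/% 2L
  cen_start <- pmax(1L, as.integer(mid - half))
  cen_end <- pmin(chrom_length - 1L, as.integer(mid + half))
  genome_model(
    chromosomes = data.frame(name = name, length = chrom_length),
    centromeres = data.frame(chrom = name, start = cen_start, end = cen_end)
  )
}

#' Window grid of a genome
#'
#' Tiles every chromosome with fixed-size windows starting at 0. A trailing
#' remainder shorter than one window is dropped.
#'
#' @param genome a [genome_model()].
#' @param window window size in bp.
#' @return data.frame with columns \code{chrom}, \code{start}.
#' @export
genome_windows <- function(genome, window = 250) {
  stopifnot(inherits(genome, "genome_model"), window > 0)
  parts <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    n <- genome$chromosomes$length[i] %/% window
    data.frame(chrom = genome$chromosomes$name[i],
               start = as.integer(window * (seq_len(n) - 1L)))
  })
  do.call(rbind, parts)
}

#' Simulate a gene annotation for a synthetic genome
#'
#' Lays non-overlapping genes along each chromosome with roughly yeast-like
#' density (~1.4 kb genes separated by short intergenic gaps), skipping the
#' centromere, and marks a random subset as essential. The essential subset
#' can anchor the essential-gene subtelomere definition.
#'
#' @param genome a [genome_model()].
#' @param mean_length,min_length gene length parameters in bp.
#' @param mean_gap mean intergenic gap in bp.
#' @param essential_fraction fraction of genes marked essential.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{essential}.
#' @export
simulate_genes <- function(genome, mean_length = 1400, min_length = 300,
                           mean_gap = 600, essential_fraction = 0.2, seed = 1) {
  stopifnot(inherits(genome, "genome_model"),
            mean_length > min_length, mean_gap > 0,
            essential_fraction >= 0, essential_fraction <= 1)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[i]
    clen <- genome$chromosomes$length[i]
    cen <- genome$centromeres[genome$centromeres$chrom == ch, ]
    pos <- 0L
    k <- 0L
    repeat {
      gap <- round(stats::rexp(1, 1 / mean_gap))
      glen <- max(min_length, round(stats::rgamma(1, shape = 4, scale = mean_length / 4)))
      start <- pos + gap
      end <- start + glen
      if (end >= clen) break
      # genes never straddle the centromere
      if (start < cen$end && end > cen$start) {
        pos <- as.integer(cen$end)
        next
      }
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%03d", ch, k), chrom = ch,
        start = as.integer(start), end = as.integer(end),
        strand = sample(c("+", "-"), 1))
      pos <- as.integer(end)
    }
  }
  genes <- do.call(rbind, rows)
  genes$essential <- stats::runif(nrow(genes)) < essential_fraction
  rownames(genes) <- NULL
  genes
}
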