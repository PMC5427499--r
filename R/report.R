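#' Cohort-level descriptive statistics
#'
#' Per-strain CNVR counts (total, duplicated, deleted), genome bp affected
#' and the fraction of the genome affected, plus cohort aggregates (mean,
#' SD, SE and median of the per-strain counts; mean fraction affected) and
#' the cohort union: the number of distinct union loci, the genome span they
#' cover, and -- when an annotation is supplied -- how many genes they
#' overlap.
#'
#' @param calls named list of per-strain CNVR data.frames.
#' @param genome a [genome_model()].
#' @param genes optional gene annotation data.frame.
#' @return object of class \code{cohort_summary}: list with \code{strains}
#'   (per-strain table), \code{aggregate}, \code{union}.
#' @export
cohort_summary <- function(calls, genome, genes = NULL) {
  stopifnot(is.list(calls), !is.null(names(calls)),
            inherits(genome, "genome_model"))
  gsize <- sum(genome$chromosomes$length)
  rows <- lapply(names(calls), function(s) {
    x <- as.data.frame(calls[[s]])
    bp <- if (nrow(x)) sum(x$end - x$start) else 0L
    data.frame(strain_id = s, n_cnvrs = nrow(x),
               n_dup = sum(x$class == "dup"), n_del = sum(x$class == "del"),
               genome_affected_bp = bp,
               genome_affected_fraction = bp / gsize)
  })
  strains <- do.call(rbind, rows)
  n <- nrow(strains)
  aggregate <- list(
    n_strains = n,
    mean_cnvrs = mean(strains$n_cnvrs),
    sd_cnvrs = stats::sd(strains$n_cnvrs),
    se_cnvrs = stats::sd(strains$n_cnvrs) / sqrt(n),
    median_cnvrs = stats::median(strains$n_cnvrs),
    mean_fraction = mean(strains$genome_affected_fraction),
    sd_fraction = stats::sd(strains$genome_affected_fraction))
  pooled <- do.call(rbind, lapply(calls, function(x)
    as.data.frame(x)[, c("chrom", "start", "end")]))
  union <- list(n_loci = 0L, span_bp = 0L, n_genes_overlapped = NA_integer_)
  if (!is.null(pooled) && nrow(pooled)) {
    gr <- as_granges0(pooled$chrom, pooled$start, pooled$end,
                      seqlevels = genome$chromosomes$name)
    un <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    union$n_loci <- length(un)
    union$span_bp <- sum(GenomicRanges::width(un))
    if (!is.null(genes)) {
      gg <- as_granges0(genes$chrom, genes$start, genes$end,
                        seqlevels = genome$chromosomes$name)
      union$n_genes_overlapped <-
        sum(GenomicRanges::countOverlaps(gg, un, minoverlap = 1L) > 0)
    }
  }
  structure(list(strains = strains, aggregate = aggregate, union = union),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("cohort_summary: %d strains\n", a$n_strains))
  cat(sprintf("  CNVRs per strain: %.1f +/- %.1f SD (SE %.2f), median = %.1f\n",
              a$mean_cnvrs, a$sd_cnvrs, a$se_cnvrs, a$median_cnvrs))
  cat(sprintf("  genome affected: %.2f%% on average\n", 100 * a$mean_fraction))
  cat(sprintf("  cohort union: %d loci spanning %.2f Mb", x$union$n_loci,
              x$union$span_bp / 1e6))
  if (!is.na(x$union$n_genes_overlapped))
    cat(sprintf(", overlapping %d genes", x$union$n_genes_overlapped))
  cat("\n")
  invisible(x)
}

#' CNVR size distribution
#'
#' Fractions of CNVRs per size bin, overall and optionally split by
#' duplication/deletion. Default bins expose both the sub-kilobase
#' duplication mode and the 5-7 kb deletion mode:
#' (0,1], (1,2], (2,3], (3,4], (4,5], (5,7], (7,10], >10 kb.
#'
#' @param cnvrs CNVR data.frame (pool strains with \code{rbind} for a cohort
#'   view); needs \code{start}, \code{end} and -- for the split -- a
#'   \code{class} column.
#' @param bin_edges ascending bp bin edges; bins are left-open.
#' @param split_by_class also report per-class series.
#' @return long data.frame with columns \code{series}, \code{bin}, \code{n},
#'   \code{fraction}; fractions sum to 1 within each series.
#' @export
size_distribution <- function(cnvrs,
                              bin_edges = c(0, 1000, 2000, 3000, 4000, 5000,
                                            7000, 10000, Inf),
                              split_by_class = TRUE) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  x <- as.data.frame(cnvrs)
  if (!nrow(x)) {
    warning("no CNVRs; size distribution is empty")
    return(data.frame(series = character(), bin = character(), n = integer(),
                      fraction = numeric()))
  }
  len <- x$end - x$start
  series <- list(all = rep(TRUE, nrow(x)))
  if (split_by_class && "class" %in% names(x)) {
    series$dup <- x$class == "dup"
    series$del <- x$class == "del"
  }
  out <- lapply(names(series), function(nm) {
    sel <- series[[nm]]
    if (!any(sel)) return(NULL)
    tab <- table(cut(len[sel], breaks = bin_edges, right = TRUE))
    data.frame(series = nm, bin = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / sum(tab))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-family CN view
#'
#' The heat-map-ready integer CN matrix of a set of genes (rows) across all
#' strains (columns), together with each gene's per-strain proportions of
#' duplication (CN > 1), deletion (CN < 1) and no change (CN = 1). The three
#' proportions sum to 1 per gene.
#'
#' @param gcm a [genic_cn_matrix()].
#' @param family character vector of gene IDs; all must be present.
#' @return object of class \code{gene_family_view}: list with \code{cn}
#'   (integer matrix) and \code{proportions} (data.frame with counts,
#'   proportions and percentages).
#' @export
gene_family_view <- function(gcm, family) {
  stopifnot(inherits(gcm, "genic_cn_matrix"), length(family) >= 1)
  miss <- setdiff(family, gcm$genes$gene_id)
  if (length(miss))
    stop_fmt("gene(s) absent from the CN matrix: %s",
             paste(miss, collapse = ", "))
  idx <- match(family, gcm$genes$gene_id)
  m <- gcm$cn_int[idx, , drop = FALSE]
  rownames(m) <- family
  ns <- ncol(m)
  props <- data.frame(
    gene_id = family,
    n_dup = as.integer(rowSums(m > 1L)),
    n_del = as.integer(rowSums(m < 1L)),
    n_unchanged = as.integer(rowSums(m == 1L)))
  props$prop_dup <- props$n_dup / ns
  props$prop_del <- props$n_del / ns
  props$prop_unchanged <- props$n_unchanged / ns
  props$pct_dup <- round(100 * props$prop_dup, 2)
  props$pct_del <- round(100 * props$prop_del, 2)
  rownames(props) <- NULL
  structure(list(cn = m, proportions = props, n_strains = ns),
            class = "gene_family_view")
}

#' @export
print.gene_family_view <- function(x, ...) {
  cat(sprintf("gene_family_view: %d genes x %d strains\n", nrow(x$cn),
              x$n_strains))
  p <- x$proportions
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s: duplicated in %d (%.2f%%), deleted in %d (%.2f%%)\n",
                p$gene_id[i], p$n_dup[i], p$pct_dup[i], p$n_del[i],
                p$pct_del[i]))
  invisible(x)
}

#' Intragenic CN profile at fine window resolution
#'
#' Re-normalizes a depth track at a fine window size (25 bp by convention,
#' for dissecting CN variation inside repeat-rich genes) and restricts it to
#' the gene body, returning the per-window CN states, the contiguous
#' non-neutral blocks inside the gene (single-window blocks allowed at this
#' resolution), the fractions of gene windows duplicated/deleted, and a
#' label: \code{intact}, \code{duplication}/\code{partial_duplication},
#' \code{deletion}/\code{partial_deletion}, or \code{complex} when both
#' occur.
#'
#' @param depth fine-resolution depth data.frame or file path (windows must
#'   tile the genome at \code{fine_window} bp).
#' @param genome a [genome_model()].
#' @param gene one-row data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param fine_window fine window size in bp.
#' @param gc_bins GC bins for the fine-mode normalization.
#' @param mask_telocentromeric normalization mask in bp.
#' @return object of class \code{intragenic_profile}: list with
#'   \code{profile} (per-window data.frame), \code{blocks}, \code{frac_dup},
#'   \code{frac_del}, \code{label}, \code{gene_id}.
#' @export
intragenic_profile <- function(depth, genome, gene, fine_window = 25,
                               gc_bins = 10, mask_telocentromeric = 7000) {
  stopifnot(nrow(gene) == 1)
  track <- normalize_track(depth, genome, window = fine_window,
                           gc_bins = gc_bins,
                           mask_telocentromeric = mask_telocentromeric)
  sel <- track$chrom == gene$chrom & track$start < gene$end &
    (track$start + fine_window) > gene$start
  if (!any(sel))
    stop_fmt("gene %s: no fine windows overlap %s:%d-%d", gene$gene_id,
             gene$chrom, gene$start, gene$end)
  sub <- keep_track_attrs(track[sel, , drop = FALSE], track)
  rownames(sub) <- NULL
  blocks <- segment_track(sub, min_windows = 1)
  frac_dup <- mean(sub$cn_state > 1L)
  frac_del <- mean(sub$cn_state < 1L)
  label <- if (frac_dup == 0 && frac_del == 0) "intact"
  else if (frac_del == 0) {
    if (frac_dup == 1) "duplication" else "partial_duplication"
  } else if (frac_dup == 0) {
    if (frac_del == 1) "deletion" else "partial_deletion"
  } else "complex"
  structure(list(profile = as.data.frame(sub)[, c("chrom", "start", "ratio",
                                                  "cn_state")],
                 blocks = blocks, frac_dup = frac_dup, frac_del = frac_del,
                 label = label, gene_id = gene$gene_id),
            class = "intragenic_profile")
}

#' @export
print.intragenic_profile <- function(x, ...) {
  cat(sprintf("intragenic_profile (%s): %s; %.0f%% windows duplicated, %.0f%% deleted, %d block(s)\n",
              x$gene_id, x$label, 100 * x$frac_dup, 100 * x$frac_del,
              nrow(x$blocks)))
  invisible(x)
}
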