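#' Polymorphic information content of a CN allele vector
#'
#' \code{PIC = 1 - sum(f_i^2)} over the distinct copy-number alleles at a
#' locus, where \code{f_i} is the frequency of allele \code{i} among the
#' strains. 0 for a monomorphic locus; approaches 1 as alleles diversify
#' (maximum \code{1 - 1/n} when all n values are distinct). Every strain is
#' included, baseline CN 1 carriers as well.
#'
#' @param values vector of per-strain CN values (length >= 1, no NA).
#' @return a number in \code{[0, 1 - 1/length(values)]}.
#' @examples
#' pic(rep(1, 132))        # monomorphic: 0
#' pic(c(rep(1, 66), rep(2, 66)))  # two equal-frequency alleles: 0.5
#' @export
pic <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  f <- tabulate(match(values, unique(values))) / length(values)
  1 - sum(f^2)
}

#' log10 of the across-strain sample variance of CN
#'
#' The sample variance (n - 1 denominator) of the CN values at a locus, log10
#' transformed. Returns NA for a zero-variance (monomorphic) locus, which is
#' then excluded from the percentile pool.
#'
#' @param values vector of per-strain CN values (length >= 2, no NA).
#' @return \code{log10(var(values))}, or \code{NA_real_} if the variance is 0.
#' @examples
#' log_variance(c(1, 1, 1, 3))  # s2 = 1, log10 = 0
#' @export
log_variance <- function(values) {
  stopifnot(length(values) >= 2, !anyNA(values))
  s2 <- stats::var(values)
  if (s2 == 0) NA_real_ else log10(s2)
}

#' Build a locus-by-strain CN matrix from per-strain CNVR calls
#'
#' Loci are the connected components of overlapping CNVR intervals pooled
#' across strains (union regions; >= 1 bp overlap connects two intervals,
#' half-open abutment does not). Each cell holds the strain's integer CN over
#' the locus -- the CN of its overlapping CNVR (the one with the largest
#' overlap if several) -- or the baseline 1 if the strain has no call there.
#'
#' @param calls named list of per-strain CNVR data.frames.
#' @param strain_ids strain identifiers (default: names of \code{calls});
#'   must be unique.
#' @param genome optional [genome_model()] fixing the chromosome order.
#' @return object of class \code{cn_matrix}: list with \code{loci}
#'   (data.frame: locus_id, chrom, start, end) and \code{cn} (integer matrix,
#'   loci x strains).
#' @export
build_cn_matrix <- function(calls, strain_ids = names(calls), genome = NULL) {
  stopifnot(is.list(calls), length(calls) >= 1)
  if (is.null(strain_ids) || anyDuplicated(strain_ids))
    stop_fmt("strain IDs must be present and unique")
  pooled <- do.call(rbind, lapply(seq_along(calls), function(i) {
    x <- as.data.frame(calls[[i]])
    if (!nrow(x)) return(NULL)
    data.frame(strain = strain_ids[i], chrom = x$chrom, start = x$start,
               end = x$end, cn = x$cn)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(list(loci = data.frame(locus_id = character(),
                                            chrom = character(),
                                            start = integer(), end = integer()),
                          cn = matrix(integer(), 0, length(strain_ids),
                                      dimnames = list(NULL, strain_ids))),
                     class = "cn_matrix"))
  }
  lev <- if (!is.null(genome)) genome$chromosomes$name
  else sort(unique(pooled$chrom))
  gr <- as_granges0(pooled$chrom, pooled$start, pooled$end, seqlevels = lev)
  un <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  loci <- data.frame(locus_id = sprintf("locus_%d", seq_along(un)),
                     chrom = as.character(GenomicRanges::seqnames(un)),
                     start = GenomicRanges::start(un) - 1L,
                     end = GenomicRanges::end(un))
  mat <- matrix(1L, nrow(loci), length(strain_ids),
                dimnames = list(loci$locus_id, strain_ids))
  h <- GenomicRanges::findOverlaps(gr, un)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[qi], un[si]))
  assign_df <- data.frame(strain = pooled$strain[qi], locus = si,
                          cn = pooled$cn[qi], ov = ov)
  assign_df <- assign_df[order(assign_df$locus, assign_df$strain, -assign_df$ov), ]
  assign_df <- assign_df[!duplicated(assign_df[, c("locus", "strain")]), ]
  mat[cbind(assign_df$locus, match(assign_df$strain, strain_ids))] <-
    as.integer(assign_df$cn)
  structure(list(loci = loci, cn = mat), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d loci x %d strains\n", nrow(x$cn), ncol(x$cn)))
  invisible(x)
}

#' Score per-locus CN diversity
#'
#' Computes, for every locus (row) of a CN matrix: the number of distinct CN
#' alleles, the sample variance s2 and its log10 (NA when s2 = 0), and the
#' polymorphic information content.
#'
#' @param x a \code{cn_matrix}, a \code{genic_cn_matrix} (its integer-binned
#'   matrix is used), or a plain integer matrix (rows = loci).
#' @param ... unused.
#' @return data.frame with columns \code{locus_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_alleles}, \code{s2}, \code{log10_s2},
#'   \code{pic}.
#' @export
score_diversity <- function(x, ...) UseMethod("score_diversity")

score_rows <- function(mat, ids, chrom = NA, start = NA, end = NA) {
  if (!nrow(mat)) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_alleles = integer(), s2 = numeric(),
                      log10_s2 = numeric(), pic = numeric()))
  }
  s2 <- apply(mat, 1, stats::var)
  data.frame(locus_id = ids, chrom = chrom, start = start, end = end,
             n_alleles = apply(mat, 1, function(v) length(unique(v))),
             s2 = s2,
             log10_s2 = ifelse(s2 > 0, log10(s2), NA_real_),
             pic = apply(mat, 1, pic),
             row.names = NULL)
}

#' @rdname score_diversity
#' @export
score_diversity.cn_matrix <- function(x, ...) {
  score_rows(x$cn, x$loci$locus_id, x$loci$chrom, x$loci$start, x$loci$end)
}

#' @rdname score_diversity
#' @param variable_only for the genic method: restrict scoring to genes
#'   harboring at least one CN variant (some strain with integer CN != 1), so
#'   that invariant genes do not dilute the percentile pools. Default TRUE.
#' @export
score_diversity.genic_cn_matrix <- function(x, variable_only = TRUE, ...) {
  keep <- if (variable_only && nrow(x$cn_int))
    apply(x$cn_int, 1, function(v) any(v != 1L))
  else rep(TRUE, nrow(x$cn_int))
  score_rows(x$cn_int[keep, , drop = FALSE], x$genes$gene_id[keep],
             x$genes$chrom[keep], x$genes$start[keep], x$genes$end[keep])
}

#' @rdname score_diversity
#' @export
score_diversity.matrix <- function(x, ...) {
  ids <- rownames(x) %||% sprintf("locus_%d", seq_len(nrow(x)))
  score_rows(x, ids)
}

#' Select CN-diverse loci by the top-50% rule
#'
#' Flags loci in the top 50% (>= median, inclusive) of defined log10(s2)
#' values, the top 50% of PIC values, and their union (the CN-diverse set).
#' Zero-variance loci are excluded from the log10(s2) percentile pool. The
#' median uses midpoint interpolation for even counts.
#'
#' @param diversity data.frame from [score_diversity()].
#' @return the table with added logical columns \code{top50_s2},
#'   \code{top50_pic}, \code{cn_diverse}; class \code{cn_diversity}. The
#'   selection summary (counts in both, each measure alone, and the union,
#'   plus the two medians) is attached as attribute \code{"summary"} and
#'   returned by \code{summary()}.
#' @export
select_diverse <- function(diversity) {
  stopifnot(is.data.frame(diversity), nrow(diversity) >= 1,
            all(c("log10_s2", "pic") %in% names(diversity)))
  ls <- diversity$log10_s2
  defined <- !is.na(ls)
  med_s2 <- if (any(defined)) stats::median(ls[defined]) else NA_real_
  diversity$top50_s2 <- defined & !is.na(med_s2) & ls >= med_s2
  med_pic <- stats::median(diversity$pic)
  diversity$top50_pic <- diversity$pic >= med_pic
  diversity$cn_diverse <- diversity$top50_s2 | diversity$top50_pic
  smry <- list(n_loci = nrow(diversity),
               n_both = sum(diversity$top50_s2 & diversity$top50_pic),
               n_s2_only = sum(diversity$top50_s2 & !diversity$top50_pic),
               n_pic_only = sum(!diversity$top50_s2 & diversity$top50_pic),
               n_diverse = sum(diversity$cn_diverse),
               median_log10_s2 = med_s2, median_pic = med_pic)
  attr(diversity, "summary") <- smry
  class(diversity) <- c("cn_diversity", "data.frame")
  diversity
}

#' @export
print.cn_diversity <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("cn_diversity: %d loci scored\n", s$n_loci))
  cat(sprintf("  top 50%% by both measures: %d; log10(s2) only: %d; PIC only: %d\n",
              s$n_both, s$n_s2_only, s$n_pic_only))
  cat(sprintf("  CN-diverse (union): %d  [median log10(s2) = %.3g, median PIC = %.3g]\n",
              s$n_diverse, s$median_log10_s2, s$median_pic))
  invisible(x)
}

#' @export
summary.cn_diversity <- function(object, ...) attr(object, "summary")
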