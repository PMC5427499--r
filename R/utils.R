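# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half up to the nearest integer
#'
#' Symmetric rounding rule used for every ratio to copy-number conversion in
#' the package: values in \code{[k - 0.5, k + 0.5)} map to \code{k}, so ratios
#' in \code{[0.5, 1.5)} are the neutral state 1.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(c(0.49, 0.5, 1.49, 1.5, 2.5))
#' @export
round_half_up <- function(x) floor(x + 0.5)

# 0-based half-open intervals -> GRanges (1-based closed). Empty input allowed.
as_granges0 <- function(chrom, start, end, seqlevels = NULL) {
  chrom <- as.character(chrom)
  lev <- unique(c(seqlevels, chrom))
  if (length(lev) == 0L) lev <- "chr_none"
  GenomicRanges::GRanges(factor(chrom, levels = lev),
                         IRanges::IRanges(start = start + 1L, end = as.integer(end)))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# restore window_track class/attributes after data.frame subsetting
keep_track_attrs <- function(new, old) {
  attr(new, "window") <- attr(old, "window")
  attr(new, "strain_id") <- attr(old, "strain_id")
  attr(new, "normalized") <- attr(old, "normalized")
  class(new) <- class(old)
  new
}
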