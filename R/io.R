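#' Read and write windowed depth tracks
#'
#' Depth tracks are 4-column TSV files (\code{chrom}, \code{start},
#' \code{depth}, \code{gc}) with a header line, one file per strain,
#' \code{start} 0-based. Paths ending in \code{.gz} are handled
#' transparently.
#'
#' @param track data.frame with columns \code{chrom}, \code{start},
#'   \code{depth}, \code{gc}.
#' @param path file path; \code{.gz} suffix triggers gzip compression.
#' @return \code{read_depth} returns the track data.frame with a
#'   \code{strain_id} attribute (taken from the file name unless given).
#' @export
write_depth <- function(track, path) {
  stopifnot(all(c("chrom", "start", "depth", "gc") %in% names(track)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(track[, c("chrom", "start", "depth", "gc")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth
#' @param strain_id strain identifier; default: file name without extension.
#' @export
read_depth <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stop_fmt("depth file not found: %s", path)
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "depth", "gc") %in% names(tr)))
  attr(tr, "strain_id") <- strain_id %||%
    sub("\\.(tsv|txt|bedgraph)(\\.gz)?$", "", basename(path))
  tr
}

#' Write and read ground-truth events
#'
#' The truth is stored as two plain-text files: a BED-compatible event table
#' (0-based half-open; columns \code{chrom}, \code{start}, \code{end},
#' \code{name}, \code{class}, \code{carrier_freq}, with a header line) and a
#' per-strain CN matrix TSV (rows = loci, columns = strains). Writing then
#' reading reproduces the truth exactly.
#'
#' @param truth list with elements \code{events} and \code{cn} as produced by
#'   [simulate_population()].
#' @param dir output directory.
#' @param prefix file name prefix (files \code{<prefix>.bed} and
#'   \code{<prefix>_cn.tsv}).
#' @return \code{read_truth} returns a list with \code{events} and \code{cn}.
#' @export
write_truth <- function(truth, dir, prefix = "truth") {
  stopifnot(is.list(truth), !is.null(truth$events), !is.null(truth$cn))
  ev <- truth$events
  bad <- ev$end <= ev$start
  if (any(bad)) stop_fmt("invalid event interval for %s",
                         paste(ev$locus_id[bad], collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                    name = ev$locus_id, class = ev$class,
                    carrier_freq = ev$carrier_freq)
  bed_path <- file.path(dir, paste0(prefix, ".bed"))
  cn_path <- file.path(dir, paste0(prefix, "_cn.tsv"))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cn <- data.frame(locus_id = if (nrow(truth$cn)) rownames(truth$cn)
                   else character(0),
                   truth$cn, check.names = FALSE)
  utils::write.table(cn, cn_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(events = bed_path, cn = cn_path))
}

#' @rdname write_truth
#' @export
read_truth <- function(dir, prefix = "truth") {
  bed_path <- file.path(dir, paste0(prefix, ".bed"))
  cn_path <- file.path(dir, paste0(prefix, "_cn.tsv"))
  for (p in c(bed_path, cn_path))
    if (!file.exists(p)) stop_fmt("truth file not found: %s", p)
  bed <- utils::read.table(bed_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  events <- data.frame(locus_id = as.character(bed$name), chrom = bed$chrom,
                       start = as.integer(bed$start), end = as.integer(bed$end),
                       class = bed$class, carrier_freq = bed$carrier_freq)
  cnt <- utils::read.table(cn_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(cnt)) {
    cn <- as.matrix(cnt[, -1, drop = FALSE])
    storage.mode(cn) <- "integer"
    rownames(cn) <- as.character(cnt$locus_id)
  } else {
    cn <- matrix(integer(), nrow = 0, ncol = max(0L, ncol(cnt) - 1L),
                 dimnames = list(NULL, setdiff(names(cnt), "locus_id")))
  }
  list(events = events, cn = cn)
}

#' Write and read CNVR tables
#'
#' Per-strain CNVRs are stored as BED-like TSV files with a header and
#' columns \code{chrom}, \code{start}, \code{end}, \code{name}, \code{cn},
#' \code{class}, \code{p_value} (0-based half-open coordinates).
#'
#' @param cnvrs data.frame of CNVRs (as returned by [call_strain()]).
#' @param path file path.
#' @export
write_cnvrs <- function(cnvrs, path) {
  strain <- attr(cnvrs, "strain_id") %||% "strain"
  n <- nrow(cnvrs)
  out <- data.frame(chrom = cnvrs$chrom, start = cnvrs$start, end = cnvrs$end,
                    name = if (n) sprintf("%s_cnvr_%d", strain, seq_len(n)) else character(),
                    cn = cnvrs$cn, class = cnvrs$class, p_value = cnvrs$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cnvrs
#' @export
read_cnvrs <- function(path) {
  if (!file.exists(path)) stop_fmt("CNVR file not found: %s", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$cn <- as.integer(x$cn)
  x
}

#' Write and read a genome model as TSV
#'
#' One row per chromosome: \code{name}, \code{length}, \code{cen_start},
#' \code{cen_end}. Essential genes, if present, go to a companion
#' \code{<path>.essential.tsv}.
#'
#' @param genome a [genome_model()].
#' @param path file path.
#' @export
write_genome <- function(genome, path) {
  cen <- genome$centromeres[match(genome$chromosomes$name, genome$centromeres$chrom), ]
  df <- data.frame(name = genome$chromosomes$name,
                   length = genome$chromosomes$length,
                   cen_start = cen$start, cen_end = cen$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(genome$essential_genes))
    utils::write.table(genome$essential_genes, paste0(path, ".essential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_fmt("genome file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ess_path <- paste0(path, ".essential.tsv")
  ess <- if (file.exists(ess_path))
    utils::read.table(ess_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  genome_model(chromosomes = data.frame(name = df$name, length = df$length),
               centromeres = data.frame(chrom = df$name, start = df$cen_start,
                                        end = df$cen_end),
               essential_genes = ess)
}

#' Read a gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) is used as-is; GFF3 input (1-based closed,
#' read via rtracklayer) is converted to 0-based half-open on read. For GFF3,
#' records of type \code{gene} are used when present, all records otherwise;
#' the identifier is taken from \code{ID} or \code{Name}.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of \code{"auto"}, \code{"bed"}, \code{"gff3"}.
#' @return data.frame with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (and \code{essential} if a BED score column of
#'   0/1 values is present).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("gene annotation not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3"
    else "bed"
  }
  if (format == "bed") {
    x <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
    cols <- c("chrom", "start", "end", "name", "score", "strand")
    names(x) <- cols[seq_len(min(ncol(x), 6))]
    out <- data.frame(gene_id = if ("name" %in% names(x)) as.character(x$name)
                      else sprintf("gene_%d", seq_len(nrow(x))),
                      chrom = x$chrom, start = as.integer(x$start),
                      end = as.integer(x$end),
                      strand = if ("strand" %in% names(x)) x$strand else "*")
    if ("score" %in% names(x) && all(x$score %in% c(0, 1)))
      out$essential <- x$score == 1
    out
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    data.frame(gene_id = ids,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
  }
}
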