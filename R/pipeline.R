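#' Pipeline configuration
#'
#' Assembles the configuration of the end-to-end pipeline: genome layout,
#' simulation parameters, caller parameters, context-zone spans and output
#' directory. Defaults describe a small demonstration cohort (5 strains, 2
#' chromosomes) that runs in seconds; any [sim_config()] or
#' [calling_config()] argument can be overridden through the \code{sim} and
#' \code{calling} lists. A configuration can also be read from a YAML file
#' with the same nested structure.
#'
#' @param outdir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_strains,n_loci cohort size.
#' @param n_chrom,chrom_length,centromere_fraction genome layout.
#' @param sim named list of [sim_config()] overrides.
#' @param calling named list of [calling_config()] overrides.
#' @param subtel_span,peri_flank context-zone spans in bp.
#' @param simulate if FALSE, skip simulation and read depth tracks from
#'   \code{depth_dir} instead.
#' @param depth_dir directory of per-strain depth TSVs (used when
#'   \code{simulate = FALSE}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(outdir, seed = 1, n_strains = 5, n_loci = 25,
                            n_chrom = 2, chrom_length = 300000,
                            centromere_fraction = 0.4,
                            sim = list(), calling = list(),
                            subtel_span = 25000, peri_flank = 7000,
                            simulate = TRUE, depth_dir = NULL) {
  stopifnot(is.character(outdir), length(outdir) == 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_strains = as.integer(n_strains),
                 n_loci = as.integer(n_loci), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 centromere_fraction = centromere_fraction,
                 sim = sim, calling = calling, subtel_span = subtel_span,
                 peri_flank = peri_flank, simulate = isTRUE(simulate),
                 depth_dir = depth_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with pipeline_config fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full CN-diversity pipeline
#'
#' Executes simulate (or load) -> call (all strains) -> locus CN matrix ->
#' diversity scoring and selection -> genic CN and gene diversity -> context
#' zones and summary -> cohort summaries -> chromosome diversity map, writing
#' every artifact as plain text under \code{config$outdir} and finishing with
#' a manifest of relative paths and MD5 checksums. Fully reproducible: the
#' same configuration and seed produce byte-identical artifacts and manifest.
#'
#' @param config a [pipeline_config()], a YAML path, or a plain list of
#'   [pipeline_config()] arguments.
#' @return (invisibly) list with the key in-memory objects (genome, truth,
#'   calls, diversity tables, summaries) and the \code{manifest} data.frame.
#' @examples
#' \donttest{
#' out <- run_pipeline(pipeline_config(tempfile("demo"), seed = 1))
#' out$manifest$file
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()
  emit <- function(p) paths[[length(paths) + 1L]] <<- p

  genome <- pipeline_stage("genome", {
    g <- build_genome(config$n_chrom, config$chrom_length,
                      config$centromere_fraction, seed = config$seed)
    write_genome(g, file.path(outdir, "genome.tsv"))
    emit("genome.tsv")
    g
  })

  genes <- pipeline_stage("genes", {
    gn <- simulate_genes(genome, seed = config$seed + 1L)
    bed <- data.frame(chrom = gn$chrom, start = gn$start, end = gn$end,
                      name = gn$gene_id, score = as.integer(gn$essential),
                      strand = gn$strand)
    utils::write.table(bed, file.path(outdir, "genes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    emit("genes.bed")
    gn
  })

  ccfg <- do.call(calling_config, config$calling)

  if (config$simulate) {
    sim <- pipeline_stage("simulate", {
      sargs <- utils::modifyList(
        list(n_strains = config$n_strains, n_loci = config$n_loci,
             seed = config$seed + 2L, window = ccfg$window),
        config$sim)
      s <- simulate_population(genome, do.call(sim_config, sargs))
      write_truth(s$truth, outdir)
      emit("truth.bed"); emit("truth_cn.tsv")
      dir.create(file.path(outdir, "depth"), showWarnings = FALSE)
      for (nm in names(s$tracks)) {
        write_depth(s$tracks[[nm]], file.path(outdir, "depth",
                                              paste0(nm, ".tsv")))
        emit(file.path("depth", paste0(nm, ".tsv")))
      }
      s
    })
    depths <- sim$tracks
    truth <- sim$truth
  } else {
    depths <- pipeline_stage("load_depth", {
      if (is.null(config$depth_dir) || !dir.exists(config$depth_dir))
        stop_fmt("depth directory not found: %s",
                 config$depth_dir %||% "<missing>")
      files <- list.files(config$depth_dir, pattern = "\\.tsv(\\.gz)?$",
                          full.names = TRUE)
      if (!length(files))
        stop_fmt("no depth files in %s", config$depth_dir)
      tr <- lapply(files, read_depth)
      stats::setNames(tr, vapply(tr, attr, "", "strain_id"))
    })
    truth <- NULL
  }

  tracks <- pipeline_stage("normalize", {
    out <- lapply(names(depths), function(s) {
      tr <- depths[[s]]
      if (is.data.frame(tr) && is.null(attr(tr, "strain_id")))
        attr(tr, "strain_id") <- s
      tryCatch(normalize_track(tr, genome, window = ccfg$window,
                               gc_bins = ccfg$gc_bins,
                               mask_telocentromeric = ccfg$mask_telocentromeric),
               error = function(e) stop_fmt("strain %s: %s", s,
                                            conditionMessage(e)))
    })
    stats::setNames(out, names(depths))
  })

  calls <- pipeline_stage("call", {
    dir.create(file.path(outdir, "cnvrs"), showWarnings = FALSE)
    out <- lapply(names(tracks), function(s) {
      cs <- tryCatch(call_strain(tracks[[s]], genome, ccfg),
                     error = function(e) stop_fmt("strain %s: %s", s,
                                                  conditionMessage(e)))
      write_cnvrs(cs, file.path(outdir, "cnvrs", paste0(s, ".bed")))
      emit(file.path("cnvrs", paste0(s, ".bed")))
      cs
    })
    stats::setNames(out, names(tracks))
  })

  cnm <- pipeline_stage("matrix", {
    m <- build_cn_matrix(calls, genome = genome)
    tab <- data.frame(m$loci, m$cn, check.names = FALSE)
    utils::write.table(tab, file.path(outdir, "cn_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("cn_matrix.tsv")
    m
  })

  div <- pipeline_stage("diversity", {
    if (!nrow(cnm$cn)) {
      warning("no CNVRs called; diversity tables empty")
      NULL
    } else {
      d <- select_diverse(score_diversity(cnm))
      utils::write.table(as.data.frame(d),
                         file.path(outdir, "diversity_loci.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("diversity_loci.tsv")
      jsonlite::write_json(summary(d),
                           file.path(outdir, "diversity_summary.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE)
      emit("diversity_summary.json")
      d
    }
  })

  gdiv <- pipeline_stage("gene_diversity", {
    gcm <- genic_cn_matrix(tracks, genes)
    sc <- score_diversity(gcm)
    if (!nrow(sc)) {
      warning("no CN-variable genes; gene diversity table empty")
      NULL
    } else {
      d <- select_diverse(sc)
      utils::write.table(as.data.frame(d),
                         file.path(outdir, "diversity_genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("diversity_genes.tsv")
      d
    }
  })

  zones <- pipeline_stage("zones", {
    z <- build_zones(genome, subtel_span = config$subtel_span,
                     peri_flank = config$peri_flank,
                     essential_genes = genes[genes$essential, , drop = FALSE])
    zb <- rbind(data.frame(z$definition_a[c("chrom", "start", "end")],
                           name = "subtelomere_A"),
                data.frame(z$definition_b[c("chrom", "start", "end")],
                           name = "subtelomere_B"),
                data.frame(z$pericentromeric[c("chrom", "start", "end")],
                           name = "pericentromere"))
    utils::write.table(zb, file.path(outdir, "zones.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    emit("zones.bed")
    z
  })

  ctx <- pipeline_stage("context", {
    dl <- if (!is.null(div)) div[div$cn_diverse, , drop = FALSE] else
      data.frame(chrom = character(), start = integer(), end = integer())
    dg <- if (!is.null(gdiv)) gdiv[gdiv$cn_diverse, , drop = FALSE] else
      data.frame(chrom = character(), start = integer(), end = integer())
    cs <- withCallingHandlers(
      context_summary(dl, dg, zones),
      warning = function(w) invokeRestart("muffleWarning"))
    jsonlite::write_json(unclass(cs), file.path(outdir, "context_summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    emit("context_summary.json")
    cs
  })

  summaries <- pipeline_stage("summaries", {
    cs <- cohort_summary(calls, genome, genes)
    utils::write.table(cs$strains, file.path(outdir, "strain_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("strain_summary.tsv")
    jsonlite::write_json(list(aggregate = cs$aggregate, union = cs$union),
                         file.path(outdir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    emit("cohort_summary.json")
    pooled <- do.call(rbind, lapply(calls, as.data.frame))
    sd <- withCallingHandlers(size_distribution(pooled),
                              warning = function(w) invokeRestart("muffleWarning"))
    utils::write.table(sd, file.path(outdir, "size_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("size_distribution.tsv")
    cs
  })

  pipeline_stage("map", {
    dl <- if (!is.null(div)) div[div$cn_diverse, , drop = FALSE] else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 pic = numeric())
    mp <- chromosome_map(dl, genome, zones, window = ccfg$window)
    utils::write.table(mp, file.path(outdir, "chromosome_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("chromosome_map.tsv")
  })

  manifest <- pipeline_stage("manifest", {
    md5 <- unname(tools::md5sum(file.path(outdir, paths)))
    m <- data.frame(file = paths, md5 = md5)
    utils::write.table(m, file.path(outdir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    m
  })

  invisible(list(genome = genome, genes = genes, truth = truth, calls = calls,
                 cn_matrix = cnm, diversity = div, gene_diversity = gdiv,
                 zones = zones, context = ctx, cohort = summaries,
                 manifest = manifest, outdir = outdir))
}
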