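# End-to-end orchestration: synthesize (or load) -> dyads/occupancy ->
# NDR and flank calls -> gap/NRL/spacing -> optional model fit, with a
# machine-readable run manifest. All randomness flows from the top-level
# seed; identical config + seed gives byte-identical tables.

#' Run the full analysis pipeline
#'
#' @param config either a list or a YAML file path. Recognized fields:
#'   `seed` (mandatory); `synthetic` (list of [synthetic_config()]
#'   arguments, or TRUE for defaults) or `fragments`/`genome`/`genes`
#'   (paths: fragment file + `fragment_format`, chromosome-size TSV
#'   `name<TAB>length`, annotation TSV); `outdir` (mandatory); stage
#'   toggles `fit_model` (default FALSE), `sequence` (default FALSE);
#'   parameter blocks `ndr` (theta, min_width, window_up, window_down) and
#'   `spacing` (min_fragments).
#' @return invisible list of stage outputs (also written under `outdir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  if (is.null(config$outdir)) stop("config error: outdir is mandatory")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list()

  if (!is.null(config$synthetic)) {
    args <- if (isTRUE(config$synthetic)) list() else config$synthetic
    cfg <- stage("simulate", do.call(synthetic_config,
                                     c(list(seed = seed), args)))
    ds <- stage("simulate", synthesize_dataset(cfg,
                                               sequence = isTRUE(config$sequence)))
    genome <- cfg$genome
    genes <- cfg$genes
    frags <- ds$frags
    write_fragments(frags, file.path(config$outdir, "fragments.bed"))
    if (!is.null(ds$seq))
      Biostrings::writeXStringSet(ds$seq,
                                  file.path(config$outdir, "genome.fa"))
    out$synthetic <- ds
  } else {
    if (is.null(config$fragments) || is.null(config$genome))
      stop("config error: need synthetic block or fragments + genome paths")
    if (is.null(config$genes) && (isTRUE(config$fit_model) ||
                                  !is.null(config$ndr)))
      stop("config error: promoter stages requested but no gene annotation given")
    gtab <- data.table::fread(config$genome, header = FALSE,
                              col.names = c("name", "length"),
                              data.table = FALSE)
    genome <- chrom_spec(gtab$name, gtab$length)
    genes <- if (!is.null(config$genes)) read_genes(config$genes, genome)
    else NULL
    frags <- stage("load", read_fragments(
      config$fragments, genome,
      format = config$fragment_format %||% "bed"))
  }

  dy <- stage("dyads", dyads_from_fragments(frags, genome))
  dyn <- stage("dyads", normalize_profile(dy))
  occ <- stage("occupancy", normalize_profile(occupancy_from_dyads(dy)))
  write_track(dyn, file.path(config$outdir, "dyads.bedgraph"))
  write_track(occ, file.path(config$outdir, "occupancy.bedgraph"))
  out$dyads <- dyn
  out$occupancy <- occ

  ge <- stage("gap", estimate_gap(frags, genome))
  data.table::fwrite(data.frame(lag = ge$lag, gap = ge$gap),
                     file.path(config$outdir, "gap.tsv"), sep = "\t")
  data.table::fwrite(data.frame(lag = as.integer(names(ge$curve)),
                                correlation = as.numeric(ge$curve)),
                     file.path(config$outdir, "gap_curve.tsv"), sep = "\t")
  out$gap <- ge

  sp <- stage("nrl", nrl_spectrum(frags, ge))
  data.table::fwrite(data.frame(length = as.integer(names(sp$hist)),
                                count = as.integer(sp$hist),
                                smoothed = sp$smoothed),
                     file.path(config$outdir, "nrl_spectrum.tsv"), sep = "\t")
  data.table::fwrite(data.frame(modal_length = sp$modal_lengths,
                                modal_nrl = sp$modal_nrl,
                                linker = sp$linkers),
                     file.path(config$outdir, "nrl_modes.tsv"), sep = "\t")
  out$nrl <- sp

  if (!is.null(genes)) {
    ndr_args <- config$ndr %||% list()
    ndr <- stage("ndr", do.call(detect_ndrs,
                                c(list(occ = occ, genes = genes), ndr_args)))
    calls <- stage("ndr", refine_flanks(dy, ndr))
    data.table::fwrite(ndr, file.path(config$outdir, "ndr_calls.tsv"),
                       sep = "\t")
    data.table::fwrite(calls, file.path(config$outdir, "nuc_calls.tsv"),
                       sep = "\t")
    write_nuc_calls_bed(calls, file.path(config$outdir, "nuc_calls.bed"))
    out$ndr <- ndr
    out$nuc_calls <- calls

    min_frag <- (config$spacing %||% list())$min_fragments %||% 5000L
    sc <- stage("spacing", per_gene_spacing(frags, genes,
                                            min_fragments = min_frag))
    data.table::fwrite(sc[setdiff(names(sc), "long_lengths")],
                       file.path(config$outdir, "gene_spacing.tsv"),
                       sep = "\t")
    out$spacing <- sc

    if (nrow(sc) >= 5) {
      plus1 <- calls[calls$role == "+1", ]
      anch <- data.frame(gene_id = plus1$gene_id, chrom = plus1$chrom,
                         pos = plus1$dyad,
                         strand = genes$strand[match(plus1$gene_id,
                                                     genes$gene_id)])
      common <- intersect(sc$gene_id, anch$gene_id)
      if (length(common) >= 5) {
        qs <- stage("quintiles", quintile_summary(
          sc[sc$gene_id %in% common, ], dyn,
          ndr[ndr$gene_id %in% common, ],
          anch[anch$gene_id %in% common, ]))
        data.table::fwrite(qs$table,
                           file.path(config$outdir, "quintiles.tsv"),
                           sep = "\t")
        out$quintiles <- qs
      }
    }

    if (isTRUE(config$fit_model) && exists("calls")) {
      pl <- calls[calls$role == "-1", c("gene_id", "chrom", "dyad")]
      pr <- calls[calls$role == "+1", c("gene_id", "chrom", "dyad")]
      fl <- merge(pl, pr, by = c("gene_id", "chrom"),
                  suffixes = c("_l", "_r"))
      nm <- genome$name[1]  # train on the first chromosome
      flc <- data.frame(p_l = fl$dyad_l[fl$chrom == nm],
                        p_r = fl$dyad_r[fl$chrom == nm])
      flc <- flc[order(flc$p_l), ]
      fit <- stage("model", fit_barrier(dyn[[nm]], flc, seed = seed))
      write_fit_yaml(fit, file.path(config$outdir, "barrier_fit.yaml"))
      pred <- stage("model", predict_genome(
        data.frame(chrom = nm, p_l = flc$p_l, p_r = flc$p_r),
        fit$params, genome[genome$name == nm, , drop = FALSE]))
      write_track(prediction_profile(pred, "n"),
                  file.path(config$outdir, "model_dyads.bedgraph"))
      write_track(prediction_profile(pred, "occ"),
                  file.path(config$outdir, "model_occupancy.bedgraph"))
      out$fit <- fit
    }
  } else if (isTRUE(config$fit_model) || !is.null(config$ndr)) {
    stop("config error: promoter stages requested but no gene annotation given")
  }

  if (isTRUE(config$sequence) && !is.null(out$synthetic$seq)) {
    dp <- stage("dinuc", dinucleotide_phasing(dy, out$synthetic$seq))
    data.table::fwrite(dp, file.path(config$outdir, "dinucleotide.tsv"),
                       sep = "\t")
    out$dinucleotide <- dp
  }

  manifest <- list(
    package = "nuclinker",
    version = as.character(utils::packageVersion("nuclinker")),
    seed = seed,
    config_hash = paste(deparse(config[sort(names(config))]),
                        collapse = ""),
    stages = names(out))
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
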