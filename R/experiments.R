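# Self-contained reproducibility experiments: each runs the full relevant
# slice of the pipeline on synthetic inputs and returns the measured
# quantities. These back the analysis scripts and the acceptance checks.

#' Cleavage-gap experiment on default synthetic chromatin
#'
#' Generates the default synthetic dataset (quantized linker mixture, cut
#' probability 0.8, 5% background; about 1.1e5 fragments), builds the
#' genome-wide end-count vectors for short-class right ends and
#' medium-class left ends, and estimates the cleavage gap by
#' cross-correlation over lags 1..20.
#'
#' @param seed integer seed.
#' @param cfg optional [synthetic_config()] override.
#' @return list: `gap_estimate`, `n_fragments`, `frags`, `config`.
#' @export
experiment_gap <- function(seed, cfg = NULL) {
  if (is.null(cfg)) cfg <- synthetic_config(seed = seed)
  ds <- synthesize_dataset(cfg)
  ge <- estimate_gap(ds$frags, cfg$genome)
  list(gap_estimate = ge, n_fragments = nrow(ds$frags),
       frags = ds$frags, config = cfg)
}

#' NRL-spectrum experiment on default synthetic chromatin
#'
#' Same dataset as [experiment_gap()]; classifies fragments, estimates the
#' gap, histograms long-class lengths, calls modes, and reports modal NRLs
#' (modal long length + gap).
#'
#' @param seed integer seed.
#' @param cfg optional [synthetic_config()] override.
#' @return list: `spectrum`, `gap_estimate`, `smallest_modal_nrl`,
#'   `n_fragments`.
#' @export
experiment_nrl <- function(seed, cfg = NULL) {
  ge <- experiment_gap(seed, cfg)
  sp <- nrl_spectrum(ge$frags, ge$gap_estimate)
  list(spectrum = sp, gap_estimate = ge$gap_estimate,
       smallest_modal_nrl = if (length(sp$modal_nrl)) min(sp$modal_nrl)
       else NA_integer_,
       n_fragments = ge$n_fragments)
}

#' Worked cleavage-geometry example: one nucleosome, both sites cut
#'
#' Places a single nucleosome on an otherwise empty chromosome, sets the
#' cut probability to 1 and background to 0, cleaves, and measures the
#' intranucleosomal fragment (the one centered on the dyad).
#'
#' @param seed integer seed (the outcome is deterministic).
#' @return list: `fragment_length`, `dyad`, `frags`.
#' @export
experiment_core_fragment <- function(seed = 1L) {
  genome <- chrom_spec("toy", 2000L)
  genes <- data.frame(gene_id = "g1", chrom = "toy", strand = "+",
                      tss = 900L, tts = 1500L)
  cfg <- synthetic_config(seed = seed, genome = genome, genes = genes,
                          n_cells = 1L, cut_probability = 1,
                          background_rate = 0)
  dyad <- 1000L
  cells <- list(list(toy = dyad))
  frags <- cleave(cells, cfg)
  len <- frags$end - frags$start + 1L
  mid <- (frags$start + frags$end) %/% 2L
  core <- which(mid == dyad & frags$start > 1L & frags$end < genome$length)
  list(fragment_length = len[core], dyad = dyad, frags = frags)
}

#' Footprint-width example: occupancy of a single dyad
#'
#' One dyad at position 500 on a 1000-bp chromosome, default half-width.
#'
#' @return list: `width` (bp of nonzero occupancy), `support` (range).
#' @export
experiment_footprint <- function() {
  genome <- chrom_spec("toy", 1000L)
  d <- new_profile(genome)
  d[["toy"]][500] <- 1
  occ <- occupancy_from_dyads(d)
  nz <- which(occ[["toy"]] > 0)
  list(width = length(nz), support = range(nz))
}

#' Reference promoter-barrier parameters
#'
#' Barrier parameters characteristic of yeast promoters: height 7.88 kT,
#' half-width 27.64 bp, centers 68 bp inside the -1/+1 dyads, baseline
#' u - mu = -2.79 kT.
#' @return a [barrier_params()].
#' @export
reference_barrier_params <- function() {
  barrier_params(H = 7.88, sigma = 27.64, x0 = 68, u_minus_mu = -2.79)
}

#' Build a regular synthetic promoter lattice
#'
#' `n_genes` promoters spaced `spacing` bp apart on one lattice, each with
#' flank dyads `p_l` and `p_r = p_l + flank_span`.
#'
#' @param n_genes number of promoters (default 200).
#' @param spacing promoter spacing in bp (default 2000).
#' @param flank_span distance between the -1 and +1 dyads (default 280).
#' @param margin bp of lattice left of the first / right of the last
#'   promoter (default 1600).
#' @return list: `L`, `flanks` (data.frame `p_l`, `p_r`).
#' @export
synthetic_promoter_lattice <- function(n_genes = 200L, spacing = 2000L,
                                       flank_span = 280L, margin = 1600L) {
  p_l <- margin + spacing * (seq_len(n_genes) - 1L)
  flanks <- data.frame(p_l = p_l, p_r = p_l + flank_span)
  list(L = as.integer(max(flanks$p_r) + margin), flanks = flanks)
}

#' Barrier parameter-recovery experiment
#'
#' Forward-simulates the dyad density on a synthetic promoter lattice at
#' the reference barrier parameters, then refits the model from random
#' initializations and reports the recovered parameters together with the
#' truth and the achieved 2D correlation.
#'
#' @param seed integer seed for the optimizer.
#' @param n_genes number of promoters (default 200).
#' @param truth true parameters (default [reference_barrier_params()]).
#' @param ... further arguments passed to [fit_barrier()] (e.g. `n_lhs`,
#'   `maxit`).
#' @return list: `truth`, `recovered`, `correlation`, `n_evaluations`.
#' @export
experiment_barrier_recovery <- function(seed, n_genes = 200L,
                                        truth = reference_barrier_params(),
                                        ...) {
  lat <- synthetic_promoter_lattice(n_genes = n_genes)
  u <- build_barrier(lat$flanks, truth, lat$L)
  pf <- partition_function(lattice_model(lat$L, u = u))
  fit <- fit_barrier(observed = pf$n, flanks = lat$flanks, seed = seed, ...)
  list(truth = truth, recovered = fit$params,
       correlation = fit$correlation, n_evaluations = fit$n_evaluations)
}
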