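# Synthetic chemical-cleavage chromatin.
#
# The generator emulates the experiment's statistical structure: per-cell
# nucleosome arrays tiled with linkers drawn from a quantized set, one
# dyad-free NDR per promoter, two Bernoulli cleavage sites per nucleosome
# that release a 51-bp core when both cut, a fixed number of bp lost at
# every realized cut, and a uniform background fraction of fragments.

#' Configuration for the synthetic cleavage generator
#'
#' Defaults encode the study conditions the analysis assumes: 147-bp
#' nucleosomes (odd, so the dyad is a single bp), quantized linkers
#' {5, 15, 25} bp with equal weights, a 51-bp intranucleosomal core, 4 bp
#' lost at every cleavage site, per-site cut probability 0.8, and a 5%
#' uniform background.
#'
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param genome [chrom_spec()] table; default one 200-kb chromosome.
#' @param genes gene annotation; default 99 tandem '+' genes every 2 kb.
#' @param n_cells number of cells (independent chromatin configurations).
#' @param nucleosome_length hard-core nucleosome footprint, odd bp (147).
#' @param linker_set allowed linker lengths in bp.
#' @param linker_weights mixture weights (default equal; must sum to 1).
#' @param ndr_width_range min/max width (bp) of the dyad-exclusion zone
#'   drawn per promoter.
#' @param ndr_offset distance (bp) from the TSS upstream to the NDR center.
#' @param cut_probability per-cleavage-site Bernoulli probability in (0, 1].
#' @param gap bp lost at each realized cleavage site (default 4).
#' @param core length of the intranucleosomal fragment released when both
#'   sites of one nucleosome cut (default 51; odd).
#' @param background_rate fraction of emitted fragments that are uniform
#'   random intervals with lengths drawn from the empirical length set.
#' @param gc_oscillation embed a 10-bp periodic WW enrichment under dyads
#'   when generating sequence.
#' @param ww_amplitude amplitude of the periodic W-base enrichment.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             genome = NULL,
                             genes = NULL,
                             n_cells = 60L,
                             nucleosome_length = 147L,
                             linker_set = c(5L, 15L, 25L),
                             linker_weights = NULL,
                             ndr_width_range = c(100L, 160L),
                             ndr_offset = 80L,
                             cut_probability = 0.8,
                             gap = 4L,
                             core = 51L,
                             background_rate = 0.05,
                             gc_oscillation = TRUE,
                             ww_amplitude = 0.2) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(genome)) genome <- chrom_spec("chrS", 200000L)
  if (is.null(genes)) {
    tss <- seq(2000L, genome$length[1] - 2000L, by = 2000L)
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_along(tss)),
                        chrom = genome$name[1], strand = "+",
                        tss = tss, tts = tss + 1200L,
                        stringsAsFactors = FALSE)
  }
  genes <- as_genes(genes, genome)
  if (is.null(linker_weights))
    linker_weights <- rep(1 / length(linker_set), length(linker_set))
  stopifnot(length(linker_weights) == length(linker_set))
  if (abs(sum(linker_weights) - 1) > 1e-9) stop("linker weights must sum to 1")
  if (!(cut_probability > 0 && cut_probability <= 1))
    stop("cut_probability must be in (0, 1]")
  if (nucleosome_length %% 2L == 0L) stop("nucleosome_length must be odd")
  if (core %% 2L == 0L) stop("core must be odd")
  structure(list(seed = as.integer(seed), genome = genome, genes = genes,
                 n_cells = as.integer(n_cells),
                 nucleosome_length = as.integer(nucleosome_length),
                 linker_set = as.integer(linker_set),
                 linker_weights = as.numeric(linker_weights),
                 ndr_width_range = as.integer(ndr_width_range),
                 ndr_offset = as.integer(ndr_offset),
                 cut_probability = cut_probability,
                 gap = as.integer(gap), core = as.integer(core),
                 background_rate = background_rate,
                 gc_oscillation = isTRUE(gc_oscillation),
                 ww_amplitude = ww_amplitude),
            class = "synthetic_config")
}

#' Read a synthetic-generator configuration from YAML
#'
#' The seed is mandatory; `genome` is given as `name: length` pairs and
#' `genes` as a path to an annotation TSV (or omitted for the defaults).
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("YAML config must set a seed")
  genome <- if (!is.null(y$genome))
    chrom_spec(names(y$genome), unlist(y$genome)) else NULL
  genes <- if (!is.null(y$genes)) read_genes(y$genes, genome) else NULL
  args <- y[setdiff(names(y), c("genome", "genes"))]
  do.call(synthetic_config, c(args, list(genome = genome, genes = genes)))
}

# NDR intervals are gene properties, fixed across cells: centered
# ndr_offset bp upstream of the TSS with a width drawn per gene.
draw_ndrs <- function(cfg) {
  g <- cfg$genes
  w <- sample(seq(cfg$ndr_width_range[1], cfg$ndr_width_range[2]),
              nrow(g), replace = TRUE)
  center <- ifelse(g$strand == "+", g$tss - cfg$ndr_offset,
                   g$tss + cfg$ndr_offset)
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             ndr_l = as.integer(center - w %/% 2L),
             ndr_r = as.integer(center + w %/% 2L),
             stringsAsFactors = FALSE)
}

#' Generate per-cell nucleosome configurations
#'
#' Each promoter carries a dyad-exclusion NDR of drawn width centered
#' between its -1 and +1 nucleosomes, whose dyads sit flush against the
#' NDR edges and are therefore identical across cells (the statistical
#' positioning anchors). For each cell, arrays are tiled outward from
#' these anchors with dyad-to-dyad spacings equal to `nucleosome_length`
#' plus a linker drawn independently from the quantized mixture; the two
#' walks growing toward each other inside an intergenic segment meet at a
#' single unquantized junction gap of at least one nucleosome length, far
#' from the promoters.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `chromatin_ensemble` with elements `cells` (list
#'   of per-cell, per-chromosome sorted dyad vectors), `ndr` (designed NDR
#'   intervals with the fixed `minus1`/`plus1` dyads), and `truth` (per
#'   gene: the flank dyads, the dyad-free interval, and its midpoint
#'   `center`, the ground truth for NDR detection).
#' @export
generate_chromatin <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  h <- (cfg$nucleosome_length - 1L) %/% 2L
  a <- cfg$nucleosome_length
  ndr <- draw_ndrs(cfg)
  ndr$minus1 <- ndr$ndr_l - h - 1L
  ndr$plus1 <- ndr$ndr_r + h + 1L
  draw <- function(n) cfg$linker_set[sample.int(length(cfg$linker_set), n,
                                                replace = TRUE,
                                                prob = cfg$linker_weights)]
  cells <- vector("list", cfg$n_cells)
  for (ci in seq_len(cfg$n_cells)) {
    cell <- list()
    for (gi in seq_len(nrow(cfg$genome))) {
      nm <- cfg$genome$name[gi]
      L <- cfg$genome$length[gi]
      nd <- ndr[ndr$chrom == nm, , drop = FALSE]
      nd <- nd[order(nd$ndr_l), , drop = FALSE]
      if (nrow(nd) && any(nd$minus1 - h < 0L | nd$plus1 + h > L))
        stop("NDR too close to a chromosome end on ", nm)
      if (nrow(nd) > 1 && any(nd$minus1[-1] - nd$plus1[-nrow(nd)] < 2L * a))
        stop("genes too dense to fit one nucleosome between NDRs")
      dy <- integer(0)
      walk_right <- function(from, stop_at) {
        # dyads from `from` rightward while dyad <= stop_at
        out <- integer(0)
        d <- from
        while (d <= stop_at) {
          out <- c(out, d)
          d <- d + a + draw(1L)
        }
        out
      }
      walk_left <- function(from, stop_at) {
        out <- integer(0)
        d <- from
        while (d >= stop_at) {
          out <- c(out, d)
          d <- d - a - draw(1L)
        }
        rev(out)
      }
      if (nrow(nd) == 0L) {
        start <- h + 1L + sample.int(a, 1L) - 1L
        dy <- walk_right(start, L - h)
      } else {
        dy <- walk_left(nd$minus1[1], h + 1L)
        for (j in seq_len(nrow(nd))) {
          right_stop <- if (j < nrow(nd))
            (nd$plus1[j] + nd$minus1[j + 1L]) %/% 2L else L - h
          right <- walk_right(nd$plus1[j], right_stop)
          dy <- c(dy, right)
          if (j < nrow(nd)) {
            r_last <- right[length(right)]
            left <- walk_left(nd$minus1[j + 1L], r_last + a)
            dy <- c(dy, left)
          }
        }
      }
      cell[[nm]] <- dy
    }
    cells[[ci]] <- cell
  }
  truth <- data.frame(gene_id = ndr$gene_id, chrom = ndr$chrom,
                      minus1 = ndr$minus1, plus1 = ndr$plus1,
                      free_l = ndr$ndr_l, free_r = ndr$ndr_r,
                      stringsAsFactors = FALSE)
  truth$center <- (truth$free_l + truth$free_r) %/% 2L
  structure(list(cells = cells, ndr = ndr, truth = truth, config = cfg),
            class = "chromatin_ensemble")
}

#' Apply the cleavage chemistry to per-cell configurations
#'
#' Each nucleosome with dyad `d` owns two cleavage sites. With
#' `c = (core - 1)/2` and gap `g`, a cut at the left site ends the upstream
#' piece at `d - (c + g + 1)` and starts the downstream piece at `d - c`
#' (the `g` intervening bp are lost); the right site is the mirror image.
#' Each site cuts independently with probability `cut_probability`. Emitted
#' fragments are the maximal uncut intervals between consecutive realized
#' cuts (chromosome ends close the terminal fragments). A
#' `background_rate` fraction of the output is uniform random intervals
#' with lengths resampled from the real fragments.
#'
#' @param cells a `chromatin_ensemble` (or its `cells` element).
#' @param cfg the [synthetic_config()] used to generate them.
#' @return Fragment data.frame (`chrom`, `start`, `end`, 1-based inclusive).
#' @export
cleave <- function(cells, cfg) {
  if (inherits(cells, "chromatin_ensemble")) cells <- cells$cells
  set.seed(cfg$seed + 1L)
  cc <- (cfg$core - 1L) %/% 2L
  g <- cfg$gap
  res <- vector("list", length(cells) * nrow(cfg$genome))
  k <- 0L
  for (cell in cells) {
    for (gi in seq_len(nrow(cfg$genome))) {
      nm <- cfg$genome$name[gi]
      L <- cfg$genome$length[gi]
      dy <- cell[[nm]]
      if (is.null(dy) || !length(dy)) next
      # site j has: end of upstream piece, start of downstream piece
      site_end <- c(dy - (cc + g + 1L), dy + cc)
      site_start <- c(dy - cc, dy + cc + g + 1L)
      o <- order(site_end)
      site_end <- site_end[o]
      site_start <- site_start[o]
      cut <- runif(length(site_end)) < cfg$cut_probability
      se <- site_end[cut]
      ss <- site_start[cut]
      if (!length(se)) {
        starts <- 1L; ends <- L
      } else {
        starts <- c(1L, ss)
        ends <- c(se, L)
      }
      ok <- starts <= ends & ends >= 1L & starts <= L
      starts <- pmax(starts[ok], 1L)
      ends <- pmin(ends[ok], L)
      k <- k + 1L
      res[[k]] <- data.frame(chrom = nm, start = starts, end = ends,
                             stringsAsFactors = FALSE)
    }
  }
  frags <- as.data.frame(data.table::rbindlist(res[seq_len(k)]))
  # background: uniform random intervals, lengths from the empirical set
  if (cfg$background_rate > 0 && nrow(frags) > 0) {
    n_bg <- round(cfg$background_rate / (1 - cfg$background_rate) * nrow(frags))
    if (n_bg > 0) {
      pool <- frags$end - frags$start + 1L
      lens <- pool[sample.int(length(pool), n_bg, replace = TRUE)]
      ci <- sample.int(nrow(cfg$genome), n_bg, replace = TRUE,
                       prob = cfg$genome$length)
      Lv <- cfg$genome$length[ci]
      lens <- pmin(lens, Lv)
      st <- floor(runif(n_bg, min = 1, max = Lv - lens + 1 + 1))
      bg <- data.frame(chrom = cfg$genome$name[ci],
                       start = as.integer(st),
                       end = as.integer(st + lens - 1L),
                       stringsAsFactors = FALSE)
      frags <- rbind(frags, bg)
    }
  }
  rownames(frags) <- NULL
  frags
}

#' Generate a genome sequence with rotational-phasing composition
#'
#' Bases are i.i.d. uniform except under nucleosomes: the probability of a
#' W base (A or T) at position `i` is modulated by
#' `amplitude * <cos(2*pi*(i - d)/10)>` averaged over the pooled dyads `d`
#' within 73 bp, so WW dinucleotide frequency around aligned dyads carries a
#' 10-bp period. With amplitude 0 the composition is flat.
#'
#' @param cfg a [synthetic_config()].
#' @param cells a `chromatin_ensemble` from [generate_chromatin()].
#' @return A [Biostrings::DNAStringSet] with one sequence per chromosome.
#' @export
generate_sequence <- function(cfg, cells) {
  if (inherits(cells, "chromatin_ensemble")) cells <- cells$cells
  set.seed(cfg$seed + 2L)
  h <- (cfg$nucleosome_length - 1L) %/% 2L
  amp <- if (cfg$gc_oscillation) cfg$ww_amplitude else 0
  seqs <- lapply(seq_len(nrow(cfg$genome)), function(gi) {
    nm <- cfg$genome$name[gi]
    L <- cfg$genome$length[gi]
    pW <- rep(0.5, L)
    if (amp > 0) {
      cnt <- numeric(L)
      for (cell in cells) {
        dyv <- cell[[nm]]
        if (length(dyv)) cnt[dyv] <- cnt[dyv] + 1
      }
      ker <- cos(2 * pi * (-h:h) / 10)
      occk <- rep(1, 2L * h + 1L)
      sig <- stats::filter(cnt, ker, sides = 2)
      den <- stats::filter(cnt, occk, sides = 2)
      sig[is.na(sig)] <- 0
      den[is.na(den)] <- 0
      mod <- ifelse(den > 0, as.numeric(sig) / as.numeric(den), 0)
      pW <- pmin(pmax(0.5 + amp * mod, 0.02), 0.98)
    }
    isW <- runif(L) < pW
    base <- character(L)
    base[isW] <- sample(c("A", "T"), sum(isW), replace = TRUE)
    base[!isW] <- sample(c("C", "G"), sum(!isW), replace = TRUE)
    paste(base, collapse = "")
  })
  names(seqs) <- cfg$genome$name
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: chromatin, fragments, and (optionally) sequence.
#'
#' @param cfg a [synthetic_config()].
#' @param sequence also generate the genome sequence (default FALSE).
#' @return list with `config`, `chromatin`, `frags`, and optionally `seq`.
#' @export
synthesize_dataset <- function(cfg, sequence = FALSE) {
  chromatin <- generate_chromatin(cfg)
  frags <- cleave(chromatin, cfg)
  out <- list(config = cfg, chromatin = chromatin, frags = frags)
  if (sequence) out$seq <- generate_sequence(cfg, chromatin)
  out
}
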