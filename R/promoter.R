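# NDR detection and template-based refinement of the +1/-1 nucleosome dyads.

#' Oscillatory dyad-cluster template
#'
#' Nucleosomes occupy alternative rotational positions in different cells,
#' spaced by the DNA helical twist (~10 bp). The cluster of dyad counts
#' around a consensus position is modeled as a symmetric sum of Gaussians at
#' 0, +/-10, +/-20, +/-30 bp with weights 1, 0.75, 0.50, 0.25 and width
#' sigma = 2 bp:
#' `D0(x) = G(x,0,2) + 0.75 G(x,10,2) + 0.50 G(x,20,2) + 0.25 G(x,30,2)
#'  + 0.75 G(x,-10,2) + 0.50 G(x,-20,2) + 0.25 G(x,-30,2)`,
#' with `G(x,c,s) = exp(-(x-c)^2 / (2 s^2))`.
#'
#' @param x integer offsets (bp) from the cluster center.
#' @return template values; symmetric, maximal at x = 0.
#' @export
template_value <- function(x) {
  G <- function(x, c, s) exp(-(x - c)^2 / (2 * s^2))
  G(x, 0, 2) +
    0.75 * (G(x, 10, 2) + G(x, -10, 2)) +
    0.50 * (G(x, 20, 2) + G(x, -20, 2)) +
    0.25 * (G(x, 30, 2) + G(x, -30, 2))
}

#' The template evaluated on its support [-35, 35] bp
#' @return named numeric vector of `template_value` at -35..35.
#' @export
oscillatory_template <- function() {
  x <- -35:35
  structure(template_value(x), names = x)
}

#' Detect nucleosome-depleted regions in promoters
#'
#' Scans a transcription-oriented promoter search window (default TSS-500
#' to TSS+150) of a normalized 101-bp-footprint occupancy profile for the
#' widest maximal run of occupancy below `theta` times the chromosome mean
#' with run length >= `min_width`. The NDR center is the run midpoint;
#' provisional -1/+1 dyads are the first local occupancy maxima flanking
#' the run; `width_halfmax` is the distance between the half-maximum
#' crossings adjacent to the flanks, and `run_length` the sub-threshold run
#' length (both are reported since either is a defensible "NDR width").
#'
#' @param occ occupancy `bp_profile` (101-bp footprints, normalized).
#' @param genes gene annotation data.frame.
#' @param theta occupancy threshold as a fraction of the chromosome mean
#'   (default 0.4).
#' @param min_width minimum sub-threshold run length in bp (default 50).
#' @param window_up,window_down promoter search window, bp upstream /
#'   downstream of the TSS in transcription orientation (defaults 500, 150).
#' @param smooth width (bp, odd) of the centered moving average applied to
#'   the occupancy before locating the flanking local maxima (default 51);
#'   suppresses single-bp background bumps on occupancy plateaus. The
#'   sub-threshold run itself is found on the raw occupancy.
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `found`, `center`, `run_length`, `width_halfmax`, `left_flank`,
#'   `right_flank` (genomic order), `minus1_prov`, `plus1_prov`
#'   (transcription orientation). Genes with no qualifying run have
#'   `found = FALSE` and NA coordinates.
#' @export
detect_ndrs <- function(occ, genes, theta = 0.4, min_width = 50L,
                        window_up = 500L, window_down = 150L, smooth = 51L) {
  genes <- as_genes(genes)
  out <- vector("list", nrow(genes))
  means <- vapply(occ, mean, numeric(1))
  # local occupancy maxima per chromosome (plateau centers of the smoothed
  # profile), computed once
  locmax <- lapply(occ, function(v) {
    s <- if (smooth > 1L) {
      sv <- as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 2))
      sv[is.na(sv)] <- 0
      sv
    } else v
    plateau_maxima(s, seq_along(s))
  })
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- occ[[g$chrom]]
    L <- length(v)
    thr <- theta * means[[g$chrom]]
    if (g$strand == "+") {
      w1 <- max(1L, g$tss - window_up); w2 <- min(L, g$tss + window_down)
    } else {
      w1 <- max(1L, g$tss - window_down); w2 <- min(L, g$tss + window_up)
    }
    below <- v[w1:w2] < thr
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= min_width)
    row <- data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                      found = FALSE, center = NA_integer_,
                      run_length = NA_integer_, width_halfmax = NA_integer_,
                      left_flank = NA_integer_, right_flank = NA_integer_,
                      minus1_prov = NA_integer_, plus1_prov = NA_integer_,
                      stringsAsFactors = FALSE)
    if (length(cand)) {
      best <- cand[which.max(r$lengths[cand])]
      rs <- w1 + starts[best] - 1L
      re <- w1 + ends[best] - 1L
      lm <- locmax[[g$chrom]]
      lf <- lm[lm < rs]
      rf <- lm[lm > re]
      left_flank <- if (length(lf)) max(lf) else NA_integer_
      right_flank <- if (length(rf)) min(rf) else NA_integer_
      # half-maximum crossings adjacent to the flanks
      lcross <- rcross <- NA_integer_
      if (!is.na(left_flank)) {
        hl <- v[left_flank] / 2
        j <- left_flank
        while (j < re && v[j] > hl) j <- j + 1L
        lcross <- j
      }
      if (!is.na(right_flank)) {
        hr <- v[right_flank] / 2
        j <- right_flank
        while (j > rs && v[j] > hr) j <- j - 1L
        rcross <- j
      }
      row$found <- TRUE
      row$center <- (rs + re) %/% 2L
      row$run_length <- re - rs + 1L
      row$width_halfmax <- if (!is.na(lcross) && !is.na(rcross))
        rcross - lcross else NA_integer_
      row$left_flank <- left_flank
      row$right_flank <- right_flank
      if (g$strand == "+") {
        row$minus1_prov <- left_flank; row$plus1_prov <- right_flank
      } else {
        row$minus1_prov <- right_flank; row$plus1_prov <- left_flank
      }
    }
    out[[i]] <- row
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Refine a provisional nucleosome dyad with the oscillatory template
#'
#' Scans candidate centers within +/- `search` bp (a 50-bp window by
#' default) of the provisional dyad and returns the center maximizing the
#' inner product of the dyad counts with [template_value()] over its
#' [-35, 35] support. Ties are broken by smallest shift from the
#' provisional position, then by lower coordinate.
#'
#' @param dyads numeric vector of dyad counts for one chromosome, or a
#'   `bp_profile` together with `chrom`.
#' @param provisional provisional dyad coordinate (bp).
#' @param chrom chromosome name when `dyads` is a profile.
#' @param search half-width of the candidate window (default 25).
#' @return list with `dyad` (refined coordinate), `score` (template inner
#'   product), `shift`, and `flagged` (TRUE when the whole window had zero
#'   counts and the provisional position was returned).
#' @export
refine_flank <- function(dyads, provisional, chrom = NULL, search = 25L) {
  v <- if (inherits(dyads, "bp_profile")) dyads[[chrom]] else dyads
  L <- length(v)
  supp <- -35:35
  tpl <- template_value(supp)
  cand <- (provisional - search):(provisional + search)
  cand <- cand[cand >= 1L & cand <= L]
  score <- vapply(cand, function(cc) {
    pos <- cc + supp
    ok <- pos >= 1L & pos <= L
    sum(v[pos[ok]] * tpl[ok])
  }, numeric(1))
  if (all(score == 0)) {
    return(list(dyad = provisional, score = 0, shift = 0L, flagged = TRUE))
  }
  best <- which(score == max(score))
  if (length(best) > 1) {
    sh <- abs(cand[best] - provisional)
    best <- best[sh == min(sh)]
    best <- best[which.min(cand[best])]
  }
  list(dyad = cand[best], score = score[best],
       shift = cand[best] - provisional, flagged = FALSE)
}

#' Refine all -1/+1 calls of an NDR table
#'
#' @param dyads dyad `bp_profile`.
#' @param ndr_calls data.frame from [detect_ndrs()].
#' @param search half-width of the search window (default 25).
#' @return data.frame with one row per (gene, role) with the refined dyad
#'   and template score; the refined dyad never moves more than `search` bp.
#' @export
refine_flanks <- function(dyads, ndr_calls, search = 25L) {
  nd <- ndr_calls[ndr_calls$found & !is.na(ndr_calls$minus1_prov) &
                    !is.na(ndr_calls$plus1_prov), , drop = FALSE]
  rows <- vector("list", 2L * nrow(nd))
  k <- 0L
  for (i in seq_len(nrow(nd))) {
    for (role in c("-1", "+1")) {
      prov <- if (role == "-1") nd$minus1_prov[i] else nd$plus1_prov[i]
      r <- refine_flank(dyads, prov, chrom = nd$chrom[i], search = search)
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = nd$gene_id[i], chrom = nd$chrom[i],
                              role = role, dyad = r$dyad, score = r$score,
                              provisional = prov, flagged = r$flagged,
                              stringsAsFactors = FALSE)
    }
  }
  as.data.frame(data.table::rbindlist(rows[seq_len(k)]))
}

#' Write -1/+1 nucleosome calls as BED6
#'
#' name = `gene_id:role`, score = template score scaled to 0-1000.
#' @param calls data.frame from [refine_flanks()].
#' @param path output path.
#' @export
write_nuc_calls_bed <- function(calls, path) {
  sc <- calls$score
  sc <- if (max(sc) > 0) round(1000 * sc / max(sc)) else 0
  bed <- data.frame(chrom = calls$chrom, start = calls$dyad - 1L,
                    end = calls$dyad,
                    name = paste0(calls$gene_id, ":", calls$role),
                    score = sc, strand = ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Classify gene neighbours at both gene ends
#'
#' Labels each gene's 5' end `divergent` (head-to-head with the upstream
#' neighbour) or `tandem`, and its 3' end `convergent` (tail-to-tail with
#' the downstream neighbour) or `tandem`, with the distance to the
#' neighbouring gene end as a sort key. Chromosome-terminal genes are
#' flagged `no neighbor`.
#'
#' @param genes gene annotation data.frame.
#' @return data.frame with `gene_id`, `class5`, `neighbor5`, `dist5`,
#'   `class3`, `neighbor3`, `dist3`.
#' @export
classify_gene_pairs <- function(genes) {
  genes <- as_genes(genes)
  lo <- pmin(genes$tss, genes$tts)
  ord <- order(genes$chrom, lo)
  g <- genes[ord, , drop = FALSE]
  n <- nrow(g)
  res <- data.frame(gene_id = g$gene_id,
                    class5 = NA_character_, neighbor5 = NA_character_,
                    dist5 = NA_integer_,
                    class3 = NA_character_, neighbor3 = NA_character_,
                    dist3 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    prev <- if (i > 1 && g$chrom[i - 1] == g$chrom[i]) i - 1L else NA
    nxt <- if (i < n && g$chrom[i + 1] == g$chrom[i]) i + 1L else NA
    up <- if (g$strand[i] == "+") prev else nxt    # upstream of the 5' end
    dn <- if (g$strand[i] == "+") nxt else prev    # downstream of the 3' end
    if (is.na(up)) {
      res$class5[i] <- "no neighbor"
    } else {
      res$class5[i] <- if (g$strand[up] != g$strand[i]) "divergent" else "tandem"
      res$neighbor5[i] <- g$gene_id[up]
      res$dist5[i] <- abs(g$tss[i] - g$tss[up])
    }
    if (is.na(dn)) {
      res$class3[i] <- "no neighbor"
    } else {
      res$class3[i] <- if (g$strand[dn] != g$strand[i]) "convergent" else "tandem"
      res$neighbor3[i] <- g$gene_id[dn]
      res$dist3[i] <- abs(g$tts[i] - g$tts[dn])
    }
  }
  res[match(genes$gene_id, res$gene_id), , drop = FALSE]
}
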