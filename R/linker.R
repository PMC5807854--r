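# Fragment classes, cleavage-gap estimation, NRL spectrum, per-gene spacing.

#' Default fragment class ranges (bp, inclusive)
#'
#' Short fragments (~51 bp) come from two cuts in the same nucleosome,
#' medium fragments (~70-130 bp) from cuts at the dyad-proximal sites of
#' two neighbours, and long fragments (~135-175 bp) from cuts at alternate
#' sites of two neighbours, so a long fragment spans one nucleosome repeat
#' minus the cleavage gap.
#'
#' @return list with elements `short`, `medium`, `long`, each `c(min, max)`.
#' @export
fragment_class_ranges <- function() {
  list(short = c(44L, 58L), medium = c(70L, 130L), long = c(135L, 175L))
}

#' Classify fragment lengths into short/medium/long/other
#'
#' @param length integer vector of fragment lengths (bp).
#' @param ranges class ranges, default [fragment_class_ranges()].
#' @return factor with levels short, medium, long, other.
#' @export
classify_fragment <- function(length, ranges = fragment_class_ranges()) {
  cls <- rep("other", base::length(length))
  for (nm in names(ranges))
    cls[length >= ranges[[nm]][1] & length <= ranges[[nm]][2]] <- nm
  factor(cls, levels = c("short", "medium", "long", "other"))
}

# per-bp end-count vectors for one fragment class
end_counts <- function(frags, genome, range, which = c("left", "right")) {
  which <- match.arg(which)
  len <- frags$end - frags$start + 1L
  f <- frags[len >= range[1] & len <= range[2], , drop = FALSE]
  pos <- if (which == "left") f$start else f$end
  out <- lapply(seq_len(nrow(genome)), function(i) {
    p <- pos[f$chrom == genome$name[i]]
    p <- p[p >= 1L & p <= genome$length[i]]
    as.numeric(tabulate(p, nbins = genome$length[i]))
  })
  names(out) <- genome$name
  out
}

#' Estimate the bp lost at a cleavage site from fragment-end cross-correlation
#'
#' Cross-correlates the genome-wide per-bp counts of one fragment class's
#' ends against another's over lags 1..`max_lag`; the best lag minus 1 is
#' the gap (two abutting fragments separated by a `g`-bp lost gap have ends
#' `g + 1` bp apart). The default pairs right ends of short-class fragments
#' with left ends of medium-class fragments.
#'
#' @param frags fragment data.frame.
#' @param genome a [chrom_spec()] table.
#' @param class_a,end_a first end set: class name in `ranges` and
#'   `"left"`/`"right"` (defaults `"short"`, `"right"`).
#' @param class_b,end_b second end set (defaults `"medium"`, `"left"`).
#' @param max_lag largest lag scanned (default 20).
#' @param ranges class ranges, default [fragment_class_ranges()].
#' @return list of class `gap_estimate`: `lag`, `gap = lag - 1`, and
#'   `curve` (named correlation values over lags).
#' @export
estimate_gap <- function(frags, genome,
                         class_a = "short", end_a = "right",
                         class_b = "medium", end_b = "left",
                         max_lag = 20L, ranges = fragment_class_ranges()) {
  A <- end_counts(frags, genome, ranges[[class_a]], end_a)
  B <- end_counts(frags, genome, ranges[[class_b]], end_b)
  if (sum(unlist(lapply(A, sum))) == 0 || sum(unlist(lapply(B, sum))) == 0)
    stop("empty end-count vector for one of the fragment classes")
  lags <- seq_len(max_lag)
  curve <- vapply(lags, function(l) {
    s <- 0
    for (nm in names(A)) {
      L <- length(A[[nm]])
      if (L > l) s <- s + sum(A[[nm]][1:(L - l)] * B[[nm]][(1 + l):L])
    }
    s
  }, numeric(1))
  names(curve) <- lags
  if (max(curve) - median(curve) < 1e-9 * max(1, max(curve)))
    stop("no unambiguous maximum in the end cross-correlation")
  lag <- lags[which.max(curve)]  # ties resolve to the smallest lag
  structure(list(lag = lag, gap = lag - 1L, curve = curve),
            class = "gap_estimate")
}

#' @export
print.gap_estimate <- function(x, ...) {
  cat(sprintf("<gap_estimate> best lag %d bp -> gap %d bp\n", x$lag, x$gap))
  invisible(x)
}

#' Nucleosome repeat length spectrum from long-class fragments
#'
#' Histograms long-class fragment lengths, smooths with a centered 3-bp
#' moving average, and reports local maxima (plateau centers) shifted by
#' the estimated gap as modal NRLs; linker = NRL - `nucleosome_length`.
#'
#' @param frags fragment data.frame.
#' @param gap a `gap_estimate` (or integer gap in bp).
#' @param ranges class ranges, default [fragment_class_ranges()].
#' @param nucleosome_length core DNA length used for linker arithmetic
#'   (default 147).
#' @param min_long minimum number of long fragments required to call modes
#'   (default 100; fewer gives a warning and no modes).
#' @param min_prominence local maxima below this fraction of the tallest
#'   smoothed peak are treated as sampling noise, not modes (default 0.1).
#' @return list: `hist` (counts over the long range), `smoothed`,
#'   `modal_lengths`, `modal_nrl`, `linkers`, `n_long`.
#' @export
nrl_spectrum <- function(frags, gap, ranges = fragment_class_ranges(),
                         nucleosome_length = 147L, min_long = 100L,
                         min_prominence = 0.1) {
  g <- if (inherits(gap, "gap_estimate")) gap$gap else as.integer(gap)
  rng <- ranges$long
  len <- frags$end - frags$start + 1L
  lenl <- len[len >= rng[1] & len <= rng[2]]
  lens <- seq(rng[1], rng[2])
  h <- tabulate(lenl - rng[1] + 1L, nbins = length(lens))
  names(h) <- lens
  sm <- as.numeric(stats::filter(h, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- 0
  names(sm) <- lens
  out <- list(hist = h, smoothed = sm, modal_lengths = integer(0),
              modal_nrl = integer(0), linkers = integer(0),
              n_long = length(lenl))
  if (length(lenl) < min_long) {
    warning("fewer than ", min_long, " long-class fragments; no modes reported")
    return(out)
  }
  # neighbouring smoothed maxima can snap to the same raw bin; deduplicate
  out$modal_lengths <- unique(plateau_maxima(sm, lens,
                                             floor = min_prominence * max(sm),
                                             raw = as.numeric(h)))
  out$modal_nrl <- out$modal_lengths + g
  out$linkers <- out$modal_nrl - nucleosome_length
  out
}

# local maxima of a vector above a noise floor; a plateau (run of equal
# values) reports the bin with the largest `raw` value when given (ties
# and missing `raw` fall back to the plateau center)
plateau_maxima <- function(v, x, floor = 0, raw = NULL) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(r$values)
  keep <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == n || r$values[i + 1] < r$values[i]
    left_ok && right_ok && r$values[i] > 0 && r$values[i] >= floor
  }, logical(1))
  pick <- function(i) {
    # the smoothed maximum localizes the mode to the plateau plus the
    # 1-bin smoothing support on either side; report the most abundant
    # raw bin there
    idx <- max(1L, starts[i] - 1L):min(length(v), ends[i] + 1L)
    if (!is.null(raw) && max(raw[idx]) > min(raw[idx]))
      return(idx[which.max(raw[idx])])
    (starts[i] + ends[i]) %/% 2L
  }
  x[vapply(which(keep), pick, integer(1))]
}

#' Per-gene nucleosome spacing from long-class fragment lengths
#'
#' Long-class fragments are assigned to the gene body their midpoint falls
#' in; genes with at least `min_fragments` midpoint-assigned fragments (all
#' classes) are scored by the mean long-fragment length, a direct measure
#' of average nucleosome spacing.
#'
#' @param frags fragment data.frame.
#' @param genes gene annotation data.frame.
#' @param min_fragments exclusion threshold on total assigned fragments
#'   (default 5000; lower it for small synthetic genomes).
#' @param ranges class ranges, default [fragment_class_ranges()].
#' @return data.frame: `gene_id`, `n_fragments`, `n_long`,
#'   `mean_long_length`, plus a `long_lengths` list-column of the raw
#'   per-gene long-fragment lengths.
#' @export
per_gene_spacing <- function(frags, genes, min_fragments = 5000L,
                             ranges = fragment_class_ranges()) {
  genes <- as_genes(genes)
  len <- frags$end - frags$start + 1L
  mid <- (frags$start + frags$end) %/% 2L
  lo <- pmin(genes$tss, genes$tts)
  hi <- pmax(genes$tss, genes$tts)
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    sel <- frags$chrom == genes$chrom[i] & mid >= lo[i] & mid <= hi[i]
    ll <- len[sel & len >= ranges$long[1] & len <= ranges$long[2]]
    rows[[i]] <- data.frame(gene_id = genes$gene_id[i],
                            n_fragments = sum(sel), n_long = length(ll),
                            mean_long_length = if (length(ll)) mean(ll) else NA_real_,
                            stringsAsFactors = FALSE)
    rows[[i]]$long_lengths <- list(ll)
  }
  res <- do.call(rbind, rows)
  res[res$n_fragments >= min_fragments, , drop = FALSE]
}

#' Quintile summary of genes ranked by nucleosome spacing
#'
#' Ranks genes by `mean_long_length` (ascending: quintile 1 = most crowded
#' arrays), splits them into five quintiles (remainders go to the earlier
#' quintiles), and reports per-quintile averages: spacing score, NDR width,
#' the +1-aligned dyad-density profile, and window means of any supplied
#' per-bp tracks over `(D-73, D+750)` and `(D-500, D-73)` relative to the
#' +1 dyad `D`. Pearson correlations between the quintile means of all
#' scalar columns are included.
#'
#' @param scores data.frame from [per_gene_spacing()].
#' @param dyads dyad `bp_profile` (normalized).
#' @param ndr_calls data.frame from [detect_ndrs()] (for NDR widths).
#' @param anchors data.frame (`gene_id`, `chrom`, `pos`, `strand`) of +1
#'   dyads.
#' @param window profile window around the +1 dyad, default `c(-500, 1000)`.
#' @param tracks optional named list of `bp_profile`s to average in the
#'   gene-body and promoter windows.
#' @return list: `table` (per-quintile scalars), `profiles` (matrix of
#'   quintile-mean dyad profiles), `correlations` (Pearson matrix).
#' @export
quintile_summary <- function(scores, dyads, ndr_calls, anchors,
                             window = c(-500L, 1000L), tracks = NULL) {
  if (nrow(scores) < 5) stop("need at least 5 genes for quintiles")
  ord <- order(scores$mean_long_length, scores$gene_id)
  s <- scores[ord, , drop = FALSE]
  n <- nrow(s)
  base_size <- n %/% 5L
  extra <- n %% 5L
  sizes <- rep(base_size, 5L) + c(rep(1L, extra), rep(0L, 5L - extra))
  qf <- rep(seq_len(5L), times = sizes)
  s$quintile <- qf
  a <- anchors[match(s$gene_id, anchors$gene_id), , drop = FALSE]
  hm <- build_aligned_heatmap(dyads, a, window, sort_key = seq_len(n))
  widths <- ndr_calls$run_length[match(s$gene_id, ndr_calls$gene_id)]
  profs <- matrix(NA_real_, 5L, ncol(hm),
                  dimnames = list(paste0("Q", 1:5), colnames(hm)))
  tab <- data.frame(quintile = 1:5, n = sizes,
                    mean_spacing_score = NA_real_, mean_ndr_width = NA_real_)
  tw <- list(body = c(-73L, 750L), promoter = c(-500L, -73L))
  for (tn in names(tracks)) tab[[tn]] <- NA_real_
  for (q in 1:5) {
    rows <- which(qf == q)
    profs[q, ] <- colMeans(hm[rows, , drop = FALSE], na.rm = TRUE)
    tab$mean_spacing_score[q] <- mean(s$mean_long_length[rows])
    tab$mean_ndr_width[q] <- mean(widths[rows], na.rm = TRUE)
    for (tn in names(tracks)) {
      vals <- vapply(rows, function(i) {
        wloc <- if (grepl("promoter", tn)) tw$promoter else tw$body
        v <- tracks[[tn]][[a$chrom[i]]]
        dirn <- if (identical(a$strand[i], "-")) -1L else 1L
        pos <- a$pos[i] + dirn * seq(wloc[1], wloc[2])
        pos <- pos[pos >= 1L & pos <= length(v)]
        mean(v[pos])
      }, numeric(1))
      tab[[tn]][q] <- mean(vals, na.rm = TRUE)
    }
  }
  num <- tab[, setdiff(names(tab), c("quintile", "n")), drop = FALSE]
  num <- num[, vapply(num, function(x) sd(x) > 0, logical(1)), drop = FALSE]
  corr <- if (ncol(num) >= 2) cor(num) else NULL
  list(table = tab, profiles = profs, correlations = corr)
}
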