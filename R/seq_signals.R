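# Sequence-composition signals around aligned dyads: WW/SS dinucleotide
# rotational phasing and A/T content.

seq_to_chars <- function(genome_seq, nm) {
  strsplit(as.character(genome_seq[[nm]]), "", fixed = TRUE)[[1]]
}

#' WW/SS dinucleotide frequencies around aligned dyads
#'
#' Every dyad (weighted by its count) contributes the dinucleotide starting
#' at each offset; the dinucleotide at offset `x` spans bases
#' `(dyad + x, dyad + x + 1)`. WW = AA/AT/TA/TT, SS = CC/CG/GC/GG; pairs
#' containing an ambiguous base are excluded from the denominator. Dyads
#' too close to a contig end are skipped (count reported as an attribute).
#'
#' @param dyads dyad `bp_profile`.
#' @param genome_seq a [Biostrings::DNAStringSet] named by chromosome.
#' @param window half-width in bp (default 73; offsets -window..window).
#' @return data.frame `offset`, `ww`, `ss` with attribute `n_skipped`.
#' @export
dinucleotide_phasing <- function(dyads, genome_seq, window = 73L) {
  offs <- seq(-window, window)
  ww <- ss <- den <- numeric(length(offs))
  n_skipped <- 0
  for (nm in names(dyads)) {
    if (!nm %in% names(genome_seq)) stop("no sequence for chromosome ", nm)
    ch <- seq_to_chars(genome_seq, nm)
    L <- length(ch)
    isW <- ch %in% c("A", "T")
    isS <- ch %in% c("C", "G")
    valid <- isW | isS
    wwi <- c(isW[-L] & isW[-1], FALSE)
    ssi <- c(isS[-L] & isS[-1], FALSE)
    vvi <- c(valid[-L] & valid[-1], FALSE)
    cnt <- dyads[[nm]]
    pos <- which(cnt > 0)
    inb <- pos - window >= 1L & pos + window + 1L <= L
    n_skipped <- n_skipped + sum(cnt[pos[!inb]])
    pos <- pos[inb]
    if (!length(pos)) next
    wts <- cnt[pos]
    for (j in seq_along(offs)) {
      p <- pos + offs[j]
      ww[j] <- ww[j] + sum(wts * wwi[p])
      ss[j] <- ss[j] + sum(wts * ssi[p])
      den[j] <- den[j] + sum(wts * vvi[p])
    }
  }
  if (all(den == 0)) stop("no usable dyads")
  out <- data.frame(offset = offs,
                    ww = ifelse(den > 0, ww / den, NA_real_),
                    ss = ifelse(den > 0, ss / den, NA_real_))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' A/T content around strand-oriented anchors
#'
#' Per-offset fraction of A or T bases across aligned windows;
#' '-'-strand anchors are flipped so offsets run in transcription
#' direction. Ambiguous bases are excluded from the denominator.
#'
#' @param anchors data.frame with `chrom`, `pos`, `strand`.
#' @param genome_seq a [Biostrings::DNAStringSet] named by chromosome.
#' @param window half-width in bp (default 500).
#' @return data.frame `offset`, `at` with attribute `n_skipped`.
#' @export
at_content <- function(anchors, genome_seq, window = 500L) {
  offs <- seq(-window, window)
  at <- den <- numeric(length(offs))
  n_skipped <- 0L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    ch <- seq_to_chars(genome_seq, a$chrom)
    L <- length(ch)
    if (a$pos - window < 1L || a$pos + window > L) {
      n_skipped <- n_skipped + 1L
      next
    }
    dirn <- if (identical(a$strand, "-")) -1L else 1L
    p <- a$pos + dirn * offs
    b <- ch[p]
    isAT <- b %in% c("A", "T")
    isV <- isAT | b %in% c("C", "G")
    at <- at + isAT
    den <- den + isV
  }
  if (all(den == 0)) stop("no usable anchors")
  out <- data.frame(offset = offs, at = ifelse(den > 0, at / den, NA_real_))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Autocorrelation of a positional profile
#'
#' Used to check the ~10-bp rotational periodicity of the WW profile.
#'
#' @param x numeric vector (e.g. the `ww` column of
#'   [dinucleotide_phasing()]).
#' @param max_lag maximum lag (default 30).
#' @return named numeric vector of autocorrelations at lags 1..max_lag.
#' @export
profile_autocorrelation <- function(x, max_lag = 30L) {
  x <- x - mean(x)
  n <- length(x)
  v <- sum(x^2)
  ac <- vapply(seq_len(max_lag), function(l)
    sum(x[1:(n - l)] * x[(1 + l):n]) / v, numeric(1))
  names(ac) <- seq_len(max_lag)
  ac
}
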