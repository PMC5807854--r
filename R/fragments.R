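# Fragment I/O and fragment -> dyad / occupancy conversion.
# Internal coordinates are 1-based inclusive everywhere; BED (0-based,
# half-open) is converted at the I/O boundary only.

#' Read paired-end fragment intervals
#'
#' Accepts two three-column dialects: BED3 (0-based, half-open) and a plain
#' TSV of 1-based inclusive coordinates. Records on chromosomes absent from
#' `genome` are dropped with a reported count.
#'
#' @param path path to the fragment file (no header).
#' @param genome a [chrom_spec()] table.
#' @param format `"bed"` (default) or `"tsv"` (1-based inclusive).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive) and attribute `n_dropped` (records on unknown chromosomes).
#' @export
read_fragments <- function(path, genome, format = c("bed", "tsv")) {
  format <- match.arg(format)
  d <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE,
                         colClasses = list(character = 1),
                         col.names = c("chrom", "start", "end"))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(d[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed fragment line %d in %s", bad[1], path))
    d[[col]] <- v
  }
  if (format == "bed") {
    zero <- which(d$end <= d$start)
    if (length(zero))
      stop(sprintf("zero- or negative-length BED interval at line %d", zero[1]))
    d$start <- d$start + 1L
  } else {
    bad <- which(d$end < d$start)
    if (length(bad))
      stop(sprintf("end < start at line %d", bad[1]))
  }
  known <- d$chrom %in% genome$name
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    message(n_dropped, " fragment(s) on unknown chromosomes dropped")
    d <- d[known, , drop = FALSE]
    rownames(d) <- NULL
  }
  structure(d, n_dropped = n_dropped)
}

#' Write fragment intervals
#'
#' @param frags fragment data.frame (1-based inclusive).
#' @param path output path.
#' @param format `"bed"` (0-based half-open) or `"tsv"` (1-based inclusive).
#' @export
write_fragments <- function(frags, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  out <- frags[c("chrom", "start", "end")]
  if (format == "bed") out$start <- out$start - 1L
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Convert fragments to a dyad count profile
#'
#' Fragments within the size window (default 51 +/- 7 bp, i.e. 44-58)
#' contribute +1 at their midpoint; the midpoint of an even-length fragment
#' is rounded down (floor of the arithmetic mean). Returns raw counts.
#'
#' @param frags fragment data.frame.
#' @param genome a [chrom_spec()] table.
#' @param size_window inclusive fragment-length window, default `c(44, 58)`.
#' @return A `bp_profile` of dyad counts.
#' @export
dyads_from_fragments <- function(frags, genome, size_window = c(44L, 58L)) {
  len <- frags$end - frags$start + 1L
  keep <- len >= size_window[1] & len <= size_window[2]
  if (!any(keep)) warning("no fragments within the size window; all-zero dyad profile")
  f <- frags[keep, , drop = FALSE]
  mid <- (f$start + f$end) %/% 2L
  out <- lapply(seq_len(nrow(genome)), function(i) {
    sel <- f$chrom == genome$name[i]
    m <- mid[sel]
    m <- m[m >= 1L & m <= genome$length[i]]
    as.numeric(tabulate(m, nbins = genome$length[i]))
  })
  names(out) <- genome$name
  as_profile(out)
}

#' Occupancy from a dyad profile by symmetric footprint extension
#'
#' Each dyad is extended `half_width` bp in both directions (default 50,
#' i.e. a 101-bp footprint); `Occ(i)` is the sum of dyad counts within
#' `i +/- half_width`, clipped at chromosome edges.
#'
#' @param d a dyad `bp_profile`.
#' @param half_width footprint half-width in bp (default 50).
#' @return An occupancy `bp_profile`.
#' @export
occupancy_from_dyads <- function(d, half_width = 50L) {
  stopifnot(inherits(d, "bp_profile"), half_width >= 0L)
  h <- as.integer(half_width)
  out <- lapply(d, function(v) {
    L <- length(v)
    cs <- c(0, cumsum(v))
    hi <- pmin(seq_len(L) + h, L)
    lo <- pmax(seq_len(L) - h, 1L)
    cs[hi + 1L] - cs[lo]
  })
  names(out) <- names(d)
  as_profile(out)
}

#' Occupancy by stacking whole fragments
#'
#' Each fragment with length inside `size_window` (default 50-200 bp) adds
#' +1 to every base pair it covers.
#'
#' @param frags fragment data.frame.
#' @param genome a [chrom_spec()] table.
#' @param size_window inclusive length window, default `c(50, 200)`.
#' @return An occupancy `bp_profile`.
#' @export
occupancy_from_fragments <- function(frags, genome, size_window = c(50L, 200L)) {
  len <- frags$end - frags$start + 1L
  keep <- len >= size_window[1] & len <= size_window[2]
  f <- frags[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    sel <- f$chrom == genome$name[i]
    delta <- numeric(L + 1L)
    if (any(sel)) {
      s <- pmax(f$start[sel], 1L)
      e <- pmin(f$end[sel], L)
      ok <- s <= e
      delta <- tabulate(s[ok], nbins = L + 1L) -
        tabulate(e[ok] + 1L, nbins = L + 1L)
    }
    as.numeric(cumsum(delta)[seq_len(L)])
  })
  names(out) <- genome$name
  as_profile(out)
}

# ---- track I/O --------------------------------------------------------------

#' Write a profile as a bedGraph or fixed-step wiggle track
#'
#' bedGraph records are 0-based half-open runs of equal value (zero runs
#' included, so integer-count profiles round-trip bit-exactly through
#' [read_track()]).
#'
#' @param p a `bp_profile`.
#' @param path output path.
#' @param format `"bedgraph"` (default) or `"wig"`.
#' @export
write_track <- function(p, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (format == "bedgraph") {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts0 <- c(0L, ends[-length(ends)])
      writeLines(sprintf("%s\t%d\t%d\t%.17g", nm, starts0, ends, r$values), con)
    } else {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", nm), con)
      writeLines(sprintf("%.17g", v), con)
    }
  }
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' @param path track file path.
#' @param genome a [chrom_spec()] table (gives vector lengths).
#' @param format `"bedgraph"` or `"wig"`.
#' @return A `bp_profile`.
#' @export
read_track <- function(path, genome, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  p <- new_profile(genome)
  if (format == "bedgraph") {
    d <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE,
                           col.names = c("chrom", "start0", "end0", "value"))
    for (nm in unique(d$chrom)) {
      if (!nm %in% genome$name) stop("unknown chromosome in track: ", nm)
      sel <- d$chrom == nm
      for (j in which(sel)) {
        p[[nm]][(d$start0[j] + 1L):d$end0[j]] <- d$value[j]
      }
    }
  } else {
    lines <- readLines(path)
    heads <- grep("^fixedStep", lines)
    bounds <- c(heads, length(lines) + 1L)
    for (i in seq_along(heads)) {
      nm <- sub('.*chrom=([^ ]+).*', '\\1', lines[heads[i]])
      if (!nm %in% genome$name) stop("unknown chromosome in track: ", nm)
      vals <- as.numeric(lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)])
      p[[nm]][seq_along(vals)] <- vals
    }
  }
  p
}
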