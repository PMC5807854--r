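# 2D occupancy (fragment length x position) matrices, V-plots, and
# anchor-aligned heatmaps.

#' Build a 2D occupancy matrix (fragment length x position)
#'
#' Rows are fragment lengths, columns genomic positions (region mode) or
#' anchor-relative positions (anchor mode). A fragment of length `l` adds
#' +1 to row `l` over every column it covers, so column sums reproduce the
#' 1D occupancy and row sums divided by `l` reproduce the fragment length
#' histogram (for fragments fully inside the column range).
#'
#' @param frags fragment data.frame.
#' @param region list with `chrom`, `start`, `end` (genomic columns), or NULL.
#' @param anchors data.frame with `chrom`, `pos`, `strand` (anchor-relative
#'   columns; '-' anchors flip the position sign), or NULL. Exactly one of
#'   `region`/`anchors` must be given.
#' @param length_range inclusive row range, default `c(20, 200)`.
#' @param window anchor-relative column range, default `c(-1000, 1000)`.
#' @param normalize divide by (number of anchors x per-chromosome mean
#'   occupancy of the fragments used) to give relative occupancy.
#' @param genome required when `normalize = TRUE` in anchor mode.
#' @return numeric matrix with rownames = lengths, colnames = positions,
#'   class `length_position_matrix`.
#' @export
build_2d_occupancy <- function(frags, region = NULL, anchors = NULL,
                               length_range = c(20L, 200L),
                               window = c(-1000L, 1000L),
                               normalize = FALSE, genome = NULL) {
  if (is.null(region) == is.null(anchors))
    stop("give exactly one of region or anchors")
  len <- frags$end - frags$start + 1L
  keep <- len >= length_range[1] & len <= length_range[2]
  f <- frags[keep, , drop = FALSE]
  flen <- len[keep]
  lens <- seq(length_range[1], length_range[2])
  if (!is.null(region)) {
    cols <- seq(region$start, region$end)
    m <- matrix(0, nrow = length(lens), ncol = length(cols),
                dimnames = list(lens, cols))
    sel <- f$chrom == region$chrom & f$end >= region$start & f$start <= region$end
    fs <- f[sel, , drop = FALSE]; fl <- flen[sel]
    for (l in unique(fl)) {
      i <- which(fl == l)
      delta <- numeric(length(cols) + 1L)
      s <- pmax(fs$start[i], region$start) - region$start + 1L
      e <- pmin(fs$end[i], region$end) - region$start + 1L
      delta <- tabulate(s, nbins = length(cols) + 1L) -
        tabulate(e + 1L, nbins = length(cols) + 1L)
      m[as.character(l), ] <- cumsum(delta)[seq_along(cols)]
    }
  } else {
    if (nrow(anchors) == 0) stop("empty anchor set")
    cols <- seq(window[1], window[2])
    m <- matrix(0, nrow = length(lens), ncol = length(cols),
                dimnames = list(lens, cols))
    W <- length(cols)
    for (ai in seq_len(nrow(anchors))) {
      a <- anchors[ai, ]
      sel <- which(f$chrom == a$chrom &
                     f$end >= a$pos + window[1] - 1L &
                     f$start <= a$pos + window[2] + 1L)
      if (!length(sel)) next
      rs <- f$start[sel] - a$pos
      re <- f$end[sel] - a$pos
      if (identical(a$strand, "-")) {
        tmp <- rs; rs <- -re; re <- -tmp
      }
      cs <- pmax(rs, window[1]) - window[1] + 1L
      ce <- pmin(re, window[2]) - window[1] + 1L
      ok <- cs <= ce
      for (j in which(ok)) {
        r <- as.character(flen[sel][j])
        m[r, cs[j]:ce[j]] <- m[r, cs[j]:ce[j]] + 1
      }
    }
  }
  if (normalize) {
    n_anchor <- if (is.null(anchors)) 1L else nrow(anchors)
    gn <- if (is.null(region)) genome else
      chrom_spec(region$chrom, max(frags$end[frags$chrom == region$chrom],
                                   region$end))
    if (is.null(gn)) stop("genome required to normalize in anchor mode")
    occ <- occupancy_from_fragments(f, gn, size_window = length_range)
    mo <- mean(unlist(occ, use.names = FALSE))
    if (mo > 0) m <- m / (n_anchor * mo)
  }
  structure(m, class = c("length_position_matrix", "matrix", "array"))
}

#' Marginals of a length-position matrix
#'
#' @param m a `length_position_matrix`.
#' @return list with `occupancy` (column sums, the 1D occupancy) and
#'   `length_hist` (row sums divided by the row's fragment length, the
#'   fragment length histogram).
#' @export
lp_marginals <- function(m) {
  lens <- as.integer(rownames(m))
  list(occupancy = colSums(m),
       length_hist = rowSums(m) / lens)
}

#' Build left/right fragment-end V-plot matrices around anchors
#'
#' Left (lower-coordinate) termini accumulate in the `left` matrix at
#' (fragment length, position relative to anchor) and right termini in the
#' `right` matrix; '-'-strand anchors flip the position sign and swap the
#' two matrices.
#'
#' @param frags fragment data.frame.
#' @param anchors data.frame with `chrom`, `pos`, `strand`.
#' @param window relative position range, default `c(-500, 500)`.
#' @param length_range inclusive fragment-length rows, default `c(20, 200)`.
#' @return list of matrices `left` and `right`.
#' @export
build_vplot <- function(frags, anchors, window = c(-500L, 500L),
                        length_range = c(20L, 200L)) {
  len <- frags$end - frags$start + 1L
  keep <- len >= length_range[1] & len <= length_range[2]
  f <- frags[keep, , drop = FALSE]
  flen <- len[keep]
  lens <- seq(length_range[1], length_range[2])
  cols <- seq(window[1], window[2])
  left <- right <- matrix(0, nrow = length(lens), ncol = length(cols),
                          dimnames = list(lens, cols))
  add <- function(m, l, x) {
    ok <- x >= window[1] & x <= window[2]
    if (any(ok)) {
      idx <- cbind(match(l[ok], lens), x[ok] - window[1] + 1L)
      tab <- table(paste(idx[, 1], idx[, 2]))
      for (nm in names(tab)) {
        ij <- as.integer(strsplit(nm, " ")[[1]])
        m[ij[1], ij[2]] <- m[ij[1], ij[2]] + tab[[nm]]
      }
    }
    m
  }
  for (ai in seq_len(nrow(anchors))) {
    a <- anchors[ai, ]
    sel <- which(f$chrom == a$chrom &
                   f$start >= a$pos + window[1] - max(lens) &
                   f$start <= a$pos + window[2] + max(lens))
    if (!length(sel)) next
    rl <- f$start[sel] - a$pos
    rr <- f$end[sel] - a$pos
    if (identical(a$strand, "-")) {
      left <- add(left, flen[sel], -rr)
      right <- add(right, flen[sel], -rl)
    } else {
      left <- add(left, flen[sel], rl)
      right <- add(right, flen[sel], rr)
    }
  }
  list(left = left, right = right)
}

#' Extract an anchor-aligned, sorted heatmap from a per-bp profile
#'
#' One row per anchor, in anchor-relative coordinates; '-'-strand rows are
#' reversed; rows are sorted ascending by `sort_key` with ties broken by
#' `gene_id`; windows that overhang a chromosome end are padded with `NA`.
#'
#' @param profile a `bp_profile`.
#' @param anchors data.frame with `gene_id`, `chrom`, `pos`, `strand`.
#' @param window relative coordinate range, e.g. `c(-1000, 1000)`.
#' @param sort_key numeric vector, one value per anchor.
#' @return matrix (rows = anchors in sorted order, rownames = gene_id,
#'   colnames = relative positions) with attribute `sort_key`.
#' @export
build_aligned_heatmap <- function(profile, anchors, window, sort_key) {
  stopifnot(nrow(anchors) == length(sort_key))
  ord <- order(sort_key, anchors$gene_id)
  a <- anchors[ord, , drop = FALSE]
  cols <- seq(window[1], window[2])
  m <- matrix(NA_real_, nrow = nrow(a), ncol = length(cols),
              dimnames = list(a$gene_id, cols))
  for (i in seq_len(nrow(a))) {
    v <- profile[[a$chrom[i]]]
    pos <- a$pos[i] + cols
    ok <- pos >= 1L & pos <= length(v)
    row <- rep(NA_real_, length(cols))
    row[ok] <- v[pos[ok]]
    if (identical(a$strand[i], "-")) row <- rev(row)
    m[i, ] <- row
  }
  attr(m, "sort_key") <- sort_key[ord]
  m
}

#' Column means of an aligned heatmap, excluding the missing-value sentinel
#' @param m matrix from [build_aligned_heatmap()].
#' @return numeric vector of per-column means.
#' @export
heatmap_colmeans <- function(m) colMeans(m, na.rm = TRUE)
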