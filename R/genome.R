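#' Define a genome as a table of chromosome names and lengths
#'
#' @param name character vector of chromosome names (unique).
#' @param length integer vector of chromosome lengths in bp (>= 1).
#' @return A `data.frame` with columns `name` and `length`.
#' @examples
#' chrom_spec("chrI", 230218L)
#' @export
chrom_spec <- function(name, length) {
  name <- as.character(name)
  length <- as.integer(length)
  if (length(name) != length(length))
    stop("name and length must have equal length")
  if (anyDuplicated(name))
    stop("chromosome names must be unique")
  if (any(is.na(length)) || any(length < 1L))
    stop("chromosome lengths must be integers >= 1")
  data.frame(name = name, length = length, stringsAsFactors = FALSE)
}

#' Validate a gene annotation table
#'
#' Genes are given as transcript end coordinates: `tss` and `tts`, with
#' `tss < tts` on the '+' strand and `tss > tts` on the '-' strand.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`, `tts` (1-based bp).
#' @param genome optional [chrom_spec()] table; if given, coordinates are
#'   checked against chromosome bounds.
#' @return The validated data.frame (coordinates coerced to integer).
#' @export
as_genes <- function(genes, genome = NULL) {
  need <- c("gene_id", "chrom", "strand", "tss", "tts")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  genes <- as.data.frame(genes)[need]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$tss <- as.integer(genes$tss)
  genes$tts <- as.integer(genes$tts)
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$tss == genes$tts)) stop("tss must differ from tts")
  bad <- (genes$strand == "+" & genes$tss > genes$tts) |
    (genes$strand == "-" & genes$tss < genes$tts)
  if (any(bad))
    stop("strand-inconsistent coordinates for: ",
         paste(head(genes$gene_id[bad], 5), collapse = ", "))
  if (!is.null(genome)) {
    m <- match(genes$chrom, genome$name)
    if (anyNA(m)) stop("unknown chromosome in gene table")
    len <- genome$length[m]
    if (any(genes$tss < 1L | genes$tss > len | genes$tts < 1L | genes$tts > len))
      stop("gene coordinates outside chromosome bounds")
  }
  genes
}

#' Read a gene annotation TSV (columns gene_id, chrom, strand, tss, tts)
#'
#' @param path path to a tab-separated file with a header line.
#' @inheritParams as_genes
#' @return A validated gene annotation data.frame.
#' @export
read_genes <- function(path, genome = NULL) {
  g <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  as_genes(g, genome)
}

#' Write a gene annotation TSV
#' @param genes gene annotation data.frame.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  data.table::fwrite(as_genes(genes), path, sep = "\t")
  invisible(path)
}

# ---- per-bp profiles --------------------------------------------------------

#' Create an all-`fill` per-base-pair profile over a genome
#'
#' A profile is a named list of numeric vectors, one entry per bp per
#' chromosome, with a `normalized` attribute. Dyad profiles and occupancy
#' profiles share this container.
#'
#' @param genome a [chrom_spec()] table.
#' @param fill fill value (default 0).
#' @return A `bp_profile` object.
#' @export
new_profile <- function(genome, fill = 0) {
  v <- lapply(genome$length, function(L) rep(as.numeric(fill), L))
  names(v) <- genome$name
  structure(v, class = "bp_profile", normalized = FALSE)
}

#' @export
print.bp_profile <- function(x, ...) {
  cat(sprintf("<bp_profile> %d chromosome(s)%s\n", length(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %d bp, total %.6g, mean %.6g\n",
                nm, length(v), sum(v), mean(v)))
  }
  invisible(x)
}

as_profile <- function(vectors, normalized = FALSE) {
  structure(vectors, class = "bp_profile", normalized = normalized)
}

#' Normalize a profile so the per-chromosome mean equals 1
#'
#' Matches the convention that average dyad density is 1 for every
#' chromosome. Idempotent.
#'
#' @param p a `bp_profile`.
#' @return The normalized profile with the `normalized` flag set.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "bp_profile"))
  out <- lapply(names(p), function(nm) {
    m <- mean(p[[nm]])
    if (m == 0) stop("cannot normalize all-zero chromosome: ", nm)
    p[[nm]] / m
  })
  names(out) <- names(p)
  as_profile(out, normalized = TRUE)
}

#' Sum of all entries of a profile
#' @param p a `bp_profile`.
#' @return numeric scalar.
#' @export
profile_total <- function(p) sum(vapply(p, sum, numeric(1)))
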