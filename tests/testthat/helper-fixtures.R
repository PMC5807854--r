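# Shared fixtures, built in code at test time.

# small genome with tandem '+' genes every 2 kb
small_genes <- function(n = 19L, chrom = "chrT", spacing = 2000L) {
  tss <- seq(2000L, by = spacing, length.out = n)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = chrom,
             strand = "+", tss = tss, tts = tss + 1200L,
             stringsAsFactors = FALSE)
}

small_cfg <- function(seed = 42L, n = 19L, n_cells = 20L, ...) {
  genes <- small_genes(n)
  genome <- chrom_spec("chrT", max(genes$tts) + 2000L)
  synthetic_config(seed = seed, genome = genome, genes = genes,
                   n_cells = n_cells, ...)
}

# gene-free configuration: one free-walk array per cell (no NDRs,
# every spacing is nucleosome + drawn linker)
free_cfg <- function(seed = 42L, L = 100000L, n_cells = 20L, ...) {
  genome <- chrom_spec("chrF", L)
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = integer(0),
                      tts = integer(0), stringsAsFactors = FALSE)
  synthetic_config(seed = seed, genome = genome, genes = genes,
                   n_cells = n_cells, ...)
}

# a profile with a single chromosome holding vector v
vec_profile <- function(v, name = "chr") {
  p <- new_profile(chrom_spec(name, length(v)))
  p[[name]] <- as.numeric(v)
  p
}

# fragments data.frame shortcut
frag_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
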