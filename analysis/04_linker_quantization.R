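#!/usr/bin/env Rscript
# Linker quantization: estimate the bp lost at each cleavage site from
# fragment-end cross-correlations, convert modal long-fragment lengths to
# nucleosome repeat lengths, score per-gene spacing, and summarize
# quintiles of nucleosome crowding.

library(nuclinker)

genome <- with(read.delim("results/data/genome.tsv", header = FALSE),
               chrom_spec(V1, V2))
genes <- read_genes("results/data/genes.tsv", genome)
frags <- read_fragments("results/data/fragments.bed", genome)

gap <- estimate_gap(frags, genome)
cat(sprintf("end cross-correlation peaks at lag %d bp -> %d bp lost per cleavage\n",
            gap$lag, gap$gap))
write.table(data.frame(lag = as.integer(names(gap$curve)),
                       correlation = as.numeric(gap$curve)),
            "results/gap_curve.tsv", sep = "\t", row.names = FALSE)

sp <- nrl_spectrum(frags, gap)
write.table(data.frame(length = as.integer(names(sp$hist)),
                       count = as.integer(sp$hist)),
            "results/nrl_spectrum.tsv", sep = "\t", row.names = FALSE)
cat("modal long-fragment lengths:", paste(sp$modal_lengths, collapse = ", "), "\n")
cat("modal NRLs (mode + gap):", paste(sp$modal_nrl, collapse = ", "),
    "-> linkers", paste(sp$linkers, collapse = ", "), "bp\n")
cat("linkers are quantized: separated by the ~10-bp helical twist\n")

sc <- per_gene_spacing(frags, genes, min_fragments = 500L)
write.table(sc[setdiff(names(sc), "long_lengths")],
            "results/gene_spacing.tsv", sep = "\t", row.names = FALSE)
cat(sprintf("per-gene spacing scored for %d genes; mean long-fragment length %.1f-%.1f bp\n",
            nrow(sc), min(sc$mean_long_length), max(sc$mean_long_length)))

dy <- normalize_profile(dyads_from_fragments(frags, genome))
occ <- normalize_profile(occupancy_from_dyads(
  dyads_from_fragments(frags, genome)))
ndr <- detect_ndrs(occ, genes)
calls <- refine_flanks(dyads_from_fragments(frags, genome), ndr)
p1 <- calls[calls$role == "+1", ]
anch <- data.frame(gene_id = p1$gene_id, chrom = p1$chrom, pos = p1$dyad,
                   strand = genes$strand[match(p1$gene_id, genes$gene_id)])
qs <- quintile_summary(sc[sc$gene_id %in% anch$gene_id, ], dy,
                       ndr, anch[anch$gene_id %in% sc$gene_id, ])
write.table(qs$table, "results/quintiles.tsv", sep = "\t", row.names = FALSE)
cat("quintile mean spacing scores:",
    paste(sprintf("%.1f", qs$table$mean_spacing_score), collapse = ", "), "\n")
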