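#!/usr/bin/env Rscript
# Fragment -> dyad -> occupancy mapping: midpoints of 44-58-bp fragments
# are single-nucleosome dyads; 101-bp symmetric footprints give the
# occupancy used for NDR detection. Also builds the 2D length-position
# matrix whose marginals are the 1D occupancy and the length histogram.

library(nuclinker)

genome <- with(read.delim("results/data/genome.tsv", header = FALSE),
               chrom_spec(V1, V2))
frags <- read_fragments("results/data/fragments.bed", genome)

dy <- dyads_from_fragments(frags, genome)
occ <- normalize_profile(occupancy_from_dyads(dy))
write_track(normalize_profile(dy), "results/dyads.bedgraph")
write_track(occ, "results/occupancy.bedgraph")

cat(sprintf("dyads mapped: %d (of %d fragments)\n",
            profile_total(dy), nrow(frags)))

# 2D occupancy around the first 2 kb of the chromosome midpoint
mid <- genome$length[1] %/% 2L
m <- build_2d_occupancy(frags, region = list(chrom = genome$name[1],
                                             start = mid - 1000L,
                                             end = mid + 1000L))
mg <- lp_marginals(m)
write.table(data.frame(length = as.integer(rownames(m)),
                       count = round(mg$length_hist)),
            "results/length_histogram.tsv", sep = "\t", row.names = FALSE)
top <- head(order(mg$length_hist, decreasing = TRUE), 5)
cat("most abundant fragment lengths in the window:",
    paste(rownames(m)[top], collapse = ", "), "\n")
cat("column sums of the 2D matrix equal the 1D occupancy; row sums / length\n")
cat("equal the fragment length histogram (checked in the test suite)\n")
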