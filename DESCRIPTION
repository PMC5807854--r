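Package: nuclinker
Title: Chemical-Cleavage Nucleosome Maps, Linker Quantization, and
    Hard-Rod Positioning Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of chemical-cleavage nucleosome mapping experiments in
    which an engineered cysteine-phenanthroline histone releases a ~51-bp
    intranucleosomal DNA fragment from every nucleosome. Converts paired-end
    fragment intervals to base-pair-resolution dyad and occupancy profiles,
    builds two-dimensional (fragment length x position) occupancy matrices and
    V-plots, detects nucleosome-depleted regions and refines +1/-1 nucleosome
    dyads with an oscillatory template, estimates the base pairs lost at each
    cleavage site and the quantized nucleosome repeat lengths genome-wide and
    per gene, measures rotational-phasing dinucleotide periodicity, and fits an
    equilibrium Tonks hard-rod model of nucleosome positioning with Gaussian
    promoter energy barriers. A synthetic-data generator emulates the cleavage
    chemistry so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    lhs,
    stats,
    utils,
    yaml,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
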