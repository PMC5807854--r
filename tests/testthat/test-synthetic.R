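test_that("degenerate single-linker set forces exact 152-bp spacings", {
  cfg <- free_cfg(seed = 5, L = 30000L, n_cells = 3L, linker_set = 5L)
  ch <- generate_chromatin(cfg)
  sp <- unlist(lapply(ch$cells, function(cell) diff(cell$chrF)))
  expect_true(all(sp == 152L))
})

test_that("free-walk spacing histogram matches the linker mixture within 3 sigma", {
  cfg <- free_cfg(seed = 11, L = 400000L, n_cells = 5L)
  ch <- generate_chromatin(cfg)
  sp <- unlist(lapply(ch$cells, function(cell) diff(cell$chrF)))
  n <- length(sp)
  expect_gt(n, 1e4)
  expect_true(all(sp %in% c(152L, 162L, 172L)))
  for (s in c(152L, 162L, 172L)) {
    k <- sum(sp == s)
    se <- sqrt(n * (1 / 3) * (2 / 3))
    expect_lt(abs(k - n / 3), 3 * se)
  }
})

test_that("the generator is reproducible under its seed", {
  cfg <- small_cfg(seed = 9, n_cells = 3L)
  d1 <- synthesize_dataset(cfg)
  d2 <- synthesize_dataset(cfg)
  expect_identical(d1$chromatin$cells, d2$chromatin$cells)
  expect_identical(d1$frags, d2$frags)
  s1 <- generate_sequence(cfg, d1$chromatin)
  s2 <- generate_sequence(cfg, d2$chromatin)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("promoter anchors are dyad-free NDRs with fixed -1/+1 dyads", {
  cfg <- small_cfg(seed = 4, n_cells = 10L)
  ch <- generate_chromatin(cfg)
  tr <- ch$truth
  for (cell in ch$cells) {
    dy <- cell$chrT
    expect_true(all(diff(dy) >= cfg$nucleosome_length))  # hard core
    for (i in seq_len(nrow(tr))) {
      expect_true(tr$minus1[i] %in% dy)
      expect_true(tr$plus1[i] %in% dy)
      expect_false(any(dy > tr$free_l[i] - 74 & dy < tr$free_r[i] + 74))
    }
  }
})

test_that("both-site cleavage releases a 51-bp fragment centered on the dyad", {
  core <- experiment_core_fragment()
  expect_equal(core$fragment_length, 51L)
  # explicit geometry: dyad 1000 -> core [975, 1025], gaps of 4 bp lost
  f <- core$frags
  expect_true(any(f$start == 975 & f$end == 1025))
})

test_that("cleavage-site geometry gives the medium and long length classes", {
  # two nucleosomes spaced 161 bp; all four sites cut -> mediums of 102 bp
  genome <- chrom_spec("toy", 3000L)
  genes <- data.frame(gene_id = "g", chrom = "toy", strand = "+",
                      tss = 2500L, tts = 2900L)
  cfg <- synthetic_config(seed = 1, genome = genome, genes = genes,
                          n_cells = 1L, cut_probability = 1,
                          background_rate = 0)
  cells <- list(list(toy = c(1000L, 1161L)))
  f <- cleave(cells, cfg)
  len <- f$end - f$start + 1L
  expect_true(all(c(51L, 102L) %in% len))   # cores + NRL - 59 medium
  expect_equal(sum(len == 51L), 2L)

  # dropping one dyad-proximal site leaves the long class NRL - 4 = 157:
  # fragment from right site of nuc 1 to right site of nuc 2
  expect_equal((1161L + 25L) - (1000L + 30L) + 1L, 157L)
})

test_that("with p = 1 interior fragments are exactly cores and mediums", {
  cfg <- free_cfg(seed = 8, L = 50000L, n_cells = 3L, cut_probability = 1,
                  background_rate = 0)
  ch <- generate_chromatin(cfg)
  f <- cleave(ch, cfg)
  len <- f$end - f$start + 1L
  interior <- f$start > 1L & f$end < 50000L
  spacings <- sort(unique(unlist(lapply(ch$cells, function(cell) diff(cell$chrF)))))
  expect_setequal(sort(unique(len[interior])), sort(c(51L, spacings - 59L)))
})

test_that("no emitted fragment overlaps a lost-gap interval", {
  cfg <- free_cfg(seed = 8, L = 50000L, n_cells = 1L, cut_probability = 1,
                  background_rate = 0)
  ch <- generate_chromatin(cfg)
  f <- cleave(ch, cfg)
  dy <- ch$cells[[1]]$chrF
  gaps <- c(outer(dy, c(-29L, 26L), "+"))  # gap starts (left, right sites)
  for (gs in gaps) {
    expect_false(any(f$start <= gs + 3L & f$end >= gs))
  }
})

test_that("long-class lengths reproduce the spacing distribution shifted by -4", {
  cfg <- free_cfg(seed = 13, L = 200000L, n_cells = 10L,
                  cut_probability = 0.8, background_rate = 0)
  ch <- generate_chromatin(cfg)
  f <- cleave(ch, cfg)
  interior <- f$start > 1L & f$end < 200000L  # chromosome-terminal pieces out
  len <- (f$end - f$start + 1L)[interior]
  long <- len[len >= 135 & len <= 175]
  expect_true(all(long %in% c(148L, 158L, 168L)))
  sp <- unlist(lapply(ch$cells, function(cell) diff(cell$chrF)))
  p_sp <- as.numeric(table(factor(sp, c(152, 162, 172)))) / length(sp)
  p_lg <- as.numeric(table(factor(long, c(148, 158, 168)))) / length(long)
  expect_lt(max(abs(p_sp - p_lg)), 0.03)
})

test_that("sequence oscillation is flat at amplitude zero and 10-bp periodic otherwise", {
  cfg <- small_cfg(seed = 3, n = 10L, n_cells = 15L)
  ds <- synthesize_dataset(cfg, sequence = TRUE)
  dy <- dyads_from_fragments(ds$frags, cfg$genome)
  dp <- dinucleotide_phasing(dy, ds$seq)
  ac <- profile_autocorrelation(dp$ww)
  expect_equal(as.integer(which.max(ac)), 10L)

  cfg0 <- small_cfg(seed = 3, n = 10L, n_cells = 15L, ww_amplitude = 0)
  ds0 <- synthesize_dataset(cfg0, sequence = TRUE)
  dp0 <- dinucleotide_phasing(dyads_from_fragments(ds0$frags, cfg0$genome),
                              ds0$seq)
  expect_lt(sd(dp0$ww), sd(dp$ww) / 3)
  # i.i.d. bases at P(W) = 0.5 give WW dinucleotide frequency 0.25
  expect_lt(abs(mean(dp0$ww) - 0.25), 0.02)
})
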