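test_that("fragment classes follow the short/medium/long ranges", {
  expect_equal(as.character(classify_fragment(c(51, 102, 157, 65, 44, 58, 135, 175, 176))),
               c("short", "medium", "long", "other", "short", "short",
                 "long", "long", "other"))
})

test_that("a constructed end offset is recovered as lag and gap", {
  # short fragments [s, s+50], medium fragments starting 5 bp past their ends
  g <- chrom_spec("c", 10000L)
  s <- seq(500, 9000, by = 400)
  f <- rbind(frag_df("c", s, s + 50L), frag_df("c", s + 55L, s + 155L))
  ge <- estimate_gap(f, g)
  expect_equal(ge$lag, 5L)
  expect_equal(ge$gap, 4L)
  expect_equal(names(which.max(ge$curve)), "5")
  # exact translation invariance
  f2 <- f; f2$start <- f2$start + 137L; f2$end <- f2$end + 137L
  expect_equal(estimate_gap(f2, g)$lag, 5L)
})

test_that("synthetic data with a modified gap recovers it", {
  cfg <- small_cfg(seed = 6, gap = 6L)
  ds <- synthesize_dataset(cfg)
  ge <- estimate_gap(ds$frags, cfg$genome)
  expect_equal(ge$lag, 7L)
  expect_equal(ge$gap, 6L)
})

test_that("identical end sets peak at the repeat-length echo, not lag 0", {
  # three nucleosomes 161 bp apart; cross-correlating short right ends
  # against themselves has its (excluded) maximum at lag 0 and an echo at
  # the spacing
  g <- chrom_spec("c", 2000L)
  d <- c(500L, 661L, 822L)
  shorts <- frag_df("c", d - 25L, d + 25L)
  ge <- estimate_gap(shorts, g, class_a = "short", end_a = "right",
                     class_b = "short", end_b = "right", max_lag = 200L)
  expect_equal(ge$lag, 161L)
})

test_that("flat correlation curves are rejected", {
  g <- chrom_spec("c", 1000L)
  f <- rbind(frag_df("c", 100, 150), frag_df("c", 300, 400))
  expect_error(estimate_gap(f, g, max_lag = 3L), "unambiguous")
  expect_error(estimate_gap(frag_df("c", 100, 150), g), "empty end-count")
})

test_that("single-linker generators give the unique NRL 147 + L", {
  for (L in c(5L, 15L, 25L)) {
    cfg <- free_cfg(seed = 20 + L, L = 150000L, n_cells = 4L,
                    linker_set = L, background_rate = 0)
    ds <- synthesize_dataset(cfg)
    f <- ds$frags[ds$frags$start > 1L & ds$frags$end < 150000L, ]
    ge <- estimate_gap(f, cfg$genome)
    sp <- nrl_spectrum(f, ge)
    expect_equal(sp$modal_nrl, 147L + L + ge$gap - 4L)
    expect_equal(ge$gap, 4L)
    expect_equal(sp$linkers, L)
  }
})

test_that("sparse long-fragment sets warn and report no modes", {
  f <- frag_df("c", seq(100, 1000, by = 100), seq(100, 1000, by = 100) + 156L)
  expect_warning(sp <- nrl_spectrum(f, 4L), "no modes")
  expect_length(sp$modal_nrl, 0)
})

test_that("per-gene spacing thresholds, means, and mixture recovery", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "c", strand = "+",
                      tss = c(1000L, 6000L), tts = c(3000L, 8000L))
  st <- seq(1100L, 2800L, by = 200L)
  f <- frag_df("c", st, st + 156L)  # 9 long fragments of 157 bp in gene a
  sc <- per_gene_spacing(f, genes, min_fragments = 5L)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$gene_id, "a")
  expect_equal(sc$mean_long_length, 157)
  expect_equal(nrow(per_gene_spacing(f, genes, min_fragments = 10L)), 0L)

  # per-gene long-length histograms match the genome-wide mixture (chi-sq)
  cfg <- synthetic_config(seed = 5)
  ds <- synthesize_dataset(cfg)
  sc2 <- per_gene_spacing(ds$frags, cfg$genes, min_fragments = 200L)
  modes <- c(148, 158, 168)
  pooled <- table(factor(unlist(sc2$long_lengths)[
    unlist(sc2$long_lengths) %in% modes], levels = modes))
  pv <- vapply(sc2$long_lengths, function(ll) {
    x <- table(factor(ll[ll %in% modes], levels = modes))
    suppressWarnings(stats::chisq.test(x, p = pooled / sum(pooled))$p.value)
  }, numeric(1))
  expect_gte(mean(pv > 0.01), 0.9)
})

test_that("quintile splitting distributes remainders to earlier quintiles", {
  mk_scores <- function(n, val = seq_len(n)) {
    data.frame(gene_id = sprintf("g%02d", seq_len(n)), n_fragments = 100L,
               n_long = 10L, mean_long_length = val)
  }
  p <- vec_profile(rep(1, 5000), "c")
  anch <- function(n) data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                                 chrom = "c", pos = 2500L, strand = "+",
                                 stringsAsFactors = FALSE)
  ndr <- function(n) data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                                run_length = 120L)
  qs <- quintile_summary(mk_scores(10L), p, ndr(10L), anch(10L))
  expect_equal(qs$table$n, rep(2L, 5))
  qs12 <- quintile_summary(mk_scores(12L), p, ndr(12L), anch(12L))
  expect_equal(qs12$table$n, c(3L, 3L, 2L, 2L, 2L))
  # monotone gradient in the sort key yields monotone quintile means
  expect_true(all(diff(qs12$table$mean_spacing_score) > 0))
  # identical scores: stable ordering by gene_id
  qeq <- quintile_summary(mk_scores(10L, val = 150), p, ndr(10L), anch(10L))
  expect_equal(qeq$table$mean_spacing_score, rep(150, 5))
})
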