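genome1 <- chrom_spec("chrI", 100000L)

test_that("fragment readers convert BED and 1-based TSV dialects", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t99\t150", "chrI\t0\t51"), bed)
  f <- read_fragments(bed, genome1, format = "bed")
  expect_equal(f$start, c(100L, 1L))
  expect_equal(f$end, c(150L, 51L))
  expect_equal(f$end - f$start + 1L, c(51L, 51L))

  tsv <- tempfile(fileext = ".tsv")
  writeLines("chrI\t100\t150", tsv)
  g <- read_fragments(tsv, genome1, format = "tsv")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 150L)
})

test_that("malformed and degenerate fragment records are rejected", {
  bad <- tempfile()
  writeLines(c("chrI\t10\t60", "chrI\tfoo\t80"), bad)
  expect_error(read_fragments(bad, genome1), "line 2")
  zero <- tempfile()
  writeLines("chrI\t100\t100", zero)
  expect_error(read_fragments(zero, genome1, format = "bed"), "length")
  rev <- tempfile()
  writeLines("chrI\t100\t50", rev)
  expect_error(read_fragments(rev, genome1, format = "tsv"), "end < start")
})

test_that("records on unknown chromosomes are dropped with a count", {
  path <- tempfile()
  writeLines(c("chrI\t99\t150", "chrZ\t99\t150"), path)
  expect_message(f <- read_fragments(path, genome1), "1 fragment")
  expect_equal(nrow(f), 1L)
  expect_equal(attr(f, "n_dropped"), 1L)
})

test_that("fragment files round-trip across both dialects", {
  set.seed(7)
  f <- frag_df("chrI", s <- sample(1000:2000, 50), s + sample(40:200, 50, TRUE))
  for (fmt in c("bed", "tsv")) {
    path <- tempfile()
    write_fragments(f, path, format = fmt)
    g <- read_fragments(path, genome1, format = fmt)
    expect_equal(g$start, f$start)
    expect_equal(g$end, f$end)
  }
})

test_that("dyad midpoints use the floor rule and the 44-58 size window", {
  f <- frag_df("chrI", c(100, 100, 100), c(150, 143, 159))
  d <- dyads_from_fragments(f, genome1)
  v <- d[["chrI"]]
  expect_equal(which(v > 0), c(121L, 125L))  # 44-bp midpoint floors to 121
  expect_equal(sum(v), 2)                    # 60-bp fragment excluded
  expect_warning(dyads_from_fragments(frag_df("chrI", 1, 200), genome1),
                 "size window")
})

test_that("dyad counts conserve the number of retained fragments", {
  set.seed(1)
  n <- 500
  st <- sample(5000:90000, n, TRUE)
  f <- frag_df("chrI", st, st + sample(30:210, n, TRUE) - 1L)
  len <- f$end - f$start + 1L
  d <- dyads_from_fragments(f, genome1)
  expect_equal(profile_total(d), sum(len >= 44 & len <= 58))
})

test_that("profile normalization matches the per-chromosome mean-1 convention", {
  p <- vec_profile(c(2, 2, 2, 2))
  expect_equal(normalize_profile(p)[[1]], c(1, 1, 1, 1))
  expect_equal(normalize_profile(vec_profile(c(4, 0, 0, 0)))[[1]], c(4, 0, 0, 0))
  expect_equal(normalize_profile(vec_profile(c(3, 1)))[[1]], c(1.5, 0.5))
  # idempotent
  q <- normalize_profile(vec_profile(runif(100)))
  expect_equal(normalize_profile(q)[[1]], q[[1]])
  expect_true(attr(q, "normalized"))
  # all-zero chromosome errors with its name
  z <- new_profile(chrom_spec(c("a", "bad"), c(10L, 10L)))
  z[["a"]][1] <- 1
  expect_error(normalize_profile(z), "bad")
})

test_that("a single dyad produces a 101-bp footprint, clipped at edges", {
  g <- chrom_spec("c", 1000L)
  d <- new_profile(g); d[["c"]][500] <- 1
  occ <- occupancy_from_dyads(d)
  nz <- which(occ[["c"]] > 0)
  expect_equal(range(nz), c(450L, 550L))
  expect_equal(length(nz), 101L)

  d2 <- new_profile(g); d2[["c"]][10] <- 1
  nz2 <- which(occupancy_from_dyads(d2)[["c"]] > 0)
  expect_equal(range(nz2), c(1L, 60L))

  d3 <- new_profile(g); d3[["c"]][c(500, 510)] <- 1
  expect_equal(occupancy_from_dyads(d3)[["c"]][505], 2)
})

test_that("occupancy mass equals 101 x dyad mass away from edges", {
  set.seed(2)
  d <- new_profile(chrom_spec("c", 5000L))
  d[["c"]][sample(200:4800, 100)] <- rpois(100, 3)
  occ <- occupancy_from_dyads(d)
  expect_equal(profile_total(occ), 101 * profile_total(d))
})

test_that("fragment-stacking occupancy adds coverage within the 50-200 window", {
  g <- chrom_spec("c", 1000L)
  occ <- occupancy_from_fragments(frag_df("c", 100, 150), g)
  expect_equal(which(occ[["c"]] > 0), 100:150)
  # 40-bp fragment excluded by the default window
  occ40 <- occupancy_from_fragments(frag_df("c", 100, 139), g)
  expect_equal(sum(occ40[["c"]]), 0)
  # overlapping fragments are additive
  occ2 <- occupancy_from_fragments(frag_df(c("c", "c"), c(100, 120), c(150, 170)), g)
  expect_equal(occ2[["c"]][130], 2)
  expect_equal(occ2[["c"]][110], 1)
})

test_that("tracks round-trip bit-exactly for integer counts", {
  g <- chrom_spec(c("a", "b"), c(300L, 200L))
  p <- new_profile(g)
  set.seed(3)
  p[["a"]][sample(300, 40)] <- sample(1:5, 40, TRUE)
  p[["b"]][sample(200, 10)] <- sample(1:9, 10, TRUE)
  for (fmt in c("bedgraph", "wig")) {
    path <- tempfile()
    write_track(p, path, format = fmt)
    q <- read_track(path, g, format = fmt)
    expect_identical(q[["a"]], p[["a"]])
    expect_identical(q[["b"]], p[["b"]])
  }
  expect_error(write_track(p, file.path(tempdir(), "no/such/dir/x.bg")),
               "cannot open")
})
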