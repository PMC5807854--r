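test_that("known small lattices match hand-enumerable partition functions", {
  # L = 10, a = 3, all weights 1: 28 non-overlapping configurations
  pf <- partition_function(lattice_model(10L, u = 0, a = 3L))
  expect_equal(exp(pf$logZ), 28, tolerance = 1e-12)
  # L = 3, a = 3: empty lattice or one rod
  pf3 <- partition_function(lattice_model(3L, u = 0, a = 3L))
  expect_equal(exp(pf3$logZ), 2, tolerance = 1e-12)
  expect_equal(pf3$n[2], 0.5, tolerance = 1e-12)
  expect_equal(pf3$occ, rep(0.5, 3), tolerance = 1e-12)
  # L = a: Z = 1 + exp(mu - u)
  pf1 <- partition_function(lattice_model(5L, u = 0.1, a = 5L, mu = 0.3))
  expect_equal(exp(pf1$logZ), 1 + exp(0.2), tolerance = 1e-12)
})

test_that("recursion matches brute-force enumeration on random instances", {
  set.seed(99)
  for (i in 1:100) {
    a <- sample(c(3L, 5L, 7L), 1)
    L <- sample(a:28L, 1)
    m <- lattice_model(L, u = runif(L, -2, 2), a = a, mu = runif(1, -1, 1))
    pf <- partition_function(m)
    bf <- brute_force_oracle(m)
    expect_lt(abs(pf$logZ - bf$logZ) / max(abs(bf$logZ), 1e-12), 1e-10)
    expect_lt(max(abs(pf$n - bf$n)), 1e-10)
    expect_lt(max(abs(pf$occ - bf$occ)), 1e-10)
  }
})

test_that("dyad probabilities are mirror-symmetric under uniform energies", {
  pf <- partition_function(lattice_model(2001L, u = -1, a = 147L, mu = 0))
  expect_equal(pf$n, rev(pf$n), tolerance = 1e-12)
  expect_true(all(pf$n >= 0 & pf$n <= 1))
  expect_true(all(pf$occ >= 0 & pf$occ <= 1 + 1e-12))
})

test_that("occupancy equals the windowed dyad-probability sum", {
  pf <- partition_function(lattice_model(1200L, u = -0.5, a = 147L))
  n <- pf$n
  cs <- c(0, cumsum(n))
  occ <- vapply(seq_along(n), function(i)
    cs[min(i + 73L, length(n)) + 1L] - cs[max(i - 73L, 1L)], numeric(1))
  expect_equal(pf$occ, occ, tolerance = 1e-12)
})

test_that("the dilute limit reduces to non-interacting weights", {
  u <- runif(800, -0.5, 0.5)
  pf <- partition_function(lattice_model(800L, u = u, a = 147L, mu = -15))
  valid <- 74:(800 - 73)
  expect_equal(pf$n[valid], exp(-15 - u[valid]), tolerance = 1e-4)
})

test_that("barrier construction matches the half-Gaussian formula", {
  p <- barrier_params(H = 5, sigma = 20, x0 = 60, u_minus_mu = -2)
  flanks <- data.frame(p_l = 500, p_r = 900)
  u <- build_barrier(flanks, p, 2000L)
  c_l <- 560; c_r <- 840
  expect_equal(u[c_l], -2 + 5)
  expect_equal(u[c_l - 20], -2 + 5 * exp(-0.5))
  expect_equal(u[(c_l + 1):(c_r - 1)], rep(3, c_r - c_l - 1))
  expect_equal(u[c_l - 200], -2, tolerance = 1e-10)
  # narrow NDR: centers crossed -> pointwise max of the half-Gaussians
  expect_warning(u2 <- build_barrier(data.frame(p_l = 500, p_r = 580), p, 2000L),
                 "narrow NDR")
  expect_lt(max(u2), -2 + 5 + 1e-12)
  # overlapping barriers from adjacent promoters combine by pointwise max
  two <- data.frame(p_l = c(500, 700), p_r = c(900, 1100))
  u3 <- build_barrier(two, p, 2000L)
  expect_equal(max(u3), 3)
  expect_true(all(u3 >= pmax(build_barrier(two[1, ], p, 2000L),
                             build_barrier(two[2, ], p, 2000L)) - 1e-12))
})

test_that("raising the barrier lowers occupancy at its center", {
  # for very weak barriers (H <~ 3 kT at this density) repacking of the
  # flanking arrays can transiently raise coverage at the center by a few
  # tenths of a percent; monotonicity is a property of the
  # barrier-dominated regime
  flanks <- data.frame(p_l = 3800, p_r = 4200)
  center <- 4000L
  occ_at <- function(H) {
    p <- barrier_params(H = H, sigma = 25, x0 = 60, u_minus_mu = -2.5)
    u <- build_barrier(flanks, p, 8000L)
    partition_function(lattice_model(8000L, u = u))$occ[center]
  }
  vals <- vapply(c(3, 5, 8, 12), occ_at, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], occ_at(0) / 10)
})

test_that("barriers phase flanking nucleosomes with decaying oscillations", {
  flanks <- data.frame(p_l = 2800, p_r = 3200)
  pred <- predict_genome(data.frame(chrom = "c", p_l = flanks$p_l,
                                    p_r = flanks$p_r),
                         reference_barrier_params(),
                         chrom_spec("c", 6000L))
  n <- pred$c$n
  # peaks right of the barrier decay inward (statistical positioning)
  right <- n[3300:5700]
  pk <- which(diff(sign(diff(right))) < 0) + 1
  pk_heights <- right[pk]
  expect_gt(length(pk), 5)
  expect_true(all(diff(pk_heights[1:5]) < 0))
  # no promoters: flat interior, edge oscillations decay inward
  flat <- partition_function(lattice_model(6000L, u = -2.79))
  mid <- flat$n[2500:3500]
  expect_lt(sd(mid) / mean(mid), 0.01)
  edge <- flat$n[74:500]
  expect_gt(sd(edge) / mean(edge), 0.1)
})

test_that("barrier spacing at integer repeat lengths interferes constructively", {
  # measure the model repeat from a single barrier, then compare peak
  # amplitude between two barriers at integer vs half-integer multiples
  params <- reference_barrier_params()
  single <- predict_genome(data.frame(chrom = "c", p_l = 2900, p_r = 3300),
                           params, chrom_spec("c", 8000L))$c$n
  right <- single[3300:4500]
  pk <- which(diff(sign(diff(right))) < 0) + 1
  nrl <- round(mean(diff(pk[1:4])))
  amp_between <- function(sep) {
    p1 <- 2000L
    fl <- data.frame(chrom = "c",
                     p_l = c(p1, p1 + 400L + sep),
                     p_r = c(p1 + 400L, p1 + 800L + sep))
    n <- predict_genome(fl, params, chrom_spec("c", 10000L))$c$n
    seg <- n[(p1 + 500L):(p1 + 300L + sep)]
    diff(range(seg))
  }
  integer_sep <- 6L * nrl
  half_sep <- as.integer(6.5 * nrl)
  expect_gt(amp_between(integer_sep), amp_between(half_sep))
})

test_that("the 2D correlation objective is exact at self-consistency", {
  lat <- synthetic_promoter_lattice(n_genes = 12L)
  truth <- reference_barrier_params()
  u <- build_barrier(lat$flanks, truth, lat$L)
  pf <- partition_function(lattice_model(lat$L, u = u))
  expect_equal(heatmap_correlation(pf$n, pf$n, lat$flanks$p_r), 1)
  # perturbing any single parameter can only lower the objective
  obj <- function(p) {
    up <- build_barrier(lat$flanks, p, lat$L)
    pp <- partition_function(lattice_model(lat$L, u = up))
    heatmap_correlation(pf$n, pp$n, lat$flanks$p_r)
  }
  for (perturbed in list(barrier_params(6.5, 27.64, 68, -2.79),
                         barrier_params(7.88, 35, 68, -2.79),
                         barrier_params(7.88, 27.64, 55, -2.79),
                         barrier_params(7.88, 27.64, 68, -2.2))) {
    expect_lt(obj(perturbed), 1)
  }
  expect_error(heatmap_correlation(rep(1, lat$L), pf$n, lat$flanks$p_r),
               "degenerate")
})

test_that("degenerate models are rejected", {
  expect_error(lattice_model(100L, a = 4L), "odd")
  expect_error(lattice_model(100L, u = c(1, 2)), "length L")
  expect_error(lattice_model(100L, u = Inf), "finite")
  expect_error(brute_force_oracle(lattice_model(40L, a = 3L)), "L <= 30")
})
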