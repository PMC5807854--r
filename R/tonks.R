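# Equilibrium Tonks (hard-rod) model of nucleosome positioning.
# Energies are in units of kT (beta = 1). Only u - mu is physically
# identified by the observables, so models carry u and mu separately but
# all defaults set mu = 0.

#' Construct a hard-rod lattice model
#'
#' @param L lattice length in bp.
#' @param u binding-energy vector in kT, one entry per bp (entries outside
#'   the valid dyad range `[(a+1)/2, L-(a-1)/2]` are ignored). A scalar is
#'   recycled.
#' @param a rod (nucleosome) length in bp, odd (default 147).
#' @param mu chemical potential in kT (default 0).
#' @return list of class `lattice_model`.
#' @export
lattice_model <- function(L, u = 0, a = 147L, mu = 0) {
  L <- as.integer(L)
  a <- as.integer(a)
  if (a %% 2L == 0L) stop("rod length a must be odd")
  if (length(u) == 1L) u <- rep(as.numeric(u), L)
  if (length(u) != L) stop("u must have length L (or be scalar)")
  if (any(!is.finite(u))) stop("u must be finite everywhere")
  structure(list(L = L, a = a, u = u, mu = mu), class = "lattice_model")
}

#' Exact dyad probabilities and occupancy by recursive partition function
#'
#' Computes the grand-canonical partition function of the hard-rod lattice
#' by forward/backward recursion in the log domain (stable for lattices up
#' to 1e7 bp), the per-position dyad probability `n(k)`, and the occupancy
#' `Occ(i) = sum_{k = i-73}^{i+73} n(k)` (for a = 147; edge-clipped).
#'
#' @param model a [lattice_model()].
#' @return list of class `tonks_output`: `logZ`, `n` (length L), `occ`
#'   (length L).
#' @export
partition_function <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  h <- (model$a - 1L) %/% 2L
  logw <- rep(-Inf, model$L)
  valid <- seq(h + 1L, model$L - h)
  if (model$L >= model$a)
    logw[valid] <- model$mu - model$u[valid]
  out <- .tonks_recursion(logw, model$a)
  structure(out, class = "tonks_output")
}

#' Brute-force enumeration oracle for small lattices
#'
#' Explicitly enumerates every non-overlapping rod configuration (any
#' number of rods), with Boltzmann weight `prod exp(mu - u(k))` over placed
#' rods, and accumulates Z, n, and Occ exactly. Verification oracle for
#' [partition_function()]; refuses L > 30.
#'
#' @param model a [lattice_model()] with `L <= 30`.
#' @return list of class `tonks_output`: `logZ`, `n`, `occ`.
#' @export
brute_force_oracle <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  if (model$L > 30L) stop("brute-force oracle limited to L <= 30")
  L <- model$L; a <- model$a; h <- (a - 1L) %/% 2L
  w <- numeric(L)
  if (L >= a) {
    valid <- seq(h + 1L, L - h)
    w[valid] <- exp(model$mu - model$u[valid])
  }
  env <- new.env()
  env$Z <- 0
  env$nsum <- numeric(L)
  rec <- function(kmin, weight, chosen) {
    env$Z <- env$Z + weight
    if (length(chosen)) env$nsum[chosen] <- env$nsum[chosen] + weight
    if (kmin > L - h) return(invisible())
    for (k in kmin:(L - h)) {
      if (w[k] > 0) rec(k + a, weight * w[k], c(chosen, k))
    }
    invisible()
  }
  rec(h + 1L, 1, integer(0))
  n <- env$nsum / env$Z
  cs <- c(0, cumsum(n))
  occ <- vapply(seq_len(L), function(i)
    cs[min(i + h, L) + 1L] - cs[max(i - h, 1L)], numeric(1))
  structure(list(logZ = log(env$Z), n = n, occ = occ), class = "tonks_output")
}

#' Promoter energy-barrier parameters
#'
#' The barrier is two half-Gaussians of height `H` and width `sigma` whose
#' centers sit `x0` bp inside the -1/+1 dyads, joined by a flat top of
#' height `H`; away from barriers the binding energy is the baseline
#' `u_minus_mu`.
#'
#' @param H barrier height, kT (>= 0).
#' @param sigma Gaussian half-width, bp (> 0).
#' @param x0 center offset from the flanking dyads, bp (>= 0).
#' @param u_minus_mu baseline binding energy minus chemical potential, kT.
#' @return list of class `barrier_params`.
#' @export
barrier_params <- function(H, sigma, x0, u_minus_mu) {
  if (H < 0) stop("H must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (x0 < 0) stop("x0 must be >= 0")
  structure(list(H = H, sigma = sigma, x0 = x0, u_minus_mu = u_minus_mu),
            class = "barrier_params")
}

#' Build the energy landscape from -1/+1 flank dyads and barrier parameters
#'
#' For each promoter with flank dyads `p_l < p_r` (genomic order), the
#' barrier centers are `c_l = p_l + x0` and `c_r = p_r - x0`; the barrier
#' term is `H` on `[c_l, c_r]`, `H exp(-(k - c_l)^2 / (2 sigma^2))` left of
#' `c_l`, and the mirror image right of `c_r`. Overlapping barrier terms
#' from neighbouring promoters combine by pointwise maximum. If
#' `c_r < c_l` (narrow NDR) the two half-Gaussians are combined by
#' pointwise maximum and the promoter is flagged with a warning.
#'
#' @param flanks data.frame with columns `p_l`, `p_r` (flank dyads, bp).
#' @param params a [barrier_params()].
#' @param L lattice length in bp.
#' @return numeric energy vector `u` of length L (baseline + barrier), kT.
#' @export
build_barrier <- function(flanks, params, L) {
  u <- rep(params$u_minus_mu, L)
  barrier <- numeric(L)
  reach <- ceiling(params$sigma * sqrt(2 * 27.7))  # exp() < 1e-12 beyond
  for (i in seq_len(nrow(flanks))) {
    c_l <- flanks$p_l[i] + params$x0
    c_r <- flanks$p_r[i] - params$x0
    lo <- max(1L, floor(min(c_l, c_r) - reach))
    hi <- min(L, ceiling(max(c_l, c_r) + reach))
    if (lo > hi) next
    k <- lo:hi
    gl <- params$H * exp(-(k - c_l)^2 / (2 * params$sigma^2))
    gr <- params$H * exp(-(k - c_r)^2 / (2 * params$sigma^2))
    if (c_r < c_l) {
      warning("narrow NDR: barrier centers crossed for promoter ", i)
      term <- pmax(gl, gr)
    } else {
      term <- ifelse(k < c_l, gl, ifelse(k > c_r, gr, params$H))
    }
    barrier[k] <- pmax(barrier[k], term)
  }
  u + barrier
}

#' Predict nucleosome organization genome-wide from fitted barriers
#'
#' Builds the energy landscape per chromosome from the called -1/+1 flank
#' dyads and runs [partition_function()].
#'
#' @param flanks data.frame with `chrom`, `p_l`, `p_r` per promoter.
#' @param params a [barrier_params()].
#' @param genome a [chrom_spec()] table.
#' @param a rod length (default 147).
#' @return named list per chromosome of `tonks_output`; also `n` and `occ`
#'   as `bp_profile`s under attributes for track export via [write_track()].
#' @export
predict_genome <- function(flanks, params, genome, a = 147L) {
  out <- lapply(seq_len(nrow(genome)), function(i) {
    nm <- genome$name[i]
    u <- build_barrier(flanks[flanks$chrom == nm, , drop = FALSE],
                       params, genome$length[i])
    partition_function(lattice_model(genome$length[i], u = u, a = a))
  })
  names(out) <- genome$name
  out
}

#' Extract n or occ tracks from a predict_genome() result
#' @param pred list from [predict_genome()].
#' @param what `"n"` or `"occ"`.
#' @return a `bp_profile`.
#' @export
prediction_profile <- function(pred, what = c("n", "occ")) {
  what <- match.arg(what)
  as_profile(lapply(pred, `[[`, what))
}
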