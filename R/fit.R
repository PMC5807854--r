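# Fitting the promoter energy barrier by maximizing the 2D correlation
# between observed and predicted dyad densities aligned at the +1 dyads.

default_barrier_bounds <- function() {
  rbind(H = c(1, 15), sigma = c(5, 60), x0 = c(20, 120),
        u_minus_mu = c(-6, 0))
}

# heatmap of a per-bp vector around anchor positions (all '+' orientation)
anchor_matrix <- function(v, anchors, window) {
  cols <- seq(window[1], window[2])
  m <- matrix(NA_real_, length(anchors), length(cols))
  for (i in seq_along(anchors)) {
    pos <- anchors[i] + cols
    ok <- pos >= 1L & pos <= length(v)
    m[i, ok] <- v[pos[ok]]
  }
  m
}

#' 2D correlation objective between observed and predicted dyad densities
#'
#' Pearson correlation between the flattened +1-aligned heatmaps of the
#' observed and predicted dyad distributions; equals 1 when they are
#' identical up to an affine transform per the correlation identity.
#'
#' @param observed per-bp observed dyad density vector (training
#'   chromosome).
#' @param predicted per-bp predicted dyad probability vector.
#' @param anchors +1 dyad coordinates (rows of the heatmaps).
#' @param window relative window, default `c(-400, 1000)`.
#' @return Pearson correlation (scalar).
#' @export
heatmap_correlation <- function(observed, predicted, anchors,
                                window = c(-400L, 1000L)) {
  mo <- anchor_matrix(observed, anchors, window)
  mp <- anchor_matrix(predicted, anchors, window)
  ok <- is.finite(mo) & is.finite(mp)
  if (sd(mo[ok]) == 0) stop("degenerate observed heatmap (zero variance)")
  cor(mo[ok], mp[ok])
}

#' Fit promoter-barrier parameters to an observed dyad distribution
#'
#' Global search over (H, sigma, x0, u - mu): seeded Latin-hypercube
#' starting points over the bounds; the best `n_screen` are screened with a
#' short Nelder-Mead run (in unit-box coordinates, proposals projected onto
#' the box), the best `n_refine` screened candidates get a full Nelder-Mead
#' run, and the incumbent is polished by seeded basin-hopping restarts. The
#' objective is the 2D Pearson correlation of [heatmap_correlation()].
#' Deterministic under `seed`.
#'
#' @param observed per-bp observed dyad density on the training chromosome.
#' @param flanks data.frame with `p_l`, `p_r` per promoter of the training
#'   chromosome.
#' @param anchors +1 dyad coordinates used to align the heatmaps (defaults
#'   to `flanks$p_r`).
#' @param L training-lattice length (defaults to `length(observed)`).
#' @param a rod length (default 147).
#' @param window alignment window, default `c(-400, 1000)`.
#' @param bounds 4 x 2 matrix of lower/upper bounds (rows H, sigma, x0,
#'   u_minus_mu).
#' @param seed integer seed (mandatory).
#' @param n_lhs number of Latin-hypercube starting points (default 40).
#' @param n_screen starts screened with a short Nelder-Mead run (default 8).
#' @param n_refine screened candidates refined in full (default 3).
#' @param maxit Nelder-Mead evaluation budget per full run (default 300;
#'   the screening runs use `maxit / 2`).
#' @return list: `params` (a [barrier_params()]), `correlation`,
#'   `n_evaluations`, `seed`.
#' @export
fit_barrier <- function(observed, flanks, anchors = NULL, L = NULL,
                        a = 147L, window = c(-400L, 1000L),
                        bounds = default_barrier_bounds(), seed,
                        n_lhs = 40L, n_screen = 8L, n_refine = 3L,
                        maxit = 300L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(L)) L <- length(observed)
  if (is.null(anchors)) anchors <- flanks$p_r
  lo <- bounds[, 1]; hi <- bounds[, 2]
  n_eval <- 0L
  obj_unit <- function(z) {
    z <- pmin(pmax(z, 0), 1)  # project proposals onto the box
    par <- lo + z * (hi - lo)
    p <- barrier_params(par[1], par[2], par[3], par[4])
    u <- build_barrier(flanks, p, L)
    pf <- partition_function(lattice_model(L, u = u, a = a))
    n_eval <<- n_eval + 1L
    heatmap_correlation(observed, pf$n, anchors, window)
  }
  set.seed(seed)
  starts <- lhs::randomLHS(n_lhs, 4L)
  vals <- apply(starts, 1, obj_unit)
  screen_rows <- order(vals, decreasing = TRUE)[seq_len(min(n_screen, n_lhs))]
  screened <- lapply(screen_rows, function(r)
    optim(starts[r, ], obj_unit, method = "Nelder-Mead",
          control = list(fnscale = -1, maxit = ceiling(maxit / 2),
                         reltol = 1e-8)))
  sv <- vapply(screened, `[[`, numeric(1), "value")
  keep <- order(sv, decreasing = TRUE)[seq_len(min(n_refine, length(sv)))]
  best_z <- screened[[keep[1]]]$par
  best_v <- sv[keep[1]]
  for (k in keep) {
    fit <- optim(screened[[k]]$par, obj_unit, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = maxit,
                                reltol = 1e-10))
    if (fit$value > best_v) {
      best_v <- fit$value
      best_z <- fit$par
    }
  }
  # basin hopping around the incumbent: a fresh simplex at a seeded jitter
  # of the best point escapes collapsed simplices and shallow ridges
  for (r in 1:5) {
    z0 <- if (r == 1) best_z else
      pmin(pmax(best_z + stats::rnorm(4, 0, 0.08), 0), 1)
    fit <- optim(z0, obj_unit, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = maxit, reltol = 1e-12))
    if (fit$value > best_v) {
      best_v <- fit$value
      best_z <- fit$par
    }
  }
  best_z <- pmin(pmax(best_z, 0), 1)
  par <- lo + best_z * (hi - lo)
  list(params = barrier_params(par[1], par[2], par[3], par[4]),
       correlation = best_v, n_evaluations = n_eval, seed = seed)
}

#' Write fitted barrier parameters with optimizer metadata as YAML
#' @param fit result of [fit_barrier()].
#' @param path output path.
#' @export
write_fit_yaml <- function(fit, path) {
  yaml::write_yaml(list(
    H = fit$params$H, sigma = fit$params$sigma, x0 = fit$params$x0,
    u_minus_mu = fit$params$u_minus_mu,
    correlation_2d = fit$correlation,
    optimizer = list(method = "LHS multistart + Nelder-Mead",
                     seed = fit$seed, n_evaluations = fit$n_evaluations)),
    path)
  invisible(path)
}
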