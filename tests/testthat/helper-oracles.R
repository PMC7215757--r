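# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: RSS surfaces are evaluated by direct arithmetic.

# RSS of the first-order model at (a, b) against observations, by hand.
oracle_rss <- function(a, b, t, y) sum((y - a * (1 - exp(-b * t)))^2)

# Best RSS over an n x n log-spaced (a, b) grid.
oracle_grid_best_rss <- function(t, y, a_lim, b_lim, n = 200L) {
  a_grid <- exp(seq(log(a_lim[1]), log(a_lim[2]), length.out = n))
  b_grid <- exp(seq(log(b_lim[1]), log(b_lim[2]), length.out = n))
  # vectorised: residual matrix per a over all b is still n^2 * length(t);
  # loop over a, vectorise over b and t
  best <- Inf
  E <- outer(b_grid, t, function(b, t) 1 - exp(-b * t))  # n x T
  for (a in a_grid) {
    R <- sweep(a * E, 2, y)            # model - obs
    best <- min(best, min(rowSums(R^2)))
  }
  best
}

# All weight vectors on the percent simplex with a given step (percent).
# Returns a matrix with one row per grid point, columns summing to 100.
oracle_simplex_grid <- function(n_comp, step = 1) {
  ticks <- seq(0, 100, by = step)
  if (n_comp == 2L) {
    cbind(ticks, 100 - ticks)
  } else if (n_comp == 3L) {
    g <- expand.grid(w1 = ticks, w2 = ticks)
    g <- g[g$w1 + g$w2 <= 100, ]
    cbind(g$w1, g$w2, 100 - g$w1 - g$w2)
  } else {
    stop("oracle supports 2 or 3 components")
  }
}

# Best RSS over the simplex grid for a linear-in-weights mixture basis.
oracle_simplex_best_rss <- function(B, y, step = 1) {
  W <- oracle_simplex_grid(ncol(B), step)
  pred <- W %*% t(B) / 100          # grid x times
  min(rowSums(sweep(pred, 2, y)^2))
}

# A standard noiseless percent-scale fixture curve.
make_noiseless_curve <- function(a = 90, b = 0.05,
                                 times = c(2, 4, 8, 24, 48, 72)) {
  release_curve(times, a * (1 - exp(-b * times)), scale = "percent",
                label = sprintf("truth a=%g b=%g", a, b))
}
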