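#' Fit the first-order release model to a curve
#'
#' Estimates `(a, b)` of \eqn{C_r(t) = a (1 - e^{-b t})} by unweighted
#' nonlinear least squares (Levenberg–Marquardt, via
#' [minpack.lm::nlsLM()]) subject to `a > 0`, `b > 0`. The start value for
#' `a` is 1.05 times the largest observed release; the start for `b` comes
#' from the slope of the log-linearised transform
#' \eqn{\log(1 - y/a_0)} vs `t`. No `t = 0` point is required: the model
#' pins \eqn{C_r(0) = 0} structurally rather than through an intercept.
#'
#' @param curve A [release_curve] with at least 3 points and at least 2
#'   distinct nonzero values.
#' @param a_upper Upper bound on `a`; default 10 times the largest observed
#'   value (release plateaus cannot credibly exceed that).
#' @param b_upper Upper bound on `b` in 1/h; default 100 (a half-life well
#'   under a minute, far faster than any sustained-release system).
#' @param maxiter Iteration cap for the Levenberg–Marquardt loop.
#' @param tol Relative convergence tolerance on parameters and RSS.
#' @return An object of class `first_order_fit`: a list with `params`
#'   ([first_order_params]), `residuals` (observed − fitted), `rss`, `r2`,
#'   `r2_adj` (`NA` when fewer than 4 points), `n_obs`, `converged`
#'   and `n_iter`.
#' @examples
#' tt <- c(2, 4, 8, 24, 48, 72)
#' cv <- release_curve(tt, 90 * (1 - exp(-0.05 * tt)))
#' fit_first_order(cv)$params
#' @export
fit_first_order <- function(curve, a_upper = NULL, b_upper = 100,
                            maxiter = 500, tol = 1e-10) {
  stopifnot(inherits(curve, "release_curve"))
  t <- curve$times
  y <- curve$values
  if (length(t) < 3L) stop("need at least 3 points to fit (got ", length(t), ")")
  nz <- unique(y[y > 0])
  if (length(nz) < 2L) {
    stop("unfittable input: need at least 2 distinct nonzero release values")
  }

  ymax <- max(y)
  if (is.null(a_upper)) a_upper <- 10 * ymax
  a0 <- 1.05 * ymax
  # log-linearised start for b: ln(1 - y/a0) = -b t on points below a0
  ok <- t > 0 & y > 0 & y < a0
  b0 <- if (sum(ok) >= 2L) {
    z <- log(1 - y[ok] / a0)
    max(-sum(z * t[ok]) / sum(t[ok]^2), 1e-6)
  } else {
    log(2) / stats::median(t[t > 0])
  }
  b0 <- min(max(b0, 1e-6), b_upper)

  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = tol,
                                     ptol = tol, gtol = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-b * t)),
                      data = data.frame(t = t, y = y),
                      start = list(a = a0, b = b0),
                      lower = c(a = 1e-12, b = 1e-12),
                      upper = c(a = a_upper, b = b_upper),
                      control = ctrl),
    error = function(e) stop("unfittable input: ", conditionMessage(e)))

  cf <- stats::coef(fit)
  params <- first_order_params(cf[["a"]], cf[["b"]])
  fitted <- eval_first_order(params, t)
  res <- y - fitted
  rss <- sum(res^2)
  gof <- r_squared(y, fitted, n_params = 2L)
  ci <- fit$convInfo
  converged <- isTRUE(ci$isConv) && ci$finIter <= maxiter

  structure(list(params = params, residuals = res, rss = rss,
                 r2 = gof$r2, r2_adj = gof$r2_adj,
                 n_obs = length(t), converged = converged,
                 n_iter = ci$finIter),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf(
    "First-order fit: a = %.6g, b = %.6g /h | RSS = %.4g, R2 = %.4f, adj R2 = %s | n = %d, %s in %d iter\n",
    x$params$a, x$params$b, x$rss, x$r2,
    if (is.na(x$r2_adj)) "NA" else sprintf("%.4f", x$r2_adj),
    x$n_obs, if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

# Shared R2 arithmetic. TSS about the observed mean; adjusted R2 uses
# n - p - 1 denominator and is NA when that is not positive.
r_squared <- function(observed, predicted, n_params = 2L) {
  n <- length(observed)
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("R-squared undefined: observations are constant (zero TSS)")
  r2 <- 1 - rss / tss
  r2_adj <- if (n - n_params - 1L > 0L) {
    1 - (1 - r2) * (n - 1) / (n - n_params - 1)
  } else {
    NA_real_
  }
  list(r2 = r2, r2_adj = r2_adj, rss = rss, tss = tss)
}

#' Goodness of fit of first-order parameters against a curve
#'
#' Computes the coefficient of determination \eqn{R^2 = 1 - RSS/TSS} (TSS
#' about the observed mean) and its adjusted form
#' \eqn{1 - (1 - R^2)(n-1)/(n-p-1)} with `p = 2` model parameters, for a
#' given parameter pair evaluated on an observed curve.
#'
#' @param curve A [release_curve] with at least 4 points (the adjusted
#'   \eqn{R^2} needs `n - 3 > 0`).
#' @param params A [first_order_params] object.
#' @return A list with `r2` and `r2_adj`.
#' @export
goodness_of_fit <- function(curve, params) {
  stopifnot(inherits(curve, "release_curve"))
  params <- as_first_order_params(params)
  if (length(curve$times) < 4L) {
    stop("need at least 4 points for adjusted R-squared (got ",
         length(curve$times), ")")
  }
  g <- r_squared(curve$values, eval_first_order(params, curve$times),
                 n_params = 2L)
  list(r2 = g$r2, r2_adj = g$r2_adj)
}
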