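#' First-order release parameters
#'
#' Container for the two parameters of the non-linear first-order release
#' model \eqn{C_r(t) = a (1 - e^{-b t})}: `a`, the asymptotic cumulative
#' release, and `b`, the first-order rate constant (per hour). `a` carries
#' the scale of the curve it models (percent of loaded drug, or µg); on the
#' percent scale it may legitimately exceed 100, since measured release
#' curves occasionally plateau slightly above 100 % through assay error.
#'
#' @param a Asymptotic cumulative release; finite, `> 0`.
#' @param b First-order rate constant in 1/h; finite, `> 0`.
#' @return An object of class `first_order_params`.
#' @examples
#' p <- first_order_params(a = 90, b = 0.05)
#' eval_first_order(p, c(0, 24, 72))
#' @export
first_order_params <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a <= 0) {
    stop("'a' (asymptotic release) must be finite and > 0, got ", a)
  }
  if (!is.finite(b) || b <= 0) {
    stop("'b' (rate constant, 1/h) must be finite and > 0, got ", b)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "first_order_params")
}

#' @export
print.first_order_params <- function(x, ...) {
  cat(sprintf("First-order release parameters: a = %.6g, b = %.6g /h (t50 = %.3g h)\n",
              x$a, x$b, log(2) / x$b))
  invisible(x)
}

#' Evaluate the first-order release model
#'
#' Computes \eqn{C_r(t) = a (1 - e^{-b t})}. The model passes through 0 at
#' `t = 0` by construction, increases monotonically and approaches `a` as
#' `t` grows.
#'
#' @param params A [first_order_params] object.
#' @param t Vector of times in hours, all `>= 0`.
#' @return Numeric vector of cumulative release on the scale of `params$a`.
#' @export
eval_first_order <- function(params, t) {
  params <- as_first_order_params(params)
  stopifnot(is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and >= 0")
  }
  params$a * (1 - exp(-params$b * t))
}

# Coerce list(a=, b=) or an existing object; used so fit results and plain
# lists interoperate.
as_first_order_params <- function(x) {
  if (inherits(x, "first_order_params")) return(x)
  if (is.list(x) && all(c("a", "b") %in% names(x))) {
    return(first_order_params(x$a, x$b))
  }
  stop("expected first_order_params or a list with elements 'a' and 'b'")
}

#' Cumulative release curve
#'
#' An ordered set of (time, cumulative release) observations for one
#' formulation. Times are in hours and strictly increasing; values are
#' non-negative and share one scale (`"percent"` of loaded drug or
#' `"mass_ug"` micrograms). If a point at `t = 0` is present its value must
#' be 0, matching the model's initial condition.
#'
#' @param times Numeric vector of hours, strictly increasing, `>= 0`.
#' @param values Numeric vector of cumulative release, same length.
#' @param scale `"percent"` or `"mass_ug"`.
#' @param label Free-text label for the formulation/run.
#' @return An object of class `release_curve`.
#' @examples
#' release_curve(c(1, 4, 24), c(12, 35, 80), scale = "percent", label = "demo")
#' @export
release_curve <- function(times, values, scale = c("percent", "mass_ug"),
                          label = "") {
  scale <- match.arg(scale)
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and >= 0")
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and >= 0")
  }
  if (length(times) > 0 && times[1] == 0 && values[1] != 0) {
    stop("a point at t = 0 must have value 0 (model initial condition)")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 scale = scale, label = as.character(label)[1]),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  unit <- if (x$scale == "percent") "%" else "µg"
  cat(sprintf("Release curve '%s': %d points, %g-%g h, scale %s\n",
              x$label, length(x$times), min(x$times), max(x$times), unit))
  print(utils::head(as.data.frame(x), 10L))
  if (length(x$times) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  data.frame(time_h = x$times, value = x$values)
}

#' @export
length.release_curve <- function(x) length(x$times)
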