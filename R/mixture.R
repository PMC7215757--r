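#' Formulation: a named microparticle preparation with fitted kinetics
#'
#' Binds a formulation name to its first-order release parameters, the
#' scale those parameters live on, and optional loading metadata. On the
#' `"percent"` scale `a` is percent of loaded drug; on the `"mass_ug"`
#' scale `a` is micrograms released by a reference aliquot, which lets
#' published per-aliquot release amounts be used directly when the drug
#' loading is unknown.
#'
#' @param name Formulation name (unique within a mixture).
#' @param a,b First-order parameters (see [first_order_params]).
#' @param scale Scale of `a`: `"percent"` or `"mass_ug"`.
#' @param loading Optional drug loading in µg drug per mg of
#'   microparticles; required for mass-scale predictions from
#'   percent-scale parameters.
#' @param ee_percent Optional encapsulation efficiency in percent.
#' @return An object of class `formulation`.
#' @examples
#' formulation("CUR-oil", a = 77.4, b = 0.02, loading = 45)
#' @export
formulation <- function(name, a, b, scale = c("percent", "mass_ug"),
                        loading = NULL, ee_percent = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(loading)) {
    stopifnot(is.numeric(loading), length(loading) == 1L)
    if (!is.finite(loading) || loading <= 0) stop("loading must be > 0 (µg/mg)")
  }
  if (!is.null(ee_percent)) {
    stopifnot(is.numeric(ee_percent), length(ee_percent) == 1L,
              is.finite(ee_percent), ee_percent >= 0)
  }
  structure(list(name = name, params = first_order_params(a, b),
                 scale = scale, loading = loading, ee_percent = ee_percent),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("Formulation '%s': a = %.6g (%s), b = %.6g /h%s%s\n",
              x$name, x$params$a, x$scale, x$params$b,
              if (is.null(x$loading)) "" else
                sprintf(", loading %.4g µg/mg", x$loading),
              if (is.null(x$ee_percent)) "" else
                sprintf(", EE %.4g%%", x$ee_percent)))
  invisible(x)
}

#' Mixture specification over a set of formulations
#'
#' Non-negative component weights, interpreted as percent of total
#' microparticle mass per component, summing to 100 (within 1e-9).
#'
#' @param components List of [formulation] objects with unique names.
#' @param weights Numeric vector of mass-percent weights, same length.
#' @return An object of class `mixture_spec`.
#' @examples
#' f1 <- formulation("slow", a = 70, b = 0.02)
#' f2 <- formulation("fast", a = 105, b = 0.3)
#' mixture_spec(list(f1, f2), c(50, 50))
#' @export
mixture_spec <- function(components, weights) {
  if (!is.list(components) || length(components) == 0L ||
      !all(vapply(components, inherits, logical(1), "formulation"))) {
    stop("components must be a non-empty list of formulation objects")
  }
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("component names must be unique: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  stopifnot(is.numeric(weights), length(weights) == length(components))
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and >= 0")
  }
  if (abs(sum(weights) - 100) > 1e-9) {
    stop("weights must sum to 100 (got ", format(sum(weights), digits = 15), ")")
  }
  structure(list(components = components, weights = as.numeric(weights)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  nm <- vapply(x$components, `[[`, character(1), "name")
  cat("Mixture:", paste(sprintf("%s %.4g%%", nm, x$weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict percent release from a mixture of formulations
#'
#' Weighted superposition of the component first-order curves:
#' \deqn{C_r(t) = \frac{\sum_n C_n a_n (1 - e^{-b_n t})}{\sum_n C_n},
#'   \qquad \sum_n C_n = 100,}
#' where \eqn{C_n} is the mass-percent weight of component `n`. The
#' prediction is a convex combination, so it lies between the pointwise
#' minimum and maximum of the component curves.
#'
#' @param mix A [mixture_spec] whose components are on the percent scale.
#' @param t Vector of times in hours, `>= 0`.
#' @return Numeric vector of percent released at each `t`.
#' @export
predict_mixture_percent <- function(mix, t) {
  stopifnot(inherits(mix, "mixture_spec"))
  scales <- vapply(mix$components, `[[`, character(1), "scale")
  if (!all(scales == "percent")) {
    stop("predict_mixture_percent needs all components on the percent scale")
  }
  B <- component_basis(mix$components, t)
  drop(B %*% (mix$weights / sum(mix$weights)))
}

#' Predict released drug mass (µg) from a mixture of formulations
#'
#' Mass-scale counterpart of the percent superposition rule. Each
#' component's own released mass at time `t` is computed for the full
#' blend mass — directly from its mass-scale parameters (which describe a
#' reference aliquot of that same total mass), or as
#' `total_mp_mass * loading * a/100 * (1 - e^(-b t))` from percent-scale
#' parameters — and the blend releases the mass-weighted average
#' \eqn{\sum_n (C_n/100)\, r_n(t)}. With equal aliquot masses this is
#' exactly the weighted mean of the per-formulation released amounts, the
#' arithmetic that links single-formulation and blend release tables.
#'
#' @param mix A [mixture_spec].
#' @param t Vector of times in hours.
#' @param total_mp_mass Total microparticle mass of the blend in mg;
#'   required when any component is percent-scale (its loading then
#'   converts percent to µg). Ignored for mass-scale components, whose `a`
#'   already refers to their reference aliquot.
#' @return Numeric vector of µg released at each `t`.
#' @examples
#' oil   <- formulation("CUR-oil",   a = 3491,  b = 0.02, scale = "mass_ug")
#' water <- formulation("CUR-water", a = 291.3, b = 0.50, scale = "mass_ug")
#' # equal-mass 50/50 blend at the 72 h plateau
#' predict_mixture_mass(mixture_spec(list(oil, water), c(50, 50)), t = 1e6)
#' @export
predict_mixture_mass <- function(mix, t, total_mp_mass = NULL) {
  stopifnot(inherits(mix, "mixture_spec"))
  per_comp <- vapply(mix$components, function(f) {
    r <- eval_first_order(f$params, t)
    if (f$scale == "mass_ug") return(r)
    if (is.null(f$loading)) {
      stop("component '", f$name,
           "' is percent-scale but has no loading (µg/mg); ",
           "mass prediction needs it")
    }
    if (is.null(total_mp_mass)) {
      stop("total_mp_mass (mg) is required for percent-scale components")
    }
    stopifnot(is.numeric(total_mp_mass), total_mp_mass > 0)
    total_mp_mass * f$loading * r / 100
  }, numeric(length(t)))
  per_comp <- matrix(per_comp, nrow = length(t))
  drop(per_comp %*% (mix$weights / 100))
}

# Basis matrix: column n is component n's first-order curve on `t`.
component_basis <- function(components, t) {
  vapply(components, function(f) eval_first_order(f$params, t),
         numeric(length(t)))
}

#' Design mixture weights for a target release profile
#'
#' Finds non-negative mass-percent weights summing to 100 that minimise
#' the sum of squared deviations between the mixture prediction and a
#' target curve. Because the superposition rule is linear in the weights,
#' this is simplex-constrained linear least squares: it is solved exactly
#' by enumerating candidate support sets and solving each
#' equality-constrained KKT system, keeping the feasible solution with the
#' smallest RSS (ties broken by the minimal Euclidean-norm weight vector).
#' The solution is deterministic for fixed inputs.
#'
#' @param components List of at least 2 [formulation] objects (percent
#'   scale) with unique names.
#' @param target A [release_curve] (percent scale) with at least 1 point.
#' @return A list with `mixture` (a [mixture_spec] carrying the designed
#'   weights), `weights` (named vector), `rss`, `fitted` (mixture
#'   prediction at the target times) and `degenerate` (`TRUE` when
#'   near-identical component curves make the weights non-unique; a
#'   warning is also raised).
#' @examples
#' f1 <- formulation("slow", a = 70, b = 0.02)
#' f2 <- formulation("fast", a = 105, b = 0.3)
#' tt <- c(1, 2, 4, 8, 24, 48, 72)
#' target <- release_curve(tt, predict_mixture_percent(
#'   mixture_spec(list(f1, f2), c(30, 70)), tt))
#' design_mixture(list(f1, f2), target)$weights
#' @export
design_mixture <- function(components, target) {
  if (!is.list(components) || length(components) < 2L) {
    stop("need at least 2 components to design a mixture")
  }
  stopifnot(inherits(target, "release_curve"))
  if (length(components) > 12L) {
    stop("exact simplex solver supports at most 12 components")
  }
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("component names must be unique")

  B <- component_basis(components, target$times)
  y <- target$values

  # degeneracy: two basis columns (curves) numerically identical
  degenerate <- FALSE
  n <- ncol(B)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (max(abs(B[, i] - B[, j])) <= 1e-8 * max(1, max(abs(B[, i])))) {
      degenerate <- TRUE
    }
  }
  if (degenerate) {
    warning("component release curves are (near-)identical: ",
            "designed weights are non-identifiable; returning the ",
            "minimal-norm solution")
  }

  sol <- simplex_lsq(B, y)
  weights <- 100 * sol$v
  # clean tiny negatives from numerics, renormalise exactly
  weights[weights < 0] <- 0
  weights <- 100 * weights / sum(weights)
  names(weights) <- nm
  mix <- mixture_spec(components, weights)
  fitted <- drop(B %*% (weights / 100))
  list(mixture = mix, weights = weights,
       rss = sum((y - fitted)^2), fitted = fitted,
       degenerate = degenerate)
}

# Exact simplex-constrained linear least squares:
#   min ||B v - y||^2  s.t.  v >= 0, sum(v) = 1.
# Enumerates every non-empty support S, solves the equality-constrained
# problem on S via its KKT system (pseudo-inverse, so rank-deficient
# supports yield the minimal-norm stationary point), keeps feasible
# candidates, and returns the best RSS with a minimal-norm tie-break.
# n is small (<= 12), so 2^n - 1 supports are cheap and the optimum's
# support is always among them.
simplex_lsq <- function(B, y) {
  n <- ncol(B)
  best <- NULL
  for (mask in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    k <- length(S)
    Bs <- B[, S, drop = FALSE]
    K <- rbind(cbind(2 * crossprod(Bs), rep(1, k)),
               c(rep(1, k), 0))
    rhs <- c(2 * crossprod(Bs, y), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      drop(MASS::ginv(K) %*% rhs)
    })
    vs <- sol[seq_len(k)]
    if (any(vs < -1e-9)) next
    vs[vs < 0] <- 0
    vs <- vs / sum(vs)
    v <- numeric(n)
    v[S] <- vs
    rss <- sum((drop(B %*% v) - y)^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && sum(v^2) < best$norm2 - 1e-12)) {
      best <- list(v = v, rss = rss, norm2 = sum(v^2))
    }
  }
  best
}
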