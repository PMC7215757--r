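#' Measurement-noise model for synthetic release curves
#'
#' @param kind `"none"`, `"additive_gaussian"` (sd `sigma` on the curve's
#'   scale) or `"proportional_gaussian"` (sd `sigma` as a fraction of the
#'   noiseless value). The default for study-like data is proportional
#'   Gaussian at `sigma = 0.05`, matching the relative spread typical of
#'   triplicate UV–vis release measurements.
#' @param sigma Noise scale, `>= 0`.
#' @param seed Integer seed; generation is a pure function of
#'   (inputs, seed).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "additive_gaussian",
                                 "proportional_gaussian"),
                        sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (kind == "none" && sigma != 0) sigma <- 0
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# Default sampling schedule of a 72 h release study: dense early points to
# capture the burst phase, sparse late points on the plateau.
default_release_times <- function() c(1, 2, 4, 8, 24, 48, 72)

#' Generate a synthetic release curve with known ground truth
#'
#' Evaluates the first-order model on a sampling schedule and adds
#' measurement noise per a [noise_model]. Output is clamped at 0 (and a
#' `t = 0` point, if present, stays exactly 0). Deterministic for a fixed
#' seed.
#'
#' @param params [first_order_params] generating the curve.
#' @param times Sampling times in hours, strictly increasing; default
#'   `c(1, 2, 4, 8, 24, 48, 72)`.
#' @param noise A [noise_model]; default noiseless.
#' @param scale Scale tag for the produced [release_curve].
#' @param label Curve label.
#' @return A [release_curve].
#' @export
generate_release_curve <- function(params, times = default_release_times(),
                                   noise = noise_model("none"),
                                   scale = c("percent", "mass_ug"),
                                   label = "synthetic") {
  params <- as_first_order_params(params)
  scale <- match.arg(scale)
  stopifnot(inherits(noise, "noise_model"))
  y <- eval_first_order(params, times)
  if (noise$kind != "none" && noise$sigma > 0) {
    y <- withr::with_seed(noise$seed, {
      eps <- stats::rnorm(length(y))
      switch(noise$kind,
             additive_gaussian = y + noise$sigma * eps,
             proportional_gaussian = y * (1 + noise$sigma * eps))
    })
    y <- pmax(y, 0)
    y[times == 0] <- 0
  }
  release_curve(times, y, scale = scale, label = label)
}

#' Generate a reproducible set of synthetic formulations
#'
#' Draws `n` formulations with first-order parameters uniform in the given
#' ranges. The default ranges bracket the two release regimes seen in
#' porous-microparticle studies: slow sustained components (low plateau,
#' small rate constant) up to fast burst-type components (plateau near or
#' slightly above 100 %, large rate constant), so that blends show
#' intermediate profiles.
#'
#' @param n Number of formulations, `>= 1`.
#' @param a_range Range of the asymptote `a` (percent), default
#'   `c(60, 110)`.
#' @param b_range Range of the rate constant `b` (1/h), default
#'   `c(0.01, 0.5)`.
#' @param loading_range Range of drug loading (µg/mg), default
#'   `c(5, 60)`.
#' @param seed Integer seed.
#' @return List of [formulation] objects named `F1 ... Fn`.
#' @export
generate_formulation_set <- function(n, a_range = c(60, 110),
                                     b_range = c(0.01, 0.5),
                                     loading_range = c(5, 60),
                                     seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  check_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        r[1] > r[2] || r[1] <= 0) {
      stop("invalid ", nm, ": need finite positive c(lo, hi) with lo <= hi")
    }
  }
  check_range(a_range, "a_range")
  check_range(b_range, "b_range")
  check_range(loading_range, "loading_range")
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      formulation(paste0("F", i),
                  a = stats::runif(1, a_range[1], a_range[2]),
                  b = stats::runif(1, b_range[1], b_range[2]),
                  loading = stats::runif(1, loading_range[1],
                                         loading_range[2]))
    })
  })
}

#' Forward-simulate a withdrawal sampling protocol
#'
#' Simulates the release study an instrument would see: drug dissolves
#' into the vessel following a mass-scale first-order curve, medium is
#' withdrawn (and optionally replaced) on a schedule, and the absorbance
#' of the (diluted) supernatant is emitted at each sampling. The true
#' cumulative dissolved mass is returned alongside, providing the ground
#' truth that withdrawal-corrected bookkeeping must reconstruct.
#'
#' @param params [first_order_params] on the µg scale (cumulative
#'   dissolved mass of the aliquot).
#' @param times Sampling schedule in hours, strictly increasing, `> 0`.
#' @param proto An [optical_protocol].
#' @param initial_volume_ml Vessel volume, mL (default 1.5).
#' @param withdrawn_ml Volume withdrawn at each sampling, mL (recycled;
#'   default 1).
#' @param replaced Whether withdrawals are replaced with fresh medium
#'   (recycled; default `TRUE`).
#' @return A list: `events` ([sampling_events]), `truth` (data frame
#'   `time_h`, `dissolved_ug` — cumulative mass that left the particles).
#' @export
simulate_sampling_protocol <- function(params, times = default_release_times(),
                                       proto, initial_volume_ml = 1.5,
                                       withdrawn_ml = 1, replaced = TRUE) {
  params <- as_first_order_params(params)
  stopifnot(inherits(proto, "optical_protocol"))
  if (any(diff(times) <= 0) || any(times <= 0)) {
    stop("sampling times must be strictly increasing and > 0")
  }
  n <- length(times)
  withdrawn_ml <- rep_len(withdrawn_ml, n)
  replaced <- rep_len(as.logical(replaced), n)

  dissolved <- eval_first_order(params, times)  # cumulative µg
  V <- initial_volume_ml
  vessel_ug <- 0
  prev_dissolved <- 0
  absorb <- numeric(n)
  for (k in seq_len(n)) {
    vessel_ug <- vessel_ug + (dissolved[k] - prev_dissolved)
    prev_dissolved <- dissolved[k]
    if (withdrawn_ml[k] > V + 1e-12) {
      stop("infeasible withdrawal at t = ", times[k], " h: ",
           withdrawn_ml[k], " mL from ", signif(V, 6), " mL")
    }
    conc <- (vessel_ug * 1e-6 / proto$mw) / (V / 1000)  # mol/dm3
    absorb[k] <- conc * proto$epsilon * proto$path_cm / proto$dilution
    vessel_ug <- vessel_ug * (1 - withdrawn_ml[k] / V)
    if (!replaced[k]) V <- V - withdrawn_ml[k]
  }
  list(events = sampling_events(times, absorb, withdrawn_ml, replaced),
       truth = data.frame(time_h = times, dissolved_ug = dissolved))
}
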