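#' UV–vis quantification protocol
#'
#' Parameters of the Beer–Lambert quantification step: molar extinction
#' coefficient of the analyte in the measurement solvent, cuvette path
#' length, any dilution applied to the withdrawn supernatant before
#' reading (e.g. 2 for a 1:1 dilution in ethanol), and the analyte's
#' molecular weight for molar-to-mass conversion.
#'
#' @param epsilon Molar extinction coefficient in dm³·mol⁻¹·cm⁻¹, `> 0`.
#'   For curcumin: 58,547 in DMSO (encapsulation assays), 28,648 in
#'   PBS/ethanol (release assays).
#' @param path_cm Optical path length in cm, `> 0` (default 1).
#' @param dilution Dilution factor applied before the absorbance reading,
#'   `>= 1` (default 1; 2 for a 1:1 dilution).
#' @param mw Molecular weight of the analyte in g·mol⁻¹ (curcumin:
#'   368.38).
#' @return An object of class `optical_protocol`.
#' @export
optical_protocol <- function(epsilon, path_cm = 1, dilution = 1, mw) {
  stopifnot(is.numeric(epsilon), is.numeric(path_cm), is.numeric(dilution),
            is.numeric(mw))
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (path_cm <= 0) stop("path_cm must be > 0")
  if (dilution < 1) stop("dilution factor must be >= 1")
  if (mw <= 0) stop("mw must be > 0")
  structure(list(epsilon = epsilon, path_cm = path_cm,
                 dilution = dilution, mw = mw),
            class = "optical_protocol")
}

#' Absorbance to molar concentration in the vessel
#'
#' Inverts the Beer–Lambert law \eqn{A = \epsilon c l} for the read
#' sample and undoes the dilution, returning the molar concentration in
#' the release vessel: `A * dilution / (epsilon * path_cm)`.
#'
#' @param A Absorbance (AU), `>= 0`; vectorised.
#' @param proto An [optical_protocol].
#' @return Molar concentration(s) in mol/dm³.
#' @export
absorbance_to_concentration <- function(A, proto) {
  stopifnot(inherits(proto, "optical_protocol"), is.numeric(A))
  if (any(!is.finite(A)) || any(A < 0)) stop("absorbance must be finite and >= 0")
  A * proto$dilution / (proto$epsilon * proto$path_cm)
}

#' Molar concentration and volume to drug mass
#'
#' `c (mol/L) * volume (L) * mw (g/mol)`, reported in µg:
#' `c * (volume_ml / 1000) * mw * 1e6`.
#'
#' @param c Molar concentration, `>= 0`; vectorised.
#' @param volume_ml Volume in mL, `> 0`.
#' @param mw Molecular weight in g·mol⁻¹.
#' @return Mass in µg.
#' @export
concentration_to_mass <- function(c, volume_ml, mw) {
  stopifnot(is.numeric(c), is.numeric(volume_ml), is.numeric(mw))
  if (any(c < 0)) stop("concentration must be >= 0")
  if (any(volume_ml <= 0)) stop("volume must be > 0")
  c * (volume_ml / 1000) * mw * 1e6
}

#' Encapsulation efficiency
#'
#' Percent of the drug offered during fabrication that is recovered from
#' the particles: `100 * measured / theoretical`. Values slightly above
#' 100 can occur through measurement error and are reported untruncated.
#'
#' @param measured_ug Drug recovered from the particles, µg, `>= 0`.
#' @param theoretical_ug Drug offered during fabrication, µg, `> 0`.
#' @return Encapsulation efficiency in percent.
#' @export
encapsulation_efficiency <- function(measured_ug, theoretical_ug) {
  stopifnot(is.numeric(measured_ug), is.numeric(theoretical_ug))
  if (any(theoretical_ug <= 0)) stop("theoretical drug amount must be > 0")
  if (any(measured_ug < 0)) stop("measured drug amount must be >= 0")
  100 * measured_ug / theoretical_ug
}

#' Sampling events of a release study
#'
#' The time-ordered record of a release experiment: at each sampling time
#' an absorbance is read on the (possibly diluted) supernatant and a
#' volume of medium is withdrawn, optionally replaced with fresh medium.
#'
#' @param time_h Sampling times in hours, strictly increasing.
#' @param absorbance Absorbance readings (AU). Readings below
#'   `blank_threshold` are clamped to 0 with a warning (blank-level
#'   noise).
#' @param withdrawn_ml Volume withdrawn at each sampling, mL, `>= 0`.
#' @param replaced Logical (recycled): whether the withdrawn volume was
#'   replaced with fresh medium. Default `TRUE`, the only mode that keeps
#'   a small vessel viable over repeated large withdrawals.
#' @param blank_threshold Absorbance below which a reading is treated as
#'   blank (default 0, i.e. only negative readings would be clamped —
#'   which are rejected anyway).
#' @return An object of class `sampling_events` (a data frame with
#'   columns `time_h`, `absorbance`, `withdrawn_ml`, `replaced`).
#' @export
sampling_events <- function(time_h, absorbance, withdrawn_ml,
                            replaced = TRUE, blank_threshold = 0) {
  stopifnot(is.numeric(time_h), is.numeric(absorbance),
            is.numeric(withdrawn_ml))
  n <- length(time_h)
  if (length(absorbance) != n) {
    stop("time_h and absorbance must have equal length")
  }
  withdrawn_ml <- rep_len(withdrawn_ml, n)
  if (any(diff(time_h) <= 0)) stop("sampling times must be strictly increasing")
  if (any(absorbance < 0)) stop("absorbance must be >= 0")
  if (any(withdrawn_ml < 0)) stop("withdrawn volume must be >= 0")
  clamp <- absorbance < blank_threshold
  if (any(clamp)) {
    warning(sum(clamp), " absorbance reading(s) below the blank threshold ",
            blank_threshold, " clamped to 0")
    absorbance[clamp] <- 0
  }
  replaced <- rep_len(as.logical(replaced), n)
  structure(data.frame(time_h = time_h, absorbance = absorbance,
                       withdrawn_ml = withdrawn_ml, replaced = replaced),
            class = c("sampling_events", "data.frame"))
}

#' Withdrawal-corrected cumulative release
#'
#' Assembles a cumulative release curve (µg) from raw sampling events by
#' mass balance. At sampling `k` with vessel volume \eqn{V_k} and vessel
#' concentration \eqn{c_k} (from [absorbance_to_concentration()]), the
#' cumulative mass released is
#' \deqn{M_k = V_k c_k\,\mathrm{mw} + \sum_{i<k} w_i c_i\,\mathrm{mw},}
#' i.e. what is in the vessel now plus everything carried away by earlier
#' withdrawals \eqn{w_i}. With replacement the vessel volume stays at
#' `initial_volume_ml`; without it the volume shrinks by each withdrawal.
#'
#' @param events A [sampling_events] object.
#' @param initial_volume_ml Vessel volume at the start, mL.
#' @param proto An [optical_protocol].
#' @return A [release_curve] on the `"mass_ug"` scale.
#' @export
cumulative_release <- function(events, initial_volume_ml, proto) {
  stopifnot(inherits(events, "sampling_events"),
            inherits(proto, "optical_protocol"),
            is.numeric(initial_volume_ml), initial_volume_ml > 0)
  n <- nrow(events)
  conc <- absorbance_to_concentration(events$absorbance, proto)
  V <- initial_volume_ml
  removed_ug <- 0
  cum <- numeric(n)
  for (k in seq_len(n)) {
    w <- events$withdrawn_ml[k]
    if (w > V + 1e-12) {
      stop("protocol error at t = ", events$time_h[k], " h: withdrawal of ",
           w, " mL exceeds vessel volume ", signif(V, 6), " mL")
    }
    cum[k] <- concentration_to_mass(conc[k], V, proto$mw) + removed_ug
    removed_ug <- removed_ug + concentration_to_mass(conc[k], w, proto$mw)
    if (!events$replaced[k]) V <- V - w
  }
  release_curve(events$time_h, pmax(cum, 0), scale = "mass_ug",
                label = "cumulative release (withdrawal-corrected)")
}
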