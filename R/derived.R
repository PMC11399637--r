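# Secondary PK parameters and TMP:sulfonamide ratio arithmetic.

#' Elimination half-life
#'
#' `T1/2 = ln(2) * Vd / CL` for the one-compartment model. Units follow
#' the inputs (h when Vd in L and CL in L/h, or per-kg values for both).
#'
#' @param p a [structural_params()] object (or list with `Vd`, `CL`).
#' @return Half-life (h).
#' @export
half_life <- function(p) {
  stop_if_not_positive(c(p$Vd, p$CL), "Vd/CL")
  log(2) * p$Vd / p$CL
}

#' Area under the curve to infinity
#'
#' Under linear kinetics: `dose / CL` after IV, `F * dose / CL` after
#' oral dosing.
#'
#' @param p a [structural_params()] object.
#' @param dose dose (mg, or mg/kg with per-kg `CL`).
#' @param route `"IV"` or `"ORAL"`.
#' @return AUC0-inf (h.ug/mL).
#' @export
auc_inf <- function(p, dose, route = c("IV", "ORAL")) {
  route <- match.arg(route)
  stop_if_not_positive(dose, "dose")
  if (route == "IV") dose / p$CL else p$F * dose / p$CL
}

#' Plasma protein binding specification
#'
#' Bound fractions used to convert total to unbound (free)
#' concentrations, assumed linear over the concentration range. Defaults:
#' SDZ 80% and TMP 77% bound (broiler label values); SMX 62% bound
#' (borrowed from cattle/sheep, no broiler value is available, so keep it
#' configurable).
#'
#' @param bound named vector of bound fractions in `[0, 1)` per drug.
#' @return Object of class `binding_spec`.
#' @export
binding_spec <- function(bound = c(SDZ = 0.80, SMX = 0.62, TMP = 0.77)) {
  if (any(bound < 0 | bound >= 1)) stop("bound fractions must lie in [0, 1)", call. = FALSE)
  structure(list(bound = bound), class = "binding_spec")
}

#' Unbound (free) concentration
#'
#' `c_free = c_total * (1 - bound_fraction)`; only the free fraction is
#' considered microbiologically active.
#'
#' @param conc total concentration(s), `>= 0`.
#' @param spec a [binding_spec()].
#' @param drug drug code.
#' @return Free concentration(s).
#' @export
unbound <- function(conc, spec = binding_spec(), drug) {
  if (any(conc < 0)) stop("'conc' must be >= 0", call. = FALSE)
  fb <- spec$bound[[drug]]
  if (is.null(fb)) stop("no binding value for drug '", drug, "'", call. = FALSE)
  conc * (1 - fb)
}

#' Unbound TMP:sulfonamide ratio trajectory and 1:19 target attainment
#'
#' Computes the elementwise free-TMP / free-sulfonamide ratio on a common
#' time grid, whether the synergy target ratio (default 1/19) is ever
#' reached, and the total duration above target (linear interpolation of
#' threshold crossings between grid points). Points where the sulfonamide
#' concentration is zero are masked (`NA`).
#'
#' @param tmp_curve,s_curve total concentrations on a common time grid.
#' @param times the time grid (h).
#' @param spec a [binding_spec()].
#' @param s_drug sulfonamide code (`"SDZ"` or `"SMX"`).
#' @param target target free ratio (default `1/19`).
#' @return List with `times`, `ratio` (free TMP:S), `attained` (logical),
#'   `duration_h` above target and `n_masked`.
#' @export
ratio_trajectory <- function(tmp_curve, s_curve, times, spec = binding_spec(),
                             s_drug = "SDZ", target = 1 / 19) {
  stopifnot(length(tmp_curve) == length(s_curve),
            length(times) == length(s_curve))
  ft <- unbound(tmp_curve, spec, "TMP")
  fs <- unbound(s_curve, spec, s_drug)
  ratio <- ifelse(fs > 0, ft / fs, NA_real_)
  above <- !is.na(ratio) & ratio >= target
  dur <- 0
  if (any(above)) {
    r <- ifelse(is.na(ratio), -Inf, ratio)
    for (i in seq_len(length(times) - 1)) {
      a <- r[i] >= target
      bb <- r[i + 1] >= target
      h <- times[i + 1] - times[i]
      if (a && bb) {
        dur <- dur + h
      } else if (a != bb && is.finite(r[i]) && is.finite(r[i + 1])) {
        frac <- (target - r[i]) / (r[i + 1] - r[i])
        dur <- dur + if (a) frac * h else (1 - frac) * h
      }
    }
  }
  list(times = times, ratio = ratio, attained = any(above),
       duration_h = dur, n_masked = sum(is.na(ratio)))
}

#' Dose from administered volume and formulation strength
#'
#' `mg/kg = (mL/kg) * (mg/mL)`; exact product, rounding only for display.
#'
#' @param volume administered volume (mL/kg).
#' @param concentration formulation strength (mg/mL).
#' @return Dose (mg/kg).
#' @export
dose_from_volume <- function(volume, concentration) {
  stop_if_not_positive(c(volume, concentration), "volume/concentration")
  volume * concentration
}
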