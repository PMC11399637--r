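# Closed-form concentration-time solutions for the structural models.
# All arithmetic is in absolute units: dose mg, Vd L, CL L/h, conc ug/mL
# (mg/L). Time is hours since the dose event.

# relative tolerance below which the oral solution switches to its
# ka -> ke analytic limit. The Bateman difference of exponentials is
# evaluated via expm1, which is numerically stable arbitrarily close to
# the flip-flop degeneracy, so the switch only needs to catch the exact
# ka == ke case; continuity across it holds to well under 1e-8 relative.
KA_KE_REL_TOL <- 1e-12

#' One-compartment IV bolus concentration
#'
#' `C(t) = (dose / Vd) * exp(-(CL / Vd) * t)`.
#'
#' @param p a [structural_params()] object (absolute units).
#' @param dose dose amount (mg).
#' @param t time since the dose (h), vectorized, `>= 0`.
#' @return Concentration (ug/mL) at each `t`.
#' @export
conc_iv_1cmt <- function(p, dose, t) {
  stop_if_not_positive(dose, "dose")
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  (dose / p$Vd) * exp(-(p$CL / p$Vd) * t)
}

#' One-compartment first-order oral concentration (Bateman)
#'
#' `C(t) = F * dose * ka / (Vd * (ka - ke)) * (exp(-ke t) - exp(-ka t))`
#' with `ke = CL / Vd`, evaluated through `expm1` so it stays accurate
#' arbitrarily close to the flip-flop degeneracy. When
#' `|ka - ke| / ke < 1e-12` the analytic limit
#' `C(t) = F * dose * ka * t * exp(-ka t) / Vd` is used; the two branches
#' agree to better than 1e-8 relative at the switch.
#'
#' @inheritParams conc_iv_1cmt
#' @return Concentration (ug/mL) at each `t`.
#' @export
conc_oral_1cmt <- function(p, dose, t) {
  stop_if_not_positive(dose, "dose")
  stop_if_not_positive(p$ka, "ka")
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  ke <- p$CL / p$Vd
  if (abs(p$ka - ke) / ke < KA_KE_REL_TOL) {
    p$F * dose * p$ka * t * exp(-p$ka * t) / p$Vd
  } else {
    # exp(-ke t) - exp(-ka t) = exp(-min(ka,ke) t) * (-expm1(-|ka-ke| t))
    # / sign, stable for either ordering of ka and ke
    d <- abs(p$ka - ke)
    p$F * dose * p$ka / (p$Vd * d) *
      (exp(-min(p$ka, ke) * t) * (-expm1(-d * t)))
  }
}

#' Two-compartment IV bolus concentration (comparator model)
#'
#' Standard bi-exponential disposition used only for structural model
#' comparison: central volume `V1`, clearance `CL`, inter-compartmental
#' clearance `Q` and peripheral volume `V2` (all absolute).
#'
#' @param p2 list with elements `V1` (L), `CL` (L/h), `Q` (L/h), `V2` (L).
#' @inheritParams conc_iv_1cmt
#' @return Concentration (ug/mL) at each `t`.
#' @export
conc_iv_2cmt <- function(p2, dose, t) {
  stop_if_not_positive(c(p2$V1, p2$CL, p2$V2), "V1/CL/V2")
  if (p2$Q < 0) stop("'Q' must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  k10 <- p2$CL / p2$V1
  k12 <- p2$Q / p2$V1
  k21 <- p2$Q / p2$V2
  s <- k10 + k12 + k21
  root <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  if (alpha - beta < 1e-12) { # degenerate: behaves as one compartment
    return(dose / p2$V1 * exp(-k10 * t))
  }
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  dose / p2$V1 * (A * exp(-alpha * t) + B * exp(-beta * t))
}

#' Superpose dose events under linear kinetics
#'
#' Sums single-dose contributions of a series of dose events (IV bolus or
#' first-order oral) for one subject. With a single event this equals the
#' corresponding single-dose function.
#'
#' @param events data frame with columns `time` (h), `amount` (mg) and
#'   `route` (`"IV"` or `"ORAL"`), sorted by time.
#' @param p a [structural_params()] object (absolute units).
#' @param times numeric vector of absolute times (h).
#' @return Concentration vector (ug/mL) at `times`.
#' @export
superpose <- function(events, p, times) {
  stopifnot(all(c("time", "amount", "route") %in% names(events)))
  if (is.unsorted(events$time)) stop("'events' must be sorted by time", call. = FALSE)
  if (!all(events$route %in% c("IV", "ORAL"))) {
    stop("'route' must be IV or ORAL", call. = FALSE)
  }
  conc <- numeric(length(times))
  for (e in seq_len(nrow(events))) {
    dt <- times - events$time[e]
    on <- dt >= 0
    if (!any(on)) next
    ce <- if (events$route[e] == "IV") {
      conc_iv_1cmt(p, events$amount[e], dt[on])
    } else {
      conc_oral_1cmt(p, events$amount[e], dt[on])
    }
    conc[on] <- conc[on] + ce
  }
  conc
}
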