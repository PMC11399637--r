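# Hierarchical layer: population parameters + covariates + correlated
# random effects -> per-subject structural parameters.
#
# Model, per structural parameter H of subject i:
#   log(H_i) = log(H_pop) + beta_sexM * 1[sex = M]
#            + beta_BW * log(BW_i / bw_median) + eta_Hi
# with eta ~ MVN(0, D corr D), D = diag(omega). Bioavailability F is
# logit-normal when it carries a random effect, else fixed at F_pop.

#' Subject descriptor
#'
#' @param subject_id identifier.
#' @param body_weight body weight (kg), in (0.3, 5) for broilers.
#' @param sex `"M"` or `"F"`.
#' @param cohort `"TMP_SDZ"` or `"TMP_SMX"`.
#' @return An object of class `subject`.
#' @export
subject <- function(subject_id, body_weight, sex = c("M", "F"),
                    cohort = c("TMP_SDZ", "TMP_SMX")) {
  sex <- match.arg(sex)
  cohort <- match.arg(cohort)
  if (!is.finite(body_weight) || body_weight < 0.3 || body_weight > 5) {
    stop("'body_weight' outside the plausible broiler range (0.3-5 kg)", call. = FALSE)
  }
  structure(list(subject_id = subject_id, body_weight = body_weight,
                 sex = sex, cohort = cohort), class = "subject")
}

#' Covariate multiplier for one structural parameter
#'
#' The multiplicative factor `exp(beta_SEXM * 1[sex = M] +
#' beta_BW * log(BW / bw_median))` applied to the typical value. Equals 1
#' when no covariate coefficient is retained for the parameter.
#'
#' @param pop a [pop_params()] object.
#' @param drug `"SDZ"`, `"SMX"` or `"TMP"`.
#' @param param `"ka"`, `"Vd"` or `"CL"`.
#' @param subj a [subject()] object (or any list with `body_weight`, `sex`).
#' @return Unitless multiplier.
#' @export
covariate_multiplier <- function(pop, drug, param, subj) {
  if (!param %in% c("ka", "Vd", "CL")) {
    stop("unknown parameter '", param, "'", call. = FALSE)
  }
  dp <- pop$drugs[[drug]]
  if (is.null(dp)) stop("no parameters for drug '", drug, "'", call. = FALSE)
  lp <- 0
  b_bw <- dp$beta[paste0(param, "_BW")]
  if (!is.na(b_bw)) lp <- lp + b_bw * log(subj$body_weight / pop$bw_median)
  b_sx <- dp$beta[paste0(param, "_SEXM")]
  if (!is.na(b_sx) && identical(subj$sex, "M")) lp <- lp + b_sx
  unname(exp(lp))
}

#' Sample correlated random effects
#'
#' Draws `n` rows from a zero-mean multivariate normal with covariance
#' `D %*% corr %*% D`, `D = diag(omega)`, in the parameter order ka, Vd, CL.
#'
#' @inheritParams covariate_multiplier
#' @param n number of subjects to draw.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param corr_threshold absolute correlation below or at which off-diagonal
#'   entries are zeroed before sampling (retention rule used for
#'   simulation); `0` keeps the full matrix.
#' @return `n x 3` matrix of random effects with columns ka, Vd, CL.
#' @export
sample_etas <- function(pop, drug, n, seed = NULL, corr_threshold = 0) {
  dp <- pop$drugs[[drug]]
  if (is.null(dp)) stop("no parameters for drug '", drug, "'", call. = FALSE)
  corr <- dp$corr
  if (corr_threshold > 0) {
    off <- abs(corr) <= corr_threshold & row(corr) != col(corr)
    corr[off] <- 0
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semidefinite", call. = FALSE)
  D <- diag(dp$omega, 3)
  sigma <- D %*% corr %*% D
  eta <- with_seed(seed, {
    if (all(dp$omega == 0)) matrix(0, n, 3) else MASS::mvrnorm(n, mu = rep(0, 3), Sigma = sigma)
  })
  eta <- matrix(eta, nrow = n, ncol = 3)
  colnames(eta) <- c("ka", "Vd", "CL")
  eta
}

#' Realized individual parameters
#'
#' Applies the covariate model and a realized random-effect vector to the
#' typical values and scales per-kg volume and clearance by body weight,
#' returning absolute-unit structural parameters. `F` is transformed
#' through the logit scale when an `F` random effect is supplied
#' (`eta["F"]`), otherwise fixed at `F_pop`.
#'
#' @inheritParams covariate_multiplier
#' @param eta named numeric vector with elements `ka`, `Vd`, `CL` (and
#'   optionally `F`).
#' @return A [structural_params()] object carrying the realized `eta` as
#'   attribute `"eta"`.
#' @export
individual_params <- function(pop, drug, subj, eta = c(ka = 0, Vd = 0, CL = 0)) {
  dp <- pop$drugs[[drug]]
  if (is.null(dp)) stop("no parameters for drug '", drug, "'", call. = FALSE)
  ka_i <- dp$ka_pop * covariate_multiplier(pop, drug, "ka", subj) * exp(eta[["ka"]])
  vd_i <- dp$Vd_pop * covariate_multiplier(pop, drug, "Vd", subj) * exp(eta[["Vd"]])
  cl_i <- dp$CL_pop * covariate_multiplier(pop, drug, "CL", subj) * exp(eta[["CL"]])
  F_i <- if ("F" %in% names(eta)) inv_logit(logit(dp$F_pop) + eta[["F"]]) else dp$F_pop
  out <- structural_params(F = F_i, ka = ka_i,
                           Vd = vd_i * subj$body_weight,
                           CL = cl_i * subj$body_weight)
  attr(out, "eta") <- eta
  attr(out, "per_kg") <- c(Vd = vd_i, CL = cl_i)
  out
}
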