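#' Structural PK parameters for one subject and one drug
#'
#' Absolute-unit parameters of the one-compartment model: bioavailability
#' `F` (fraction), absorption rate `ka` (1/h), volume of distribution `Vd`
#' (L) and clearance `CL` (L/h). Per-kilogram population values are scaled
#' by body weight before a `structural_params` object is built, so all
#' downstream arithmetic is in mg, L and L/h.
#'
#' @param F bioavailability fraction in (0, 1].
#' @param ka first-order absorption rate constant (1/h); may be `NA` for
#'   IV-only use.
#' @param Vd volume of distribution (L), strictly positive.
#' @param CL clearance (L/h), strictly positive.
#' @return An object of class `structural_params`.
#' @examples
#' p <- structural_params(F = 0.99, ka = 0.59, Vd = 3.14 * 2, CL = 1.53 * 2)
#' conc_iv_1cmt(p, dose = 12.8, t = c(0, 1, 2))
#' @export
structural_params <- function(F = 1, ka = NA_real_, Vd, CL) {
  stop_if_not_positive(Vd, "Vd")
  stop_if_not_positive(CL, "CL")
  if (!is.na(ka)) stop_if_not_positive(ka, "ka")
  if (!is.finite(F) || F <= 0 || F > 1) stop("'F' must lie in (0, 1]", call. = FALSE)
  structure(list(F = F, ka = ka, Vd = Vd, CL = CL), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("structural_params: F=%.3g ka=%.3g /h Vd=%.3g L CL=%.3g L/h (t1/2=%.3g h)\n",
              x$F, x$ka, x$Vd, x$CL, log(2) * x$Vd / x$CL))
  invisible(x)
}

#' Per-drug population parameters
#'
#' One drug's fixed effects (typical values on the per-kg scale), retained
#' covariate coefficients, random-effect standard deviations, the
#' random-effect correlation matrix and the proportional residual error SD.
#'
#' @param F_pop typical bioavailability fraction.
#' @param ka_pop typical absorption rate (1/h).
#' @param Vd_pop typical volume of distribution (L/kg).
#' @param CL_pop typical clearance (L/h/kg).
#' @param beta named numeric vector of retained covariate coefficients.
#'   Names follow `"<param>_BW"` (coefficient on `log(BW / bw_median)`) or
#'   `"<param>_SEXM"` (additive log-scale shift for males), with `<param>`
#'   one of `ka`, `Vd`, `CL`.
#' @param omega named numeric vector `c(ka=, Vd=, CL=)` of log-scale
#'   random-effect SDs (all `>= 0`).
#' @param corr 3x3 correlation matrix of the random effects, in the order
#'   ka, Vd, CL. Defaults to the identity.
#' @param b proportional residual error SD (unitless, `> 0`).
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(F_pop, ka_pop, Vd_pop, CL_pop, beta = numeric(0),
                        omega = c(ka = 0, Vd = 0, CL = 0), corr = diag(3), b) {
  stop_if_not_positive(c(ka_pop, Vd_pop, CL_pop, b), "ka_pop/Vd_pop/CL_pop/b")
  if (F_pop <= 0 || F_pop > 1) stop("'F_pop' must lie in (0, 1]", call. = FALSE)
  omega <- omega[c("ka", "Vd", "CL")]
  if (anyNA(omega) || any(omega < 0)) {
    stop("'omega' must provide nonnegative entries named ka, Vd, CL", call. = FALSE)
  }
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr))) || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("'corr' must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("'corr' must be positive semidefinite", call. = FALSE)
  }
  if (length(beta)) {
    ok <- grepl("^(ka|Vd|CL)_(BW|SEXM)$", names(beta))
    if (!all(ok)) stop("unknown beta name(s): ", paste(names(beta)[!ok], collapse = ", "),
                       call. = FALSE)
  }
  dimnames(corr) <- list(c("ka", "Vd", "CL"), c("ka", "Vd", "CL"))
  structure(list(F_pop = F_pop, ka_pop = ka_pop, Vd_pop = Vd_pop, CL_pop = CL_pop,
                 beta = beta, omega = omega, corr = corr, b = b),
            class = "drug_params")
}

#' Population parameter set for the drug combination models
#'
#' Bundles per-drug parameters with the body-weight normalization constant
#' used by the covariate model (all covariate effects act on
#' `log(BW / bw_median)`).
#'
#' @param drugs named list of [drug_params()] objects; names from
#'   `c("SDZ", "SMX", "TMP")`.
#' @param bw_median body-weight normalization constant (kg).
#' @return An object of class `pop_params`.
#' @seealso [boulanger2024()] for the built-in broiler estimate set.
#' @export
pop_params <- function(drugs, bw_median = 1.91) {
  stop_if_not_positive(bw_median, "bw_median")
  if (!length(names(drugs)) || !all(names(drugs) %in% c("SDZ", "SMX", "TMP"))) {
    stop("'drugs' must be a named list with names among SDZ, SMX, TMP", call. = FALSE)
  }
  ok <- vapply(drugs, inherits, logical(1), "drug_params")
  if (!all(ok)) stop("every element of 'drugs' must be a drug_params object", call. = FALSE)
  structure(list(drugs = drugs, bw_median = bw_median), class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat(sprintf("pop_params (BW median %.2f kg)\n", x$bw_median))
  for (d in names(x$drugs)) {
    p <- x$drugs[[d]]
    cat(sprintf("  %s: F=%.2f ka=%.2f/h Vd=%.2f L/kg CL=%.2f L/h/kg b=%.2f | omega ka/Vd/CL = %.2f/%.2f/%.2f",
                d, p$F_pop, p$ka_pop, p$Vd_pop, p$CL_pop, p$b,
                p$omega["ka"], p$omega["Vd"], p$omega["CL"]))
    if (length(p$beta)) cat(" | beta:", paste(names(p$beta), sprintf("%.2f", p$beta), collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' Published broiler parameter set
#'
#' The estimated population parameters for sulfadiazine (SDZ),
#' sulfamethoxazole (SMX) and trimethoprim (TMP) in 3-4 week old broilers:
#' typical values, the retained body-weight coefficients (heavier birds
#' have larger sulfonamide distribution volumes and larger SDZ/TMP
#' clearance), lognormal inter-individual SDs and proportional residual
#' error. No sex effect was retained. Off-diagonal random-effect
#' correlations default to zero because the estimated correlation matrix
#' is not part of the published main-text table; supply `corr` per drug to
#' override when such values are available.
#'
#' @return A [pop_params()] object.
#' @examples
#' pop <- boulanger2024()
#' pop$drugs$TMP$CL_pop # 1.53 L/h/kg
#' @export
boulanger2024 <- function() {
  pop_params(
    drugs = list(
      SDZ = drug_params(F_pop = 0.99, ka_pop = 0.71, Vd_pop = 0.51, CL_pop = 0.15,
                        beta = c(Vd_BW = 0.65, CL_BW = 0.42),
                        omega = c(ka = 0.93, Vd = 0.30, CL = 0.25), b = 0.33),
      SMX = drug_params(F_pop = 0.99, ka_pop = 0.59, Vd_pop = 0.62, CL_pop = 0.15,
                        beta = c(Vd_BW = 0.36),
                        omega = c(ka = 0.63, Vd = 0.24, CL = 0.23), b = 0.36),
      TMP = drug_params(F_pop = 0.99, ka_pop = 0.59, Vd_pop = 3.14, CL_pop = 1.53,
                        beta = c(CL_BW = 0.42),
                        omega = c(ka = 0.65, Vd = 0.28, CL = 0.27), b = 0.37)
    ),
    bw_median = 1.91
  )
}

#' Serialize / restore a population parameter set
#'
#' Flat JSON with explicit units, suitable for configuration files.
#'
#' @param pop a [pop_params()] object.
#' @param path file path.
#' @return `write_pop_params` returns `path` invisibly; `read_pop_params`
#'   returns a [pop_params()] object.
#' @export
write_pop_params <- function(pop, path) {
  stopifnot(inherits(pop, "pop_params"))
  out <- list(bw_median_kg = pop$bw_median,
              units = list(ka = "1/h", Vd = "L/kg", CL = "L/h/kg", F = "fraction"),
              drugs = lapply(pop$drugs, function(p) {
                list(F_pop = p$F_pop, ka_pop = p$ka_pop, Vd_pop = p$Vd_pop,
                     CL_pop = p$CL_pop, beta = as.list(p$beta),
                     omega = as.list(p$omega), corr = unname(p$corr), b = p$b)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pop_params
#' @export
read_pop_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  drugs <- lapply(raw$drugs, function(p) {
    drug_params(F_pop = p$F_pop, ka_pop = p$ka_pop, Vd_pop = p$Vd_pop,
                CL_pop = p$CL_pop, beta = unlist(p$beta) %||% numeric(0),
                omega = unlist(p$omega), corr = as.matrix(p$corr), b = p$b)
  })
  pop_params(drugs, bw_median = raw$bw_median_kg)
}
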