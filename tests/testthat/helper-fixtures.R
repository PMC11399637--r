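# shared fixtures, built in code

# typical absolute-unit parameters for a 2 kg bird at the published values
typical_ip <- function(drug = "TMP", bw = 2) {
  pop <- boulanger2024()
  sj <- subject(1, bw, "F", if (drug == "SMX") "TMP_SMX" else "TMP_SDZ")
  individual_params(pop, drug, sj)
}

# numeric ODE solution of the 1-compartment oral/IV model (independent
# oracle for the closed forms)
ode_conc_1cmt <- function(p, dose, times, route = "ORAL") {
  ke <- p$CL / p$Vd
  if (route == "IV") {
    init <- c(gut = 0, central = dose / p$Vd)
  } else {
    init <- c(gut = p$F * dose, central = 0)
  }
  rhs <- function(t, y, parms) {
    list(c(-p$ka * y[1], p$ka * y[1] / p$Vd - ke * y[2]))
  }
  out <- deSolve::lsoda(init, c(0, times), rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  out[-1, "central"]
}

# ODE oracle for the 2-compartment IV model
ode_conc_2cmt <- function(p2, dose, times) {
  rhs <- function(t, y, parms) {
    c1 <- y[1] / p2$V1
    c2 <- y[2] / p2$V2
    list(c(-p2$CL * c1 - p2$Q * (c1 - c2), p2$Q * (c1 - c2)))
  }
  out <- deSolve::lsoda(c(a1 = dose, a2 = 0), c(0, times), rhs, parms = NULL,
                        rtol = 1e-11, atol = 1e-13)
  out[-1, "a1"] / p2$V1
}

# one small cached fit on a full synthetic study, reused by the
# diagnostics tests (fitting is deterministic, so caching is safe)
cached_fit_env <- new.env(parent = emptyenv())
get_cached_fit <- function() {
  if (is.null(cached_fit_env$fit)) {
    d <- generate_study(seed = 424)
    cached_fit_env$data <- d
    cached_fit_env$fit <- suppressWarnings(
      fit(d, drugs = c("SDZ", "TMP"), control = list(quiet = TRUE)))
  }
  list(data = cached_fit_env$data, fit = cached_fit_env$fit)
}
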