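# independent textbook composition of the censored likelihood, used as
# the oracle for individual_loglik
oracle_loglik <- function(obs, f, b) {
  total <- 0
  for (i in seq_len(nrow(obs))) {
    s <- b * f[i]
    if (obs$cens[i] == 1) {
      total <- total + log(stats::pnorm((obs$loq[i] - f[i]) / s))
    } else {
      total <- total + log(exp(-(obs$dv[i] - f[i])^2 / (2 * s^2)) /
                             (sqrt(2 * pi) * s))
    }
  }
  total
}

test_that("individual censored log-likelihood matches the textbook oracle", {
  p <- typical_ip("SDZ")
  ev <- data.frame(time = 0, amount = 64, route = "IV")
  # density at the mode for a single exactly-predicted point
  f1 <- conc_iv_1cmt(p, 64, 2)
  obs1 <- data.frame(time = 2, dv = f1, cens = 0, loq = 0.02)
  expect_equal(individual_loglik(obs1, ev, p, b = 0.33),
               log(1 / (sqrt(2 * pi) * 0.33 * f1)))
  # censored point with prediction exactly at the LOQ contributes log(0.5)
  tl <- log((64 / p$Vd) / 0.02) / (p$CL / p$Vd) # time where f = LOQ
  obs2 <- data.frame(time = tl, dv = NA, cens = 1, loq = 0.02)
  expect_equal(individual_loglik(obs2, ev, p, b = 0.33), log(0.5), tolerance = 1e-9)
  # mixed records against the independent composition
  set.seed(31)
  for (r in 1:20) {
    tt <- sort(runif(5, 0.1, 30))
    f <- conc_iv_1cmt(p, 64, tt)
    cens <- as.integer(runif(5) < 0.3)
    obs <- data.frame(time = tt, dv = ifelse(cens == 1, NA, f * (1 + 0.3 * rnorm(5))),
                      cens = cens, loq = 0.02)
    obs$dv[obs$cens == 0] <- pmax(obs$dv[obs$cens == 0], 0.021)
    expect_equal(individual_loglik(obs, ev, p, b = 0.33),
                 oracle_loglik(obs, f, 0.33), tolerance = 1e-8)
  }
})

test_that("likelihood edge rules: zero predictions and error-SD monotonicity", {
  p <- typical_ip("SDZ")
  ev <- data.frame(time = 10, amount = 64, route = "IV") # dose after the sample
  obs_c <- data.frame(time = 5, dv = NA, cens = 1, loq = 0.02)
  expect_equal(individual_loglik(obs_c, ev, p, b = 0.33), 0)
  obs_u <- data.frame(time = 5, dv = 1, cens = 0, loq = 0.02)
  expect_lt(individual_loglik(obs_u, ev, p, b = 0.33), -1e9)
  # increasing b strictly lowers the density of an exactly-predicted point
  ev0 <- data.frame(time = 0, amount = 64, route = "IV")
  f <- conc_iv_1cmt(p, 64, 3)
  obs <- data.frame(time = 3, dv = f, cens = 0, loq = 0.02)
  lls <- sapply(c(0.2, 0.3, 0.5), function(b) individual_loglik(obs, ev0, p, b))
  expect_true(all(diff(lls) < 0))
})

# small single-drug dataset builder for the marginal-likelihood tests
toy_dataset <- function(n_subj = 1, omega_cl = 0.3, b = 0.2, seed = 17,
                        times = c(1, 4, 10)) {
  pop <- boulanger2024()
  pop$drugs$SDZ$omega[] <- 0
  pop$drugs$SDZ$omega["CL"] <- omega_cl
  pop$drugs$SDZ$b <- b
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subj)) {
    sj <- subject(i, 1.91, "F", "TMP_SDZ")
    eta <- c(ka = 0, Vd = 0, CL = rnorm(1, 0, omega_cl))
    ip <- individual_params(pop, "SDZ", sj, eta)
    f <- conc_iv_1cmt(ip, 64, times)
    y <- pmax(f * (1 + b * rnorm(length(times))), 0.03)
    rows[[length(rows) + 1L]] <- data.frame(
      ID = i, TIME = c(0, times), AMT = c(64, rep(NA, length(times))),
      ROUTE = "IV", DV = c(NA, y), BLQ = c(NA, rep(0L, length(times))),
      LOQ = c(NA, rep(0.02, length(times))), DRUG = "SDZ", BW = 1.91, SEX = "F",
      COHORT = "TMP_SDZ", EXCLUDE = 0L)
  }
  list(data = do.call(rbind, rows), pop = pop)
}

test_that("marginal likelihood matches brute-force quadrature on a 1D toy", {
  td <- toy_dataset()
  pop <- td$pop
  # brute-force trapezoid over eta_CL on [-8w, 8w]
  w <- pop$drugs$SDZ$omega[["CL"]]
  grid <- seq(-8 * w, 8 * w, length.out = 4001)
  sj <- subject(1, 1.91, "F", "TMP_SDZ")
  obs <- data.frame(time = c(1, 4, 10),
                    dv = td$data$DV[is.na(td$data$AMT)], cens = 0, loq = 0.02)
  ev <- data.frame(time = 0, amount = 64, route = "IV")
  vals <- sapply(grid, function(e) {
    ip <- individual_params(pop, "SDZ", sj, c(ka = 0, Vd = 0, CL = e))
    exp(individual_loglik(obs, ev, ip, pop$drugs$SDZ$b)) * dnorm(e, 0, w)
  })
  brute <- log(sum((vals[-1] + vals[-length(vals)]) / 2 * diff(grid)))
  agh <- marginal_loglik(td$data, pop, "SDZ", method = "agh", gh_order = 15)
  expect_equal(agh, brute, tolerance = 1e-4)
  # Laplace is close but not identical on this nonlinear model
  lap <- marginal_loglik(td$data, pop, "SDZ", method = "laplace")
  expect_equal(lap, brute, tolerance = 0.02)
})

test_that("marginal likelihood degenerates and is permutation invariant", {
  td <- toy_dataset(n_subj = 4)
  pop <- td$pop
  # omega -> 0 gives the fixed-effects-only likelihood
  pop0 <- pop
  pop0$drugs$SDZ$omega[] <- 0
  ll0 <- marginal_loglik(td$data, pop0, "SDZ")
  direct <- sum(sapply(split(td$data, td$data$ID), function(dd) {
    sj <- subject(dd$ID[1], 1.91, "F", "TMP_SDZ")
    ob <- dd[is.na(dd$AMT), ]
    individual_loglik(data.frame(time = ob$TIME, dv = ob$DV, cens = ob$BLQ,
                                 loq = ob$LOQ),
                      data.frame(time = 0, amount = 64, route = "IV"),
                      individual_params(pop0, "SDZ", sj), pop0$drugs$SDZ$b)
  }))
  expect_equal(ll0, direct, tolerance = 1e-10)
  # subject order does not matter
  perm <- td$data[order(-td$data$ID, td$data$TIME), ]
  expect_equal(marginal_loglik(perm, pop, "SDZ", gh_order = 7),
               marginal_loglik(td$data, pop, "SDZ", gh_order = 7),
               tolerance = 1e-10)
})

test_that("compiled joint likelihood agrees with the R reference (Laplace)", {
  td <- toy_dataset(n_subj = 3)
  pop <- td$pop
  ti <- sulfatrim:::tmb_inputs(td$data, 1.91)
  st <- list(F = pop$drugs$SDZ$F_pop, ka = pop$drugs$SDZ$ka_pop,
             Vd = pop$drugs$SDZ$Vd_pop, CL = pop$drugs$SDZ$CL_pop,
             omega = c(ka = 0.05, Vd = 0.05, CL = pop$drugs$SDZ$omega[["CL"]]),
             b = pop$drugs$SDZ$b)
  setup <- sulfatrim:::tmb_setup(ti$n_subj, st, character(0), "1cmt", FALSE)
  obj <- TMB::MakeADFun(data = ti$data, parameters = setup$par, random = "eta",
                        map = setup$map, DLL = "sulfatrim", silent = TRUE)
  tmb_ll <- -as.numeric(obj$fn(obj$par))
  # R reference with matching small omegas on ka and Vd
  pop_ref <- pop
  pop_ref$drugs$SDZ$omega <- c(ka = 0.05, Vd = 0.05, CL = pop$drugs$SDZ$omega[["CL"]])
  ref <- marginal_loglik(td$data, pop_ref, "SDZ", method = "laplace")
  expect_equal(tmb_ll, ref, tolerance = 1e-4)
})
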