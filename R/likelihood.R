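# Reference (pure-R) likelihood implementations. The production fitter
# evaluates the same joint likelihood inside compiled code and applies the
# Laplace approximation there; these functions define the estimand and
# back the oracle tests.

#' Individual-level censored log-likelihood
#'
#' Conditional log-density of one subject's observations given realized
#' individual parameters, under the proportional error model
#' `y ~ Normal(f, b * f)` with left-censored (BLQ) points contributing
#' `log Phi((loq - f) / (b * f))` (the M3 treatment: censored probability
#' mass, never an imputed value).
#'
#' @param obs data frame with columns `time` (h), `dv` (ug/mL, `NA` when
#'   censored), `cens` (0/1) and `loq` (ug/mL).
#' @param events dose-event data frame (`time`, `amount`, `route`) for the
#'   same subject and drug.
#' @param ip a [structural_params()] object (absolute units).
#' @param b proportional residual error SD.
#' @return Scalar log-likelihood. A zero prediction under a censored point
#'   contributes 0 (censoring is certain); a zero prediction under an
#'   uncensored point contributes a large negative sentinel (-1e10).
#' @export
individual_loglik <- function(obs, events, ip, b) {
  stop_if_not_positive(b, "b")
  f <- superpose(events, ip, obs$time)
  ll <- numeric(nrow(obs))
  cns <- obs$cens == 1
  zero <- f <= 0
  ll[cns & zero] <- 0
  ll[cns & !zero] <- stats::pnorm((obs$loq[cns & !zero] - f[cns & !zero]) /
                                    (b * f[cns & !zero]), log.p = TRUE)
  ll[!cns & zero] <- -1e10
  ok <- !cns & !zero
  ll[ok] <- stats::dnorm(obs$dv[ok], f[ok], b * f[ok], log = TRUE)
  sum(ll)
}

# split a single-drug dataset into per-subject obs/events lists
split_subjects <- function(data) {
  stopifnot(length(unique(data$DRUG)) == 1)
  ids <- unique(data$ID)
  lapply(stats::setNames(ids, ids), function(id) {
    d <- data[data$ID == id, ]
    ev <- d[!is.na(d$AMT), c("TIME", "AMT", "ROUTE")]
    ob <- d[is.na(d$AMT), c("TIME", "DV", "BLQ", "LOQ")]
    list(
      subj = subject(id, d$BW[1], d$SEX[1], d$COHORT[1]),
      events = data.frame(time = ev$TIME, amount = ev$AMT, route = ev$ROUTE),
      obs = data.frame(time = ob$TIME, dv = ob$DV, cens = ob$BLQ, loq = ob$LOQ)
    )
  })
}

#' Marginal log-likelihood of the hierarchical model
#'
#' Log of the likelihood with the per-subject random effects integrated
#' out, `sum_i log integral p(y_i | eta) p(eta) d eta`, for one drug's
#' dataset. Random effects are those with `omega > 0`. Integration is by
#' mode-centered (adaptive) Gauss-Hermite quadrature or by the Laplace
#' approximation (`gh_order = 1`). With all omegas zero this degenerates
#' to the fixed-effects-only log-likelihood.
#'
#' @param data single-drug dataset in the [read_dataset()] column layout.
#' @param pop a [pop_params()] object.
#' @param drug drug code present in `data`.
#' @param method `"agh"` (default) or `"laplace"`.
#' @param gh_order Gauss-Hermite nodes per dimension (default 9).
#' @return Scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(data, pop, drug = unique(data$DRUG),
                            method = c("agh", "laplace"), gh_order = 9) {
  method <- match.arg(method)
  dp <- pop$drugs[[drug]]
  data <- data[data$DRUG == drug & !(data$EXCLUDE %||% 0), ]
  subs <- split_subjects(data)
  active <- which(dp$omega > 1e-12)
  k <- length(active)
  b <- dp$b
  if (k == 0) {
    return(sum(vapply(subs, function(s) {
      individual_loglik(s$obs, s$events, individual_params(pop, drug, s$subj), b)
    }, numeric(1))))
  }
  D <- diag(dp$omega[active], k)
  sigma <- D %*% dp$corr[active, active, drop = FALSE] %*% D
  full_eta <- function(ea) {
    eta <- c(ka = 0, Vd = 0, CL = 0)
    eta[active] <- ea
    eta
  }
  sum(vapply(subs, function(s) {
    nll <- function(ea) {
      -individual_loglik(s$obs, s$events,
                         individual_params(pop, drug, s$subj, full_eta(ea)), b) -
        dmvnorm0_log(ea, sigma)
    }
    opt <- stats::nlminb(rep(0, k), nll)
    H <- stats::optimHess(opt$par, nll)
    Hc <- tryCatch(chol(H), error = function(e) chol(H + diag(1e-6, k)))
    if (method == "laplace" || gh_order == 1) {
      return(-opt$objective + k / 2 * log(2 * pi) - sum(log(diag(Hc))))
    }
    gq <- statmod::gauss.quad(gh_order, kind = "hermite")
    grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(gh_order)), k)))
    A <- solve(Hc) # sigma_hat = A %*% t(A)
    logw <- apply(grid, 1, function(ix) sum(log(gq$weights[ix])))
    terms <- vapply(seq_len(nrow(grid)), function(r) {
      z <- gq$nodes[grid[r, ]]
      ea <- opt$par + sqrt(2) * as.numeric(A %*% z)
      logw[r] + sum(z^2) - nll(ea)
    }, numeric(1))
    m <- max(terms)
    m + log(sum(exp(terms - m))) + k / 2 * log(2) - sum(log(diag(Hc)))
  }, numeric(1)))
}
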