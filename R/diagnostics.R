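# Model-validation machinery: weighted residuals, normalized prediction
# distribution errors and the prediction-corrected visual predictive
# check. All routines are simulation-based and work from a fitted (or
# assumed) population parameter set, so they are estimator-agnostic.


# simulate nsim replicate observation vectors at the design points of a
# single-drug dataset; returns a list per subject with matrix nsim x n_i
simulate_replicates <- function(data, pop, drug, nsim, seed = NULL,
                                residual = TRUE) {
  dp <- pop$drugs[[drug]]
  subs <- split_subjects(data[data$DRUG == drug, ])
  with_seed(seed, {
    lapply(subs, function(s) {
      n_i <- nrow(s$obs)
      etas <- sample_etas(pop, drug, nsim)
      sims <- matrix(0, nsim, n_i)
      for (r in seq_len(nsim)) {
        ip <- individual_params(pop, drug, s$subj, etas[r, ])
        f <- superpose(s$events, ip, s$obs$time)
        sims[r, ] <- if (residual) f * (1 + dp$b * stats::rnorm(n_i)) else f
      }
      sims
    })
  })
}

#' Population and individual weighted residuals
#'
#' `IWRES = (y - f_i) / (b * f_i)` with `f_i` the prediction at the
#' empirical Bayes estimates; `PWRES` decorrelates `y - E[y]` with the
#' model-implied covariance of each subject's observation vector, both
#' moments approximated by Monte Carlo simulation from the population
#' model. Censored rows are excluded (their count is reported in
#' attribute `"n_censored_excluded"`).
#'
#' @param fitres a `ts_fit` object with estimates.
#' @param data the dataset that was fitted.
#' @param drug drug to diagnose.
#' @param nsim simulation replicates for the PWRES moments.
#' @param seed optional seed.
#' @return Data frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `IWRES`,
#'   `PWRES`.
#' @export
weighted_residuals <- function(fitres, data, drug, nsim = 500, seed = NULL) {
  pop <- fitres$estimates
  dp <- pop$drugs[[drug]]
  d <- data[data$DRUG == drug & !(data$EXCLUDE %||% 0L), ]
  subs <- split_subjects(d)
  eta <- fitres$fits[[drug]]$eta
  sims <- simulate_replicates(d, pop, drug, nsim, seed = seed)
  rows <- list()
  n_cens <- 0L
  for (j in seq_along(subs)) {
    s <- subs[[j]]
    keep <- s$obs$cens == 0
    n_cens <- n_cens + sum(!keep)
    if (!any(keep)) next
    ip <- individual_params(pop, drug, s$subj, eta[as.character(s$subj$subject_id), ])
    ipred <- superpose(s$events, ip, s$obs$time)[keep]
    sim <- sims[[j]][, keep, drop = FALSE]
    m <- colMeans(sim)
    S <- stats::cov(sim) + diag(1e-10, ncol(sim))
    y <- s$obs$dv[keep]
    R <- chol(S)
    pw <- backsolve(R, y - m, transpose = TRUE)
    ip0 <- individual_params(pop, drug, s$subj)
    pred <- superpose(s$events, ip0, s$obs$time)[keep]
    rows[[j]] <- data.frame(ID = s$subj$subject_id, TIME = s$obs$time[keep],
                            DV = y, PRED = pred, IPRED = ipred,
                            IWRES = (y - ipred) / (dp$b * ipred),
                            PWRES = pw)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_censored_excluded") <- n_cens
  out
}

#' Normalized prediction distribution errors
#'
#' Simulation-based decorrelated residuals: each subject's observation
#' vector and `nsim` simulated replicates are decorrelated with the
#' empirical mean and Cholesky factor of the simulated distribution; the
#' rank of the decorrelated observation among its decorrelated simulations
#' is probit-transformed. Under the true model NPDE ~ N(0, 1). Censored
#' observations are imputed at a uniformly drawn quantile of their
#' simulated marginal below the LOQ before decorrelation and flagged in
#' the output.
#'
#' @inheritParams weighted_residuals
#' @param nsim simulation replicates (>= 500 recommended; a smaller value
#'   triggers a warning).
#' @return Data frame with `ID`, `TIME`, `censored`, `pd` and `NPDE`.
#' @export
npde <- function(fitres, data, drug, nsim = 1000, seed = NULL) {
  if (nsim < 500) warning("nsim < 500: NPDE will be noisy", call. = FALSE)
  pop <- fitres$estimates %||% fitres
  if (!inherits(pop, "pop_params")) stop("no estimates in 'fitres'", call. = FALSE)
  d <- data[data$DRUG == drug & !(data$EXCLUDE %||% 0L), ]
  subs <- split_subjects(d)
  sims <- simulate_replicates(d, pop, drug, nsim, seed = seed)
  rows <- with_seed(sub_seed(seed, "impute"), {
    lapply(seq_along(subs), function(j) {
      s <- subs[[j]]
      sim <- sims[[j]]
      n_i <- nrow(s$obs)
      y <- s$obs$dv
      cens <- s$obs$cens == 1
      # impute censored observations within the simulated sub-LOQ mass
      for (q in which(cens)) {
        p_loq <- max(mean(sim[, q] < s$obs$loq[q]), 1 / nsim)
        y[q] <- stats::quantile(sim[, q], stats::runif(1, 0, p_loq), names = FALSE)
      }
      m <- colMeans(sim)
      R <- chol(stats::cov(sim) + diag(1e-10, n_i))
      yd <- backsolve(R, y - m, transpose = TRUE)
      simd <- t(backsolve(R, t(sim) - m, transpose = TRUE))
      pd <- vapply(seq_len(n_i), function(q) {
        (sum(simd[, q] < yd[q]) + 0.5) / (nsim + 1)
      }, numeric(1))
      data.frame(ID = s$subj$subject_id, TIME = s$obs$time, censored = cens,
                 pd = pd, NPDE = stats::qnorm(pd))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# time after most recent dose, per observation row of a split subject
time_after_dose <- function(obs_time, ev_time) {
  vapply(obs_time, function(tt) {
    prior <- ev_time[ev_time <= tt]
    if (!length(prior)) NA_real_ else tt - max(prior)
  }, numeric(1))
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulated replicates are rescaled by
#' `bin-median population prediction / own population prediction`
#' (prediction correction), then empirical percentiles (10/50/90 by
#' default) per time bin are compared with the envelope of the same
#' percentiles across simulated replicates. Bins default to the nominal
#' sampling times (the design is scheduled); bins with fewer than
#' `min_bin` uncensored observations are merged with their left neighbor.
#' Censored observations contribute a per-bin censored fraction, not
#' percentile values. Stratified by route.
#'
#' @inheritParams weighted_residuals
#' @param bins numeric vector of bin edges on the time-after-dose axis;
#'   defaults to midpoints between nominal sampling times.
#' @param probs percentiles displayed.
#' @param envelope quantiles of the simulated percentile distribution.
#' @param max_time drop observations beyond this time after dose (h).
#' @param min_bin minimum uncensored observations per bin before merging.
#' @return Object of class `vpc_result`: data frame with one row per
#'   (route, bin, percentile) holding empirical value, simulation envelope
#'   and censored fraction.
#' @export
pcvpc <- function(fitres, data, drug, nsim = 500, bins = NULL, seed = NULL,
                  probs = c(0.1, 0.5, 0.9), envelope = c(0.1, 0.9),
                  max_time = 24, min_bin = 3) {
  pop <- fitres$estimates %||% fitres
  if (!inherits(pop, "pop_params")) stop("no estimates in 'fitres'", call. = FALSE)
  d <- data[data$DRUG == drug & !(data$EXCLUDE %||% 0L), ]
  subs <- split_subjects(d)
  sims <- simulate_replicates(d, pop, drug, nsim, seed = seed)
  tab <- list()
  for (j in seq_along(subs)) {
    s <- subs[[j]]
    ip0 <- individual_params(pop, drug, s$subj)
    tab[[j]] <- data.frame(
      route = vapply(s$obs$time, function(tt) {
        pri <- s$events$time <= tt
        if (!any(pri)) NA_character_ else s$events$route[max(which(pri))]
      }, character(1)),
      tad = time_after_dose(s$obs$time, s$events$time),
      dv = s$obs$dv, cens = s$obs$cens,
      pred = superpose(s$events, ip0, s$obs$time),
      sub = j, col = seq_len(nrow(s$obs)))
  }
  tab <- do.call(rbind, tab)
  keep <- !is.na(tab$tad) & tab$tad <= max_time
  tab <- tab[keep, ]
  out <- list()
  merged_log <- character(0)
  for (rt in unique(tab$route)) {
    tr <- tab[tab$route == rt, ]
    if (is.null(bins)) {
      nom <- sort(unique(tr$tad))
      edges <- c(0, (nom[-1] + nom[-length(nom)]) / 2, max_time + 1e-9)
    } else edges <- bins
    bin <- cut(tr$tad, edges, include.lowest = TRUE, labels = FALSE)
    # merge under-filled bins leftward
    repeat {
      cnt <- tapply(tr$cens == 0, bin, sum)
      small <- names(cnt)[which(cnt < min_bin)]
      if (!length(small)) break
      b <- as.integer(small[1])
      cand <- if (any(bin < b)) max(bin[bin < b]) else
        if (any(bin > b)) min(bin[bin > b]) else NA_integer_
      tgt <- cand
      if (is.na(tgt)) break
      merged_log <- c(merged_log, sprintf("%s: bin %d merged into %d", rt, b, tgt))
      bin[bin == b] <- tgt
    }
    for (bb in sort(unique(bin))) {
      sel <- which(bin == bb)
      trb <- tr[sel, ]
      ok <- trb$cens == 0
      if (!any(ok)) next
      binmed <- stats::median(trb$pred)
      pc_obs <- trb$dv[ok] * binmed / trb$pred[ok]
      emp <- stats::quantile(pc_obs, probs, names = FALSE)
      # simulated percentile envelope under the same correction
      simq <- matrix(NA_real_, nsim, length(probs))
      for (r in seq_len(nsim)) {
        vals <- vapply(seq_len(nrow(trb)), function(q) {
          sims[[trb$sub[q]]][r, trb$col[q]]
        }, numeric(1))
        vals <- pmax(vals, 0)
        simq[r, ] <- stats::quantile(vals * binmed / trb$pred, probs, names = FALSE)
      }
      for (pi in seq_along(probs)) {
        out[[length(out) + 1L]] <- data.frame(
          drug = drug, route = rt, bin = bb,
          time = stats::median(trb$tad), n = nrow(trb),
          frac_censored = mean(trb$cens == 1), percentile = 100 * probs[pi],
          empirical = emp[pi],
          sim_lo = stats::quantile(simq[, pi], envelope[1], names = FALSE),
          sim_med = stats::median(simq[, pi]),
          sim_hi = stats::quantile(simq[, pi], envelope[2], names = FALSE))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "merged_bins") <- merged_log
  class(res) <- c("vpc_result", class(res))
  res
}

#' Export a VPC result as tidy CSV
#'
#' Long format (`bin`, `series`, `percentile`, `value`) so any plotting
#' stack can render the ribbons.
#'
#' @param vpc a `vpc_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vpc_csv <- function(vpc, path) {
  long <- do.call(rbind, lapply(c("empirical", "sim_lo", "sim_med", "sim_hi"),
                                function(sr) {
    data.frame(drug = vpc$drug, route = vpc$route, bin = vpc$bin,
               time = vpc$time, percentile = vpc$percentile,
               frac_censored = vpc$frac_censored, series = sr,
               value = vpc[[sr]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
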