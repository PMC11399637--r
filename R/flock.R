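# Monte Carlo simulation of a virtual broiler flock under a dosing
# regimen, and external validation against literature mean profiles.

# joint 6-dim random-effect draw for (sulfonamide, TMP): within-drug
# correlation matrices on the block diagonal, optional per-parameter
# cross-drug correlations off the blocks
sample_cross_etas <- function(pop, s_drug, n, corr_threshold, cross_corr) {
  cross_corr <- cross_corr[c("ka", "Vd", "CL")]
  if (anyNA(cross_corr)) cross_corr[is.na(cross_corr)] <- 0
  if (all(cross_corr == 0)) {
    return(list(s = sample_etas(pop, s_drug, n, corr_threshold = corr_threshold),
                tmp = sample_etas(pop, "TMP", n, corr_threshold = corr_threshold)))
  }
  thin <- function(corr) {
    off <- abs(corr) <= corr_threshold & row(corr) != col(corr)
    corr[off] <- 0
    corr
  }
  R <- diag(6)
  R[1:3, 1:3] <- thin(pop$drugs[[s_drug]]$corr)
  R[4:6, 4:6] <- thin(pop$drugs$TMP$corr)
  for (k in 1:3) R[k, k + 3] <- R[k + 3, k] <- cross_corr[[k]]
  om <- c(pop$drugs[[s_drug]]$omega, pop$drugs$TMP$omega)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("cross-drug correlation makes the joint matrix non-PSD", call. = FALSE)
  }
  S <- diag(om) %*% R %*% diag(om)
  eta <- MASS::mvrnorm(n, rep(0, 6), S)
  cn <- c("ka", "Vd", "CL")
  list(s = matrix(eta[, 1:3], n, 3, dimnames = list(NULL, cn)),
       tmp = matrix(eta[, 4:6], n, 3, dimnames = list(NULL, cn)))
}

#' Dosing-regimen specification for flock simulation
#'
#' Defaults correspond to the registered single oral dose of the
#' SDZ-based formulation: 25 mg/kg sulfonamide + 5 mg/kg TMP (use
#' `dose_s = 37.5, dose_tmp = 7.5, s_drug = "SMX"` for the SMX-based
#' product). Body weights are drawn from a truncated normal spanning the
#' study's observed range.
#'
#' @param s_drug sulfonamide (`"SDZ"` or `"SMX"`).
#' @param dose_s,dose_tmp doses (mg/kg).
#' @param route `"ORAL"` or `"IV"`.
#' @param dose_times dose times (h); single dose at 0 by default.
#' @param n virtual population size.
#' @param bw_mean,bw_sd,bw_range body-weight distribution (kg).
#' @param seed integer seed.
#' @return Object of class `regimen_spec`.
#' @export
regimen_spec <- function(s_drug = c("SDZ", "SMX"), dose_s = 25, dose_tmp = 5,
                         route = c("ORAL", "IV"), dose_times = 0, n = 1000,
                         bw_mean = 1.91, bw_sd = 0.35,
                         bw_range = c(1.07, 2.98), seed = NULL) {
  s_drug <- match.arg(s_drug)
  route <- match.arg(route)
  stop_if_not_positive(c(dose_s, dose_tmp, n), "dose_s/dose_tmp/n")
  structure(list(s_drug = s_drug, dose_s = dose_s, dose_tmp = dose_tmp,
                 route = route, dose_times = dose_times, n = as.integer(n),
                 bw_mean = bw_mean, bw_sd = bw_sd, bw_range = bw_range,
                 seed = seed), class = "regimen_spec")
}

#' Simulate a virtual broiler flock
#'
#' Draws `n` subjects (body weight, sex), correlated random effects for
#' the sulfonamide and TMP (within-drug correlations retained only above
#' `corr_threshold`; cross-drug random effects are independent by
#' default), builds each bird's concentration curves for both drugs,
#' applies protein binding and summarizes the unbound TMP:S ratio over
#' the time grid: per-time percentiles and per-subject 1:19 target
#' attainment (flag and duration).
#'
#' @param pop a [pop_params()] object.
#' @param regimen a [regimen_spec()].
#' @param binding a [binding_spec()].
#' @param grid time grid (h), default 0-24 h by 0.05 h.
#' @param corr_threshold retain within-drug correlations only when
#'   `|r|` exceeds this value (default 0.2).
#' @param cross_corr named vector `c(ka =, Vd =, CL =)` of cross-drug
#'   correlations between the same parameter's random effects in the two
#'   co-administered drugs (default all 0: independent). Nonzero values
#'   support sensitivity analyses for co-formulated products, where
#'   absorption and disposition effects plausibly co-vary between the
#'   drugs within a bird; the estimated values are not identifiable from
#'   single-drug fits.
#' @param target target free ratio (default 1/19).
#' @param probs percentiles of the ratio reported per time point.
#' @param keep_curves keep the per-subject concentration matrices.
#' @return Object of class `flock_sim`: `percentiles` (data frame, one
#'   row per grid time), `attainment` (per subject), `fraction_attained`,
#'   `subjects`, and optionally `curves`.
#' @export
simulate_flock <- function(pop, regimen, binding = binding_spec(),
                           grid = seq(0, 24, by = 0.05), corr_threshold = 0.2,
                           cross_corr = c(ka = 0, Vd = 0, CL = 0),
                           target = 1 / 19, probs = seq(0.05, 0.95, by = 0.05),
                           keep_curves = FALSE) {
  s_drug <- regimen$s_drug
  n <- regimen$n
  with_seed(regimen$seed, {
    bw <- rtruncnorm(n, regimen$bw_mean, regimen$bw_sd,
                     regimen$bw_range[1], regimen$bw_range[2])
    sex <- sample(c("M", "F"), n, replace = TRUE)
    etas <- sample_cross_etas(pop, s_drug, n, corr_threshold, cross_corr)
    eta_s <- etas$s
    eta_t <- etas$tmp
    ratio <- matrix(NA_real_, n, length(grid))
    curves <- if (keep_curves) list(S = matrix(0, n, length(grid)),
                                    TMP = matrix(0, n, length(grid)))
    att <- data.frame(ID = seq_len(n), attained = FALSE, duration_h = 0)
    cohort <- if (s_drug == "SDZ") "TMP_SDZ" else "TMP_SMX"
    for (i in seq_len(n)) {
      sj <- subject(i, bw[i], sex[i], cohort)
      ip_s <- individual_params(pop, s_drug, sj, eta_s[i, ])
      ip_t <- individual_params(pop, "TMP", sj, eta_t[i, ])
      ev_s <- data.frame(time = regimen$dose_times,
                         amount = regimen$dose_s * bw[i], route = regimen$route)
      ev_t <- data.frame(time = regimen$dose_times,
                         amount = regimen$dose_tmp * bw[i], route = regimen$route)
      cs <- superpose(ev_s, ip_s, grid)
      ct <- superpose(ev_t, ip_t, grid)
      rt <- ratio_trajectory(ct, cs, grid, spec = binding, s_drug = s_drug,
                             target = target)
      ratio[i, ] <- rt$ratio
      att$attained[i] <- rt$attained
      att$duration_h[i] <- rt$duration_h
      if (keep_curves) {
        curves$S[i, ] <- cs
        curves$TMP[i, ] <- ct
      }
    }
    qs <- apply(ratio, 2, stats::quantile, probs = probs, na.rm = TRUE)
    pct <- data.frame(time = grid, t(qs))
    names(pct) <- c("time", sprintf("p%02d", round(100 * probs)))
    out <- list(percentiles = pct, attainment = att,
                fraction_attained = mean(att$attained),
                subjects = data.frame(ID = seq_len(n), BW = bw, SEX = sex),
                regimen = regimen, target = target)
    if (keep_curves) out$curves <- curves
    class(out) <- "flock_sim"
    out
  })
}

#' @export
print.flock_sim <- function(x, ...) {
  r <- x$regimen
  cat(sprintf("flock_sim: %d broilers, %s %g + TMP %g mg/kg (%s)\n",
              r$n, r$s_drug, r$dose_s, r$dose_tmp, r$route))
  cat(sprintf("  free TMP:%s ratio >= 1:%g at any time: %.1f%% of subjects\n",
              r$s_drug, round(1 / x$target), 100 * x$fraction_attained))
  md <- x$attainment$duration_h[x$attainment$attained]
  if (length(md)) cat(sprintf("  median duration above target (attainers): %.2f h\n",
                              stats::median(md)))
  invisible(x)
}

#' External validation against literature mean profiles
#'
#' Simulates the stated design (dose, body-weight distribution), forms
#' per-time prediction intervals for the mean of `group_size` birds and
#' reports the fraction of observed literature means falling inside.
#'
#' @param pop a [pop_params()] object.
#' @param design list with `drug`, `dose` (mg/kg), `route`, `bw_mean`,
#'   `bw_sd` (kg), optional `bw_range`, optional `group_size` (animals
#'   per literature mean, default 6).
#' @param observed_means data frame with columns `time` (h) and `conc`
#'   (ug/mL), e.g. digitized literature profiles.
#' @param nrep simulated groups.
#' @param level prediction-interval coverage (default 0.90, i.e. 5-95%).
#' @param seed integer seed.
#' @return List with `coverage`, `table` (per-time bounds and inclusion
#'   flags) and `n_outside_window`.
#' @export
external_validation <- function(pop, design, observed_means, nrep = 1000,
                                level = 0.90, seed = NULL) {
  if (is.null(observed_means) || !nrow(observed_means)) {
    stop("'observed_means' is empty", call. = FALSE)
  }
  stopifnot(all(c("time", "conc") %in% names(observed_means)))
  drug <- design$drug
  m <- design$group_size %||% 6
  bw_range <- design$bw_range %||% (design$bw_mean + c(-4, 4) * design$bw_sd)
  window <- c(0, max(observed_means$time))
  tgrid <- observed_means$time
  alpha <- (1 - level) / 2
  dp <- pop$drugs[[drug]]
  cohort <- if (drug == "SMX") "TMP_SMX" else "TMP_SDZ"
  with_seed(seed, {
    means <- matrix(NA_real_, nrep, length(tgrid))
    for (r in seq_len(nrep)) {
      bw <- rtruncnorm(m, design$bw_mean, design$bw_sd, bw_range[1], bw_range[2])
      sex <- sample(c("M", "F"), m, replace = TRUE)
      eta <- sample_etas(pop, drug, m)
      sims <- matrix(0, m, length(tgrid))
      for (i in seq_len(m)) {
        sj <- subject(i, max(min(bw[i], 4.99), 0.31), sex[i], cohort)
        ip <- individual_params(pop, drug, sj, eta[i, ])
        ev <- data.frame(time = 0, amount = design$dose * bw[i],
                         route = design$route %||% "ORAL")
        f <- superpose(ev, ip, tgrid)
        sims[i, ] <- f * (1 + dp$b * stats::rnorm(length(tgrid)))
      }
      means[r, ] <- colMeans(sims)
    }
    lo <- apply(means, 2, stats::quantile, probs = alpha)
    hi <- apply(means, 2, stats::quantile, probs = 1 - alpha)
    tab <- data.frame(time = tgrid, observed = observed_means$conc,
                      lo = lo, hi = hi,
                      inside = observed_means$conc >= lo & observed_means$conc <= hi,
                      in_window = tgrid >= window[1] & tgrid <= window[2])
    list(coverage = mean(tab$inside[tab$in_window]), table = tab,
         n_outside_window = sum(!tab$in_window))
  })
}

#' Export flock-simulation summaries as tidy CSV
#'
#' @param fs a `flock_sim` object.
#' @param percentile_path,attainment_path output files (either may be
#'   `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_flock_csv <- function(fs, percentile_path = NULL, attainment_path = NULL) {
  stopifnot(inherits(fs, "flock_sim"))
  if (!is.null(percentile_path)) {
    utils::write.csv(fs$percentiles, percentile_path, row.names = FALSE)
  }
  if (!is.null(attainment_path)) {
    utils::write.csv(fs$attainment, attainment_path, row.names = FALSE)
  }
  invisible(c(percentile_path, attainment_path))
}
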