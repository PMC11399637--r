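# Maximum-likelihood fitting of the hierarchical model. The joint
# likelihood (structural model + correlated lognormal random effects +
# proportional error with M3 censoring) is implemented in compiled code;
# the marginal likelihood is obtained by the Laplace approximation over
# the per-subject random effects and maximized with nlminb. This targets
# the same estimand as stochastic EM estimators (the marginal ML), with a
# deterministic approximation so that fits are exactly reproducible.

tmb_inputs <- function(data, bw_median) {
  ids <- unique(data$ID)
  sub <- data[!duplicated(data$ID), c("ID", "BW", "SEX")]
  sub <- sub[match(ids, sub$ID), ]
  idx <- function(id) match(id, ids) - 1L
  ev <- data[!is.na(data$AMT), ]
  ob <- data[is.na(data$AMT), ]
  list(
    data = list(
      obs_subj = idx(ob$ID), obs_time = ob$TIME,
      obs_dv = ifelse(ob$BLQ == 1L, 0, ob$DV),
      obs_cens = as.integer(ob$BLQ), obs_loq = ob$LOQ,
      ev_subj = idx(ev$ID), ev_time = ev$TIME, ev_amt = ev$AMT,
      ev_oral = as.integer(ev$ROUTE == "ORAL"),
      bw = sub$BW, logbw_norm = log(sub$BW / bw_median),
      sexM = as.integer(sub$SEX == "M"), ncmt = 1L),
    ids = ids, n_subj = length(ids), n_obs = nrow(ob))
}

#' Naive-pooled starting values
#'
#' Crude NCA-style initial estimates for one drug: volume from the
#' earliest post-IV concentration (C0 back-extrapolation), elimination
#' rate from a pooled log-linear regression on the IV tail, `ka` fixed at
#' 1/h, `F` at 0.9, all omegas at 0.3 and `b` at 0.3.
#'
#' @param data single-drug dataset in the [read_dataset()] layout.
#' @return Named list of starting values (per-kg scale).
#' @keywords internal
nca_init <- function(data) {
  ob <- data[is.na(data$AMT) & data$BLQ == 0L, ]
  ev <- data[!is.na(data$AMT), ]
  iv_ev <- ev[ev$ROUTE == "IV", ]
  vd <- 0.5
  ke <- 0.3
  if (nrow(iv_ev)) {
    # time since the subject's IV dose
    iv_ob <- merge(ob, iv_ev[, c("ID", "TIME", "AMT")], by = "ID",
                   suffixes = c("", ".ev"))
    iv_ob$tad <- iv_ob$TIME - iv_ob$TIME.ev
    iv_ob <- iv_ob[iv_ob$tad >= 0 & iv_ob$tad <= 32 & iv_ob$ROUTE == "IV", ]
    if (nrow(iv_ob)) {
      first <- iv_ob[order(iv_ob$ID, iv_ob$tad), ]
      first <- first[!duplicated(first$ID) & first$tad <= 1, ]
      if (nrow(first)) vd <- stats::median(first$AMT.ev / first$DV / first$BW)
      tail <- iv_ob[iv_ob$tad >= 1, ]
      if (nrow(tail) >= 3) {
        sl <- stats::coef(stats::lm(log(DV) ~ tad, data = tail))[2]
        if (is.finite(sl) && sl < 0) ke <- -sl
      }
    }
  }
  list(F = 0.9, ka = 1, Vd = max(vd, 1e-3), CL = max(ke * vd, 1e-4),
       omega = c(ka = 0.3, Vd = 0.3, CL = 0.3), b = 0.3)
}

# build TMB parameter list + map for one drug fit
tmb_setup <- function(n_subj, start, retained_beta, model, estimate_corr) {
  par <- list(
    logit_F = logit(min(start$F, 0.99)),
    log_ka = log(start$ka), log_Vd = log(start$Vd), log_CL = log(start$CL),
    beta_ka_bw = 0, beta_Vd_bw = 0, beta_CL_bw = 0,
    beta_ka_sex = 0, beta_Vd_sex = 0, beta_CL_sex = 0,
    log_omega = log(pmax(start$omega, 0.05)),
    corr_theta = rep(0, 3), log_b = log(start$b),
    log_Q = log(0.5), log_V2 = log(0.5),
    eta = matrix(0, n_subj, 3))
  map <- list()
  beta_names <- c("ka_BW", "Vd_BW", "CL_BW", "ka_SEXM", "Vd_SEXM", "CL_SEXM")
  beta_pars <- c("beta_ka_bw", "beta_Vd_bw", "beta_CL_bw",
                 "beta_ka_sex", "beta_Vd_sex", "beta_CL_sex")
  for (i in seq_along(beta_names)) {
    if (!(beta_names[i] %in% retained_beta)) map[[beta_pars[i]]] <- factor(NA)
  }
  if (model == "1cmt") {
    map$log_Q <- factor(NA)
    map$log_V2 <- factor(NA)
    theta_map <- if (estimate_corr) factor(1:3) else factor(rep(NA, 3))
    map$corr_theta <- theta_map
  } else { # IV-only comparison fits: no absorption, no bioavailability
    map$logit_F <- factor(NA)
    map$log_ka <- factor(NA)
    map$beta_ka_bw <- factor(NA)
    map$beta_ka_sex <- factor(NA)
    map$log_omega <- factor(c(NA, 1, 2))
    par$log_omega[1] <- 0
    map$eta <- factor(c(rep(NA, n_subj), seq_len(2 * n_subj)))
    map$corr_theta <- if (estimate_corr) factor(c(NA, NA, 1)) else factor(rep(NA, 3))
    if (model == "1cmt_iv") {
      map$log_Q <- factor(NA)
      map$log_V2 <- factor(NA)
    }
  }
  list(par = par, map = map)
}

tmb_bounds <- function(parnames) {
  lw <- c(logit_F = -9, log_ka = -7, log_Vd = -7, log_CL = -9,
          beta_ka_bw = -5, beta_Vd_bw = -5, beta_CL_bw = -5,
          beta_ka_sex = -5, beta_Vd_sex = -5, beta_CL_sex = -5,
          log_omega = log(1e-3), corr_theta = -8, log_b = log(1e-3),
          log_Q = -9, log_V2 = -7)
  up <- c(logit_F = 9, log_ka = 5, log_Vd = 5, log_CL = 5,
          beta_ka_bw = 5, beta_Vd_bw = 5, beta_CL_bw = 5,
          beta_ka_sex = 5, beta_Vd_sex = 5, beta_CL_sex = 5,
          log_omega = log(5), corr_theta = 8, log_b = log(3),
          log_Q = 5, log_V2 = 5)
  list(lower = unname(lw[parnames]), upper = unname(up[parnames]))
}

fit_drug <- function(data, drug, model = "1cmt", start = NULL,
                     retained_beta = NULL, estimate_corr = TRUE,
                     bw_median = 1.91, se = TRUE, control = list()) {
  d <- data[data$DRUG == drug & !(data$EXCLUDE %||% 0L), ]
  if (model %in% c("1cmt_iv", "2cmt_iv")) d <- d[d$ROUTE == "IV", ]
  if (!nrow(d) || !any(is.na(d$AMT))) stop("no observations for drug ", drug, call. = FALSE)
  ti <- tmb_inputs(d, bw_median)
  if (model == "2cmt_iv") ti$data$ncmt <- 2L
  if (is.null(start)) start <- nca_init(d)
  if (model == "2cmt_iv") {
    start$Vd <- start$Vd * 0.6 # split the 1-cmt volume over the two compartments
  }
  setup <- tmb_setup(ti$n_subj, start, retained_beta %||% character(0),
                     model, estimate_corr)
  obj <- TMB::MakeADFun(data = ti$data, parameters = setup$par,
                        random = "eta", map = setup$map,
                        DLL = "sulfatrim", silent = TRUE)
  bb <- tmb_bounds(names(obj$par))
  nlminb_ctl <- utils::modifyList(list(iter.max = 500, eval.max = 1000),
                                  control[setdiff(names(control), "quiet")])
  opt <- stats::nlminb(obj$par, obj$fn, obj$gr,
                       lower = bb$lower, upper = bb$upper,
                       control = nlminb_ctl)
  # polish: restart from the optimum until the gradient settles
  for (r in 1:3) {
    if (opt$convergence == 0) break
    opt2 <- tryCatch(stats::nlminb(opt$par, obj$fn, obj$gr,
                                   lower = bb$lower, upper = bb$upper,
                                   control = nlminb_ctl),
                     error = function(e) NULL)
    if (is.null(opt2) || opt2$objective > opt$objective + 1e-8) break
    opt <- opt2
  }
  grad <- tryCatch(obj$gr(opt$par), error = function(e) rep(NA_real_, length(opt$par)))
  conv <- list(code = opt$convergence, message = opt$message,
               iterations = opt$iterations, max_abs_gradient = max(abs(grad)))
  if (opt$convergence != 0 && !isTRUE(control$quiet)) {
    warning(sprintf("fit for %s (%s) did not formally converge: %s (|grad|max=%.3g)",
                    drug, model, opt$message, max(abs(grad))), call. = FALSE)
  }
  se_tab <- NULL
  if (se) {
    rep <- TMB::sdreport(obj)
    se_tab <- list(report = summary(rep, select = "report"),
                   fixed = summary(rep, select = "fixed"))
  }
  pl <- obj$env$parList(opt$par)
  eta <- pl$eta
  colnames(eta) <- c("ka", "Vd", "CL")
  rownames(eta) <- ti$ids
  # free-parameter bookkeeping for the corrected BIC
  free <- names(opt$par)
  n_omega <- sum(free == "log_omega")
  n_theta <- sum(free == "corr_theta")
  omega_free <- setdiff(c("ka", "Vd", "CL"), if (model == "1cmt") character(0) else "ka")
  re_fixed <- sum(c("log_ka", "log_Vd", "log_CL")[c("ka", "Vd", "CL") %in% omega_free]
                  %in% free)
  P_R <- n_omega + n_theta + re_fixed
  P_F <- length(free) - P_R
  list(drug = drug, model = model, opt = opt, sdr = se_tab,
       loglik = -opt$objective, eta = eta, ids = ti$ids,
       n_subj = ti$n_subj, n_obs = ti$n_obs, P_R = P_R, P_F = P_F,
       convergence = conv, map = setup$map, obj = obj)
}

# pull natural-scale estimates and RSE% out of a fitted drug component
extract_drug_params <- function(fd, retained_beta) {
  sr <- fd$sdr$report
  get <- function(name) sr[rownames(sr) == name, , drop = FALSE]
  omega <- get("omega")
  corr <- matrix(get("corr")[, "Estimate"], 3, 3,
                 dimnames = list(c("ka", "Vd", "CL"), c("ka", "Vd", "CL")))
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  fx <- fd$sdr$fixed
  beta <- numeric(0)
  beta_map <- c(ka_BW = "beta_ka_bw", Vd_BW = "beta_Vd_bw", CL_BW = "beta_CL_bw",
                ka_SEXM = "beta_ka_sex", Vd_SEXM = "beta_Vd_sex",
                CL_SEXM = "beta_CL_sex")
  rse_beta <- numeric(0)
  for (bn in retained_beta) {
    row <- fx[rownames(fx) == beta_map[bn], , drop = FALSE]
    if (nrow(row)) {
      beta[bn] <- row[1, "Estimate"]
      rse_beta[paste0("beta_", bn)] <- 100 * row[1, "Std. Error"] / abs(row[1, "Estimate"])
    }
  }
  dp <- drug_params(F_pop = get("F_pop")[1, "Estimate"],
                    ka_pop = get("ka_pop")[1, "Estimate"],
                    Vd_pop = get("Vd_pop")[1, "Estimate"],
                    CL_pop = get("CL_pop")[1, "Estimate"],
                    beta = beta, omega = stats::setNames(omega[, "Estimate"],
                                                         c("ka", "Vd", "CL")),
                    corr = corr, b = get("b_err")[1, "Estimate"])
  rse <- c(F = 100 * get("F_pop")[1, "Std. Error"] / get("F_pop")[1, "Estimate"],
           ka = 100 * get("ka_pop")[1, "Std. Error"] / get("ka_pop")[1, "Estimate"],
           Vd = 100 * get("Vd_pop")[1, "Std. Error"] / get("Vd_pop")[1, "Estimate"],
           CL = 100 * get("CL_pop")[1, "Std. Error"] / get("CL_pop")[1, "Estimate"],
           stats::setNames(100 * omega[, "Std. Error"] / pmax(omega[, "Estimate"], 1e-12),
                           c("omega_ka", "omega_Vd", "omega_CL")),
           b = 100 * get("b_err")[1, "Std. Error"] / get("b_err")[1, "Estimate"],
           rse_beta)
  list(params = dp, rse = rse)
}

#' Fit the population PK model
#'
#' Fits the hierarchical one-compartment model per drug by maximizing the
#' Laplace-approximated marginal likelihood: lognormal random effects on
#' `ka`, `Vd`, `CL` with a full (Cholesky-parameterized) correlation
#' matrix, logit-scale bioavailability, retained body-weight covariates
#' and proportional error with BLQ observations as left-censored mass.
#' TMP data from both cohorts are pooled into a single TMP model.
#'
#' @param data dataset in the [read_dataset()] layout (rows with
#'   `EXCLUDE == 1` are dropped).
#' @param drugs drugs to fit (default: all present).
#' @param model `"1cmt"` (default, both routes), or the IV-only
#'   comparators `"1cmt_iv"` / `"2cmt_iv"` used for structural model
#'   selection.
#' @param init optional [pop_params()] supplying starting values and the
#'   retained-covariate structure; by default starting values are
#'   naive-pooled NCA-style estimates ([nca_init()]) and the retained
#'   body-weight coefficients follow [boulanger2024()].
#' @param estimate_corr estimate random-effect correlations (default TRUE).
#' @param bw_median body-weight normalization constant (kg).
#' @param se compute standard errors / RSE% via the observed information
#'   (TMB sdreport); required for [extract_drug_params()]-based output.
#' @param control passed to [stats::nlminb()] (plus `quiet = TRUE` to
#'   silence non-convergence warnings).
#' @return An object of class `ts_fit` with elements `estimates`
#'   ([pop_params()]), `rse`, `loglik`, `bicc`, `ebes` (per-subject random
#'   effects and realized parameters), `convergence` and `info`.
#' @export
fit <- function(data, drugs = NULL, model = "1cmt", init = NULL,
                estimate_corr = TRUE, bw_median = 1.91, se = TRUE,
                control = list()) {
  stopifnot(model %in% c("1cmt", "1cmt_iv", "2cmt_iv"))
  drugs <- drugs %||% intersect(c("SDZ", "SMX", "TMP"), unique(data$DRUG))
  registry <- boulanger2024()
  fits <- list()
  for (drug in drugs) {
    start <- NULL
    if (inherits(init, "pop_params")) {
      p0 <- init$drugs[[drug]]
      start <- list(F = p0$F_pop, ka = p0$ka_pop, Vd = p0$Vd_pop,
                    CL = p0$CL_pop, omega = p0$omega, b = p0$b)
      rb <- names(p0$beta)
    } else {
      rb <- names(registry$drugs[[drug]]$beta)
    }
    if (model != "1cmt") rb <- setdiff(rb, c("ka_BW", "ka_SEXM"))
    fits[[drug]] <- fit_drug(data, drug, model = model, start = start,
                             retained_beta = rb, estimate_corr = estimate_corr,
                             bw_median = bw_median, se = se, control = control)
    fits[[drug]]$retained_beta <- rb
  }
  loglik <- sum(vapply(fits, `[[`, numeric(1), "loglik"))
  out <- list(fits = fits, loglik = loglik, bw_median = bw_median, model = model)
  if (se && model == "1cmt") {
    ex <- lapply(fits, function(fd) extract_drug_params(fd, fd$retained_beta))
    out$estimates <- pop_params(lapply(ex, `[[`, "params"), bw_median = bw_median)
    out$rse <- lapply(ex, `[[`, "rse")
    out$ebes <- ebe_table(fits, out$estimates, data)
  }
  out$convergence <- lapply(fits, `[[`, "convergence")
  out$info <- data.frame(
    drug = names(fits),
    n_subj = vapply(fits, `[[`, numeric(1), "n_subj"),
    n_obs = vapply(fits, `[[`, numeric(1), "n_obs"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    P_R = vapply(fits, `[[`, numeric(1), "P_R"),
    P_F = vapply(fits, `[[`, numeric(1), "P_F"))
  class(out) <- "ts_fit"
  out$bicc <- bicc(out)
  out
}

ebe_table <- function(fits, estimates, data) {
  rows <- list()
  for (drug in names(fits)) {
    fd <- fits[[drug]]
    sub <- data[!duplicated(data$ID), c("ID", "BW", "SEX", "COHORT")]
    for (j in seq_along(fd$ids)) {
      id <- fd$ids[j]
      s <- sub[sub$ID == id, ]
      sj <- subject(id, s$BW, s$SEX, s$COHORT)
      ip <- individual_params(estimates, drug, sj, fd$eta[j, ])
      perkg <- attr(ip, "per_kg")
      rows[[length(rows) + 1L]] <- data.frame(
        ID = id, DRUG = drug, BW = s$BW, SEX = s$SEX,
        eta_ka = fd$eta[j, "ka"], eta_Vd = fd$eta[j, "Vd"],
        eta_CL = fd$eta[j, "CL"], F_i = ip$F, ka_i = ip$ka,
        Vd_i_L = ip$Vd, CL_i_Lh = ip$CL,
        Vd_i_perkg = unname(perkg["Vd"]), CL_i_perkg = unname(perkg["CL"]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Corrected BIC for a fitted model
#'
#' Hybrid-penalty BIC for nonlinear mixed-effects models:
#' `-2 loglik + P_R log(N_subjects) + P_F log(N_obs)`, where `P_R` counts
#' parameters tied to the random-effect distribution (fixed effects of
#' parameters carrying random effects, variances and correlations) and
#' `P_F` counts purely fixed parameters (bioavailability, covariate
#' coefficients, residual error, peripheral-compartment constants). For a
#' multi-drug fit the per-drug criteria are summed.
#'
#' @param fitres a `ts_fit` object.
#' @return Scalar BICc; per-drug values in attribute `"by_drug"`.
#' @export
bicc <- function(fitres) {
  stopifnot(inherits(fitres, "ts_fit"))
  per <- vapply(fitres$fits, function(fd) {
    -2 * fd$loglik + fd$P_R * log(fd$n_subj) + fd$P_F * log(fd$n_obs)
  }, numeric(1))
  structure(sum(per), by_drug = per)
}

#' @export
print.ts_fit <- function(x, ...) {
  cat(sprintf("ts_fit (%s): loglik = %.2f, BICc = %.2f\n", x$model,
              x$loglik, as.numeric(x$bicc)))
  print(x$info, row.names = FALSE)
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fitres a `ts_fit` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fitres, path) {
  stopifnot(inherits(fitres, "ts_fit"))
  out <- list(model = fitres$model, loglik = fitres$loglik,
              bicc = as.numeric(fitres$bicc),
              bicc_by_drug = as.list(attr(fitres$bicc, "by_drug")),
              info = fitres$info, convergence = fitres$convergence)
  if (!is.null(fitres$estimates)) {
    out$estimates <- lapply(fitres$estimates$drugs, function(p) {
      list(F_pop = p$F_pop, ka_pop = p$ka_pop, Vd_pop = p$Vd_pop,
           CL_pop = p$CL_pop, beta = as.list(p$beta), omega = as.list(p$omega),
           corr = unname(p$corr), b = p$b)
    })
    out$rse <- lapply(fitres$rse, as.list)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
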