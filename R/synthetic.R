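# Synthetic-study generator emulating the broiler crossover experiment:
# two cohorts (TMP/SDZ n = 19, TMP/SMX n = 20), each bird receiving a
# single IV and a single oral dose in a two-period crossover separated by
# a 5-day washout, sparse sampling of 7-8 of the 15 nominal times per
# period, proportional residual error and LOQ censoring.

#' Study design description
#'
#' Defaults reproduce the crossover broiler experiment: IV doses of
#' 32 mg/kg sulfonamide + 6.4 mg/kg TMP; oral doses of 29.2 + 5.8 mg/kg
#' (SDZ cohort) or 37.5 + 7.5 mg/kg (SMX cohort); nominal sampling times
#' 0.083 (IV only), 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24,
#' 32 h; 7-8 samples per bird per period; 5-day washout. Body weights are
#' drawn from truncated normals spanning each cohort's observed range.
#'
#' @param n_sdz,n_smx cohort sizes.
#' @param males_sdz,males_smx number of males per cohort.
#' @param loq named vector of quantification limits (ug/mL) per drug.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_sdz = 19, n_smx = 20, males_sdz = 13, males_smx = 9,
                         loq = c(SDZ = 0.02, SMX = 0.02, TMP = 0.004)) {
  structure(list(
    nominal_times = c(0.083, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24, 32),
    iv_only_times = 0.083,
    samples_per_period = c(7L, 8L),
    washout_h = 5 * 24,
    last_sample_h = 32,
    loq = loq,
    cohorts = list(
      TMP_SDZ = list(n = n_sdz, males = males_sdz, s_drug = "SDZ",
                     iv = c(S = 32, TMP = 6.4), oral = c(S = 29.2, TMP = 5.8),
                     bw_mean = 1.90, bw_sd = 0.45, bw_range = c(1.07, 2.98)),
      TMP_SMX = list(n = n_smx, males = males_smx, s_drug = "SMX",
                     iv = c(S = 32, TMP = 6.4), oral = c(S = 37.5, TMP = 7.5),
                     bw_mean = 2.25, bw_sd = 0.20, bw_range = c(1.86, 2.65))
    )
  ), class = "study_design")
}

#' Sparse sampling-time allocation
#'
#' Assigns each bird 7-8 of the nominal times for one study period using a
#' cyclic (latin-square-style) allocation: consecutive blocks of the
#' nominal-time list wrap around the cohort, so every nominal time is
#' covered and per-time usage counts differ by at most 2 across times.
#' The 0.083 h sample is available only in IV periods.
#'
#' @param n_birds number of birds.
#' @param route `"IV"` or `"ORAL"` (controls the 0.083 h availability).
#' @param design a [study_design()].
#' @param n_per_bird optional integer vector (7 or 8) per bird; sampled
#'   uniformly when `NULL`.
#' @param seed optional seed.
#' @return List of numeric time vectors, one per bird.
#' @export
sampling_schedule <- function(n_birds, route = c("IV", "ORAL"),
                              design = study_design(), n_per_bird = NULL,
                              seed = NULL) {
  route <- match.arg(route)
  pool <- design$nominal_times
  if (route == "ORAL") pool <- setdiff(pool, design$iv_only_times)
  with_seed(seed, {
    if (is.null(n_per_bird)) {
      n_per_bird <- sample(design$samples_per_period, n_birds, replace = TRUE)
    }
    stopifnot(all(n_per_bird %in% design$samples_per_period))
    np <- length(pool)
    cursor <- sample.int(np, 1) - 1L
    out <- vector("list", n_birds)
    for (i in seq_len(n_birds)) {
      idx <- (cursor + seq_len(n_per_bird[i]) - 1L) %% np + 1L
      cursor <- (cursor + n_per_bird[i]) %% np
      out[[i]] <- sort(pool[idx])
    }
    out
  })
}

#' Generate a complete synthetic crossover study
#'
#' Draws subjects (body weight, sex), correlated random effects (TMP
#' effects drawn once per bird and shared across periods), builds true
#' concentration curves by superposition over both crossover periods,
#' applies proportional residual noise `y = f * (1 + b * eps)` and flags
#' observations below the drug's LOQ (or negative) as left-censored. The
#' result is an estimation-ready event/observation table; the simulation
#' truth (subjects, random effects) is attached as attribute `"truth"`.
#'
#' @param design a [study_design()].
#' @param pop a [pop_params()] parameter set.
#' @param seed integer seed for full reproducibility.
#' @param contamination optional `list(fraction =, multiplier =)` adding
#'   multiplicative outliers to test exclusion handling (off by default).
#' @return A `data.frame` with columns `ID, TIME, AMT, ROUTE, DV, BLQ,
#'   LOQ, DRUG, BW, SEX, COHORT, EXCLUDE`; dose rows carry `AMT` and no
#'   `DV`, observation rows the reverse. `TIME` is absolute study time
#'   (period 2 starts after the washout).
#' @export
generate_study <- function(design = study_design(), pop = boulanger2024(),
                           seed = NULL, contamination = NULL) {
  with_seed(seed, {
    rows <- list()
    truth <- list()
    p2_offset <- design$last_sample_h + design$washout_h
    id0 <- 0L
    for (cohort in names(design$cohorts)) {
      ch <- design$cohorts[[cohort]]
      s_drug <- ch$s_drug
      n <- ch$n
      bw <- rtruncnorm(n, ch$bw_mean, ch$bw_sd, ch$bw_range[1], ch$bw_range[2])
      sex <- sample(c(rep("M", ch$males), rep("F", n - ch$males)))
      iv_first <- sample(rep(c(TRUE, FALSE), length.out = n))
      eta_s <- sample_etas(pop, s_drug, n)
      eta_t <- sample_etas(pop, "TMP", n)
      sched_iv <- sampling_schedule(n, "IV", design)
      sched_or <- sampling_schedule(n, "ORAL", design)
      truth[[cohort]] <- list(
        subjects = data.frame(ID = id0 + seq_len(n), BW = bw, SEX = sex,
                              COHORT = cohort, IV_FIRST = iv_first),
        eta = stats::setNames(list(eta_s, eta_t), c(s_drug, "TMP"))
      )
      for (i in seq_len(n)) {
        id <- id0 + i
        subj <- subject(id, bw[i], sex[i], cohort)
        ip <- list(individual_params(pop, s_drug, subj, eta_s[i, ]),
                   individual_params(pop, "TMP", subj, eta_t[i, ]))
        names(ip) <- c(s_drug, "TMP")
        per_route <- if (iv_first[i]) c("IV", "ORAL") else c("ORAL", "IV")
        offs <- c(0, p2_offset)
        for (drug in c(s_drug, "TMP")) {
          dkey <- if (drug == "TMP") "TMP" else "S"
          events <- data.frame(
            time = offs,
            amount = ifelse(per_route == "IV", ch$iv[dkey], ch$oral[dkey]) * bw[i],
            route = per_route)
          for (per in 1:2) {
            rows[[length(rows) + 1L]] <- data.frame(
              ID = id, TIME = offs[per], AMT = events$amount[per],
              ROUTE = per_route[per], DV = NA_real_, BLQ = NA_integer_,
              LOQ = NA_real_, DRUG = drug, BW = bw[i], SEX = sex[i],
              COHORT = cohort, EXCLUDE = 0L)
            tau <- if (per_route[per] == "IV") sched_iv[[i]] else sched_or[[i]]
            f <- superpose(events, ip[[drug]], offs[per] + tau)
            b <- pop$drugs[[drug]]$b
            y <- f * (1 + b * stats::rnorm(length(f)))
            loq <- design$loq[[drug]]
            blq <- y < loq
            rows[[length(rows) + 1L]] <- data.frame(
              ID = id, TIME = offs[per] + tau, AMT = NA_real_,
              ROUTE = per_route[per], DV = ifelse(blq, NA_real_, y),
              BLQ = as.integer(blq), LOQ = loq, DRUG = drug, BW = bw[i],
              SEX = sex[i], COHORT = cohort, EXCLUDE = 0L)
          }
        }
      }
      id0 <- id0 + n
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$ID, out$DRUG, out$TIME, is.na(out$AMT)), ]
    rownames(out) <- NULL
    if (!is.null(contamination)) {
      obs <- which(is.na(out$AMT) & out$BLQ == 0L)
      k <- max(1L, round(contamination$fraction * length(obs)))
      pick <- sample(obs, k)
      out$DV[pick] <- out$DV[pick] * contamination$multiplier
      attr(out, "contaminated_rows") <- pick
    }
    attr(out, "truth") <- truth
    class(out) <- c("pk_dataset", class(out))
    out
  })
}
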