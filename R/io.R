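# Dataset reading/validation/writing and the end-to-end pipeline driver.
# One canonical CSV dialect: comma-separated, period decimal, UTF-8,
# header row required; times in hours, concentrations in ug/mL, doses in
# mg. Unit conversions happen only at this boundary.

DATASET_COLUMNS <- c("ID", "TIME", "AMT", "ROUTE", "DV", "BLQ", "LOQ",
                     "DRUG", "BW", "SEX", "COHORT", "EXCLUDE")

#' Validate an event/observation dataset
#'
#' Hard schema validation of the flat event-stream layout: dose rows
#' carry `AMT` and no `DV`; observation rows carry no `AMT`; BLQ rows
#' carry no `DV`; uncensored `DV` must be `>= LOQ`; route/drug/sex values
#' must come from their enumerations. Violations raise a single error
#' itemizing the offending row numbers.
#'
#' @param data data frame in the [read_dataset()] column layout.
#' @return `data`, classed `pk_dataset`, invisibly usable downstream; a
#'   per-column summary is attached as attribute `"summary"`.
#' @export
validate_dataset <- function(data) {
  miss <- setdiff(DATASET_COLUMNS, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  probs <- character(0)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) probs <<- c(probs, sprintf("%s (rows %s)", msg,
      paste(utils::head(rows, 10), collapse = ", ")))
  }
  dose <- !is.na(data$AMT)
  bad(!data$ROUTE %in% c("IV", "ORAL"), "ROUTE must be IV or ORAL")
  bad(!data$DRUG %in% c("SDZ", "SMX", "TMP"), "unknown DRUG")
  bad(!data$SEX %in% c("M", "F"), "SEX must be M or F")
  bad(!data$COHORT %in% c("TMP_SDZ", "TMP_SMX"), "unknown COHORT")
  bad(dose & data$AMT <= 0, "dose rows must have AMT > 0")
  bad(dose & !is.na(data$DV), "dose rows must not carry DV")
  bad(!dose & is.na(data$BLQ), "observation rows need BLQ 0/1")
  bad(!dose & !is.na(data$BLQ) & data$BLQ == 1 & !is.na(data$DV),
      "BLQ rows must not carry DV")
  bad(!dose & !is.na(data$BLQ) & data$BLQ == 0 &
        (is.na(data$DV) | is.na(data$LOQ) | data$DV < data$LOQ),
      "uncensored DV must be present and >= LOQ")
  bad(!is.finite(data$TIME) | data$TIME < 0, "TIME must be finite and >= 0")
  bad(!is.finite(data$BW) | data$BW <= 0, "BW must be positive")
  bad(!data$EXCLUDE %in% c(0, 1), "EXCLUDE must be 0/1")
  if (length(probs)) {
    stop("dataset validation failed:\n  - ", paste(probs, collapse = "\n  - "),
         call. = FALSE)
  }
  smry <- data.frame(
    drug = sort(unique(data$DRUG)),
    n_obs = vapply(sort(unique(data$DRUG)), function(d)
      sum(!dose & data$DRUG == d), numeric(1)),
    n_blq = vapply(sort(unique(data$DRUG)), function(d)
      sum(!dose & data$DRUG == d & data$BLQ == 1), numeric(1)),
    n_dose = vapply(sort(unique(data$DRUG)), function(d)
      sum(dose & data$DRUG == d), numeric(1)))
  attr(data, "summary") <- smry
  if (!inherits(data, "pk_dataset")) class(data) <- c("pk_dataset", class(data))
  data
}

#' Read and validate a dataset CSV
#'
#' @param path CSV file in the documented column contract (`ID, TIME,
#'   AMT, ROUTE, DV, BLQ, LOQ, DRUG, BW, SEX, COHORT, EXCLUDE`).
#' @param verbose print the per-column summary.
#' @return A validated `pk_dataset` data frame.
#' @export
read_dataset <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  data <- validate_dataset(data)
  if (verbose) {
    message("dataset ", path, ":")
    for (i in seq_len(nrow(attr(data, "summary")))) {
      s <- attr(data, "summary")[i, ]
      message(sprintf("  %s: %d obs (%d BLQ), %d dose events",
                      s$drug, s$n_obs, s$n_blq, s$n_dose))
    }
  }
  data
}

#' Write a dataset CSV (and optional simulation-truth sidecar)
#'
#' @param data a `pk_dataset` data frame.
#' @param path output CSV.
#' @param truth_path optional JSON path for the simulation truth attached
#'   by [generate_study()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, truth_path = NULL) {
  utils::write.csv(data[, DATASET_COLUMNS], path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- attr(data, "truth")
    if (is.null(truth)) stop("no simulation truth attached to 'data'", call. = FALSE)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run the full pipeline: generate, fit, diagnose, simulate
#'
#' Drives the standard analysis end to end and writes all artifacts under
#' `config$out_dir`: the (synthetic or provided) dataset, the fit result
#' JSON and EBE table, VPC/NPDE diagnostics, flock-simulation summaries
#' and a manifest recording the configuration and seeds. Outputs are
#' deterministic given the same configuration.
#'
#' @param config list with elements `out_dir`; `seed`; optional
#'   `dataset` (path to an existing CSV; otherwise a synthetic study is
#'   generated); `params` (`"boulanger2024"`, a [pop_params()] or a JSON
#'   path) used for simulation-based stages; `nsim_vpc` (default 300);
#'   `nsim_npde` (default 500); `flock_n` (default 1000);
#'   `estimate_corr` (default TRUE).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir), !is.null(config$seed))
  if (!is.null(config$params) && is.character(config$params) &&
      config$params != "boulanger2024" && !file.exists(config$params)) {
    stop("parameter file not found: ", config$params, call. = FALSE)
  }
  if (!is.null(config$dataset) && !file.exists(config$dataset)) {
    stop("dataset file not found: ", config$dataset, call. = FALSE)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pop <- config$params %||% "boulanger2024"
  if (is.character(pop)) {
    pop <- if (pop == "boulanger2024") boulanger2024() else read_pop_params(pop)
  }
  seed <- as.integer(config$seed)
  # 1. data
  if (is.null(config$dataset)) {
    data <- generate_study(pop = pop, seed = seed)
    write_dataset(data, file.path(out, "dataset.csv"),
                  truth_path = file.path(out, "truth.json"))
  } else {
    data <- read_dataset(config$dataset)
  }
  # 2. fit
  fitres <- fit(data, estimate_corr = config$estimate_corr %||% TRUE,
                control = list(quiet = TRUE))
  write_fit_json(fitres, file.path(out, "fit.json"))
  utils::write.csv(fitres$ebes, file.path(out, "ebes.csv"), row.names = FALSE)
  # 3. diagnostics
  nsim_vpc <- config$nsim_vpc %||% 300
  for (drug in names(fitres$fits)) {
    vpc <- pcvpc(fitres, data, drug, nsim = nsim_vpc,
                 seed = sub_seed(seed, paste0("vpc", drug)))
    write_vpc_csv(vpc, file.path(out, sprintf("vpc_%s.csv", drug)))
    nd <- suppressWarnings(
      npde(fitres, data, drug, nsim = config$nsim_npde %||% 500,
           seed = sub_seed(seed, paste0("npde", drug))))
    utils::write.csv(nd, file.path(out, sprintf("npde_%s.csv", drug)),
                     row.names = FALSE)
  }
  # 4. flock simulations at the registered oral doses
  regs <- list(
    TMP_SDZ = regimen_spec("SDZ", 25, 5, n = config$flock_n %||% 1000,
                           seed = sub_seed(seed, "flockSDZ")),
    TMP_SMX = regimen_spec("SMX", 37.5, 7.5, n = config$flock_n %||% 1000,
                           seed = sub_seed(seed, "flockSMX")))
  attain <- list()
  for (nm in names(regs)) {
    fs <- simulate_flock(fitres$estimates, regs[[nm]])
    write_flock_csv(fs,
                    file.path(out, sprintf("flock_%s_percentiles.csv", nm)),
                    file.path(out, sprintf("flock_%s_attainment.csv", nm)))
    attain[[nm]] <- fs$fraction_attained
  }
  manifest <- list(seed = seed, config = config[setdiff(names(config), "out_dir")],
                   package_version = as.character(utils::packageVersion("sulfatrim")),
                   fraction_attained = attain)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
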