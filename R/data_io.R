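#' Run configuration for reading pharmacometric datasets
#'
#' Describes how a NONMEM-style flat CSV maps onto the internal dataset:
#' which numeric `DVID` codes tag which observation stream, which columns are
#' subject-level covariates, and the unit labels. Can be loaded from a YAML
#' file with the same field names.
#'
#' @param stream_map Named character vector mapping DVID codes (as names) to
#'   stream tags, default `c("1" = "total", "2" = "unbound")`.
#' @param covariates Character vector of covariate column names, or `NULL`
#'   to treat every column beyond the reserved NONMEM columns as a covariate.
#' @param units Named list of unit labels (documentation only; the package
#'   works internally in h, mg, mg/L).
#' @param file Optional path to a YAML file whose fields override the
#'   arguments above.
#' @return A list of class `pk_config`.
#' @export
pk_config <- function(stream_map = c("1" = "total", "2" = "unbound"),
                      covariates = NULL,
                      units = list(conc = "mg/L", time = "h", dose = "mg"),
                      file = NULL) {
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$stream_map)) stream_map <- unlist(y$stream_map)
    if (!is.null(y$covariates)) covariates <- unlist(y$covariates)
    if (!is.null(y$units)) units <- y$units
  }
  structure(list(stream_map = stream_map, covariates = covariates,
                 units = units), class = "pk_config")
}

.reserved_cols <- c("ID", "TIME", "AMT", "EVID", "DV", "DVID", "MDV")

#' Construct and validate a PK dataset
#'
#' Internal container used throughout the package: long-format observation
#' and dosing tables plus one row of covariates per subject. Enforced
#' invariants: every subject has at least one dose and one observation,
#' observation times are not before the subject's first dose, stream tags
#' are among the declared streams, and non-missing concentrations are
#' strictly positive (the data are modelled on the log scale).
#'
#' @param obs Data frame with columns `ID`, `TIME`, `DV`, `stream`, `MDV`.
#' @param doses Data frame with columns `ID`, `TIME`, `AMT`.
#' @param covariates Data frame with column `ID` plus one column per
#'   covariate (one row per subject), or `NULL`.
#' @param streams Character vector of declared stream tags.
#' @param units Unit labels (see [pk_config()]).
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(obs, doses, covariates = NULL,
                       streams = c("total", "unbound"),
                       units = list(conc = "mg/L", time = "h", dose = "mg")) {
  obs <- as.data.frame(obs); doses <- as.data.frame(doses)
  need_obs <- c("ID", "TIME", "DV", "stream", "MDV")
  if (!all(need_obs %in% names(obs))) {
    stop("obs needs columns: ", paste(need_obs, collapse = ", "))
  }
  if (!all(c("ID", "TIME", "AMT") %in% names(doses))) {
    stop("doses needs columns ID, TIME, AMT")
  }
  if (nrow(obs) == 0L || nrow(doses) == 0L) {
    stop("every subject must have at least one dosing event and one observation")
  }
  ids <- sort(unique(c(obs$ID, doses$ID)))
  if (!all(obs$ID %in% doses$ID)) {
    stop("every subject must have at least one dosing event")
  }
  if (!all(doses$ID %in% obs$ID)) {
    stop("every subject must have at least one observation")
  }
  if (any(doses$AMT <= 0)) stop("dose amounts must be > 0")
  if (!all(obs$stream %in% streams)) {
    stop("observation stream tags must be among: ", paste(streams, collapse = ", "))
  }
  bad <- which(obs$MDV == 0 & (!is.finite(obs$DV) | obs$DV <= 0))
  if (length(bad)) {
    stop("non-positive observed concentration with MDV = 0 in observation row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  first_dose <- tapply(doses$TIME, doses$ID, min)
  if (any(obs$TIME < first_dose[as.character(obs$ID)] - 1e-9)) {
    stop("observation before the subject's first dose")
  }
  o <- order(obs$ID, obs$TIME, obs$stream)
  obs <- obs[o, , drop = FALSE]
  doses <- doses[order(doses$ID, doses$TIME), , drop = FALSE]
  rownames(obs) <- rownames(doses) <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"ID" %in% names(covariates)) stop("covariates needs an ID column")
    if (anyDuplicated(covariates$ID)) stop("one covariate row per subject")
    covariates <- covariates[match(ids, covariates$ID), , drop = FALSE]
    rownames(covariates) <- NULL
  }
  structure(list(obs = obs, doses = doses, covariates = covariates,
                 streams = streams, units = units, ids = ids),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("PK dataset: %d subjects, %d observation rows (%s), %d dosing events\n",
              length(x$ids), nrow(x$obs),
              paste(x$streams, collapse = " + "), nrow(x$doses)))
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(setdiff(names(x$covariates), "ID"),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of subjects in a PK dataset
#' @param data A [pk_dataset()].
#' @return Integer subject count.
#' @export
n_subjects <- function(data) length(data$ids)

#' Read a NONMEM-style CSV into a PK dataset
#'
#' Expects one row per event with columns `ID`, `TIME`, `AMT`, `EVID`, `DV`,
#' `DVID`, `MDV` plus any covariate columns. Dosing rows have `EVID = 1`,
#' observation rows `EVID = 0`; `DVID` is mapped to stream tags through the
#' configuration. Rows flagged `MDV = 1` are retained but excluded from the
#' likelihood by every downstream consumer.
#'
#' @param path Path to the CSV file.
#' @param config A [pk_config()].
#' @return A validated [pk_dataset()].
#' @export
read_pk_dataset <- function(path, config = pk_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  missing_cols <- setdiff(.reserved_cols, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  obs_rows <- raw[raw$EVID == 0, , drop = FALSE]
  dose_rows <- raw[raw$EVID == 1, , drop = FALSE]
  dvid_chr <- as.character(obs_rows$DVID)
  unknown <- setdiff(unique(dvid_chr), names(config$stream_map))
  if (length(unknown)) {
    stop("validation error: unknown DVID code(s): ",
         paste(unknown, collapse = ", "))
  }
  obs <- data.frame(ID = obs_rows$ID, TIME = obs_rows$TIME, DV = obs_rows$DV,
                    stream = unname(config$stream_map[dvid_chr]),
                    MDV = obs_rows$MDV)
  obs$DV[is.na(obs$DV)] <- NA_real_
  doses <- data.frame(ID = dose_rows$ID, TIME = dose_rows$TIME,
                      AMT = dose_rows$AMT)
  cov_cols <- config$covariates
  if (is.null(cov_cols)) cov_cols <- setdiff(names(raw), .reserved_cols)
  covariates <- NULL
  if (length(cov_cols)) {
    missing_cov <- setdiff(cov_cols, names(raw))
    if (length(missing_cov)) {
      stop("schema error: configured covariate column(s) absent: ",
           paste(missing_cov, collapse = ", "))
    }
    covariates <- unique(raw[, c("ID", cov_cols), drop = FALSE])
    covariates <- covariates[!duplicated(covariates$ID), , drop = FALSE]
  }
  pk_dataset(obs, doses, covariates,
             streams = unique(unname(config$stream_map)),
             units = config$units)
}

#' Write a PK dataset back to NONMEM-style CSV
#'
#' Inverse of [read_pk_dataset()]: one row per dosing or observation event,
#' covariates repeated on each row. `read_pk_dataset(write_pk_dataset(x))`
#' reproduces `x`.
#'
#' @param data A [pk_dataset()].
#' @param path Output CSV path.
#' @param config A [pk_config()] (used for the stream -> DVID mapping).
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path, config = pk_config()) {
  inv_map <- setNames(names(config$stream_map), unname(config$stream_map))
  obs <- data.frame(ID = data$obs$ID, TIME = data$obs$TIME, AMT = NA_real_,
                    EVID = 0L, DV = data$obs$DV,
                    DVID = as.integer(inv_map[data$obs$stream]),
                    MDV = data$obs$MDV)
  dose <- data.frame(ID = data$doses$ID, TIME = data$doses$TIME,
                     AMT = data$doses$AMT, EVID = 1L, DV = NA_real_,
                     DVID = NA_integer_, MDV = 1L)
  all_rows <- rbind(dose, obs)
  all_rows <- all_rows[order(all_rows$ID, all_rows$TIME, -all_rows$EVID), ]
  if (!is.null(data$covariates)) {
    all_rows <- merge(all_rows, data$covariates, by = "ID", sort = FALSE)
    all_rows <- all_rows[order(all_rows$ID, all_rows$TIME, -all_rows$EVID), ]
  }
  .write_csv_precise(all_rows, path)
  invisible(path)
}

# write.csv at full double precision (%.17g) so round-trips are exact
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- sprintf("%.17g", out[[j]])
      x[is.na(out[[j]])] <- NA
      out[[j]] <- x
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Impute missing continuous covariates with the population median
#'
#' Each missing covariate value is replaced by the median (continuous) or
#' mode (binary 0/1) over subjects with observed values. A warning is issued
#' when more than 2% of a covariate's values are missing, the regime beyond
#' which median imputation was considered acceptable in this analysis.
#'
#' @param data A [pk_dataset()] with covariates.
#' @return A list with elements `data` (imputed dataset) and `report`
#'   (data frame: covariate, n_imputed, imputed_value, missing_fraction).
#' @export
impute_missing_covariates <- function(data) {
  stopifnot(inherits(data, "pk_dataset"))
  if (is.null(data$covariates)) stop("dataset has no covariates")
  cv <- data$covariates
  report <- data.frame(covariate = character(), n_imputed = integer(),
                       imputed_value = numeric(), missing_fraction = numeric(),
                       stringsAsFactors = FALSE)
  for (cn in setdiff(names(cv), "ID")) {
    x <- cv[[cn]]
    if (!is.numeric(x)) next
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stop("covariate '", cn, "' is entirely missing")
    obs_vals <- x[!miss]
    val <- if (all(obs_vals %in% c(0, 1))) {
      as.numeric(names(which.max(table(obs_vals))))  # mode for binaries
    } else {
      median(obs_vals)
    }
    frac <- mean(miss)
    if (frac > 0.02) {
      warning(sprintf("covariate '%s': %.1f%% missing exceeds the 2%% regime",
                      cn, 100 * frac))
    }
    cv[[cn]][miss] <- val
    report <- rbind(report, data.frame(covariate = cn, n_imputed = sum(miss),
                                       imputed_value = val,
                                       missing_fraction = frac))
  }
  data$covariates <- cv
  list(data = data, report = report)
}

#' Write fit or simulation results to CSV files plus a run manifest
#'
#' For a fitted model ([saem_fit()] result) writes parameter estimates,
#' relative standard errors, empirical Bayes estimates and the iteration
#' trace; for a dosing-simulation summary writes the regimen-by-metric
#' percentile table. A JSON manifest records the seed, package version and
#' object type so a result directory is self-describing. Numeric values are
#' written at full double precision; [read_results()] reproduces the fitted
#' estimates field-for-field.
#'
#' @param x A `pk_fit` or `simulation_summary` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("I/O error: cannot create directory ", dir)
  manifest <- list(package = "pamipk",
                   version = as.character(utils::packageVersion("pamipk")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   type = class(x)[1], seed = x$seed)
  if (inherits(x, "pk_fit")) {
    .write_csv_precise(flatten_params(x$estimates, as_df = TRUE),
                       file.path(dir, "estimates.csv"))
    if (!is.null(x$rse)) {
      .write_csv_precise(data.frame(parameter = names(x$rse),
                                    rse_percent = unname(x$rse)),
                         file.path(dir, "rse.csv"))
    }
    if (!is.null(x$ebes)) .write_csv_precise(x$ebes, file.path(dir, "ebes.csv"))
    if (!is.null(x$trace)) .write_csv_precise(x$trace, file.path(dir, "trace.csv"))
    manifest$ofv <- x$ofv
    manifest$n_subjects <- x$n_subjects
  } else if (inherits(x, "simulation_summary")) {
    .write_csv_precise(x$table, file.path(dir, "percentiles.csv"))
    manifest$n_datasets <- x$n_datasets
    manifest$n_subjects <- x$n_subjects
  } else {
    stop("write_results supports pk_fit and simulation_summary objects")
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a result directory written by [write_results()]
#'
#' @param dir Directory previously written by [write_results()].
#' @return For a `pk_fit` manifest: a list with `estimates`
#'   (a [pop_params()]), `rse`, `ebes`, `trace`, `ofv`, `seed`. For a
#'   simulation summary: the percentile table plus metadata.
#' @export
read_results <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (identical(manifest$type, "pk_fit")) {
    est <- read.csv(file.path(dir, "estimates.csv"), stringsAsFactors = FALSE)
    out <- list(estimates = unflatten_params(est), seed = manifest$seed,
                ofv = manifest$ofv)
    rse_path <- file.path(dir, "rse.csv")
    if (file.exists(rse_path)) {
      r <- read.csv(rse_path)
      out$rse <- setNames(r$rse_percent, r$parameter)
    }
    for (f in c("ebes", "trace")) {
      p <- file.path(dir, paste0(f, ".csv"))
      if (file.exists(p)) out[[f]] <- read.csv(p)
    }
    out
  } else {
    list(table = read.csv(file.path(dir, "percentiles.csv"),
                          check.names = FALSE),
         n_datasets = manifest$n_datasets, n_subjects = manifest$n_subjects,
         seed = manifest$seed)
  }
}

# Flatten a pop_params object to a named vector (or two-column data frame)
# and back. Names: theta.Ka, omega.CL, beta.V.PCC, error.total.a, ...
flatten_params <- function(pop, as_df = FALSE) {
  v <- c(setNames(pop$theta, paste0("theta.", names(pop$theta))),
         setNames(pop$omegas, paste0("omega.", names(pop$omegas))))
  if (!is.null(pop$betas)) {
    v <- c(v, setNames(pop$betas$beta, paste0("beta.", pop$betas$parameter,
                                              ".", pop$betas$covariate)))
  }
  for (s in names(pop$error)) {
    v <- c(v, setNames(pop$error[[s]], paste0("error.", s, ".",
                                              names(pop$error[[s]]))))
  }
  if (as_df) data.frame(parameter = names(v), value = unname(v)) else v
}

unflatten_params <- function(df) {
  v <- setNames(df$value, df$parameter)
  nm <- names(v)
  theta <- v[startsWith(nm, "theta.")]
  names(theta) <- sub("^theta\\.", "", names(theta))
  omegas <- v[startsWith(nm, "omega.")]
  names(omegas) <- sub("^omega\\.", "", names(omegas))
  beta_nm <- nm[startsWith(nm, "beta.")]
  betas <- NULL
  if (length(beta_nm)) {
    parts <- strsplit(sub("^beta\\.", "", beta_nm), ".", fixed = TRUE)
    betas <- data.frame(parameter = vapply(parts, `[`, "", 1),
                        covariate = vapply(parts, `[`, "", 2),
                        beta = unname(v[beta_nm]))
  }
  err_nm <- nm[startsWith(nm, "error.")]
  error <- list()
  for (en in err_nm) {
    parts <- strsplit(sub("^error\\.", "", en), ".", fixed = TRUE)[[1]]
    error[[parts[1]]][parts[2]] <- v[[en]]
  }
  pop_params(theta = theta, betas = betas, omegas = omegas, error = error)
}
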