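# one quantile convention everywhere: median-unbiased (type 8)
q8 <- function(x, probs) quantile(x, probs, type = 8, names = FALSE)

#' Goodness-of-fit table
#'
#' Per observation: the population prediction (random effects at 0,
#' covariates applied), the individual prediction (empirical Bayes
#' estimates), and the individual weighted residual
#' `IWRES = (log y - log ipred) / sigma(ipred)` on the log scale of the
#' fitted error model. The summary attribute reports the mean IWRES per
#' stream.
#'
#' @param fit A `pk_fit` with EBEs (or supply `ebes`).
#' @param data The fitted [pk_dataset()].
#' @param ebes Optional EBE data frame overriding `fit$ebes`.
#' @return Data frame: `ID`, `TIME`, `stream`, `DV`, `pred`, `ipred`,
#'   `iwres`; attribute `summary` with the per-stream mean IWRES.
#' @export
gof_tables <- function(fit, data, ebes = NULL) {
  pop <- if (inherits(fit, "pk_fit")) fit$estimates else fit
  if (is.null(ebes)) ebes <- fit$ebes
  if (is.null(ebes)) stop("fit carries no EBEs; run with ebe_draws > 0 or pass ebes")
  ctx <- build_fit_context(data)
  if (!all(ctx$ids %in% ebes$ID)) stop("missing EBE record for some subject(s)")
  mu <- .subject_mu(ctx, pop)
  pars <- names(pop$theta)
  pred <- .ctx_predict(ctx, exp(mu))
  psi_i <- as.matrix(ebes[match(ctx$ids, ebes$ID), pars])
  ipred <- .ctx_predict(ctx, psi_i)
  oe <- .obs_error(ctx, pop$error)
  sig <- oe$a / ipred + oe$b
  iwres <- (ctx$logdv - log(ipred)) / sig
  out <- data.frame(ID = ctx$ids[ctx$sid], TIME = ctx$time,
                    stream = ctx$streams[ctx$stream_idx],
                    DV = exp(ctx$logdv), pred = pred, ipred = ipred,
                    iwres = iwres)
  attr(out, "summary") <- aggregate(iwres ~ stream, out, mean)
  out
}

#' Nonparametric bootstrap of the population parameters
#'
#' Subjects are the resampling unit: each replicate draws `n` subject slots
#' with replacement (covariates travel with their subject), the model is
#' refitted by [saem_fit()] with the supplied (typically reduced) iteration
#' budget, and the replicate estimates are pooled into medians and
#' percentile 95% confidence intervals. Replicates whose refit fails are
#' recorded and excluded; more than 10% failures triggers a warning.
#'
#' @param data A [pk_dataset()].
#' @param init A [pop_params()]: the final model structure and starting
#'   values (bootstrap replicates inherit the covariate structure; no
#'   re-selection).
#' @param n_resamples Number of bootstrap replicates (500 in the full
#'   analysis; reduce for desk-scale checks).
#' @param seed Integer seed (drives both the resampling and the refits).
#' @param opts [saem_options()] for the replicate refits.
#' @return List of class `bootstrap_result`: `replicates` (matrix of
#'   per-replicate flattened estimates), `median`, `ci` (2.5/97.5 percentile
#'   rows), `n_failed`, `seed`.
#' @export
bootstrap <- function(data, init,
                      n_resamples = 500, seed = 1L,
                      opts = saem_options(iter_burn = 150, iter_smooth = 100,
                                          ofv_samples = 0, ebe_draws = 0)) {
  set.seed(seed)
  ids <- data$ids
  n <- length(ids)
  template <- flatten_params(init)
  reps <- matrix(NA_real_, n_resamples, length(template),
                 dimnames = list(NULL, names(template)))
  resample_seeds <- sample.int(.Machine$integer.max, n_resamples)
  n_failed <- 0L
  for (r in seq_len(n_resamples)) {
    take <- sample(ids, n, replace = TRUE)
    boot <- .resample_dataset(data, take)
    o <- opts; o$seed <- resample_seeds[r]
    f <- tryCatch(saem_fit(boot, init = init, opts = o),
                  error = function(e) e)
    if (inherits(f, "error") || any(!is.finite(flatten_params(f$estimates)))) {
      n_failed <- n_failed + 1L
      next
    }
    reps[r, ] <- flatten_params(f$estimates)
  }
  if (n_failed > 0.1 * n_resamples) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, n_resamples))
  }
  ok <- reps[complete.cases(reps), , drop = FALSE]
  med <- apply(ok, 2, median)
  ci <- apply(ok, 2, q8, probs = c(0.025, 0.975))
  rownames(ci) <- c("2.5%", "97.5%")
  structure(list(replicates = ok, median = med, ci = ci,
                 n_resamples = n_resamples, n_failed = n_failed, seed = seed),
            class = "bootstrap_result")
}

# rebuild a dataset from resampled subject ids (duplicates become new ids)
.resample_dataset <- function(data, take) {
  obs_by <- split(data$obs, data$obs$ID)
  dose_by <- split(data$doses, data$doses$ID)
  obs <- list(); doses <- list(); covs <- list()
  for (k in seq_along(take)) {
    o <- obs_by[[as.character(take[k])]]
    d <- dose_by[[as.character(take[k])]]
    o$ID <- k; d$ID <- k
    obs[[k]] <- o; doses[[k]] <- d
    if (!is.null(data$covariates)) {
      cr <- data$covariates[data$covariates$ID == take[k], , drop = FALSE]
      cr$ID <- k
      covs[[k]] <- cr
    }
  }
  pk_dataset(do.call(rbind, obs), do.call(rbind, doses),
             if (length(covs)) do.call(rbind, covs) else NULL,
             streams = data$streams, units = data$units)
}

# simulate replicate datasets from fitted population parameters, reusing the
# study's doses and covariates; returns a list of DV matrices (obs x n_sim)
.simulate_replicates <- function(data, pop, n_sim, seed, residual_error) {
  set.seed(seed)
  ctx <- build_fit_context(data)
  pars <- names(pop$theta)
  mu <- .subject_mu(ctx, pop)
  oe <- .obs_error(ctx, pop$error)
  sims <- matrix(NA_real_, ctx$n_obs, n_sim)
  for (s in seq_len(n_sim)) {
    eta <- vapply(pars, function(p) rnorm(ctx$n, 0, pop$omegas[[p]]),
                  numeric(ctx$n))
    if (ctx$n == 1L) eta <- matrix(eta, 1, dimnames = list(NULL, pars))
    f <- .ctx_predict(ctx, exp(mu + eta))
    if (residual_error) {
      sig <- oe$a / f + oe$b
      # clamp so extreme random-effect draws cannot under/overflow exp()
      f <- exp(pmin(pmax(log(f) + sig * rnorm(ctx$n_obs), -600), 600))
    }
    sims[, s] <- f
  }
  list(ctx = ctx, sims = sims)
}

#' Visual predictive check
#'
#' Simulates `n_sim` full replicates of the study (same subjects' doses and
#' covariates, new random effects and residual errors), then compares the
#' observed 5th/50th/95th percentiles per nominal time and stream with the
#' medians and 95% confidence bands of the same percentiles across
#' replicates. The design is balanced so bins are the exact nominal times.
#' Also reports the fraction of observations inside the simulated 5th-95th
#' percentile band (median ribbon).
#'
#' @param data Observed [pk_dataset()].
#' @param fit A `pk_fit` or [pop_params()].
#' @param n_sim Number of simulated replicates (default 500).
#' @param seed Integer seed.
#' @return List of class `vpc_result`: `bins` (data frame per time/stream:
#'   observed and simulated percentile columns with CI bounds), `coverage`
#'   (fraction of observations inside the simulated 5-95 band),
#'   `n_simulations`.
#' @export
vpc <- function(data, fit, n_sim = 500, seed = 1L) {
  pop <- if (inherits(fit, "pk_fit")) fit$estimates else fit
  sr <- .simulate_replicates(data, pop, n_sim, seed, residual_error = TRUE)
  ctx <- sr$ctx
  bin <- interaction(ctx$time, ctx$stream_idx, drop = TRUE)
  probs <- c(0.05, 0.5, 0.95)
  rows <- list()
  inside <- logical(ctx$n_obs)
  for (b in levels(bin)) {
    idx <- which(bin == b)
    obs_q <- q8(exp(ctx$logdv[idx]), probs)
    # per-replicate percentiles of this bin, then summaries across replicates
    sim_q <- apply(sr$sims[idx, , drop = FALSE], 2, q8, probs = probs)
    med <- apply(sim_q, 1, median)
    lo <- apply(sim_q, 1, q8, probs = 0.025)
    hi <- apply(sim_q, 1, q8, probs = 0.975)
    inside[idx] <- exp(ctx$logdv[idx]) >= med[1] & exp(ctx$logdv[idx]) <= med[3]
    rows[[b]] <- data.frame(
      time = ctx$time[idx][1], stream = ctx$streams[ctx$stream_idx[idx][1]],
      n = length(idx),
      obs_p5 = obs_q[1], obs_p50 = obs_q[2], obs_p95 = obs_q[3],
      sim_p5 = med[1], sim_p50 = med[2], sim_p95 = med[3],
      sim_p5_lo = lo[1], sim_p5_hi = hi[1],
      sim_p50_lo = lo[2], sim_p50_hi = hi[2],
      sim_p95_lo = lo[3], sim_p95_hi = hi[3])
  }
  bins <- do.call(rbind, rows)
  bins <- bins[order(bins$stream, bins$time), ]
  rownames(bins) <- NULL
  structure(list(bins = bins, coverage = mean(inside), n_simulations = n_sim,
                 seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d simulations; %.1f%% of observations inside the 5th-95th band\n",
              x$n_simulations, 100 * x$coverage))
  invisible(x)
}

#' Prediction-distribution diagnostic (simulations without residual error)
#'
#' Replicates of the study are simulated drawing new random effects only
#' (the residual error is switched off), isolating structural plus
#' interindividual variability. Per time and stream the 2.5th/50th/97.5th
#' percentiles are summarised across replicates; the reported 95%
#' prediction band spans from the lower confidence bound of the 2.5th
#' percentile to the upper confidence bound of the 97.5th percentile,
#' matching how such plots shade the percentile uncertainty. Reports the
#' fraction of observed data inside that band.
#'
#' @inheritParams vpc
#' @return List of class `preddist_result`: `bins`, `coverage`,
#'   `n_simulations`.
#' @export
prediction_distribution <- function(data, fit, n_sim = 500, seed = 1L) {
  pop <- if (inherits(fit, "pk_fit")) fit$estimates else fit
  sr <- .simulate_replicates(data, pop, n_sim, seed, residual_error = FALSE)
  ctx <- sr$ctx
  bin <- interaction(ctx$time, ctx$stream_idx, drop = TRUE)
  probs <- c(0.025, 0.5, 0.975)
  rows <- list()
  inside <- logical(ctx$n_obs)
  for (b in levels(bin)) {
    idx <- which(bin == b)
    sim_q <- apply(sr$sims[idx, , drop = FALSE], 2, q8, probs = probs)
    med <- apply(sim_q, 1, median)
    lo_band <- q8(sim_q[1, ], 0.025)
    hi_band <- q8(sim_q[3, ], 0.975)
    inside[idx] <- exp(ctx$logdv[idx]) >= lo_band &
      exp(ctx$logdv[idx]) <= hi_band
    rows[[b]] <- data.frame(
      time = ctx$time[idx][1], stream = ctx$streams[ctx$stream_idx[idx][1]],
      sim_p2.5 = med[1], sim_p50 = med[2], sim_p97.5 = med[3],
      band_lo = lo_band, band_hi = hi_band)
  }
  bins <- do.call(rbind, rows)
  bins <- bins[order(bins$stream, bins$time), ]
  rownames(bins) <- NULL
  structure(list(bins = bins, coverage = mean(inside), n_simulations = n_sim,
                 seed = seed),
            class = "preddist_result")
}

#' @export
print.preddist_result <- function(x, ...) {
  cat(sprintf(
    "Prediction distribution: %d simulations (no residual error); %.1f%% of observations inside the 95%% band\n",
    x$n_simulations, 100 * x$coverage))
  invisible(x)
}
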