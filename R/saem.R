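#' SAEM algorithm options
#'
#' Defaults follow standard SAEM practice: an exploratory (burn-in) phase
#' with step size 1 followed by a smoothing phase with step size
#' `1 / k^step_exponent`, a small number of MCMC transitions of the
#' subject-level random effects per iteration, and one chain per subject
#' whose state is carried across iterations.
#'
#' @param iter_burn Exploratory iterations (step size 1).
#' @param iter_smooth Smoothing iterations (decreasing step size).
#' @param mcmc_transitions MCMC sweeps over the random-effect components per
#'   SAEM iteration.
#' @param step_exponent Exponent of the smoothing-phase step size, in
#'   (0.5, 1].
#' @param ofv_samples Importance-sampling size for the final objective
#'   function value; `0` skips the OFV evaluation.
#' @param ebe_draws Post-burn-in MCMC draws averaged for the empirical Bayes
#'   estimates; `0` skips EBEs.
#' @param ebe_burn Extra MCMC sweeps discarded before EBE averaging.
#' @param seed Integer seed; the fit is bit-reproducible given the seed,
#'   dataset and options.
#' @return A list of class `saem_options`.
#' @export
saem_options <- function(iter_burn = 300, iter_smooth = 200,
                         mcmc_transitions = 2, step_exponent = 0.7,
                         ofv_samples = 1000, ebe_draws = 300, ebe_burn = 100,
                         seed = 1L) {
  stopifnot(iter_burn >= 1, iter_smooth >= 1, mcmc_transitions >= 1,
            step_exponent > 0.5, step_exponent <= 1)
  structure(list(iter_burn = iter_burn, iter_smooth = iter_smooth,
                 mcmc_transitions = mcmc_transitions,
                 step_exponent = step_exponent, ofv_samples = ofv_samples,
                 ebe_draws = ebe_draws, ebe_burn = ebe_burn,
                 seed = as.integer(seed)), class = "saem_options")
}

# ---- internal fit context -------------------------------------------------
# Flattens a pk_dataset into index vectors so the joint likelihood of all
# subjects is a handful of vectorised operations. Observations flagged
# MDV = 1 are excluded here, which is the single point enforcing the
# missing-data contract.
build_fit_context <- function(data) {
  stopifnot(inherits(data, "pk_dataset"))
  obs <- data$obs[data$obs$MDV == 0, , drop = FALSE]
  if (nrow(obs) == 0L) stop("dataset has no non-missing observations")
  ids <- data$ids
  n <- length(ids)
  sid <- match(obs$ID, ids)
  streams <- data$streams
  for (s in streams) {
    if (!any(obs$stream == s)) {
      stop("no observations for declared stream '", s,
           "' (stream-specific error parameters would be unidentifiable)")
    }
  }
  stream_idx <- match(obs$stream, streams)
  # pair expansion: one row per (observation, prior dose) combination
  pair_obs <- integer(0); pair_dt <- numeric(0); pair_amt <- numeric(0)
  doses_by_id <- split(data$doses[, c("TIME", "AMT")], data$doses$ID)
  po <- vector("list", nrow(obs))
  for (k in seq_len(nrow(obs))) {
    d <- doses_by_id[[as.character(obs$ID[k])]]
    keep <- d$TIME <= obs$TIME[k] + 1e-12
    po[[k]] <- cbind(k, obs$TIME[k] - d$TIME[keep], d$AMT[keep])
  }
  pm <- do.call(rbind, po)
  # group-boundary indices for cumsum-based aggregation (pairs are stored in
  # observation order, observations in subject order)
  pair_counts <- tabulate(pm[, 1], nbins = nrow(obs))
  obs_counts <- tabulate(sid, nbins = n)
  list(n = n, ids = ids, n_obs = nrow(obs),
       sid = sid, logdv = log(obs$DV), time = obs$TIME,
       stream_idx = stream_idx, streams = streams,
       pair_obs = pm[, 1], pair_sid = sid[pm[, 1]],
       pair_dt = pm[, 2], pair_amt = pm[, 3],
       pair_end = cumsum(pair_counts), obs_end = cumsum(obs_counts),
       covariates = data$covariates)
}

# natural-scale predictions for all observations given an n x 4 psi matrix
.ctx_predict <- function(ctx, psi) {
  ka <- psi[ctx$pair_sid, 1L]
  v <- psi[ctx$pair_sid, 2L]
  ke <- psi[ctx$pair_sid, 3L] / v
  dif <- ka - ke
  term <- ctx$pair_amt * ka / (v * dif) *
    (exp(-ke * ctx$pair_dt) - exp(-ka * ctx$pair_dt))
  deg <- which(abs(dif) < 1e-6 * ke)
  if (length(deg)) {
    term[deg] <- ctx$pair_amt[deg] * ka[deg] * ctx$pair_dt[deg] *
      exp(-ka[deg] * ctx$pair_dt[deg]) / v[deg]
  }
  cp <- diff(c(0, cumsum(term)[ctx$pair_end]))
  f <- cp
  unb <- ctx$stream_idx == match("unbound", ctx$streams)
  if (any(unb)) f[unb] <- f[unb] * psi[ctx$sid[unb], 4L]
  f
}

# per-subject log-likelihood of the observations given psi (n x 4) and the
# per-observation error coefficient vectors a_obs, b_obs
.ctx_loglik <- function(ctx, psi, a_obs, b_obs) {
  f <- .ctx_predict(ctx, psi)
  ok <- f > 0
  sig <- a_obs / f + b_obs
  ll <- rep(-1e10, ctx$n_obs)
  ll[ok] <- dnorm(ctx$logdv[ok], log(f[ok]), sig[ok], log = TRUE)
  ll[!is.finite(ll)] <- -1e10
  diff(c(0, cumsum(ll)[ctx$obs_end]))
}

# per-observation error coefficient lookup for an error list
.obs_error <- function(ctx, error) {
  a <- vapply(ctx$streams, function(s) error[[s]][["a"]], numeric(1))
  b <- vapply(ctx$streams, function(s) error[[s]][["b"]], numeric(1))
  list(a = a[ctx$stream_idx], b = b[ctx$stream_idx])
}

# covariate design matrix for one parameter given the betas spec.
# exponential form contributes the raw covariate, power the log covariate;
# linear forms are handled by a nonlinear M-step and are rejected here.
.design_matrix <- function(ctx, betas, param) {
  X <- matrix(1, ctx$n, 1)
  colnames(X) <- "(intercept)"
  if (is.null(betas)) return(X)
  rows <- which(betas$parameter == param)
  for (i in rows) {
    cn <- betas$covariate[i]
    if (is.null(ctx$covariates) || !cn %in% names(ctx$covariates)) {
      stop("covariate '", cn, "' required by the model but absent from the dataset")
    }
    x <- ctx$covariates[[cn]]
    if (any(is.na(x))) stop("covariate '", cn, "' has missing values; impute first")
    col <- switch(betas$form[i],
                  exponential = x,
                  power = log(x),
                  stop("linear covariate form is not supported by saem_fit; ",
                       "use exponential or power"))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0(param, ".", cn)
  }
  X
}

#' Data-driven deterministic initial estimates
#'
#' Naive pooled starting values: per-subject apparent clearance from
#' dose / AUC with the AUC by trapezoid over the observed total-stream
#' samples, volume from `CL x 12 / ln 2` (a half-life-scale fallback),
#' `Ka` at 1.5 1/h, and `Fu` from the median unbound/total concentration
#' ratio at matched sampling times. Random-effect SDs start at 0.3 and the
#' residual coefficients at `a = 0.1`, `b = 0.2` on every stream; covariate
#' coefficients start at 0.
#'
#' @param data A [pk_dataset()].
#' @param betas Optional covariate-effect structure (data frame with
#'   `parameter`, `covariate`, optional `form`); `beta` values are set to 0.
#' @return A [pop_params()] suitable as `init` for [saem_fit()].
#' @export
initial_estimates <- function(data, betas = NULL) {
  obs <- data$obs[data$obs$MDV == 0, , drop = FALSE]
  tot <- obs[obs$stream == "total", , drop = FALSE]
  tau <- median(unlist(tapply(data$doses$TIME, data$doses$ID,
                              function(x) diff(sort(x)))))
  if (!is.finite(tau) || tau <= 0) tau <- 12
  amt <- median(data$doses$AMT)
  cl_i <- vapply(split(tot, tot$ID), function(d) {
    d <- d[order(d$TIME), ]
    if (nrow(d) < 2) return(NA_real_)
    auc <- sum(diff(d$TIME) * (head(d$DV, -1) + tail(d$DV, -1)) / 2)
    cav <- auc / (max(d$TIME) - min(d$TIME))
    amt / (cav * tau)
  }, numeric(1))
  cl0 <- median(cl_i, na.rm = TRUE)
  if (!is.finite(cl0) || cl0 <= 0) cl0 <- 1
  v0 <- cl0 * 12 / log(2)
  fu0 <- 0.1
  unb <- obs[obs$stream == "unbound", , drop = FALSE]
  if (nrow(unb)) {
    m <- merge(tot[, c("ID", "TIME", "DV")], unb[, c("ID", "TIME", "DV")],
               by = c("ID", "TIME"), suffixes = c("_t", "_u"))
    if (nrow(m)) fu0 <- min(1, median(m$DV_u / m$DV_t))
  }
  if (!is.null(betas)) {
    betas <- as.data.frame(betas)
    betas$beta <- 0
  }
  streams <- data$streams
  err <- setNames(rep(list(c(a = 0.1, b = 0.2)), length(streams)), streams)
  pop_params(theta = c(Ka = 1.5, V = v0, CL = cl0, Fu = fu0), betas = betas,
             omegas = c(Ka = 0.3, V = 0.3, CL = 0.3, Fu = 0.3), error = err)
}

# one componentwise Metropolis-Hastings sweep over the free random-effect
# components, for all subjects simultaneously. Returns the updated state.
.mcmc_sweep <- function(state, ctx, mu, omegas, free, a_obs, b_obs, prop_sd) {
  eta <- state$eta
  ll <- state$ll
  acc <- numeric(4)
  for (p in free) {
    prop <- eta
    prop[, p] <- eta[, p] + prop_sd[p] * rnorm(ctx$n)
    ll_prop <- .ctx_loglik(ctx, exp(mu + prop), a_obs, b_obs)
    logr <- ll_prop - ll +
      dnorm(prop[, p], 0, omegas[p], log = TRUE) -
      dnorm(eta[, p], 0, omegas[p], log = TRUE)
    take <- log(runif(ctx$n)) < logr
    if (any(take)) {
      eta[take, p] <- prop[take, p]
      ll[take] <- ll_prop[take]
    }
    acc[p] <- mean(take)
  }
  list(eta = eta, ll = ll, acc = acc)
}

# negative expected complete-data log-likelihood of the residual-error
# coefficients for one stream, using SA-smoothed squared residuals r2 and
# predictions f
.error_objective <- function(par, fpred, resid2) {
  a <- exp(par[1]); b <- exp(par[2])
  sig <- a / fpred + b
  sum(log(sig) + resid2 / (2 * sig^2))
}

#' Fit the joint population model by SAEM
#'
#' Stochastic Approximation EM with MCMC conditional sampling of the
#' subject-level random effects. Sufficient statistics are accumulated in
#' the log-parameter space, so the typical values, covariate coefficients
#' and random-effect variances have closed-form updates (a weighted linear
#' regression of the sampled log-parameters on the covariate design per
#' parameter). Residual-error coefficients are updated each iteration by
#' numerical minimisation of the smoothed error objective; fixed effects
#' without interindividual variability (omega set to 0 in `init`) are
#' updated by direct conditional maximisation of the observed-data
#' likelihood.
#'
#' @param data A validated [pk_dataset()].
#' @param init A [pop_params()] giving starting values and the model
#'   structure (which parameters carry IIV, which covariate effects are
#'   estimated, error streams); `NULL` uses [initial_estimates()].
#' @param opts A [saem_options()].
#' @return An object of class `pk_fit`: `estimates` ([pop_params()]),
#'   `ofv` and `ofv_se` (importance-sampling objective function value,
#'   -2 log-likelihood), `ebes` (per-subject conditional-mean random
#'   effects and individual parameters), `trace` (per-iteration parameter
#'   path, one row per iteration), `convergence`, `rse` (filled by
#'   [standard_errors()]), `seed`, `options`.
#' @export
saem_fit <- function(data, init = NULL, opts = saem_options()) {
  stopifnot(inherits(data, "pk_dataset"))
  if (is.null(init)) init <- initial_estimates(data)
  stopifnot(inherits(init, "pop_params"))
  set.seed(opts$seed)
  ctx <- build_fit_context(data)
  pars <- names(init$theta)
  free <- which(init$omegas > 0)         # components with IIV
  fixed_eff <- which(init$omegas == 0)   # no-IIV fixed effects
  if (!is.null(init$betas) && any(init$betas$parameter %in% pars[fixed_eff])) {
    stop("covariate effects on parameters without IIV are not supported")
  }
  X <- lapply(pars, function(p) .design_matrix(ctx, init$betas, p))
  names(X) <- pars
  qrX <- lapply(X, qr)

  theta <- init$theta
  omegas <- init$omegas
  error <- init$error
  coefs <- lapply(pars, function(p) {
    cf <- numeric(ncol(X[[p]]))
    cf[1] <- log(theta[[p]])
    if (!is.null(init$betas)) {
      rows <- which(init$betas$parameter == p)
      if (length(rows)) cf[-1] <- init$betas$beta[rows]
    }
    cf
  })
  names(coefs) <- pars
  mu_of <- function() {
    m <- vapply(pars, function(p) as.vector(X[[p]] %*% coefs[[p]]), numeric(ctx$n))
    if (ctx$n == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, pars))
    m
  }
  mu <- mu_of()
  eta <- matrix(0, ctx$n, 4, dimnames = list(NULL, pars))
  oe <- .obs_error(ctx, error)
  state <- list(eta = eta,
                ll = .ctx_loglik(ctx, exp(mu + eta), oe$a, oe$b))
  prop_sd <- pmax(omegas, 0.2)

  n_iter <- opts$iter_burn + opts$iter_smooth
  S1 <- matrix(0, ctx$n, 4); S2 <- matrix(0, ctx$n, 4)
  R1 <- numeric(ctx$n_obs); F1 <- numeric(ctx$n_obs)
  err_par <- lapply(ctx$streams, function(s) log(pmax(error[[s]], 1e-8)))
  names(err_par) <- ctx$streams
  trace <- matrix(NA_real_, n_iter, length(flatten_params(init)),
                  dimnames = list(NULL, names(flatten_params(init))))

  for (k in seq_len(n_iter)) {
    gamma <- if (k <= opts$iter_burn) 1 else (k - opts$iter_burn)^(-opts$step_exponent)
    # --- simulation step: MCMC transitions of eta | y, current parameters
    for (tr in seq_len(opts$mcmc_transitions)) {
      state <- .mcmc_sweep(state, ctx, mu, omegas, free, oe$a, oe$b, prop_sd)
      adapt <- if (k <= opts$iter_burn) 0.4 else 0.4 * gamma
      prop_sd[free] <- pmin(pmax(
        prop_sd[free] * exp(adapt * (state$acc[free] - 0.3)), 1e-3), 50)
    }
    # --- stochastic approximation of the sufficient statistics
    phi <- mu + state$eta
    S1 <- S1 + gamma * (phi - S1)
    S2 <- S2 + gamma * (phi^2 - S2)
    f_cur <- .ctx_predict(ctx, exp(phi))
    f_cur <- pmax(f_cur, 1e-12)
    r2 <- (ctx$logdv - log(f_cur))^2
    R1 <- R1 + gamma * (r2 - R1)
    F1 <- F1 + gamma * (f_cur - F1)
    if (any(!is.finite(S1)) || any(!is.finite(S2))) {
      stop("SAEM diverged (non-finite sufficient statistics) at iteration ", k)
    }
    # --- M-step: regression of smoothed log-parameters on the design
    for (p in free) {
      pn <- pars[p]
      cf <- qr.coef(qrX[[pn]], S1[, p])
      cf[is.na(cf)] <- 0
      coefs[[pn]] <- cf
      mu_p <- as.vector(X[[pn]] %*% cf)
      om2 <- mean(S2[, p] - 2 * mu_p * S1[, p] + mu_p^2)
      if (k <= opts$iter_burn) om2 <- max(om2, 0.95 * omegas[p]^2)  # annealing
      omegas[p] <- sqrt(max(om2, 1e-8))
    }
    mu <- mu_of()
    # --- conditional maximisation for fixed effects without IIV
    if (length(fixed_eff)) {
      theta <- .maximise_fixed(theta, fixed_eff, mu, state$eta, ctx, oe,
                               maxit = 30)
      for (p in fixed_eff) coefs[[pars[p]]][1] <- log(theta[[p]])
      mu <- mu_of()
    }
    theta[free] <- exp(vapply(pars[free], function(p) coefs[[p]][1], numeric(1)))
    # --- residual-error update (numerical, per stream)
    for (si in seq_along(ctx$streams)) {
      s <- ctx$streams[si]
      idx <- ctx$stream_idx == si
      o <- optim(err_par[[s]], .error_objective, fpred = F1[idx],
                 resid2 = R1[idx], method = "Nelder-Mead",
                 control = list(maxit = 30))
      err_par[[s]] <- o$par
      error[[s]] <- c(a = unname(exp(o$par[1])), b = unname(exp(o$par[2])))
    }
    oe <- .obs_error(ctx, error)
    state$ll <- .ctx_loglik(ctx, exp(mu + state$eta), oe$a, oe$b)
    trace[k, ] <- flatten_params(.assemble_pop(theta, init$betas, coefs,
                                               omegas, error, pars))
  }

  if (length(fixed_eff)) {
    # long conditional polish of the no-IIV fixed effects at the final state
    theta <- .maximise_fixed(theta, fixed_eff, mu, state$eta, ctx, oe,
                             maxit = 2000)
    for (p in fixed_eff) coefs[[pars[p]]][1] <- log(theta[[p]])
    mu <- mu_of()
  }
  est <- .assemble_pop(theta, init$betas, coefs, omegas, error, pars)
  fit <- structure(list(estimates = est, rse = NULL, ofv = NA_real_,
                        ofv_se = NA_real_, ebes = NULL,
                        trace = as.data.frame(trace),
                        convergence = list(iterations = n_iter,
                                           final_acceptance = state$acc),
                        seed = opts$seed, options = opts,
                        n_subjects = ctx$n, init = init),
                   class = "pk_fit")
  if (opts$ebe_draws > 0) {
    fit$ebes <- .ebe_from_state(ctx, mu, omegas, free, oe, prop_sd, state,
                                opts$ebe_draws, opts$ebe_burn, pars, est)
  }
  if (opts$ofv_samples > 0) {
    llis <- log_likelihood_is(data, est, M = opts$ofv_samples,
                              seed = opts$seed + 1L)
    fit$ofv <- llis$ofv
    fit$ofv_se <- llis$se
  }
  fit
}

# conditional maximisation of fixed effects without IIV, given the current
# random effects, by Nelder-Mead on the log scale (Brent for one parameter)
.maximise_fixed <- function(theta, fixed_eff, mu, eta, ctx, oe, maxit) {
  obj <- function(lt) {
    th <- theta
    th[fixed_eff] <- exp(lt)
    if (any(!is.finite(th)) || th[["Fu"]] > 1) return(1e12)
    mu_try <- mu
    for (p in fixed_eff) mu_try[, p] <- log(th[[p]])
    -sum(.ctx_loglik(ctx, exp(mu_try + eta), oe$a, oe$b))
  }
  start <- log(unlist(theta[fixed_eff]))
  o <- if (length(fixed_eff) == 1L) {
    optim(start, obj, method = "Brent", lower = start - 2, upper = start + 2)
  } else {
    optim(start, obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-12))
  }
  theta[fixed_eff] <- exp(o$par)
  theta
}

.assemble_pop <- function(theta, betas_spec, coefs, omegas, error, pars) {
  betas <- NULL
  if (!is.null(betas_spec)) {
    betas <- betas_spec
    for (i in seq_len(nrow(betas))) {
      p <- betas$parameter[i]
      pos <- 1L + which(which(betas_spec$parameter == p) == i)
      betas$beta[i] <- coefs[[p]][pos]
    }
  }
  pop_params(theta = theta, betas = betas, omegas = omegas, error = error)
}

# conditional-mean EBEs from a continued chain
.ebe_from_state <- function(ctx, mu, omegas, free, oe, prop_sd, state,
                            n_draws, n_burn, pars, est) {
  for (b in seq_len(n_burn)) {
    state <- .mcmc_sweep(state, ctx, mu, omegas, free, oe$a, oe$b, prop_sd)
  }
  acc_eta <- matrix(0, ctx$n, 4)
  for (d in seq_len(n_draws)) {
    state <- .mcmc_sweep(state, ctx, mu, omegas, free, oe$a, oe$b, prop_sd)
    acc_eta <- acc_eta + state$eta
  }
  eta_mean <- acc_eta / n_draws
  psi <- exp(mu + eta_mean)
  out <- data.frame(ID = ctx$ids)
  for (j in seq_along(pars)) out[[paste0("eta_", pars[j])]] <- eta_mean[, j]
  for (j in seq_along(pars)) out[[pars[j]]] <- psi[, j]
  out
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("SAEM fit: %d subjects, %d iterations, OFV %.1f (seed %d)\n",
              x$n_subjects, x$convergence$iterations, x$ofv, x$seed))
  print(x$estimates)
  invisible(x)
}

#' MCMC samples from a subject's conditional random-effect distribution
#'
#' Componentwise random-walk Metropolis-Hastings targeting
#' `p(eta | y_subject, pop)`, with proposal scales adapted toward an
#' acceptance rate of ~0.3 during warm-up. With no observations the target
#' reduces to the `N(0, omega^2)` prior; components with omega = 0 stay at 0.
#'
#' @param data A [pk_dataset()].
#' @param subject_id Subject identifier within `data`.
#' @param pop A [pop_params()].
#' @param n Number of post-warm-up draws.
#' @param seed Integer seed.
#' @param warmup Warm-up sweeps (adaptation happens here).
#' @return An `n` x 4 matrix of eta draws (columns `Ka`, `V`, `CL`, `Fu`).
#' @export
mcmc_conditional_sample <- function(data, subject_id, pop, n = 1000,
                                    seed = 1L, warmup = 500) {
  stopifnot(subject_id %in% data$ids)
  sub <- subset_subjects(data, subject_id)
  set.seed(seed)
  ctx <- try(build_fit_context(sub), silent = TRUE)
  pars <- names(pop$theta)
  no_obs <- inherits(ctx, "try-error")
  if (no_obs) {
    # no usable observations: conditional = prior
    draws <- vapply(pars, function(p) rnorm(n, 0, pop$omegas[[p]]),
                    numeric(n))
    return(draws)
  }
  mu <- .subject_mu(ctx, pop)
  free <- which(pop$omegas > 0)
  oe <- .obs_error(ctx, pop$error)
  state <- list(eta = matrix(0, 1, 4, dimnames = list(NULL, pars)), ll = NULL)
  state$ll <- .ctx_loglik(ctx, exp(mu + state$eta), oe$a, oe$b)
  prop_sd <- pmax(pop$omegas, 0.2)
  for (w in seq_len(warmup)) {
    state <- .mcmc_sweep(state, ctx, mu, pop$omegas, free, oe$a, oe$b, prop_sd)
    prop_sd[free] <- pmin(pmax(
      prop_sd[free] * exp(0.3 * (state$acc[free] - 0.3)), 1e-3), 50)
  }
  draws <- matrix(0, n, 4, dimnames = list(NULL, pars))
  for (d in seq_len(n)) {
    state <- .mcmc_sweep(state, ctx, mu, pop$omegas, free, oe$a, oe$b, prop_sd)
    draws[d, ] <- state$eta
  }
  draws
}

# log-scale typical values (covariate-adjusted) for the subjects of a context
.subject_mu <- function(ctx, pop) {
  pars <- names(pop$theta)
  mu <- matrix(rep(log(pop$theta), each = ctx$n), ctx$n, 4,
               dimnames = list(NULL, pars))
  if (!is.null(pop$betas)) {
    for (i in seq_len(nrow(pop$betas))) {
      cn <- pop$betas$covariate[i]
      if (is.null(ctx$covariates) || !cn %in% names(ctx$covariates)) {
        stop("covariate '", cn, "' required by the model but absent")
      }
      p <- pop$betas$parameter[i]
      mu[, p] <- mu[, p] + log(.cov_multiplier(pop$betas$form[i],
                                               pop$betas$beta[i],
                                               ctx$covariates[[cn]]))
    }
  }
  mu
}

#' Subset a PK dataset to selected subjects
#' @param data A [pk_dataset()].
#' @param ids Subject identifiers to keep.
#' @return A [pk_dataset()] restricted to `ids`.
#' @export
subset_subjects <- function(data, ids) {
  cov <- if (is.null(data$covariates)) NULL else
    data$covariates[data$covariates$ID %in% ids, , drop = FALSE]
  pk_dataset(data$obs[data$obs$ID %in% ids, , drop = FALSE],
             data$doses[data$doses$ID %in% ids, , drop = FALSE],
             cov, streams = data$streams, units = data$units)
}

#' Empirical Bayes estimates (conditional means) for every subject
#'
#' Post hoc Bayesian estimation: the conditional mean of each subject's
#' random effects over a long MCMC run of the conditional distribution,
#' mapped to individual parameters through the covariate model. With no
#' observations (or omega = 0) the estimate falls back to the
#' covariate-adjusted typical values.
#'
#' @param data A [pk_dataset()].
#' @param pop A fitted [pop_params()].
#' @param seed Integer seed.
#' @param n_draws Post-burn-in draws averaged.
#' @param burn Warm-up sweeps discarded.
#' @return Data frame: `ID`, `eta_*` conditional means, individual `Ka`,
#'   `V`, `CL`, `Fu`.
#' @export
ebe <- function(data, pop, seed = 1L, n_draws = 500, burn = 200) {
  set.seed(seed)
  ctx <- build_fit_context(data)
  pars <- names(pop$theta)
  mu <- .subject_mu(ctx, pop)
  free <- which(pop$omegas > 0)
  oe <- .obs_error(ctx, pop$error)
  state <- list(eta = matrix(0, ctx$n, 4, dimnames = list(NULL, pars)))
  state$ll <- .ctx_loglik(ctx, exp(mu + state$eta), oe$a, oe$b)
  prop_sd <- pmax(pop$omegas, 0.2)
  for (b in seq_len(burn)) {
    state <- .mcmc_sweep(state, ctx, mu, pop$omegas, free, oe$a, oe$b, prop_sd)
    prop_sd[free] <- pmin(pmax(
      prop_sd[free] * exp(0.3 * (state$acc[free] - 0.3)), 1e-3), 50)
  }
  .ebe_from_state(ctx, mu, pop$omegas, free, oe, prop_sd, state,
                  n_draws, 0L, pars, pop)
}

#' Marginal likelihood by importance sampling
#'
#' Per-subject marginal likelihoods are estimated by importance sampling
#' with a t(5) proposal centred at the subject's conditional mean with the
#' conditional SD (both from an MCMC warm run). Components with omega = 0
#' are fixed at 0 and excluded from the integral; with no free components
#' the likelihood is the closed-form Gaussian likelihood of the log-scale
#' residuals. Returns the objective function value `OFV = -2 sum log L_i`
#' and its Monte-Carlo standard error.
#'
#' @param data A [pk_dataset()].
#' @param pop A [pop_params()].
#' @param M Importance-sampling size per subject (>= 100 recommended).
#' @param seed Integer seed.
#' @param proposal Optional precomputed proposal (list with `mean` and `sd`
#'   matrices as returned in the result); used by [standard_errors()] to
#'   share one proposal across finite-difference evaluations.
#' @return List: `ofv`, `se` (Monte-Carlo SE of the OFV), `logLi`
#'   (per-subject log-likelihood contributions), `proposal`.
#' @export
log_likelihood_is <- function(data, pop, M = 1000, seed = 1L,
                              proposal = NULL) {
  set.seed(seed)
  ctx <- build_fit_context(data)
  pars <- names(pop$theta)
  mu <- .subject_mu(ctx, pop)
  free <- which(pop$omegas > 0)
  oe <- .obs_error(ctx, pop$error)
  if (length(free) == 0L) {
    ll <- .ctx_loglik(ctx, exp(mu), oe$a, oe$b)
    return(list(ofv = -2 * sum(ll), se = 0, logLi = ll))
  }
  if (is.null(proposal)) {
    # conditional location/scale from a warm MCMC run
    state <- list(eta = matrix(0, ctx$n, 4, dimnames = list(NULL, pars)))
    state$ll <- .ctx_loglik(ctx, exp(mu + state$eta), oe$a, oe$b)
    prop_sd <- pmax(pop$omegas, 0.2)
    keep <- 150L; warm <- 150L
    acc_m <- matrix(0, ctx$n, 4); acc_m2 <- matrix(0, ctx$n, 4)
    for (w in seq_len(warm + keep)) {
      state <- .mcmc_sweep(state, ctx, mu, pop$omegas, free, oe$a, oe$b, prop_sd)
      if (w <= warm) {
        prop_sd[free] <- pmin(pmax(
          prop_sd[free] * exp(0.3 * (state$acc[free] - 0.3)), 1e-3), 50)
      } else {
        acc_m <- acc_m + state$eta
        acc_m2 <- acc_m2 + state$eta^2
      }
    }
    cmean <- acc_m / keep
    csd <- sqrt(pmax(acc_m2 / keep - cmean^2, 0))
    for (p in free) {
      csd[, p] <- pmax(csd[, p], 0.05 * pop$omegas[p])
      if (any(!is.finite(csd[, p]))) {
        stop("degenerate importance-sampling proposal")
      }
    }
  } else {
    cmean <- proposal$mean
    csd <- proposal$sd
    if (any(csd[, free] <= 0)) stop("degenerate importance-sampling proposal")
  }
  df <- 5
  logw <- matrix(NA_real_, ctx$n, M)
  for (m in seq_len(M)) {
    eta <- matrix(0, ctx$n, 4, dimnames = list(NULL, pars))
    logq <- numeric(ctx$n)
    logp <- numeric(ctx$n)
    for (p in free) {
      z <- rt(ctx$n, df)
      eta[, p] <- cmean[, p] + csd[, p] * z
      logq <- logq + dt(z, df, log = TRUE) - log(csd[, p])
      logp <- logp + dnorm(eta[, p], 0, pop$omegas[p], log = TRUE)
    }
    ll <- .ctx_loglik(ctx, exp(mu + eta), oe$a, oe$b)
    logw[, m] <- ll + logp - logq
  }
  mx <- apply(logw, 1, max)
  w <- exp(logw - mx)
  wbar <- rowMeans(w)
  logLi <- mx + log(wbar)
  se_logLi <- apply(w, 1, sd) / (sqrt(M) * wbar)
  list(ofv = -2 * sum(logLi), se = 2 * sqrt(sum(se_logLi^2)), logLi = logLi,
       proposal = list(mean = cmean, sd = csd))
}

#' Relative standard errors from the observed Fisher information
#'
#' The Hessian of the importance-sampling log-likelihood is computed by
#' central finite differences on the transformed parameter scale (log for
#' typical values, omegas and error coefficients; identity for covariate
#' coefficients), with common random numbers (the same seed for every
#' evaluation) so the Monte-Carlo noise cancels in the differences. SEs are
#' the square roots of the inverse-information diagonal, mapped back by the
#' delta method; `RSE% = 100 SE / |estimate|`. If the information matrix is
#' not positive definite the Moore-Penrose pseudo-inverse is used and the
#' result flagged.
#'
#' @param fit A `pk_fit` from [saem_fit()] (or a [pop_params()]).
#' @param data The fitted [pk_dataset()].
#' @param M Importance-sampling size per likelihood evaluation.
#' @param seed Seed shared by all evaluations (common random numbers).
#' @param h Relative finite-difference step.
#' @return Named numeric vector of RSE percentages with attribute
#'   `pseudo_inverse` (logical).
#' @export
standard_errors <- function(fit, data, M = 300, seed = 1L, h = 0.05) {
  pop <- if (inherits(fit, "pk_fit")) fit$estimates else fit
  pk <- .pack_params(pop)
  # one proposal, built at the MLE, shared by every evaluation; with the
  # shared seed this gives common random numbers across the differences
  center <- log_likelihood_is(data, pop, M = M, seed = seed)
  eval_ll <- function(x) {
    -0.5 * log_likelihood_is(data, .unpack_params(x, pk), M = M, seed = seed,
                             proposal = center$proposal)$ofv
  }
  p <- length(pk$value)
  H <- matrix(NA_real_, p, p)
  hh <- rep(h, p)
  f0 <- eval_ll(pk$value)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- hh[i]
    fp[i] <- eval_ll(pk$value + ei)
    fm[i] <- eval_ll(pk$value - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hh[i]^2
  }
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      ei <- numeric(p); ei[i] <- hh[i]
      ej <- numeric(p); ej[j] <- hh[j]
      fpp <- eval_ll(pk$value + ei + ej)
      fmm <- eval_ll(pk$value - ei - ej)
      H[i, j] <- H[j, i] <-
        (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) /
        (2 * hh[i] * hh[j])
    }
  }
  info <- -H
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  pseudo <- any(ev <= 0)
  covm <- if (pseudo) {
    warning("information matrix not positive definite; pseudo-inverse SEs flagged")
    MASS::ginv(info)
  } else {
    solve(info)
  }
  se_trans <- sqrt(pmax(diag(covm), 0))
  # delta method back to the natural scale; RSE of log-parameterised
  # quantities is directly 100 * SE(log x)
  rse <- numeric(p)
  for (i in seq_len(p)) {
    rse[i] <- if (pk$log_scale[i]) 100 * se_trans[i]
              else 100 * se_trans[i] / abs(pk$natural[i])
  }
  names(rse) <- pk$name
  attr(rse, "pseudo_inverse") <- pseudo
  rse
}

# pack a pop_params into a transformed vector for SE computation
.pack_params <- function(pop) {
  nm <- character(0); val <- numeric(0); logs <- logical(0); nat <- numeric(0)
  for (p in names(pop$theta)) {
    nm <- c(nm, paste0("theta.", p)); val <- c(val, log(pop$theta[[p]]))
    logs <- c(logs, TRUE); nat <- c(nat, pop$theta[[p]])
  }
  if (!is.null(pop$betas)) {
    for (i in seq_len(nrow(pop$betas))) {
      nm <- c(nm, paste0("beta.", pop$betas$parameter[i], ".",
                         pop$betas$covariate[i]))
      val <- c(val, pop$betas$beta[i]); logs <- c(logs, FALSE)
      nat <- c(nat, pop$betas$beta[i])
    }
  }
  for (p in names(pop$omegas)) {
    if (pop$omegas[[p]] > 0) {
      nm <- c(nm, paste0("omega.", p)); val <- c(val, log(pop$omegas[[p]]))
      logs <- c(logs, TRUE); nat <- c(nat, pop$omegas[[p]])
    }
  }
  for (s in names(pop$error)) {
    for (e in c("a", "b")) {
      x <- pop$error[[s]][[e]]
      if (x > 1e-8) {
        nm <- c(nm, paste0("error.", s, ".", e)); val <- c(val, log(x))
        logs <- c(logs, TRUE); nat <- c(nat, x)
      }
    }
  }
  list(name = nm, value = val, log_scale = logs, natural = nat, template = pop)
}

.unpack_params <- function(x, pk) {
  pop <- pk$template
  for (i in seq_along(x)) {
    nm <- pk$name[i]
    v <- if (pk$log_scale[i]) exp(x[i]) else x[i]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "theta") pop$theta[[parts[2]]] <- v
    else if (parts[1] == "omega") pop$omegas[[parts[2]]] <- v
    else if (parts[1] == "beta") {
      r <- which(pop$betas$parameter == parts[2] & pop$betas$covariate == parts[3])
      pop$betas$beta[r] <- v
    } else if (parts[1] == "error") pop$error[[parts[2]]][[parts[3]]] <- v
  }
  pop
}
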