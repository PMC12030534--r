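#' GAM screening of covariate-parameter relationships
#'
#' Marginal (one covariate at a time) screening of each candidate covariate
#' against the log empirical Bayes estimate of each PK parameter. Continuous
#' covariates are centred at their median and fitted as a penalised
#' thin-plate spline (`mgcv::gam(y ~ s(x))`, default smoothness selection);
#' binary covariates enter as a two-group linear term. A (parameter,
#' covariate) pair is selected when the covariate term's p-value is below
#' `alpha`. Zero-variance covariates are excluded with a warning.
#'
#' @param ebes Data frame from [ebe()] (or [saem_fit()]'s `$ebes`):
#'   column `ID` plus individual parameter columns.
#' @param covariates Data frame with column `ID` plus candidate covariates.
#' @param alpha Screening significance level.
#' @param params Parameters to screen (columns of `ebes`).
#' @return Data frame of class `screen_result`: `parameter`, `covariate`,
#'   `p_value`, `aic_with`, `aic_without`, `selected`.
#' @export
gam_screen <- function(ebes, covariates, alpha = 0.05,
                       params = c("Ka", "V", "CL", "Fu")) {
  stopifnot(nrow(ebes) >= 10)
  cv <- covariates[match(ebes$ID, covariates$ID), , drop = FALSE]
  cand <- setdiff(names(cv), "ID")
  out <- NULL
  for (cn in cand) {
    x <- cv[[cn]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("covariate '", cn, "' has no variation; excluded from screening")
      next
    }
    binary <- all(x %in% c(0, 1, NA))
    if (!binary) x <- x - median(x, na.rm = TRUE)  # centred for screening only
    for (p in params) {
      y <- log(ebes[[p]])
      if (binary) {
        fit <- mgcv::gam(y ~ x)
        pv <- summary(fit)$p.table["x", "Pr(>|t|)"]
      } else {
        kk <- min(10, length(unique(x)) - 1)
        fit <- mgcv::gam(y ~ s(x, k = kk))
        pv <- summary(fit)$s.table[1, "p-value"]
      }
      null_fit <- mgcv::gam(y ~ 1)
      out <- rbind(out, data.frame(parameter = p, covariate = cn,
                                   p_value = pv,
                                   aic_with = stats::AIC(fit),
                                   aic_without = stats::AIC(null_fit),
                                   selected = pv < alpha))
    }
  }
  if (is.null(out)) {
    out <- data.frame(parameter = character(), covariate = character(),
                      p_value = numeric(), aic_with = numeric(),
                      aic_without = numeric(), selected = logical())
  }
  structure(out, class = c("screen_result", "data.frame"))
}

#' Stepwise covariate modelling on the objective function value
#'
#' Forward selection then backward elimination of covariate effects. At each
#' forward round every remaining candidate is added to the current model
#' (default exponential form `theta * exp(beta * COV)`), the model is
#' refitted in full by [saem_fit()], and the candidate giving the largest
#' OFV reduction is accepted if the reduction exceeds `forward_th`
#' (default 3.875, p < 0.05). Backward elimination then removes each
#' retained effect in turn and keeps the removal unless the OFV rises by
#' more than `backward_th` (default 10.828, p < 0.001). All OFVs are
#' importance-sampling evaluations with a shared seed and sample size so
#' model comparisons share their Monte-Carlo noise. Ties are broken by the
#' larger OFV reduction, then alphabetically by covariate then parameter
#' name. Candidates whose refit fails are skipped for that round and logged
#' in the trace.
#'
#' @param data A [pk_dataset()] (covariates imputed).
#' @param base_init A [pop_params()] giving the base-model structure and
#'   starting values (typically a fitted base model's estimates).
#' @param candidates Data frame of candidate effects: `parameter`,
#'   `covariate` (e.g. the selected rows of [gam_screen()]).
#' @param forward_th,backward_th OFV-change thresholds.
#' @param form Covariate functional form for all candidates
#'   (`"exponential"` or `"power"`).
#' @param opts [saem_options()] used for every refit (reduced budgets are
#'   sensible here).
#' @param ofv_M,ofv_seed Importance-sampling size and seed shared by all
#'   OFV evaluations.
#' @return List of class `scm_result`: `trace` (data frame of steps:
#'   action, parameter, covariate, delta_ofv, accepted), `final`
#'   (final [pop_params()]), `final_fit` (the `pk_fit` of the final model),
#'   `ofv` (final OFV).
#' @export
scm <- function(data, base_init, candidates,
                forward_th = 3.875, backward_th = 10.828,
                form = "exponential",
                opts = saem_options(iter_burn = 150, iter_smooth = 100,
                                    ofv_samples = 0, ebe_draws = 0),
                ofv_M = 1000, ofv_seed = 1L) {
  candidates <- unique(as.data.frame(candidates)[, c("parameter", "covariate")])
  included <- base_init$betas
  trace <- data.frame(action = character(), parameter = character(),
                      covariate = character(), delta_ofv = numeric(),
                      accepted = logical(), note = character())
  fit_with <- function(betas) {
    init <- base_init
    init$betas <- betas
    saem_fit(data, init = init, opts = opts)
  }
  ofv_of <- function(pop) log_likelihood_is(data, pop, M = ofv_M,
                                            seed = ofv_seed)$ofv
  cur_fit <- fit_with(included)
  cur_ofv <- ofv_of(cur_fit$estimates)
  remaining <- candidates
  # ---- forward selection
  repeat {
    if (nrow(remaining) == 0L) break
    best <- NULL
    for (i in order(remaining$covariate, remaining$parameter)) {
      cand_row <- data.frame(parameter = remaining$parameter[i],
                             covariate = remaining$covariate[i],
                             beta = 0, form = form)
      betas_try <- rbind(included, cand_row)
      f <- tryCatch(fit_with(betas_try), error = function(e) e)
      if (inherits(f, "error")) {
        trace <- rbind(trace, data.frame(action = "add",
                                         parameter = cand_row$parameter,
                                         covariate = cand_row$covariate,
                                         delta_ofv = NA, accepted = FALSE,
                                         note = paste("fit failed:",
                                                      conditionMessage(f))))
        next
      }
      d_ofv <- cur_ofv - ofv_of(f$estimates)
      if (is.null(best) || d_ofv > best$d_ofv + 1e-9) {
        best <- list(i = i, d_ofv = d_ofv, fit = f)
      }
    }
    if (is.null(best) || best$d_ofv <= forward_th) {
      if (!is.null(best)) {
        trace <- rbind(trace, data.frame(
          action = "add", parameter = remaining$parameter[best$i],
          covariate = remaining$covariate[best$i], delta_ofv = best$d_ofv,
          accepted = FALSE, note = "below forward threshold"))
      }
      break
    }
    trace <- rbind(trace, data.frame(
      action = "add", parameter = remaining$parameter[best$i],
      covariate = remaining$covariate[best$i], delta_ofv = best$d_ofv,
      accepted = TRUE, note = ""))
    included <- rbind(included,
                      data.frame(parameter = remaining$parameter[best$i],
                                 covariate = remaining$covariate[best$i],
                                 beta = 0, form = form))
    cur_fit <- best$fit
    cur_ofv <- cur_ofv - best$d_ofv
    remaining <- remaining[-best$i, , drop = FALSE]
  }
  # ---- backward elimination
  n_base_effects <- if (is.null(base_init$betas)) 0L else nrow(base_init$betas)
  repeat {
    if (is.null(included) || nrow(included) <= n_base_effects) break
    removed_any <- FALSE
    for (i in rev(seq(n_base_effects + 1L, nrow(included)))) {
      reduced <- included[-i, , drop = FALSE]
      if (nrow(reduced) == 0L) reduced <- NULL
      f <- tryCatch(fit_with(reduced), error = function(e) e)
      if (inherits(f, "error")) next
      rise <- ofv_of(f$estimates) - cur_ofv
      keep_removal <- rise <= backward_th
      trace <- rbind(trace, data.frame(
        action = "remove", parameter = included$parameter[i],
        covariate = included$covariate[i], delta_ofv = rise,
        accepted = keep_removal, note = ""))
      if (keep_removal) {
        included <- reduced
        cur_fit <- f
        cur_ofv <- cur_ofv + rise
        removed_any <- TRUE
        break
      }
    }
    if (!removed_any) break
  }
  structure(list(trace = trace, final = cur_fit$estimates,
                 final_fit = cur_fit, ofv = cur_ofv),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate modelling trace:\n")
  print(x$trace, row.names = FALSE)
  eff <- x$final$betas
  if (is.null(eff) || nrow(eff) == 0) {
    cat("Final model: no covariate effects retained\n")
  } else {
    cat("Final model effects:\n")
    print(eff, row.names = FALSE)
  }
  invisible(x)
}
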