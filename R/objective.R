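#' Weighted sum of squared residuals
#'
#' The data part of the objective: for every record, the squared residual
#' between the observed replicate mean and the model prediction, weighted by
#' the record's measurement SD,
#' `chi2 = sum_ij ((y_ij - y_i(k, t_j)) / sigma_ij)^2`.
#' Under Gaussian measurement error this equals `-2 log L` up to a constant
#' that does not depend on the parameters.
#'
#' @param data an [longitudinal_dataset()] (or data.frame with the same
#'   columns); every `sd` must be > 0.
#' @param predictions `data.frame` with columns `observable`, `time_days`,
#'   `value`, containing a prediction for every data record (as produced by
#'   [observe()]).
#' @return Non-negative scalar; 0 iff all predictions equal the means.
#' @export
chi_squared <- function(data, predictions) {
  if (any(data$sd <= 0)) stop("sd must be > 0 for every record")
  r <- weighted_residuals(data, predictions)
  sum(r * r)
}

# per-record weighted residuals (y_data - y_model)/sigma, in data row order
weighted_residuals <- function(data, predictions) {
  key_d <- paste(data$observable, data$time_days)
  key_p <- paste(predictions$observable, predictions$time_days)
  idx <- match(key_d, key_p)
  if (any(is.na(idx)))
    stop("no prediction for record(s): ",
         paste(key_d[is.na(idx)], collapse = "; "))
  (data$mean - predictions$value[idx]) / data$sd
}

#' Gaussian parameter prior on log10 scale
#'
#' The prior used during estimation: each parameter `k` contributes
#' `((log10 k - log10 mean) / log10 sigma)^2` to the objective, a Gaussian
#' penalty on the log10-transformed parameter with the stated natural-scale
#' `mean` and width `sigma` read as a centre of `log10(mean)` and a standard
#' deviation of `log10(sigma)` decades. The default (`mean = 1e0`,
#' `sigma = 1e1`) is centred at 1 with a one-decade SD.
#'
#' @param mean prior centre on natural scale (> 0).
#' @param sigma prior width on natural scale (> 1, so the log10 width is
#'   positive).
#' @param applies_to parameter names the prior penalizes; `NULL` means every
#'   free parameter of the fitted model.
#' @return Object of class `ibd_prior`.
#' @export
ibd_prior <- function(mean = 1e0, sigma = 1e1, applies_to = NULL) {
  stopifnot(is.numeric(mean), mean > 0, is.numeric(sigma), sigma > 1)
  structure(list(mean = mean, sigma = sigma, applies_to = applies_to),
            class = "ibd_prior")
}

#' Prior penalty of a parameter vector
#'
#' @param params named numeric vector, strictly positive.
#' @param prior an [ibd_prior()] or `NULL` (no penalty, returns 0).
#' @return Non-negative scalar, 0 when every penalized parameter sits at the
#'   prior mean.
#' @export
prior_penalty <- function(params, prior) {
  r <- prior_residuals(params, prior)
  sum(r * r)
}

# per-parameter prior residuals on log10 scale
prior_residuals <- function(params, prior) {
  if (is.null(prior)) return(numeric(0))
  stopifnot(inherits(prior, "ibd_prior"))
  sel <- if (is.null(prior$applies_to)) names(params) else prior$applies_to
  miss <- setdiff(sel, names(params))
  if (length(miss))
    stop("prior applies to missing parameter(s): ",
         paste(miss, collapse = ", "))
  v <- params[sel]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("prior'd parameters must be finite and > 0")
  (log10(v) - log10(prior$mean)) / log10(prior$sigma)
}

#' Full objective: chi-squared plus prior penalty
#'
#' Simulates the model at the data time points and returns
#' `chi_squared + prior_penalty`. Deterministic for fixed inputs; equals
#' [chi_squared()] exactly when `prior = NULL`.
#'
#' @param model an [ibd_model()].
#' @param params named free-parameter vector on natural scale.
#' @param data an [longitudinal_dataset()].
#' @param protocol an [input_protocol()].
#' @param prior an [ibd_prior()] or `NULL`.
#' @param obs_map observable map, defaulting to [default_observables()].
#' @return Scalar objective value.
#' @export
ibd_objective <- function(model, params, data, protocol, prior = NULL,
                          obs_map = NULL) {
  pred <- predict_observations(model, params, data, protocol, obs_map)
  chi_squared(data, pred) + prior_penalty(params, prior)
}

# simulate and return predictions aligned to the dataset's time grid
predict_observations <- function(model, params, data, protocol,
                                 obs_map = NULL, rtol = 1e-8, atol = 1e-10,
                                 maxsteps = 5000) {
  times <- sort(unique(data$time_days))
  traj <- integrate_model(model, params, protocol, times,
                          rtol = rtol, atol = atol, maxsteps = maxsteps)
  observe(traj, obs_map = obs_map)
}
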