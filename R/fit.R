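#' Fit a colitis ODE model by multi-start maximum likelihood
#'
#' Estimates all free parameters (rate constants and estimated initial
#' abundances) of an [ibd_model()] from a [longitudinal_dataset()] by
#' minimizing the weighted sum of squared residuals plus an optional
#' log10-scale Gaussian prior penalty. Parameters are fitted on the log10
#' scale, so positivity holds by construction. Each of `n_starts` local
#' optimizations starts from a point drawn uniformly from the log10 box
#' `bounds` with a seeded generator and is run with a Levenberg-Marquardt
#' trust-region least-squares optimizer on the stacked residual vector
#' (data residuals followed by prior residuals). The best converged
#' solution is reported and the full ensemble retained for waterfall
#' diagnostics.
#'
#' @param model an [ibd_model()].
#' @param data an [longitudinal_dataset()]; the SD floor of
#'   [apply_sd_floor()] is applied with fraction `sd_floor`.
#' @param protocol an [input_protocol()].
#' @param prior an [ibd_prior()] or `NULL` for pure maximum likelihood.
#' @param n_starts number of random starts (the reference analysis used
#'   100).
#' @param seed integer seed controlling the start points.
#' @param bounds length-2 log10 box for start sampling, default `c(-2, 2)`
#'   (the +/- 2 SD range of the default prior).
#' @param obs_map observable map; defaults to [default_observables()].
#' @param sd_floor SD floor fraction passed to [apply_sd_floor()].
#' @param init optional matrix (or vector) of explicit start points in
#'   log10 space, one row per start; they replace the first rows of the
#'   random start set. Used e.g. to polish a regularized fit without the
#'   prior (see the vignette's two-stage workflow).
#' @param auto_init for the murine variants, prepend deterministic
#'   structure-aware start points obtained from a closed-form log-linear
#'   grid search (see the vignette); strongly recommended (default `TRUE`).
#' @param control list of optimizer knobs: `maxiter` (default 150), `rtol`,
#'   `atol` (integration tolerances, default 1e-8 / 1e-10), `box_margin`
#'   (decades the optimizer may move beyond the start box, default 2).
#' @return An object of class `ibd_fit`; see [coef.ibd_fit()],
#'   [predict.ibd_fit()], [profile.ibd_fit()], [waterfall()].
#' @examples
#' \donttest{
#' truth <- true_params_core()
#' d <- synth_counts_dataset(ibd_model("core"), truth, frede_protocol(),
#'                           times = c(0, 3, 7, 10, 14), n_reps = 3,
#'                           cv = 0.05, seed = 1)$data
#' fit <- fit_ibd(ibd_model("core"), d, frede_protocol(), n_starts = 5,
#'                seed = 1)
#' coef(fit)
#' }
#' @export
fit_ibd <- function(model, data, protocol, prior = ibd_prior(),
                    n_starts = 100, seed = 1, bounds = c(-2, 2),
                    obs_map = NULL, sd_floor = 0.05, control = list(),
                    init = NULL, auto_init = TRUE) {
  stopifnot(inherits(model, "ibd_model"), n_starts >= 1)
  if (nrow(data) == 0L) stop("dataset is empty")
  data <- apply_sd_floor(data, frac = sd_floor)
  ctrl <- utils::modifyList(
    list(maxiter = 150, rtol = 1e-8, atol = 1e-10, box_margin = 2,
         maxsteps = 2000), control)

  pnames <- free_param_names(model)
  npar <- length(pnames)
  box <- c(bounds[1L] - ctrl$box_margin, bounds[2L] + ctrl$box_margin)
  resid_fn <- make_residual_fn(model, data, protocol, prior, obs_map, ctrl,
                               box)

  starts <- sample_starts(n_starts, npar, bounds, seed)
  colnames(starts) <- pnames
  if (isTRUE(auto_init) && is.null(init))
    init <- structural_init(model, data, protocol)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = npar)
    if (nrow(init) > n_starts)
      init <- init[seq_len(n_starts), , drop = FALSE]
    starts[seq_len(nrow(init)), ] <- init
  }

  final <- matrix(NA_real_, n_starts, npar, dimnames = list(NULL, pnames))
  objective <- rep(NA_real_, n_starts)
  converged <- rep(FALSE, n_starts)
  info <- rep(NA_integer_, n_starts)
  for (s in seq_len(n_starts)) {
    res <- run_lm(resid_fn, starts[s, ], maxiter = ctrl$maxiter)
    final[s, ] <- res$par
    objective[s] <- res$objective
    converged[s] <- res$converged
    info[s] <- res$info
  }
  if (any(converged)) {
    ibest <- which(converged)[which.min(objective[converged])]
  } else {
    # info -1 marks iteration-capped runs: usable points, just unpolished
    usable <- is.finite(objective) & objective < 1e10
    if (!any(usable))
      stop("all ", n_starts, " starts failed; optimizer info: ",
           paste(info, collapse = ", "))
    warning("no start met the convergence criteria; reporting the best ",
            "point found (optimizer info: ",
            paste(info, collapse = ", "), ")")
    ibest <- which(usable)[which.min(objective[usable])]
  }
  best_log10 <- final[ibest, ]
  best_params <- stats::setNames(10^best_log10, pnames)

  fit <- structure(list(
    model = model, data = data, protocol = protocol, prior = prior,
    obs_map = obs_map,
    best_params = best_params,
    best_log10 = best_log10,
    best_objective = objective[ibest],
    starts = list(start_par = starts, final_par = final,
                  objective = objective, converged = converged, info = info),
    n_starts = n_starts, seed = seed, bounds = bounds,
    control = ctrl), class = "ibd_fit")
  fit
}

# residual closure on log10 parameters: data residuals ++ prior residuals
# ++ soft box-penalty residuals (hard optimizer bounds pin parameters at
# the box and stall the trust region, so the box is enforced as a steeply
# weighted penalty that is exactly zero inside). Integration failures yield
# a large finite residual so the optimizer backs off instead of aborting
# the start.
make_residual_fn <- function(model, data, protocol, prior, obs_map, ctrl,
                             box = c(-4, 4)) {
  nr <- nrow(data) + length(prior_residuals(
    stats::setNames(rep(1, length(free_param_names(model))),
                    free_param_names(model)), prior))
  pnames <- free_param_names(model)
  function(theta) {
    params <- stats::setNames(10^theta, pnames)
    r <- tryCatch({
      # capture the Fortran solver's console chatter for hopeless draws
      utils::capture.output(suppressWarnings(
        pred <- predict_observations(model, params, data, protocol, obs_map,
                                     rtol = ctrl$rtol, atol = ctrl$atol,
                                     maxsteps = ctrl$maxsteps)),
        type = "output")
      c(weighted_residuals(data, pred), prior_residuals(params, prior))
    }, error = function(e) rep(1e6, nr))
    r[!is.finite(r)] <- 1e6
    c(r, 10 * pmax(0, theta - box[2L], box[1L] - theta))
  }
}

# uniform start points in the log10 box, reproducible and local in RNG use
sample_starts <- function(n_starts, npar, bounds, seed) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::runif(n_starts * npar, bounds[1], bounds[2]),
         nrow = n_starts, byrow = TRUE)
}

# one Levenberg-Marquardt run; info codes 1-4 count as converged
run_lm <- function(resid_fn, par0, maxiter = 100, lower = NULL,
                   upper = NULL) {
  res <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, nprint = 0))),
    error = function(e) NULL)
  if (is.null(res))
    return(list(par = par0, objective = Inf, converged = FALSE, info = -1L))
  obj <- sum(res$fvec^2)
  list(par = stats::setNames(as.numeric(res$par), names(par0)),
       objective = obj,
       converged = res$info %in% 1:4 && is.finite(obj) && obj < 1e10,
       info = as.integer(res$info))
}

#' @export
print.ibd_fit <- function(x, ...) {
  wf <- tryCatch(waterfall(x),
                 error = function(e) list(fraction_at_global = NA_real_))
  cat(sprintf("Multi-start ML fit of the '%s' colitis model\n",
              x$model$variant))
  cat(sprintf("  %d free parameters, %d data records\n",
              length(x$best_params), nrow(x$data)))
  cat(sprintf("  best objective: %.6g  (%d/%d starts converged, %.0f%% at the optimum)\n",
              x$best_objective, sum(x$starts$converged), x$n_starts,
              100 * wf$fraction_at_global))
  cat("  best-fit parameters:\n")
  print(signif(x$best_params, 4))
  invisible(x)
}

#' @export
coef.ibd_fit <- function(object, log10 = FALSE, ...) {
  if (log10) object$best_log10 else object$best_params
}

#' @export
logLik.ibd_fit <- function(object, ...) {
  chi2 <- chi_squared(object$data, stats::predict(object))
  structure(-chi2 / 2, df = length(object$best_params),
            nobs = nrow(object$data), class = "logLik")
}

#' @export
predict.ibd_fit <- function(object, times = NULL, obs_map = NULL, ...) {
  if (is.null(obs_map)) obs_map <- object$obs_map
  data_times <- sort(unique(object$data$time_days))
  if (is.null(times)) times <- data_times
  grid <- sort(unique(c(data_times, times)))
  traj <- integrate_model(object$model, object$best_params, object$protocol,
                          grid, rtol = object$control$rtol,
                          atol = object$control$atol)
  observe(traj, obs_map = obs_map, times = times)
}

#' @export
residuals.ibd_fit <- function(object, ...) {
  weighted_residuals(object$data, stats::predict(object))
}

#' @export
summary.ibd_fit <- function(object, ...) {
  pred <- stats::predict(object)
  chi2 <- chi_squared(object$data, pred)
  pen <- prior_penalty(object$best_params, object$prior)
  wf <- tryCatch(waterfall(object),
                 error = function(e) list(fraction_at_global = NA_real_))
  out <- list(
    variant = object$model$variant,
    wiring = object$model$stimulus_wiring,
    n_params = length(object$best_params),
    n_data = nrow(object$data),
    chi_squared = chi2,
    prior_penalty = pen,
    best_objective = object$best_objective,
    aicc = aicc(chi2, length(object$best_params), nrow(object$data)),
    fraction_at_global = wf$fraction_at_global,
    n_converged = sum(object$starts$converged),
    n_starts = object$n_starts,
    coefficients = cbind(estimate = object$best_params,
                         log10 = object$best_log10))
  class(out) <- "summary.ibd_fit"
  out
}

#' @export
print.summary.ibd_fit <- function(x, ...) {
  cat(sprintf("Fit of '%s' model: chi2 = %.6g, prior penalty = %.4g, AICc = %.6g\n",
              x$variant, x$chi_squared, x$prior_penalty, x$aicc))
  cat(sprintf("  %d / %d starts converged; %.0f%% reached the global plateau\n",
              x$n_converged, x$n_starts, 100 * x$fraction_at_global))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new longitudinal datasets from the fitted trajectory using the
#' noise model of the data: per record, `n` replicates from a
#' truncated-at-zero normal centred at the model prediction with the
#' record's SD.
#'
#' @param object an `ibd_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of `ibd_data` objects (length `nsim`).
#' @export
simulate.ibd_fit <- function(object, nsim = 1, seed = 1, ...) {
  pred <- stats::predict(object)
  key_p <- paste(pred$observable, pred$time_days)
  key_d <- paste(object$data$observable, object$data$time_days)
  mu <- pred$value[match(key_d, key_p)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    d <- object$data
    for (j in seq_len(nrow(d))) {
      reps <- truncnorm::rtruncnorm(d$n[j], a = 0, mean = mu[j],
                                    sd = d$sd[j])
      d$mean[j] <- mean(reps)
      d$sd[j] <- if (d$n[j] > 1) stats::sd(reps) else d$sd[j]
    }
    longitudinal_dataset(apply_sd_floor(d),
                         provenance = sprintf("simulate.ibd_fit replicate %d", i))
  })
}

#' Plot data and fitted trajectories
#'
#' One panel per observable: replicate means with +/- SD error bars and the
#' fitted model trajectory on a fine grid.
#'
#' @param x an `ibd_fit`.
#' @param n_grid number of curve evaluation points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ibd_fit <- function(x, n_grid = 101, ...) {
  obs_map <- if (is.null(x$obs_map)) default_observables(x$model) else x$obs_map
  tmax <- max(x$data$time_days)
  grid <- seq(0, tmax, length.out = n_grid)
  traj <- integrate_model(x$model, x$best_params, x$protocol,
                          unique(sort(c(grid, x$data$time_days))))
  sim <- observe(traj, obs_map = obs_map)
  obs <- unique(x$data$observable)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(obs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (o in obs) {
    d <- x$data[x$data$observable == o, ]
    s <- sim[sim$observable == o, ]
    ylim <- range(0, d$mean + d$sd, d$mean - d$sd, s$value)
    graphics::plot(d$time_days, d$mean, ylim = ylim, pch = 19,
                   xlab = "time [days]", ylab = o, main = o, ...)
    graphics::arrows(d$time_days, d$mean - d$sd, d$time_days, d$mean + d$sd,
                     angle = 90, code = 3, length = 0.03)
    graphics::lines(s$time_days, s$value, lwd = 2)
  }
  invisible(x)
}

#' Waterfall diagnostics of a multi-start fit
#'
#' Sorts the final objective values of all converged starts and reports the
#' fraction that reached the global optimum plateau (within `tol` of the
#' best value). A large plateau indicates a robust optimization.
#'
#' @param fit an `ibd_fit`.
#' @param tol objective tolerance for "same optimum" (default 1e-2).
#' @return Object of class `ibd_waterfall`: list with sorted `objectives`
#'   and `fraction_at_global`.
#' @export
waterfall <- function(fit, tol = 1e-2) {
  stopifnot(inherits(fit, "ibd_fit"))
  ok <- fit$starts$converged
  if (!any(ok)) stop("no converged starts")
  obj <- sort(fit$starts$objective[ok])
  structure(list(objectives = obj,
                 fraction_at_global = mean(obj <= obj[1L] + tol),
                 tol = tol),
            class = "ibd_waterfall")
}

#' @export
print.ibd_waterfall <- function(x, ...) {
  cat(sprintf("Waterfall over %d converged starts: best %.6g, %.1f%% at the global optimum (tol %g)\n",
              length(x$objectives), x$objectives[1L],
              100 * x$fraction_at_global, x$tol))
  invisible(x)
}

#' @export
plot.ibd_waterfall <- function(x, ...) {
  graphics::plot(seq_along(x$objectives), x$objectives, log = "y",
                 xlab = "start (sorted)", ylab = "final objective",
                 pch = 19, ...)
  graphics::abline(h = x$objectives[1L] + x$tol, lty = 2)
  invisible(x)
}
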