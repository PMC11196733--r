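#' Chi-squared threshold for profile-likelihood confidence intervals
#'
#' Pointwise threshold above the optimum for a `level` confidence interval
#' of a single parameter: the `level` quantile of the chi-squared
#' distribution with 1 degree of freedom (3.84 at 95%, 1.00 at ~68.3%).
#'
#' @param level confidence level in (0, 1).
#' @return Scalar threshold.
#' @export
chi2_threshold <- function(level = 0.95) {
  stopifnot(level > 0, level < 1)
  stats::qchisq(level, df = 1)
}

#' Profile likelihood of fitted parameters
#'
#' For each requested parameter, steps its log10 value away from the
#' optimum in both directions, re-optimizing all remaining parameters at
#' every step (warm-started from the neighbouring solution), until the
#' objective exceeds the confidence threshold or the log10 bounds are
#' reached. Step sizes adapt to target an objective increment of about
#' `step_target` per step. The resulting curves classify each parameter as
#' identifiable (threshold crossed on both sides), practically
#' non-identifiable (one side) or structurally non-identifiable (flat), and
#' carry the profile confidence interval.
#'
#' @param fitted an `ibd_fit` from [fit_ibd()].
#' @param which parameter names to profile; default all free parameters.
#' @param level confidence level (default 0.95).
#' @param step_init initial log10 step.
#' @param step_target target objective increment per step.
#' @param max_steps maximum steps per side.
#' @param bound_decades log10 distance from the optimum at which stepping
#'   stops.
#' @param maxiter re-optimization iteration cap per step.
#' @param ... unused.
#' @return Object of class `ibd_profile`: named list of
#'   `ibd_profile_curve` objects.
#' @export
profile.ibd_fit <- function(fitted, which = NULL, level = 0.95,
                            step_init = 0.05, step_target = 0.25,
                            max_steps = 40, bound_decades = 3,
                            maxiter = 40, ...) {
  pnames <- names(fitted$best_log10)
  if (is.null(which)) which <- pnames
  bad <- setdiff(which, pnames)
  if (length(bad))
    stop("not a fitted parameter: ", paste(bad, collapse = ", "))
  margin <- fitted$control$box_margin %||% 2
  box <- c(fitted$bounds[1L] - margin, fitted$bounds[2L] + margin)
  resid_fn <- make_residual_fn(fitted$model, fitted$data, fitted$protocol,
                               fitted$prior, fitted$obs_map, fitted$control,
                               box)
  out <- lapply(which, function(pn) {
    profile_engine(resid_fn, fitted$best_log10, match(pn, pnames),
                   f0 = fitted$best_objective,
                   threshold = chi2_threshold(level), level = level,
                   step_init = step_init, step_target = step_target,
                   max_steps = max_steps, bound_decades = bound_decades,
                   maxiter = maxiter, parameter = pn)
  })
  names(out) <- which
  structure(out, class = "ibd_profile", best_objective = fitted$best_objective)
}

# generic profile walker over a residual-vector function; works in the
# coordinates of resid_fn (log10 for model fits). Re-optimizes the free
# coordinates at each fixed value of coordinate idx.
profile_engine <- function(resid_fn, par0, idx, f0, threshold, level = 0.95,
                           step_init = 0.05, step_target = 0.25,
                           max_steps = 40, bound_decades = 3,
                           maxiter = 40, parameter = names(par0)[idx]) {
  npar <- length(par0)
  reopt <- function(theta_i, others_start) {
    if (npar == 1L) {
      full <- theta_i
      return(list(others = numeric(0), obj = sum(resid_fn(full)^2)))
    }
    fn_red <- function(po) {
      full <- numeric(npar)
      full[idx] <- theta_i
      full[-idx] <- po
      resid_fn(full)
    }
    res <- run_lm(fn_red, others_start, maxiter = maxiter)
    list(others = res$par, obj = res$objective)
  }

  min_step <- 1e-5
  walk <- function(dir) {
    grid <- numeric(0); obj <- numeric(0)
    theta <- par0[idx]
    others <- if (npar > 1L) par0[-idx] else numeric(0)
    step <- step_init
    last_obj <- f0
    for (s in seq_len(max_steps)) {
      # take a trial step; on gross overshoot shrink (quadratic model)
      # and retry so the threshold crossing is resolved, not leapt over
      r <- NULL
      for (try in 1:15) {
        cand <- theta + dir * step
        r <- reopt(cand, others)
        dobj <- r$obj - last_obj
        overshoot <- (r$obj - f0 > threshold + 0.5) &&
          (last_obj - f0 < threshold) && step > min_step * 1.01
        if (!overshoot) break
        step <- max(min_step,
                    step * max(0.1, sqrt(step_target / max(dobj, 1e-12))))
      }
      theta <- cand
      grid <- c(grid, theta); obj <- c(obj, r$obj)
      others <- r$others
      dobj <- abs(r$obj - last_obj)
      last_obj <- r$obj
      if (r$obj - f0 > threshold + 0.5) break
      if (abs(theta - par0[idx]) > bound_decades) break
      fac <- if (dobj < 1e-12) 2 else min(max(step_target / dobj, 0.5), 2)
      step <- min(max(step * fac, min_step), 0.5)
    }
    list(grid = grid, obj = obj)
  }

  lo <- walk(-1)
  hi <- walk(+1)
  grid <- c(rev(lo$grid), par0[idx], hi$grid)
  prof <- c(rev(lo$obj), f0, hi$obj)

  ci <- profile_crossings(grid, prof, par0[idx], f0 + threshold, f0)
  flat <- (max(prof) - min(prof)) < 0.01 &&
    (length(lo$grid) + length(hi$grid)) > 0
  status <- if (flat) "structurally_nonidentifiable"
  else if (is.finite(ci[1L]) && is.finite(ci[2L])) "identifiable"
  else if (is.finite(ci[1L]) || is.finite(ci[2L])) "practically_nonidentifiable"
  else "structurally_nonidentifiable"

  structure(list(parameter = parameter,
                 grid = grid, profile_objective = prof,
                 optimum = unname(par0[idx]), best_objective = f0,
                 level = level, threshold = f0 + threshold,
                 ci_lower_log10 = ci[1L], ci_upper_log10 = ci[2L],
                 ci_lower = 10^ci[1L], ci_upper = 10^ci[2L],
                 status = status),
            class = "ibd_profile_curve")
}

# first threshold crossing on each side of the optimum, interpolated on
# the sqrt(delta objective) scale (exact for a quadratic profile);
# -Inf/Inf mark open (uncrossed) sides
profile_crossings <- function(grid, prof, opt, thr, f0 = min(prof)) {
  cross_side <- function(g, p) {
    above <- which(p > thr)
    if (!length(above)) return(NA_real_)
    i <- above[1L]
    if (i == 1L) return(g[1L])
    s1 <- sqrt(max(p[i - 1L] - f0, 0))
    s2 <- sqrt(max(p[i] - f0, 0))
    st <- sqrt(thr - f0)
    if (s2 <= s1) return(g[i])
    g[i - 1L] + (st - s1) / (s2 - s1) * (g[i] - g[i - 1L])
  }
  left <- grid <= opt
  lo <- cross_side(rev(grid[left]), rev(prof[left]))
  hi <- cross_side(grid[!left | grid == opt], prof[!left | grid == opt])
  c(if (is.na(lo)) -Inf else lo, if (is.na(hi)) Inf else hi)
}

#' Confidence interval from a profile curve
#'
#' Reads the interval where the profile crosses
#' `best_objective + chi2_threshold(level)`; sides the profile never
#' crosses within its bounds are open (`-Inf`/`Inf` on log10 scale, `0`/
#' `Inf` on natural scale).
#'
#' @param object an `ibd_profile_curve` (or `ibd_profile` for the matrix
#'   variant over all profiled parameters).
#' @param parm unused (intervals are per profiled parameter).
#' @param level confidence level.
#' @param ... unused.
#' @return For a curve, named numeric `c(lower, upper)` on natural scale;
#'   for a profile set, a matrix with one row per parameter.
#' @export
confint.ibd_profile_curve <- function(object, parm = NULL, level = 0.95, ...) {
  ci <- profile_crossings(object$grid, object$profile_objective,
                          object$optimum,
                          object$best_objective + chi2_threshold(level),
                          object$best_objective)
  c(lower = 10^ci[1L], upper = 10^ci[2L])
}

#' @rdname confint.ibd_profile_curve
#' @export
confint.ibd_profile <- function(object, parm = NULL, level = 0.95, ...) {
  curves <- if (is.null(parm)) object else object[parm]
  t(vapply(curves, confint, numeric(2), level = level))
}

#' Classify identifiability of a profiled parameter
#'
#' * `identifiable`: the profile crosses the threshold on both sides.
#' * `practically_nonidentifiable`: crossed on exactly one side within the
#'   profiling bounds.
#' * `structurally_nonidentifiable`: the profile is flat (objective range
#'   below `flatness_eps`) across the bounds.
#'
#' @param profile an `ibd_profile_curve`.
#' @param flatness_eps objective range under which a profile counts as
#'   flat.
#' @return One of the three status strings.
#' @export
classify_identifiability <- function(profile, flatness_eps = 0.01) {
  stopifnot(inherits(profile, "ibd_profile_curve"))
  prof <- profile$profile_objective
  if ((max(prof) - min(prof)) < flatness_eps && length(prof) > 1L)
    return("structurally_nonidentifiable")
  ci <- profile_crossings(profile$grid, prof, profile$optimum,
                          profile$threshold, profile$best_objective)
  if (is.finite(ci[1L]) && is.finite(ci[2L])) "identifiable"
  else if (is.finite(ci[1L]) || is.finite(ci[2L])) "practically_nonidentifiable"
  else "structurally_nonidentifiable"
}

#' @export
print.ibd_profile_curve <- function(x, ...) {
  cat(sprintf("Profile of %s: optimum %.4g, %d points, status %s\n",
              x$parameter, 10^x$optimum, length(x$grid), x$status))
  cat(sprintf("  %.0f%% CI: [%.4g, %.4g]\n", 100 * x$level,
              x$ci_lower, x$ci_upper))
  invisible(x)
}

#' @export
print.ibd_profile <- function(x, ...) {
  cat("Profile likelihood of", length(x), "parameter(s)\n")
  for (cu in x)
    cat(sprintf("  %-10s %-28s CI [%.4g, %.4g]\n", cu$parameter,
                cu$status, cu$ci_lower, cu$ci_upper))
  invisible(x)
}

#' @export
plot.ibd_profile <- function(x, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(x)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cu in x) {
    graphics::plot(cu$grid, cu$profile_objective, type = "b", pch = 19,
                   cex = 0.5, xlab = paste0("log10(", cu$parameter, ")"),
                   ylab = "profile objective", main = cu$parameter, ...)
    graphics::abline(h = cu$threshold, lty = 2)
    graphics::abline(v = cu$optimum, lty = 3)
  }
  invisible(x)
}
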