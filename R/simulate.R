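#' Integrate a colitis model over a time grid
#'
#' Solves the initial-value problem for an [ibd_model()] with the compiled
#' right-hand sides and a stiff-capable solver (`deSolve::lsoda`).
#' Integration is restarted at every protocol switch time, so the
#' piecewise-constant input is represented exactly rather than smoothed;
#' within each segment the system is autonomous. Integration always starts
#' at day 0, where the fixed and estimated initial conditions are defined.
#'
#' @param model an [ibd_model()].
#' @param params named numeric vector of free parameters on natural scale
#'   (see [free_param_names()]); all strictly positive.
#' @param protocol an [input_protocol()]; ignored by the human variant,
#'   whose drive is the internal `Cue` state.
#' @param times strictly increasing output times in days, `times[1] >= 0`.
#' @param rtol,atol relative / absolute integration tolerances.
#' @param maxsteps solver step cap per output interval.
#' @return An object of class `ibd_trajectory`: list with `times`, `states`
#'   (matrix time x state), `model`, `params`.
#' @examples
#' tr <- integrate_model(ibd_model("core"), true_params_core(),
#'                       frede_protocol(), times = 0:14)
#' head(as.data.frame(tr))
#' @export
integrate_model <- function(model, params, protocol, times,
                            rtol = 1e-8, atol = 1e-10, maxsteps = 5000) {
  stopifnot(inherits(model, "ibd_model"), inherits(protocol, "input_protocol"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (times[1L] < 0)
    stop("times must be >= 0")

  sp <- split_free_params(model, params)
  y0 <- sp$y0
  rates <- sp$rates
  tmax <- max(times)

  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0),
                dimnames = list(NULL, model$state_names))
  if (tmax == 0) {
    out[1L, ] <- y0
    return(structure(list(times = times, states = out, model = model,
                          params = params), class = "ibd_trajectory"))
  }

  if (model$variant == "human") {
    bounds <- c(0, tmax)
  } else {
    bounds <- c(0, protocol_breaks(protocol, 0, tmax), tmax)
  }

  state <- y0
  if (times[1L] == 0) out[1L, ] <- y0
  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    inside <- times[times > a & times <= b]
    tt <- unique(c(a, inside, b))
    if (model$variant == "human") {
      sol <- deSolve::ode(y = unname(state), times = tt,
                          func = "colitisdyn_derivs_human",
                          parms = unname(rates),
                          dllname = "colitisdyn",
                          initfunc = "colitisdyn_init_human",
                          method = "lsoda", rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
    } else {
      u <- input_value(protocol, a)
      w <- model$stimulus_wiring
      kE <- if (model$variant == "extended") rates[["k_turnE"]] else 1
      pv <- c(rates[["k_heal"]], rates[["k_turnB"]], rates[["k_turnM"]],
              rates[["k_turnN"]], rates[["k_turnT"]], kE, u,
              as.numeric(w[["Mac"]] == "Damage"),
              as.numeric(w[["Neutr"]] == "Damage"),
              as.numeric(w[["Tcell"]] == "Damage"))
      sol <- deSolve::ode(y = unname(state), times = tt,
                          func = "colitisdyn_derivs_murine",
                          parms = pv,
                          dllname = "colitisdyn",
                          initfunc = "colitisdyn_init_murine",
                          method = "lsoda", rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
    }
    if (nrow(sol) < length(tt) || any(!is.finite(sol)))
      stop(sprintf("integration failed on segment [%g, %g]", a, b))
    smat <- sol[, -1L, drop = FALSE]
    for (tv in inside)
      out[times == tv, ] <- smat[match(tv, tt), ]
    state <- smat[nrow(smat), ]
    names(state) <- model$state_names
    state[state < 0 & state > -1e-8] <- 0
  }
  # clip solver noise below the absolute tolerance: the exact solution is
  # non-negative by construction
  out[out < 0 & out > -1e-8] <- 0
  structure(list(times = times, states = out, model = model,
                 params = params), class = "ibd_trajectory")
}

#' @export
print.ibd_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of '%s' model: %d time points, %d states\n",
              x$model$variant, length(x$times), ncol(x$states)))
  invisible(x)
}

#' @export
as.data.frame.ibd_trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = ncol(x$states)),
    state = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states),
    stringsAsFactors = FALSE)
}

#' Default observable map of a model
#'
#' The observed quantities are the cell-population states themselves:
#' absolute counts for the murine variants, relative abundances for the
#' human variant. Latent states (`Damage`, `healedMucosa`, `Cue`,
#' `ActiveIBD`, `Resolution`) are unobserved.
#'
#' @param model an [ibd_model()].
#' @return Named character vector, observable name -> state name.
#' @export
default_observables <- function(model) {
  cells <- switch(model$variant,
                  core = c("Bcell", "Mac", "Neutr", "Tcell"),
                  extended = c("Bcell", "Mac", "Neutr", "Tcell", "Epi"),
                  human = c("Bcell", "Mac", "Neutr", "Tcell", "Epi"))
  stats::setNames(cells, cells)
}

#' Map a trajectory to predicted observations
#'
#' @param traj an `ibd_trajectory` from [integrate_model()].
#' @param obs_map named character vector (observable -> state); defaults to
#'   [default_observables()] of the trajectory's model.
#' @param times times at which predictions are requested; must be a subset
#'   of the integrated grid. Defaults to the full grid.
#' @return `data.frame` with columns `observable`, `time_days`, `value`.
#' @export
observe <- function(traj, obs_map = NULL, times = NULL) {
  stopifnot(inherits(traj, "ibd_trajectory"))
  if (is.null(obs_map)) obs_map <- default_observables(traj$model)
  if (is.null(names(obs_map)) || any(!nzchar(names(obs_map))))
    stop("obs_map must be a named character vector")
  bad <- setdiff(obs_map, colnames(traj$states))
  if (length(bad))
    stop("observable map references unknown state(s): ",
         paste(bad, collapse = ", "))
  if (is.null(times)) times <- traj$times
  idx <- match(times, traj$times)
  if (any(is.na(idx)))
    stop("requested time(s) outside the integrated grid: ",
         paste(times[is.na(idx)], collapse = ", "))
  data.frame(
    observable = rep(names(obs_map), each = length(times)),
    time_days = rep(times, times = length(obs_map)),
    value = as.vector(traj$states[idx, obs_map, drop = FALSE]),
    stringsAsFactors = FALSE)
}
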