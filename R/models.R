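#' Construct a colitis ODE model
#'
#' Declarative description of one of three model variants describing colonic
#' cell-population dynamics:
#'
#' * `"core"` (murine): states `Damage`, `healedMucosa`, `Bcell`, `Mac`,
#'   `Neutr`, `Tcell`; 5 rate constants (`k_heal` plus one turnover rate per
#'   immune population) and 4 estimated initial abundances.
#' * `"extended"` (murine): adds an epithelial state `Epi` whose turnover is
#'   suppressed by DSS; 6 rate constants, 5 estimated initials.
#' * `"human"` (remission): states `Cue`, `ActiveIBD`, `Resolution` plus the
#'   five cell populations; 8 rate constants. The external DSS input is
#'   replaced by the decaying `Cue` state (fixed `Cue(0) = 1`), active
#'   disease and resolution relax towards `k_act^2` and `k_res^2`.
#'
#' Each cell population `X` follows first-order mass-action kinetics
#' `dX/dt = (k_turnX * driver - 1/k_turnX) * X`, where `k_turnX` is the
#' population's turnover rate (the ratio of proliferation to death rate; the
#' two factors are never represented separately) and `driver` is the
#' stimulus wired to that population. In the murine variants the drivers of
#' macrophages, neutrophils and T cells may each be either the DSS input or
#' the accumulated tissue `Damage`; B cells are always driven by
#' `healedMucosa`. The default wiring is the selected best model:
#' neutrophils stimulated by DSS, macrophages and T cells by tissue damage.
#'
#' @param variant `"core"`, `"extended"` or `"human"`.
#' @param wiring optional named character vector overriding murine stimulus
#'   drivers, e.g. `c(Mac = "DSS")`; values must be `"DSS"` or `"Damage"`,
#'   names a subset of `c("Mac", "Neutr", "Tcell")`. Not accepted for the
#'   human variant (its wiring is fixed).
#' @param candidate_id optional integer label used by [enumerate_wirings()].
#' @return An object of class `ibd_model` with fields `variant`,
#'   `state_names`, `rate_param_names`, `stimulus_wiring`,
#'   `estimated_initials`, `fixed_initials`, `candidate_id`.
#' @examples
#' m <- ibd_model("core")
#' m$rate_param_names      # 5 rate constants
#' m$stimulus_wiring       # Neutr -> DSS, Mac/Tcell -> Damage
#' @export
ibd_model <- function(variant = c("core", "extended", "human"),
                      wiring = NULL, candidate_id = NA_integer_) {
  variant <- match.arg(variant)
  if (variant == "human") {
    if (!is.null(wiring))
      stop("the human variant has a fixed wiring; 'wiring' must be NULL")
    spec <- list(
      variant = "human",
      state_names = c("Cue", "ActiveIBD", "Resolution",
                      "Bcell", "Mac", "Neutr", "Tcell", "Epi"),
      rate_param_names = c("k_cue", "k_act", "k_res", "k_turnB", "k_turnM",
                           "k_turnN", "k_turnT", "k_turnE"),
      stimulus_wiring = c(Bcell = "Resolution", Mac = "ActiveIBD",
                          Neutr = "Cue", Tcell = "ActiveIBD", Epi = "Cue"),
      estimated_initials = c("ActiveIBD", "Resolution",
                             "Bcell", "Mac", "Neutr", "Tcell", "Epi"),
      fixed_initials = c(Cue = 1),
      candidate_id = as.integer(candidate_id))
    return(structure(spec, class = "ibd_model"))
  }

  stim <- c(Bcell = "healedMucosa",
            Mac = "Damage", Neutr = "DSS", Tcell = "Damage")
  if (!is.null(wiring)) {
    if (is.null(names(wiring)) ||
        !all(names(wiring) %in% c("Mac", "Neutr", "Tcell")))
      stop("wiring may only name Mac, Neutr and Tcell")
    if (!all(wiring %in% c("DSS", "Damage")))
      stop("wiring drivers must be 'DSS' or 'Damage'")
    stim[names(wiring)] <- wiring
  }

  states <- c("Damage", "healedMucosa", "Bcell", "Mac", "Neutr", "Tcell")
  rates <- c("k_heal", "k_turnB", "k_turnM", "k_turnN", "k_turnT")
  inits <- c("Bcell", "Mac", "Neutr", "Tcell")
  if (variant == "extended") {
    states <- c(states, "Epi")
    rates <- c(rates, "k_turnE")
    inits <- c(inits, "Epi")
    stim <- c(stim, Epi = "DSS")
  }
  structure(list(
    variant = variant,
    state_names = states,
    rate_param_names = rates,
    stimulus_wiring = stim,
    estimated_initials = inits,
    fixed_initials = c(Damage = 0, healedMucosa = 0),
    candidate_id = as.integer(candidate_id)),
    class = "ibd_model")
}

#' @export
print.ibd_model <- function(x, ...) {
  cat("Colitis ODE model, variant:", x$variant,
      if (!is.na(x$candidate_id)) sprintf("(candidate %d)", x$candidate_id),
      "\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat("  rate constants:", paste(x$rate_param_names, collapse = ", "), "\n")
  cat("  estimated initials:",
      paste(x$estimated_initials, collapse = ", "), "\n")
  w <- x$stimulus_wiring
  cat("  stimulus wiring:",
      paste(sprintf("%s<-%s", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the free (estimated) parameters of a model
#'
#' Rate constants first, then the estimated initial abundances with an `_0`
#' suffix (e.g. `Bcell_0`). This is the parameter ordering used throughout
#' fitting and profiling.
#'
#' @param model an [ibd_model()].
#' @return Character vector.
#' @export
free_param_names <- function(model) {
  c(model$rate_param_names, paste0(model$estimated_initials, "_0"))
}

#' Enumerate candidate stimulus wirings
#'
#' Produces all assignments of the drivers DSS vs. tissue damage to the
#' toggleable murine cell types (macrophages, neutrophils, T cells), for
#' corrected-AIC model selection. Ordering is a fixed binary enumeration
#' with `Mac` as the most significant toggle and the bit values
#' 0 = DSS, 1 = Damage, so `candidate_id` runs 1..8 and the wiring
#' (Neutr -> DSS, Mac -> Damage, Tcell -> Damage) is candidate 6. B cells
#' keep their fixed `healedMucosa` driver in every candidate.
#'
#' @param base a murine [ibd_model()] used as template.
#' @param toggle character vector of cell types to toggle; defaults to all
#'   three. An empty vector yields the single base wiring.
#' @return List of `ibd_model` objects with `candidate_id` set.
#' @export
enumerate_wirings <- function(base, toggle = c("Mac", "Neutr", "Tcell")) {
  stopifnot(inherits(base, "ibd_model"))
  if (base$variant == "human")
    stop("the human variant has no DSS/Damage wiring alternatives")
  if (!all(toggle %in% c("Mac", "Neutr", "Tcell")))
    stop("toggleable cell types are Mac, Neutr, Tcell")
  k <- length(toggle)
  drivers <- c("DSS", "Damage")
  out <- vector("list", 2^k)
  for (id in seq_len(2^k)) {
    bits <- as.integer(intToBits(id - 1L))[seq_len(max(k, 1L))]
    # most significant toggle first
    w <- base$stimulus_wiring
    if (k > 0) {
      assign_bits <- rev(bits[seq_len(k)])
      w[toggle] <- drivers[assign_bits + 1L]
    }
    out[[id]] <- ibd_model(base$variant,
                           wiring = w[c("Mac", "Neutr", "Tcell")],
                           candidate_id = id)
  }
  out
}

#' Evaluate the model right-hand side
#'
#' Returns the time derivative of every state at one time point, with the
#' input term taken from the protocol. Each cell-population derivative is
#' proportional to that population's current value, so non-negative states
#' can never be driven negative. Used for spot checks and tests; numerical
#' integration itself runs on the compiled equivalents.
#'
#' @param model an [ibd_model()].
#' @param state named numeric vector over `model$state_names`.
#' @param params named numeric vector covering `model$rate_param_names`,
#'   all strictly positive.
#' @param protocol an [input_protocol()] (ignored by the human variant).
#' @param t time in days.
#' @return Named numeric derivative vector.
#' @export
ode_rhs <- function(model, state, params, protocol = null_protocol(), t = 0) {
  stopifnot(inherits(model, "ibd_model"))
  if (!setequal(names(state), model$state_names))
    stop("state names must match the model's state_names")
  state <- state[model$state_names]
  miss <- setdiff(model$rate_param_names, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(params[model$rate_param_names] <= 0))
    stop("rate parameters must be strictly positive")
  p <- as.list(params)

  if (model$variant == "human") {
    d <- with(c(p, as.list(state)), c(
      Cue        = -k_cue * Cue,
      ActiveIBD  = k_act - (1 / k_act) * ActiveIBD,
      Resolution = k_res - (1 / k_res) * Resolution,
      Bcell      = (k_turnB * Resolution - 1 / k_turnB) * Bcell,
      Mac        = (k_turnM * ActiveIBD - 1 / k_turnM) * Mac,
      Neutr      = (k_turnN * Cue - 1 / k_turnN) * Neutr,
      Tcell      = (k_turnT * ActiveIBD - 1 / k_turnT) * Tcell,
      Epi        = (k_turnE - (1 / k_turnE) * Cue) * Epi))
  } else {
    u <- input_value(protocol, t)
    drv <- function(cell) {
      switch(model$stimulus_wiring[[cell]],
             DSS = u, Damage = state[["Damage"]],
             healedMucosa = state[["healedMucosa"]])
    }
    d <- with(c(p, as.list(state)), {
      dd <- c(
        Damage       = u - k_heal * Damage,
        healedMucosa = k_heal * Damage,
        Bcell        = (k_turnB * drv("Bcell") - 1 / k_turnB) * Bcell,
        Mac          = (k_turnM * drv("Mac") - 1 / k_turnM) * Mac,
        Neutr        = (k_turnN * drv("Neutr") - 1 / k_turnN) * Neutr,
        Tcell        = (k_turnT * drv("Tcell") - 1 / k_turnT) * Tcell)
      if (model$variant == "extended")
        dd <- c(dd, Epi = (k_turnE - (1 / k_turnE) * u) * Epi)
      dd
    })
  }
  d
}

# split a free-parameter vector (natural scale) into rates and initial state
split_free_params <- function(model, params) {
  need <- free_param_names(model)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(params[need])) || any(params[need] <= 0))
    stop("all free parameters must be finite and > 0")
  rates <- params[model$rate_param_names]
  y0 <- numeric(length(model$state_names))
  names(y0) <- model$state_names
  y0[names(model$fixed_initials)] <- model$fixed_initials
  y0[model$estimated_initials] <-
    params[paste0(model$estimated_initials, "_0")]
  list(rates = rates, y0 = y0)
}
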