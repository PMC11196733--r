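# Structure-aware start points for the murine variants.
#
# Given k_heal, the damage/healing subsystem has a closed form under a
# piecewise-constant input, and every cell population is exactly
# X(t) = X0 * exp(k * I(t) - t / k) with I(t) the cumulative integral of
# that population's driver. On log scale the only nonlinearity left is the
# scalar k per observable, so a coarse grid over (k_heal, k) with the
# profiled-out log X0 finds the neighbourhood of the global optimum
# deterministically and in milliseconds. The resulting points seed the
# multi-start optimizer alongside random starts.

# Damage, healedMucosa and their time integrals at `times`, closed form
damage_integrals <- function(k_heal, protocol, times) {
  times <- sort(unique(c(0, times)))
  bounds <- sort(unique(c(0, protocol_breaks(protocol, 0, max(times)),
                          max(times))))
  grid <- sort(unique(c(times, bounds)))
  D <- hM <- iD <- ihM <- numeric(length(grid))
  for (i in seq_along(grid)[-1L]) {
    a <- grid[i - 1L]; t <- grid[i]; dt <- t - a
    u <- input_value(protocol, a)
    Da <- D[i - 1L]
    e <- exp(-k_heal * dt)
    D[i] <- u / k_heal + (Da - u / k_heal) * e
    # hM gain over segment: u*dt - (D - Da); integrals by exact quadrature
    hM[i] <- hM[i - 1L] + u * dt - (D[i] - Da)
    intD <- (u / k_heal) * dt + (Da - u / k_heal) * (1 - e) / k_heal
    iD[i] <- iD[i - 1L] + intD
    # int hM = hM_a*dt + int over segment of (u*(s-a) - D(s) + Da)
    ihM[i] <- ihM[i - 1L] + hM[i - 1L] * dt + u * dt^2 / 2 - intD + Da * dt
  }
  idx <- match(times, grid)
  list(times = times, D = D[idx], hM = hM[idx], iD = iD[idx],
       ihM = ihM[idx], iDSS = cumulative_input(protocol, times))
}

# cumulative integral of the piecewise-constant input at `times`
cumulative_input <- function(protocol, times) {
  vapply(times, function(t) {
    seg <- protocol$segments
    if (nrow(seg) == 0L) return(0)
    sum(pmax(0, pmin(t, seg[, "end"]) - seg[, "start"]) * seg[, "value"])
  }, numeric(1))
}

# best (log10 k, log10 X0) for one observable given driver integrals I(t):
# grid over k, X0 profiled out in closed form on the log scale
fit_loglinear <- function(times, y, I, k_grid) {
  eps <- 1e-3 * mean(abs(y))
  ly <- log(pmax(y, eps))
  best <- c(NA_real_, NA_real_, Inf)
  for (lk in k_grid) {
    k <- 10^lk
    ex <- k * I - times / k
    lx0 <- mean(ly - ex)
    sse <- sum((ly - ex - lx0)^2)
    if (sse < best[3L]) best <- c(lk, lx0 / log(10), sse)
  }
  best
}

# deterministic structural start points (log10 scale), murine variants only
structural_init <- function(model, data, protocol, n_points = 3,
                            kh_grid = seq(-2, 2, by = 0.1),
                            k_grid = seq(-2, 2, by = 0.05)) {
  if (model$variant == "human") return(NULL)
  obs <- intersect(model$state_names, unique(data$observable))
  pnames <- free_param_names(model)
  cand <- matrix(NA_real_, length(kh_grid), length(pnames),
                 dimnames = list(NULL, pnames))
  sse_tot <- numeric(length(kh_grid))
  times_by_obs <- split(data$time_days, data$observable)
  y_by_obs <- split(data$mean, data$observable)
  for (g in seq_along(kh_grid)) {
    kh <- 10^kh_grid[g]
    theta <- stats::setNames(numeric(length(pnames)), pnames)
    theta["k_heal"] <- kh_grid[g]
    tot <- 0
    for (o in obs) {
      tt <- times_by_obs[[o]]
      ord <- order(tt)
      di <- damage_integrals(kh, protocol, tt[ord])
      I <- switch(model$stimulus_wiring[[o]],
                  DSS = di$iDSS, Damage = di$iD, healedMucosa = di$ihM)
      if (o == "Epi") {
        # dEpi/dt = (k - DSS/k) Epi: exponent k*t - iDSS(t)/k
        b <- fit_epi_loglinear(di$times, y_by_obs[[o]][ord], di$iDSS, k_grid)
      } else {
        b <- fit_loglinear(di$times, y_by_obs[[o]][ord], I, k_grid)
      }
      kname <- switch(o, Bcell = "k_turnB", Mac = "k_turnM",
                      Neutr = "k_turnN", Tcell = "k_turnT", Epi = "k_turnE")
      theta[kname] <- b[1L]
      theta[paste0(o, "_0")] <- b[2L]
      tot <- tot + b[3L]
    }
    cand[g, ] <- theta
    sse_tot[g] <- tot
  }
  keep <- order(sse_tot)[seq_len(min(n_points, nrow(cand)))]
  pmin(pmax(cand[keep, , drop = FALSE], -4), 4)
}

# epithelium variant of the log-linear grid fit (input suppresses growth)
fit_epi_loglinear <- function(times, y, iDSS, k_grid) {
  eps <- 1e-3 * mean(abs(y))
  ly <- log(pmax(y, eps))
  best <- c(NA_real_, NA_real_, Inf)
  for (lk in k_grid) {
    k <- 10^lk
    ex <- k * times - iDSS / k
    lx0 <- mean(ly - ex)
    sse <- sum((ly - ex - lx0)^2)
    if (sse < best[3L]) best <- c(lk, lx0 / log(10), sse)
  }
  best
}
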