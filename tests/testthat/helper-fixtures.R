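# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# noise-free core-model dataset under the default study design
core_nf_data <- function() {
  memo("core_nf", synth_counts_dataset(ibd_model("core"), cv = 0, seed = 1))
}

# cv = 5% core dataset
core_noisy_data <- function(seed = 11) {
  memo(paste0("core_cv5_", seed),
       synth_counts_dataset(ibd_model("core"), cv = 0.05, seed = seed))
}

# small labelled single-cell reference and its signature
ref_signature <- function() {
  memo("refsig", {
    ref <- synth_reference_scrnaseq(n_genes = 300, cells_per_type = 30,
                                    markers_per_type = 20, fold = 8,
                                    seed = 1)
    list(ref = ref, sig = build_signature(ref$counts, ref$labels))
  })
}

# a quick prior-then-polish fit of the noise-free core fixture
core_nf_fit <- function() {
  memo("core_nf_fit", {
    d <- core_nf_data()$data
    f1 <- fit_ibd(ibd_model("core"), d, frede_protocol(), n_starts = 6,
                  seed = 1)
    fit_ibd(ibd_model("core"), d, frede_protocol(), prior = NULL,
            n_starts = 2, seed = 1, init = f1$best_log10)
  })
}

# aligned model predictions for a dataset's time grid
predict_obs_for_test <- function(model, params, data,
                                 protocol = frede_protocol()) {
  colitisdyn:::predict_observations(model, params, data, protocol)
}

# naive reference for the weighted sum of squared residuals: explicit
# double loop over observables and time points
chi_squared_naive <- function(data, predictions) {
  tot <- 0
  for (obs in unique(data$observable)) {
    drec <- data[data$observable == obs, ]
    for (j in seq_len(nrow(drec))) {
      p <- predictions[predictions$observable == obs &
                         predictions$time_days == drec$time_days[j], ]
      stopifnot(nrow(p) == 1L)
      tot <- tot + ((drec$mean[j] - p$value) / drec$sd[j])^2
    }
  }
  tot
}

# random small dataset + prediction table pair for oracle checks
random_dataset_pair <- function(n_obs, n_times) {
  obs <- paste0("obs", seq_len(n_obs))
  tt <- sort(sample(0:20, n_times))
  d <- expand.grid(observable = obs, time_days = tt,
                   stringsAsFactors = FALSE)
  d$mean <- stats::rnorm(nrow(d), 5, 3)
  d$sd <- stats::runif(nrow(d), 0.2, 2)
  d$n <- 3L
  p <- d[, c("observable", "time_days")]
  p$value <- d$mean + stats::rnorm(nrow(d), 0, 2)
  list(data = d, pred = p)
}
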