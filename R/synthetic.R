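#' Reference parameter sets for the synthetic study conditions
#'
#' Ground-truth parameter values used by the synthetic-data generators and
#' examples. They are chosen to give bounded, non-degenerate dynamics under
#' the matching treatment protocol: tissue damage accumulating during DSS
#' and healing afterwards, neutrophils peaking at the end of DSS exposure,
#' macrophages and T cells rising and falling with damage, B cells dipping
#' and then expanding with mucosal healing, epithelium collapsing under DSS
#' and recovering, and (human) active disease giving way to resolution with
#' neutrophil depletion. Abundances are in arbitrary count units (murine)
#' or relative-abundance units (human).
#'
#' @return Named numeric vector over [free_param_names()] of the variant.
#' @export
true_params_core <- function() {
  c(k_heal = 0.2, k_turnB = 0.36, k_turnM = 0.43, k_turnN = 0.8,
    k_turnT = 0.42,
    Bcell_0 = 2, Mac_0 = 1, Neutr_0 = 0.5, Tcell_0 = 1.5)
}

#' @rdname true_params_core
#' @export
true_params_extended <- function() {
  c(k_heal = 0.2, k_turnB = 0.48, k_turnM = 0.6, k_turnN = 1.0,
    k_turnT = 0.59, k_turnE = 0.9,
    Bcell_0 = 2, Mac_0 = 1, Neutr_0 = 0.5, Tcell_0 = 1.5, Epi_0 = 3)
}

#' @rdname true_params_core
#' @export
true_params_human <- function() {
  c(k_cue = 0.5, k_act = 0.8, k_res = 1.2, k_turnB = 0.8333,
    k_turnM = 1.25, k_turnN = 0.7, k_turnT = 1.25, k_turnE = 0.15,
    ActiveIBD_0 = 1.5, Resolution_0 = 0.3,
    Bcell_0 = 0.15, Mac_0 = 0.1, Neutr_0 = 0.2, Tcell_0 = 0.25,
    Epi_0 = 0.3)
}

#' Default experimental design of a model variant
#'
#' Sampling days, replicate counts and treatment protocol mirroring the
#' three study designs: the 2.5% DSS flow-cytometry course (days 0, 3, 7,
#' 10, 14; 3 mice per time point), the 1.5% DSS scRNA-seq course (days 0,
#' 3, 6, 9, 12, 15; 10 technical replicates) and the human remission
#' course sampled at 0 h, 4 h, 24 h, 2, 6 and 14 weeks (days 0, 1/6, 1,
#' 14, 42, 98; 3 subjects).
#'
#' @param variant model variant id.
#' @return List with `times`, `n_reps`, `protocol`, `true_params`.
#' @export
default_design <- function(variant = c("core", "extended", "human")) {
  variant <- match.arg(variant)
  switch(variant,
    core = list(times = c(0, 3, 7, 10, 14), n_reps = 3,
                protocol = frede_protocol(),
                true_params = true_params_core()),
    extended = list(times = c(0, 3, 6, 9, 12, 15), n_reps = 10,
                    protocol = ho_protocol(),
                    true_params = true_params_extended()),
    human = list(times = c(0, 1/6, 1, 14, 42, 98), n_reps = 3,
                 protocol = null_protocol(),
                 true_params = true_params_human()))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a noisy longitudinal cell-abundance dataset
#'
#' Simulates the true trajectory of a model and, per observable and time
#' point, draws `n_reps` replicate observations from a truncated-at-zero
#' normal centred at the true value with SD equal to `cv` times the true
#' value, then records the replicate mean and SD. SDs are floored with
#' [apply_sd_floor()] exactly as during inference, so `cv = 0` yields a
#' valid noise-free dataset whose means equal the trajectory.
#'
#' @param model an [ibd_model()].
#' @param true_params ground-truth free-parameter vector.
#' @param protocol an [input_protocol()].
#' @param times sampling days; defaults to the variant's [default_design()].
#' @param n_reps replicates per observable/time (>= 2 when `cv > 0`).
#' @param cv coefficient of variation of the measurement noise (>= 0).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param sd_floor floor fraction for [apply_sd_floor()].
#' @param obs_map observable map, defaulting to [default_observables()].
#' @return List with `data` (an [longitudinal_dataset()]) and `truth`
#'   (class `synthetic_truth`: variant, true parameters, true trajectory,
#'   noise description, seed).
#' @export
synth_counts_dataset <- function(model, true_params = NULL, protocol = NULL,
                                 times = NULL, n_reps = NULL, cv = 0.1,
                                 seed = 1, sd_floor = 0.05, obs_map = NULL) {
  stopifnot(inherits(model, "ibd_model"), cv >= 0)
  des <- default_design(model$variant)
  if (is.null(true_params)) true_params <- des$true_params
  if (is.null(protocol)) protocol <- des$protocol
  if (is.null(times)) times <- des$times
  if (is.null(n_reps)) n_reps <- des$n_reps
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (cv > 0 && n_reps < 2)
    stop("n_reps >= 2 required when cv > 0 so replicate SDs exist")

  traj <- integrate_model(model, true_params, protocol, sort(unique(times)))
  pred <- observe(traj, obs_map = obs_map)

  rec <- with_seed(seed, {
    out <- pred
    out$mean <- NA_real_; out$sd <- 0; out$n <- n_reps
    for (i in seq_len(nrow(pred))) {
      v <- pred$value[i]
      if (cv == 0 || v == 0) {
        reps <- rep(v, n_reps)
      } else {
        reps <- truncnorm::rtruncnorm(n_reps, a = 0, mean = v, sd = cv * v)
      }
      out$mean[i] <- mean(reps)
      out$sd[i] <- if (n_reps > 1) stats::sd(reps) else 0
    }
    out
  })
  rec$value <- NULL
  rec <- apply_sd_floor(rec, frac = sd_floor)
  data <- longitudinal_dataset(
    rec, units = if (model$variant == "human") "relative abundance" else "cells",
    provenance = sprintf("synthetic (%s, cv=%g, n_reps=%d, seed=%d)",
                         model$variant, cv, n_reps, seed))
  truth <- structure(list(variant = model$variant, model = model,
                          true_params = true_params, trajectory = traj,
                          noise = sprintf("truncated normal, cv=%g", cv),
                          seed = seed),
                     class = "synthetic_truth")
  list(data = data, truth = truth)
}

#' Generate a labelled single-cell reference count matrix
#'
#' Negative-binomial counts for `n_genes` genes over `cells_per_type` cells
#' of each type, with a disjoint block of `markers_per_type` marker genes
#' per type whose expected expression is up-regulated `fold`-fold in that
#' type. Disjoint marker blocks guarantee distinguishable (full-rank)
#' pseudo-bulk signatures for `fold > 1`.
#'
#' @param n_genes total genes.
#' @param cell_types character vector of type names.
#' @param cells_per_type cells per type (scalar or per-type vector).
#' @param markers_per_type markers per type;
#'   `markers_per_type * n_types <= n_genes` required.
#' @param base_mean mean expression of non-marker genes.
#' @param fold marker up-regulation factor (>= 1).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param seed integer seed.
#' @return List with `counts` (gene x cell integer matrix), `labels`
#'   (per-cell type), `markers` (named list of marker genes per type).
#' @export
synth_reference_scrnaseq <- function(n_genes = 400,
                                     cell_types = c("Bcell", "Mac", "Neutr",
                                                    "Tcell", "Epi", "Other"),
                                     cells_per_type = 40,
                                     markers_per_type = 25,
                                     base_mean = 1, fold = 8,
                                     dispersion = 0.5, seed = 1) {
  k <- length(cell_types)
  if (markers_per_type * k > n_genes)
    stop("infeasible marker allocation: markers_per_type * n_types > n_genes")
  if (fold < 1) stop("fold must be >= 1")
  cells_per_type <- rep_len(cells_per_type, k)
  genes <- sprintf("g%04d", seq_len(n_genes))
  markers <- lapply(seq_len(k), function(i)
    genes[((i - 1) * markers_per_type + 1):(i * markers_per_type)])
  names(markers) <- cell_types

  with_seed(seed, {
    gene_mean <- base_mean * stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.8)
    labels <- rep(cell_types, times = cells_per_type)
    n_cells <- length(labels)
    counts <- matrix(0L, n_genes, n_cells,
                     dimnames = list(genes, sprintf("c%04d", seq_len(n_cells))))
    for (j in seq_len(n_cells)) {
      mu <- gene_mean
      mk <- markers[[labels[j]]]
      mu[match(mk, genes)] <- mu[match(mk, genes)] * fold
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts, labels = labels, markers = markers)
  })
}

#' Generate bulk mixtures with known cell-type fractions
#'
#' Forms each bulk sample as the convex combination `S f` of the signature
#' columns with the given fractions, optionally multiplied by mean-one
#' lognormal noise of coefficient of variation `noise_cv`.
#'
#' @param signature gene x cell-type [build_signature()] matrix.
#' @param fractions sample x cell-type matrix; every row must be
#'   non-negative and sum to 1 (columns matched to the signature by name
#'   when named).
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param seed integer seed.
#' @return Gene x sample numeric matrix.
#' @export
synth_bulk_mixtures <- function(signature, fractions, noise_cv = 0, seed = 1) {
  S <- as.matrix(signature)
  f <- as.matrix(fractions)
  if (!is.null(colnames(f))) {
    if (!setequal(colnames(f), colnames(S)))
      stop("fraction columns must match signature cell types")
    f <- f[, colnames(S), drop = FALSE]
  }
  if (ncol(f) != ncol(S))
    stop("fractions must have one column per signature cell type")
  if (any(f < 0) || any(abs(rowSums(f) - 1) > 1e-8))
    stop("every fraction row must be >= 0 and sum to 1")
  B <- S %*% t(f)
  colnames(B) <- if (!is.null(rownames(f))) rownames(f)
                 else sprintf("s%03d", seq_len(nrow(f)))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    B <- with_seed(seed, B * matrix(
      stats::rlnorm(length(B), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow(B), ncol(B)))
  }
  B
}

#' Generate an expression fixture linking module score to turnover
#'
#' Builds a log-normalized expression matrix in which the mean expression
#' of a gene module increases linearly with each cell type's assigned
#' turnover rate, so the downstream module-score vs. turnover Pearson
#' correlation is positive by construction.
#'
#' @param turnover named numeric vector (>= 3 cell types, not all equal).
#' @param n_genes total genes.
#' @param module_size number of module genes.
#' @param cells_per_type cells per type.
#' @param effect module shift (in SD units of the baseline noise) between
#'   the lowest and highest turnover type.
#' @param noise_sd baseline expression SD.
#' @param seed integer seed.
#' @return List with `expression` (gene x cell), `labels`, `module`
#'   (character vector of module genes), `turnover`.
#' @export
synth_module_turnover <- function(turnover, n_genes = 300, module_size = 40,
                                  cells_per_type = 40, effect = 2,
                                  noise_sd = 0.5, seed = 1) {
  if (length(turnover) < 3 || is.null(names(turnover)))
    stop("turnover must be a named vector over >= 3 cell types")
  if (diff(range(turnover)) == 0)
    stop("degenerate turnover map: all values equal")
  if (module_size > n_genes) stop("module_size > n_genes")
  types <- names(turnover)
  genes <- sprintf("g%04d", seq_len(n_genes))
  module <- genes[seq_len(module_size)]
  rel <- (turnover - min(turnover)) / diff(range(turnover))

  with_seed(seed, {
    labels <- rep(types, each = cells_per_type)
    n_cells <- length(labels)
    expr <- matrix(stats::rnorm(n_genes * n_cells, 0, noise_sd),
                   n_genes, n_cells,
                   dimnames = list(genes, sprintf("c%04d", seq_len(n_cells))))
    shift <- effect * noise_sd * rel[labels]
    expr[seq_len(module_size), ] <-
      expr[seq_len(module_size), ] + rep(shift, each = module_size)
    list(expression = expr, labels = labels, module = module,
         turnover = turnover)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: '%s' model, seed %d, %s\n",
              x$variant, x$seed, x$noise))
  print(signif(x$true_params, 4))
  invisible(x)
}
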