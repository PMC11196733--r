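#' Longitudinal cell-abundance dataset
#'
#' The data side of the weighted least-squares objective: one record per
#' observable and time point, carrying the replicate mean, the replicate
#' standard deviation (the measurement error used as weight; treated as
#' known, never estimated) and the number of replicates.
#'
#' @param records `data.frame` with columns `observable`, `time_days`,
#'   `mean`, `sd`, `n` (extra columns are kept). `sd` must be > 0 and
#'   `(observable, time_days)` pairs unique; apply [apply_sd_floor()] first
#'   if raw replicate SDs can be zero.
#' @param units free-text unit description.
#' @param provenance free-text origin description.
#' @return Object of class `ibd_data` (a `data.frame`).
#' @export
longitudinal_dataset <- function(records, units = "cells", provenance = "") {
  need <- c("observable", "time_days", "mean", "sd", "n")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$observable <- as.character(records$observable)
  for (cl in c("time_days", "mean", "sd")) {
    records[[cl]] <- as.numeric(records[[cl]])
    if (any(!is.finite(records[[cl]])))
      stop("non-finite values in column ", cl)
  }
  if (any(records$time_days < 0)) stop("time_days must be >= 0")
  if (any(records$sd <= 0)) stop("sd must be > 0 for every record")
  key <- paste(records$observable, records$time_days)
  if (anyDuplicated(key))
    stop("duplicate (observable, time_days) record(s)")
  attr(records, "units") <- units
  attr(records, "provenance") <- provenance
  class(records) <- c("ibd_data", "data.frame")
  records
}

#' Floor degenerate standard deviations
#'
#' Replicate SDs from few animals can be zero or near-zero, which would give
#' single records unbounded weight in the objective. Each record's SD is
#' floored at `frac` times the mean absolute level of its observable across
#' time points.
#'
#' @param records `data.frame` with columns `observable`, `mean`, `sd`.
#' @param frac floor as a fraction of the per-observable mean level
#'   (default 0.05).
#' @return The records with floored `sd`.
#' @export
apply_sd_floor <- function(records, frac = 0.05) {
  lev <- tapply(abs(records$mean), records$observable, mean)
  floor_vec <- frac * as.numeric(lev[records$observable])
  records$sd <- pmax(records$sd, floor_vec)
  records
}

#' Read / write the dataset CSV schema
#'
#' Plain CSV with columns `observable`, `time_days`, `mean`, `sd`, `n`.
#'
#' @param path file path.
#' @param data an `ibd_data` object (for writing).
#' @param ... passed to [longitudinal_dataset()].
#' @return `read_dataset_csv()` returns an `ibd_data`;
#'   `write_dataset_csv()` returns `path` invisibly.
#' @export
read_dataset_csv <- function(path, ...) {
  longitudinal_dataset(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.ibd_data <- function(x, ...) {
  cat(sprintf("Longitudinal dataset: %d records, %d observable(s), %d time point(s)\n",
              nrow(x), length(unique(x$observable)),
              length(unique(x$time_days))))
  NextMethod()
}
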