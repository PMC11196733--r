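#' Piecewise-constant input protocol
#'
#' Defines the time course of the external drive of a colitis model as a set
#' of non-overlapping constant segments, e.g. "2.5% DSS in the drinking water
#' for seven days, then plain water".  Outside all segments the input is 0.
#' Segment membership uses the half-open convention `[start, end)`, so a
#' treatment switch at day 7 means day 7 itself is already off-treatment.
#'
#' @param segments numeric matrix or data.frame with columns
#'   `start`, `end`, `value` (days, days, concentration in % w/v or a
#'   dimensionless cue), or a list of length-3 vectors. Segments must be
#'   non-overlapping with `start < end` and `value >= 0`.
#' @param name optional protocol label.
#' @return An object of class `input_protocol`.
#' @examples
#' frede <- input_protocol(rbind(c(0, 7, 2.5)), name = "Frede")
#' input_value(frede, 3)   # 2.5
#' input_value(frede, 10)  # 0
#' @seealso [input_value()], [frede_protocol()], [ho_protocol()]
#' @export
input_protocol <- function(segments, name = "protocol") {
  if (is.list(segments) && !is.data.frame(segments))
    segments <- do.call(rbind, lapply(segments, as.numeric))
  segments <- as.matrix(segments)
  if (length(segments) == 0L) {
    segments <- matrix(numeric(0), ncol = 3)
  }
  if (ncol(segments) != 3L)
    stop("segments must have three columns: start, end, value")
  colnames(segments) <- c("start", "end", "value")
  storage.mode(segments) <- "double"
  if (nrow(segments) > 0L) {
    if (any(!is.finite(segments)))
      stop("protocol segments must be finite")
    if (any(segments[, "start"] >= segments[, "end"]))
      stop("every segment needs start < end")
    if (any(segments[, "value"] < 0))
      stop("segment values must be >= 0")
    o <- order(segments[, "start"])
    segments <- segments[o, , drop = FALSE]
    if (nrow(segments) > 1L &&
        any(segments[-1L, "start"] < segments[-nrow(segments), "end"]))
      stop("protocol segments overlap")
  }
  structure(list(segments = segments, name = as.character(name)[1L]),
            class = "input_protocol")
}

#' Evaluate a protocol at a time point
#'
#' @param protocol an [input_protocol()].
#' @param t time in days, non-negative; vectorized.
#' @return Numeric vector of input values (0 outside all segments).
#' @export
input_value <- function(protocol, t) {
  stopifnot(inherits(protocol, "input_protocol"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  seg <- protocol$segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    hit <- t >= seg[i, "start"] & t < seg[i, "end"]
    out[hit] <- seg[i, "value"]
  }
  out
}

#' Canonical DSS colitis protocols
#'
#' `frede_protocol()`: 2.5% DSS on days 0-7 of a 14-day experiment (the
#' flow-cytometry protocol). `ho_protocol()`: 1.5% DSS on days 0-6 of a
#' 15-day experiment (the scRNA-seq protocol). `ki67_protocol()`: 1.8% DSS on
#' days 0-7 (the staining-validation protocol). `null_protocol()`: no input,
#' used by the human remission model whose drive is the `Cue` state.
#'
#' @return An [input_protocol()].
#' @export
frede_protocol <- function() input_protocol(rbind(c(0, 7, 2.5)), "Frede-2.5pct-DSS")

#' @rdname frede_protocol
#' @export
ho_protocol <- function() input_protocol(rbind(c(0, 6, 1.5)), "Ho-1.5pct-DSS")

#' @rdname frede_protocol
#' @export
ki67_protocol <- function() input_protocol(rbind(c(0, 7, 1.8)), "KI67-1.8pct-DSS")

#' @rdname frede_protocol
#' @export
null_protocol <- function() input_protocol(matrix(numeric(0), ncol = 3), "null")

#' @export
print.input_protocol <- function(x, ...) {
  cat("Input protocol:", x$name, "\n")
  if (nrow(x$segments) == 0L) {
    cat("  (identically zero)\n")
  } else {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  [%g, %g) days : %g\n", x$segments[i, 1],
                  x$segments[i, 2], x$segments[i, 3]))
  }
  invisible(x)
}

# switch times of a protocol falling strictly inside (t0, t1)
protocol_breaks <- function(protocol, t0, t1) {
  b <- sort(unique(as.numeric(protocol$segments[, c("start", "end")])))
  b[b > t0 & b < t1]
}
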