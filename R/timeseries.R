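#' Timeseries container
#'
#' A thin wrapper around a numeric matrix of timeseries (rows = ROI vertices
#' or non-ROI sources, columns = timepoints) that records where scan runs
#' begin and end. Values are in units of percent signal change once
#' [percent_signal_change()] has been applied.
#'
#' @param data Numeric matrix, rows = vertices/sources, columns = timepoints.
#' @param run_offsets Integer vector of run boundaries: strictly increasing,
#'   starting at 0 and ending at `ncol(data)`. A recording with runs of 100
#'   and 120 timepoints has `run_offsets = c(0, 100, 220)`.
#' @return An object of class `cnp_timeseries`.
#' @export
#' @examples
#' ts <- cnp_timeseries(matrix(rnorm(40), 4, 10), run_offsets = c(0, 5, 10))
#' n_runs(ts)
cnp_timeseries <- function(data, run_offsets) {
  data <- check_matrix(data, "data")
  run_offsets <- as.integer(round(run_offsets))
  if (length(run_offsets) < 2 || run_offsets[1] != 0 ||
      run_offsets[length(run_offsets)] != ncol(data) ||
      any(diff(run_offsets) <= 0)) {
    abort("`run_offsets` must be strictly increasing, start at 0 and end at ncol(data)")
  }
  structure(list(data = data, run_offsets = run_offsets), class = "cnp_timeseries")
}

#' @export
print.cnp_timeseries <- function(x, ...) {
  cat(sprintf("<cnp_timeseries> %d series x %d timepoints in %d run(s)\n",
              nrow(x$data), ncol(x$data), n_runs(x)))
  invisible(x)
}

#' @rdname cnp_timeseries
#' @param ts A `cnp_timeseries`.
#' @export
n_runs <- function(ts) length(ts$run_offsets) - 1L

run_lengths <- function(ts) diff(ts$run_offsets)

run_columns <- function(ts, r) (ts$run_offsets[r] + 1L):ts$run_offsets[r + 1L]

#' Convert raw timeseries to percent signal change
#'
#' Each row is rescaled, run by run, to `100 * (x - mean(x)) / mean(x)` where
#' the mean is the row's temporal mean within that run. Runs are normalised
#' independently and then re-concatenated, so slow offset differences between
#' runs do not leak into the correlation structure.
#'
#' @param raw A [cnp_timeseries()] in raw signal units with non-zero row
#'   means within every run.
#' @return A [cnp_timeseries()] in percent-signal-change units; every row has
#'   zero mean within each run.
#' @export
percent_signal_change <- function(raw) {
  stopifnot(inherits(raw, "cnp_timeseries"))
  out <- raw$data
  for (r in seq_len(n_runs(raw))) {
    cols <- run_columns(raw, r)
    mu <- rowMeans(raw$data[, cols, drop = FALSE])
    if (any(abs(mu) < .Machine$double.eps * 100)) {
      abort(sprintf("row %d has (near-)zero temporal mean in run %d; percent signal change is undefined",
                    which(abs(mu) < .Machine$double.eps * 100)[1], r))
    }
    out[, cols] <- 100 * (raw$data[, cols, drop = FALSE] - mu) / mu
  }
  cnp_timeseries(out, raw$run_offsets)
}

#' Partition a recording into odd and even scan runs
#'
#' Splits a multi-run timeseries into two half-recordings — the concatenated
#' odd-numbered runs and the concatenated even-numbered runs — the data
#' partition used for cross-validated parameter selection.
#'
#' @param ts A [cnp_timeseries()] with at least two runs.
#' @return A named list with elements `odd` and `even`, each a
#'   [cnp_timeseries()].
#' @export
split_odd_even <- function(ts) {
  stopifnot(inherits(ts, "cnp_timeseries"))
  if (n_runs(ts) < 2) abort("odd/even splitting requires at least 2 runs")
  take <- function(runs) {
    cols <- unlist(lapply(runs, run_columns, ts = ts))
    cnp_timeseries(ts$data[, cols, drop = FALSE],
                   c(0L, cumsum(run_lengths(ts)[runs])))
  }
  runs <- seq_len(n_runs(ts))
  list(odd = take(runs[runs %% 2 == 1]), even = take(runs[runs %% 2 == 0]))
}

#' Replace timeseries with moment-matched Gaussian noise
#'
#' Substitutes every row with i.i.d. normal noise matched in sample mean and
#' variance to that row. The substitute reproduces amplitude differences
#' across rows but carries no consistent temporal signal — the control used
#' to show that fingerprint topography, not shared signal, drives the
#' connectopic maps.
#'
#' @param ts A [cnp_timeseries()].
#' @param seed Integer seed; the substitution is deterministic given it.
#' @return A [cnp_timeseries()] with the same shape and run boundaries.
#' @export
noise_substitute <- function(ts, seed) {
  stopifnot(inherits(ts, "cnp_timeseries"))
  if (nrow(ts$data) == 0) abort("empty timeseries")
  mu <- rowMeans(ts$data)
  sdv <- apply(ts$data, 1, sd)
  out <- with_seed_(seed, {
    matrix(rnorm(length(ts$data)), nrow(ts$data), ncol(ts$data)) * sdv + mu
  })
  cnp_timeseries(out, ts$run_offsets)
}

#' @export
tidy.cnp_timeseries <- function(x, ...) {
  run_of <- rep(seq_len(n_runs(x)), run_lengths(x))
  tibble(
    series = rep(seq_len(nrow(x$data)), each = ncol(x$data)),
    time = rep(seq_len(ncol(x$data)), nrow(x$data)),
    run = rep(run_of, nrow(x$data)),
    value = as.vector(t(x$data))
  )
}
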