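#' Detect spikes by upward threshold crossing
#'
#' A spike is registered at each upward crossing of `level`
#' (`sample[i-1] < level <= sample[i]`) inside the window; the detector
#' re-arms only after the trace falls back below the level, so one action
#' potential yields one spike. Crossing times are refined by linear
#' interpolation between the straddling samples.
#'
#' @param ss an `ek_sweepset` of membrane-potential sweeps (mV).
#' @param level detection threshold (mV); 0 mV is a common choice for
#'   somatic action potentials.
#' @param window optional [window_spec()] restricting the search (default:
#'   whole sweep).
#' @return an `ek_raster`: list with `times` (list of per-sweep spike-time
#'   vectors, ms), `level`, and `n_sweeps`.
#' @export
detect_spikes <- function(ss, level = 0, window = NULL) {
  stopifnot(inherits(ss, "ek_sweepset"))
  times <- lapply(ss$traces, function(tr) {
    idx <- if (is.null(window)) seq_along(tr$samples)
           else window_index(tr, window)
    x <- tr$samples[idx]
    tt <- trace_times(tr)[idx]
    if (length(x) < 2) return(numeric(0))
    up <- which(x[-1] >= level & x[-length(x)] < level) + 1
    if (length(up) == 0) return(numeric(0))
    ## linear interpolation of the crossing time
    frac <- (level - x[up - 1]) / (x[up] - x[up - 1])
    tt[up - 1] + frac * (tt[up] - tt[up - 1])
  })
  structure(list(times = times, level = level, n_sweeps = n_sweeps(ss)),
            class = "ek_raster")
}

#' @export
print.ek_raster <- function(x, ...) {
  cat(sprintf("<spike raster> %d sweep(s), %d spikes, level = %g mV\n",
              x$n_sweeps, sum(lengths(x$times)), x$level))
  invisible(x)
}

#' Per-sweep mean firing rate
#'
#' @param raster an `ek_raster`.
#' @param window a [window_spec()] giving the counting interval (ms).
#' @return numeric vector of rates in Hz, one per sweep.
#' @export
mean_rate <- function(raster, window) {
  if (is.numeric(window) && length(window) == 2 && diff(window) <= 0)
    stop("zero-length rate window")
  w <- as_window(window)
  dur_s <- (w$xend - w$xbgn) / 1000
  if (dur_s <= 0) stop("zero-length rate window")
  vapply(raster$times,
         function(tt) sum(tt >= w$xbgn & tt <= w$xend) / dur_s, 0)
}

#' Firing rate versus stimulus amplitude (FI relation)
#'
#' @param raster an `ek_raster`.
#' @param amplitudes per-sweep stimulus amplitude (e.g. command current, pA).
#' @param window counting window (ms).
#' @return data.frame with columns `amp` and `rate` (Hz), ordered by `amp`.
#' @export
fi_relation <- function(raster, amplitudes, window) {
  if (length(amplitudes) != raster$n_sweeps)
    stop("need one amplitude per sweep")
  rate <- mean_rate(raster, window)
  out <- data.frame(amp = amplitudes, rate = rate)
  out[order(out$amp), , drop = FALSE]
}

#' Inter-spike-interval histogram pooled across sweeps
#'
#' @param raster an `ek_raster`.
#' @param bin bin width (ms).
#' @return data.frame with columns `center` (ms) and `count`.
#' @export
isi_histogram <- function(raster, bin) {
  isi <- unlist(lapply(raster$times, function(tt)
    if (length(tt) > 1) diff(tt) else numeric(0)))
  histogram_counts(isi, bin_width = bin, origin = 0)
}

#' Peristimulus time histogram
#'
#' Counts spikes in bins of width `bin` relative to `t0` and normalizes to
#' spikes per second per sweep.
#'
#' @param raster an `ek_raster`.
#' @param bin bin width (ms).
#' @param t0 stimulus reference time (ms).
#' @return data.frame with `center` (ms relative to `t0`), `count` (pooled
#'   spike count) and `rate` (spikes/s per sweep).
#' @export
psth <- function(raster, bin, t0 = 0) {
  all_t <- unlist(raster$times) - t0
  h <- histogram_counts(all_t, bin_width = bin, origin = 0)
  h$rate <- h$count / raster$n_sweeps / (bin / 1000)
  h
}

#' Copy detected spikes into aligned sweeps
#'
#' One sweep per spike covering `[t_spike - pre_ms, t_spike + post_ms)`,
#' aligned so `t = 0` at the window start; spikes whose window falls off the
#' sweep are dropped and counted in attribute `n_dropped`.
#'
#' @param ss the source `ek_sweepset`.
#' @param raster the matching `ek_raster`.
#' @param pre_ms,post_ms window before/after the crossing (ms).
#' @return an `ek_sweepset` of spike-aligned sweeps.
#' @export
spikes_to_waves <- function(ss, raster, pre_ms = 2, post_ms = 5) {
  stopifnot(inherits(ss, "ek_sweepset"), inherits(raster, "ek_raster"),
            n_sweeps(ss) == raster$n_sweeps)
  traces <- list(); dropped <- 0L
  for (sw in seq_len(n_sweeps(ss))) {
    tr <- ss$traces[[sw]]
    len <- round((pre_ms + post_ms) / tr$dt)
    for (ts in raster$times[[sw]]) {
      i0 <- round((ts - pre_ms - tr$t_start) / tr$dt) + 1
      i1 <- i0 + len - 1
      if (i0 < 1 || i1 > length(tr$samples)) { dropped <- dropped + 1L; next }
      str <- trace(tr$samples[i0:i1], dt = tr$dt, t_start = 0,
                   units = tr$units,
                   label = sprintf("Spike%d", length(traces)))
      traces[[length(traces) + 1]] <-
        add_note(str, "spikes_to_waves",
                 sprintf("sweep=%d;t=%g;pre=%g;post=%g", sw - 1, ts, pre_ms, post_ms))
    }
  }
  out <- sweep_set(traces, prefix = "Spike")
  attr(out, "n_dropped") <- dropped
  out
}
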