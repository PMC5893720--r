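#' Configuration for sliding-baseline threshold event detection
#'
#' The detector scans sample-by-sample; at each position the baseline is the
#' mean over a window of width `baseline_win` ending `offset` ms before the
#' current sample, and a crossing fires when the sample deviates from that
#' baseline by more than the level in the configured polarity.
#'
#' @param polarity `"neg"` (inward currents / EPSCs) or `"pos"`.
#' @param level_mode `"absolute"` (level in signal units) or `"n_stdv"`
#'   (level in multiples of the rolling SD of the baseline window).
#' @param level threshold magnitude (> 0).
#' @param baseline_win sliding baseline window width b (ms; typical 2-10).
#' @param offset forward offset between baseline window and test sample (ms).
#' @param onset_win backward search window for the event onset (ms).
#' @param peak_win forward search window for the event peak (ms).
#' @param require_onset,require_peak reject events whose onset/peak search
#'   fails (rejected events are returned with `accepted = FALSE`).
#' @param min_sep minimum separation before the search re-arms (ms).
#' @param lowpass_khz optional low-pass corner applied to a detection copy of
#'   the data (the reported amplitudes still come from that filtered copy, as
#'   detection-time filtering implies); `NULL` to disable.
#' @param onset_frac fraction of the event amplitude within which the signal
#'   counts as "back at baseline" for the onset search (default 0.1).
#' @export
detection_config <- function(polarity = c("neg", "pos"),
                             level_mode = c("absolute", "n_stdv"),
                             level = 6, baseline_win = 5, offset = 2.5,
                             onset_win = 2, peak_win = 5,
                             require_onset = FALSE, require_peak = TRUE,
                             min_sep = 1, lowpass_khz = NULL,
                             onset_frac = 0.1) {
  polarity <- match.arg(polarity)
  level_mode <- match.arg(level_mode)
  stopifnot(level > 0, baseline_win > 0, offset > 0, onset_win > 0,
            peak_win > 0, min_sep >= 0, onset_frac > 0, onset_frac < 1)
  structure(list(polarity = polarity, level_mode = level_mode, level = level,
                 baseline_win = baseline_win, offset = offset,
                 onset_win = onset_win, peak_win = peak_win,
                 require_onset = require_onset, require_peak = require_peak,
                 min_sep = min_sep, lowpass_khz = lowpass_khz,
                 onset_frac = onset_frac),
            class = "ek_detcfg")
}

event_table <- function(sweep = integer(), t_cross = numeric(),
                        t_onset = numeric(), t_peak = numeric(),
                        peak_amp = numeric(), baseline = numeric(),
                        accepted = logical(), reason = character()) {
  structure(data.frame(sweep = sweep, t_cross = t_cross, t_onset = t_onset,
                       t_peak = t_peak, peak_amp = peak_amp,
                       baseline = baseline, accepted = accepted,
                       reason = reason, stringsAsFactors = FALSE),
            class = c("ek_events", "data.frame"))
}

## rolling mean/SD over the b-window ending `off_n` samples before i
rolling_baseline <- function(x, bn, off_n) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  hi <- i - off_n            # last sample of the baseline window
  lo <- hi - bn + 1
  ok <- lo >= 1
  mu <- rep(NA_real_, n)
  sdv <- rep(NA_real_, n)
  s <- cs[pmax(hi, 0) + 1] - cs[pmax(lo - 1, 0) + 1]
  s2 <- cs2[pmax(hi, 0) + 1] - cs2[pmax(lo - 1, 0) + 1]
  mu[ok] <- s[ok] / bn
  v <- pmax(s2[ok] / bn - mu[ok]^2, 0) * bn / max(bn - 1, 1)
  sdv[ok] <- sqrt(v)
  list(mean = mu, sd = sdv)
}

#' Detect spontaneous events by sliding-baseline threshold crossing
#'
#' Scans the trace left to right. At sample `i` the baseline is the mean of
#' the window `[t_i - offset - baseline_win, t_i - offset]`; a crossing fires
#' when the sample deviates from the baseline beyond the level (absolute
#' units, or multiples of the rolling baseline SD). After a crossing, the
#' peak is the polarity extremum within `peak_win` after the crossing and
#' the onset is the latest pre-crossing sample at which the signal is still
#' within `onset_frac` of the event amplitude from baseline. Events whose
#' required onset/peak search fails are returned with `accepted = FALSE` and
#' a reason. The scan resumes `min_sep` after the peak (or the crossing when
#' no peak was found).
#'
#' @param tr an `ek_trace`.
#' @param config a [detection_config()].
#' @param sweep sweep index recorded in the output table.
#' @return an event table (class `ek_events`): one row per event with
#'   `t_cross`, `t_onset`, `t_peak`, `peak_amp` (baseline-relative),
#'   `baseline`, `accepted`, `reason`.
#' @export
detect_threshold <- function(tr, config = detection_config(), sweep = 0L) {
  stopifnot(inherits(tr, "ek_trace"), inherits(config, "ek_detcfg"))
  dt <- tr$dt
  bn <- max(2L, round(config$baseline_win / dt))
  off_n <- max(1L, round(config$offset / dt))
  if (length(tr$samples) <= bn + off_n)
    stop("trace shorter than baseline window plus offset")
  x <- tr$samples
  if (!is.null(config$lowpass_khz))
    x <- conv_same(x, gaussian_kernel(dt, config$lowpass_khz))
  bl <- rolling_baseline(x, bn, off_n)
  sgn <- if (config$polarity == "neg") -1 else 1
  dev <- sgn * (x - bl$mean)                 # positive in event direction
  thr <- if (config$level_mode == "absolute") config$level
         else config$level * bl$sd
  crossed <- !is.na(dev) & dev > thr
  n <- length(x)
  tt <- trace_times(tr)
  onset_n <- round(config$onset_win / dt)
  peak_n <- round(config$peak_win / dt)
  sep_n <- max(1L, round(config$min_sep / dt))
  ev <- event_table()
  i <- bn + off_n + 1L
  cross_idx <- which(crossed)
  while (TRUE) {
    cross_idx <- cross_idx[cross_idx >= i]
    if (length(cross_idx) == 0) break
    ic <- cross_idx[1]
    base <- bl$mean[ic]
    ## peak: polarity extremum within the peak window after the crossing
    pk_end <- min(ic + peak_n, n)
    seg <- dev[ic:pk_end]
    ipk_rel <- which.max(seg)
    peak_found <- ipk_rel < length(seg)  # extremum at window edge = no turn
    ipk <- ic + ipk_rel - 1L
    amp <- sgn * seg[ipk_rel]            # signed, baseline-relative
    ## onset: last pre-crossing sample within onset_frac * |amp| of baseline
    on_bgn <- max(ic - onset_n, 1L)
    near <- dev[on_bgn:ic] <= config$onset_frac * abs(amp)
    onset_found <- any(near)
    ion <- if (onset_found) on_bgn + max(which(near)) - 1L else NA_integer_
    accepted <- TRUE; reason <- ""
    if (config$require_peak && !peak_found) { accepted <- FALSE; reason <- "no peak" }
    if (accepted && config$require_onset && !onset_found) {
      accepted <- FALSE; reason <- "no onset"
    }
    ev <- rbind(ev, event_table(
      sweep = as.integer(sweep), t_cross = tt[ic],
      t_onset = if (onset_found) tt[ion] else NA_real_,
      t_peak = if (peak_found) tt[ipk] else NA_real_,
      peak_amp = amp, baseline = base, accepted = accepted, reason = reason))
    i <- (if (peak_found) ipk else ic) + sep_n
  }
  class(ev) <- c("ek_events", "data.frame")
  ev
}

#' Template configuration for matched-filter event detection
#'
#' @param template numeric vector: the template waveform, baseline 0, unit
#'   peak magnitude (use e.g. a unit-peak [synexp_params()] waveform sampled
#'   at the data `dt`, or a normalized average of detected events).
#' @param level detection criterion level; negative (e.g. -3 or -4) for
#'   negative-going events against a positive unit template.
#' @param polarity `"neg"` or `"pos"`: which side of the criterion counts.
#' @param min_sep minimum separation between events (ms).
#' @export
template_config <- function(template, level = -3,
                            polarity = c("neg", "pos"), min_sep = 1) {
  polarity <- match.arg(polarity)
  template <- as.numeric(template)
  if (length(template) < 3) stop("template needs at least 3 samples")
  if (stats::sd(template) == 0) stop("template must not be constant")
  structure(list(template = template, level = level, polarity = polarity,
                 min_sep = min_sep), class = "ek_tmplcfg")
}

#' Detect events by sliding template matching
#'
#' At every offset `k` the data segment is fit to `s * template + c` by least
#' squares (closed form via rolling sums); the detection criterion is
#' `DC(k) = s / sigma_res` with `sigma_res = sqrt(SSE / (K - 1))`. The
#' criterion is scale-free: adding a constant to the data is absorbed by `c`.
#' An event is registered at the extremum of `DC` within each contiguous
#' region beyond the criterion level, respecting `min_sep`.
#'
#' @param tr an `ek_trace`.
#' @param config a [template_config()].
#' @param sweep sweep index recorded in the output table.
#' @return list with `criterion` (the `DC` trace, aligned to the template
#'   start) and `events` (an `ek_events` table; `peak_amp` is the fitted
#'   template scale `s`, `baseline` the fitted offset `c`).
#' @export
detect_template <- function(tr, config, sweep = 0L) {
  stopifnot(inherits(tr, "ek_trace"), inherits(config, "ek_tmplcfg"))
  w <- config$template
  K <- length(w)
  x <- tr$samples
  n <- length(x)
  if (K >= n) stop("template must be shorter than the trace")
  Sw <- sum(w); Sww <- sum(w^2)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  m <- n - K + 1
  Sd <- cs[(K + 1):(n + 1)] - cs[1:m]
  Sdd <- cs2[(K + 1):(n + 1)] - cs2[1:m]
  ## sliding cross-correlation sum(d * w) via FFT convolution
  Sdw <- as.numeric(stats::convolve(x, w, conj = TRUE, type = "filter"))
  denom <- K * Sww - Sw^2
  s <- (K * Sdw - Sw * Sd) / denom
  cc <- (Sd - s * Sw) / K
  sse <- Sdd + s^2 * Sww + K * cc^2 - 2 * s * Sdw - 2 * cc * Sd + 2 * s * cc * Sw
  sse <- pmax(sse, 0)
  sigma <- sqrt(sse / (K - 1))
  dc <- s / pmax(sigma, 1e-12)   # epsilon guard for perfect matches
  sgn <- if (config$polarity == "neg") -1 else 1
  score <- sgn * dc              # positive beyond criterion in event direction
  thr <- abs(config$level)
  above <- score > thr
  sep_n <- max(1L, round(config$min_sep / tr$dt))
  tt <- trace_times(tr)
  ev <- event_table()
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  last_i <- -Inf
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    ipk <- seg[which.max(score[seg])]
    if (ipk - last_i < sep_n) next
    last_i <- ipk
    ev <- rbind(ev, event_table(
      sweep = as.integer(sweep), t_cross = tt[ipk], t_onset = NA_real_,
      t_peak = NA_real_, peak_amp = s[ipk], baseline = cc[ipk],
      accepted = TRUE, reason = ""))
  }
  class(ev) <- c("ek_events", "data.frame")
  crit <- trace(dc, dt = tr$dt, t_start = tr$t_start, units = "",
                label = "detection_criterion")
  list(criterion = add_note(crit, "detect_template",
                            sprintf("K=%d;level=%g", K, config$level)),
       events = ev)
}

#' Copy detected events into an aligned sweep set
#'
#' Each accepted event is copied to its own sweep covering
#' `[t_cross - pre_ms, t_cross + post_ms)` (half-open, so the sweep length is
#' `round((pre_ms + post_ms)/dt)` samples) with `t = 0` at the window start.
#' Events whose window falls off the trace are dropped and counted.
#'
#' @param tr the source `ek_trace`.
#' @param events an `ek_events` table.
#' @param pre_ms,post_ms window before/after the crossing time (ms).
#' @return an `ek_sweepset` (attribute `n_dropped` counts edge events).
#' @export
events_to_waves <- function(tr, events, pre_ms = 5, post_ms = 25) {
  stopifnot(inherits(tr, "ek_trace"))
  acc <- events[events$accepted, , drop = FALSE]
  acc <- acc[order(acc$t_cross), , drop = FALSE]
  len <- round((pre_ms + post_ms) / tr$dt)
  tt0 <- tr$t_start
  traces <- list(); dropped <- 0L
  for (k in seq_len(nrow(acc))) {
    i0 <- round((acc$t_cross[k] - pre_ms - tt0) / tr$dt) + 1
    i1 <- i0 + len - 1
    if (i0 < 1 || i1 > length(tr$samples)) { dropped <- dropped + 1L; next }
    etr <- trace(tr$samples[i0:i1], dt = tr$dt, t_start = 0,
                 units = tr$units, label = sprintf("Event%d", k - 1))
    traces[[length(traces) + 1]] <-
      add_note(etr, "events_to_waves",
               sprintf("t_cross=%g;pre=%g;post=%g", acc$t_cross[k], pre_ms, post_ms))
  }
  if (dropped > 0)
    warning(sprintf("%d event(s) dropped at trace edges", dropped))
  out <- sweep_set(traces, prefix = "Event")
  attr(out, "n_dropped") <- dropped
  out
}

#' Accept or reject a detected event
#'
#' @param events an `ek_events` table.
#' @param index row index (1-based), or a vector of indices.
#' @param accept logical flag to store.
#' @param reason reason string stored alongside the flag.
#' @return the updated table; attribute `counts` holds the accepted/rejected
#'   totals.
#' @export
review_set <- function(events, index, accept, reason = "") {
  if (any(index < 1 | index > nrow(events))) stop("invalid event index")
  events$accepted[index] <- accept
  events$reason[index] <- reason
  attr(events, "counts") <- c(accepted = sum(events$accepted),
                              rejected = sum(!events$accepted))
  events
}

#' Build a unit-normalized template from detected events
#'
#' Averages the accepted events (copied with [events_to_waves()]) and
#' normalizes the average to baseline 0, peak magnitude 1, truncated to
#' `length_ms` with `baseline_ms` of pre-onset baseline.
#'
#' @param tr source trace.
#' @param events `ek_events` table.
#' @param length_ms template length (ms).
#' @param baseline_ms leading baseline retained before the crossing (ms).
#' @return numeric template vector suitable for [template_config()].
#' @export
make_template <- function(tr, events, length_ms = 3, baseline_ms = 0.2) {
  ss <- events_to_waves(tr, events, pre_ms = baseline_ms,
                        post_ms = length_ms - baseline_ms)
  if (n_sweeps(ss) == 0) stop("no accepted events to average")
  avg <- average_sweeps(ss)$mean
  nb <- max(1L, round(baseline_ms / tr$dt))
  y <- avg$samples - mean(avg$samples[1:nb])
  pk <- y[which.max(abs(y))]
  if (pk == 0) stop("flat average; cannot normalize template")
  ## dividing by the signed peak gives baseline 0, peak +1; negative events
  ## then yield negative fitted scales and a negative detection criterion
  y / pk
}
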