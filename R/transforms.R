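#' Subtract the mean within a baseline window
#'
#' Computes the average value within `window` (typically a ~1 ms window just
#' before the stimulus) and subtracts it from the whole trace.
#'
#' @param tr an `ek_trace`.
#' @param window a [window_spec()] or numeric `c(xbgn, xend)` in ms.
#' @return the baseline-subtracted trace (one note appended).
#' @export
baseline_subtract <- function(tr, window) {
  stopifnot(inherits(tr, "ek_trace"))
  idx <- window_index(tr, window)
  b <- mean(tr$samples[idx])
  w <- as_window(window)
  tr$samples <- tr$samples - b
  add_note(tr, "baseline_subtract",
           sprintf("xbgn=%g;xend=%g;mean=%.6g", w$xbgn, w$xend, b))
}

## reflection padding used by the FIR smoothers: x[-1] mirrors x[2] etc.
reflect_pad <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  k <- min(k, n - 1)
  c(x[(k + 1):2], x, x[(n - 1):(n - k)])
}

conv_same <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  xp <- reflect_pad(x, half)
  as.numeric(stats::filter(xp, kernel, method = "convolution",
                           sides = 2))[(half + 1):(half + length(x))]
}

#' Binomial smoothing
#'
#' Applies the (1, 2, 1)/4 binomial kernel `n_passes` times, with reflection
#' at the edges; `n` passes equal one convolution with the order-2n binomial
#' kernel. Length is preserved.
#'
#' @param tr an `ek_trace`.
#' @param n_passes number of passes (>= 0; 0 is the identity).
#' @export
smooth_binomial <- function(tr, n_passes) {
  stopifnot(inherits(tr, "ek_trace"), n_passes >= 0)
  n_passes <- as.integer(n_passes)
  x <- tr$samples
  for (i in seq_len(n_passes)) x <- conv_same(x, c(1, 2, 1) / 4)
  tr$samples <- x
  add_note(tr, "smooth_binomial", sprintf("n_passes=%d", n_passes))
}

## Gaussian FIR kernel with -3 dB at f_c (kHz when dt is in ms):
## |G(f)| = exp(-2 pi^2 sigma^2 f^2) = 2^(-1/2) at f = f_c
gaussian_kernel <- function(dt, f_c) {
  sigma <- sqrt(log(2) / 2) / (pi * f_c * sqrt(2))  # ms
  half <- max(1L, ceiling(4 * sigma / dt))
  k <- exp(-((-half:half) * dt)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Zero-phase Gaussian low-pass filter
#'
#' Symmetric Gaussian FIR with its -3 dB point at `f_c`; zero phase shift and
#' unit DC gain, reflection padding at the edges.
#'
#' @param tr an `ek_trace`.
#' @param f_c corner frequency in kHz; must be below Nyquist (`1/(2 dt)`).
#' @export
lowpass <- function(tr, f_c) {
  stopifnot(inherits(tr, "ek_trace"))
  nyq <- 1 / (2 * tr$dt)
  if (!(f_c > 0 && f_c < nyq))
    stop(sprintf("f_c must be in (0, %g) kHz (Nyquist for dt = %g ms)",
                 nyq, tr$dt))
  tr$samples <- conv_same(tr$samples, gaussian_kernel(tr$dt, f_c))
  add_note(tr, "lowpass", sprintf("f_c=%g kHz", f_c))
}

#' Align sweeps by per-sweep time offsets
#'
#' Shifts each trace's `t_start` by minus its offset so that the per-sweep
#' reference time (e.g. a fitted onset `t0`) lands at time zero. Samples are
#' untouched.
#'
#' @param ss an `ek_sweepset`.
#' @param offsets numeric vector of reference times (ms), one per sweep.
#' @export
align_sweeps <- function(ss, offsets) {
  stopifnot(inherits(ss, "ek_sweepset"))
  if (length(offsets) != n_sweeps(ss))
    stop("need exactly one offset per sweep")
  ss$traces <- Map(function(tr, off) {
    tr$t_start <- tr$t_start - off
    add_note(tr, "align", sprintf("offset=%g", off))
  }, ss$traces, offsets)
  ss
}

#' Resample all sweeps onto a common grid
#'
#' Linear interpolation of every sweep onto a shared grid with step
#' `dt_target`, covering the intersection of all sweep time ranges.
#'
#' @param ss an `ek_sweepset`.
#' @param dt_target target sample interval (ms).
#' @export
interpolate_common <- function(ss, dt_target) {
  stopifnot(inherits(ss, "ek_sweepset"), dt_target > 0)
  t0 <- max(vapply(ss$traces, function(tr) tr$t_start, 0))
  t1 <- min(vapply(ss$traces, trace_t_end, 0))
  if (t1 <= t0) stop("sweep time ranges have empty intersection")
  grid <- seq(t0, t1, by = dt_target)
  ss$traces <- lapply(ss$traces, function(tr) {
    y <- stats::approx(trace_times(tr), tr$samples, xout = grid)$y
    out <- trace(y, dt = dt_target, t_start = t0, units = tr$units,
                 label = tr$label)
    out$notes <- tr$notes
    add_note(out, "interpolate", sprintf("dt=%g;t=[%g,%g]", dt_target, t0, t1))
  })
  ss
}

check_common_grid <- function(ss) {
  dts <- vapply(ss$traces, function(tr) tr$dt, 0)
  t0s <- vapply(ss$traces, function(tr) tr$t_start, 0)
  ns <- vapply(ss$traces, function(tr) length(tr$samples), 0L)
  if (diff(range(dts)) > 1e-12 * max(dts) ||
      diff(range(t0s)) > 1e-9 ||
      diff(range(ns)) != 0)
    stop("sweeps are not on a common grid; run interpolate_common() first")
}

#' Pointwise mean and standard deviation of sweeps
#'
#' @param ss an `ek_sweepset` whose sweeps share a grid.
#' @return list with elements `mean` and `stdv` (both `ek_trace`; `stdv` is
#'   the pointwise sample standard deviation, 0 for a single sweep).
#' @export
average_sweeps <- function(ss) {
  stopifnot(inherits(ss, "ek_sweepset"), n_sweeps(ss) >= 1)
  check_common_grid(ss)
  m <- do.call(cbind, lapply(ss$traces, function(tr) tr$samples))
  tr1 <- ss$traces[[1]]
  mu <- trace(rowMeans(m), dt = tr1$dt, t_start = tr1$t_start,
              units = tr1$units, label = paste0("Avg_", ss$prefix))
  sdv <- if (ncol(m) > 1) apply(m, 1, stats::sd) else rep(0, nrow(m))
  sd_tr <- trace(sdv, dt = tr1$dt, t_start = tr1$t_start, units = tr1$units,
                 label = paste0("Stdv_Avg_", ss$prefix))
  note <- sprintf("n=%d;sweeps=%s", n_sweeps(ss),
                  paste(seq_len(n_sweeps(ss)) - 1, collapse = ","))
  list(mean = add_note(mu, "average", note),
       stdv = add_note(sd_tr, "average", note))
}

unit_divide <- function(u_num, u_den) {
  if (u_num == "pA" && u_den == "mV") return("nS")  # pA/mV = nS exactly
  if (u_num == u_den) return("")
  paste0(u_num, "/", u_den)
}

#' Combine a trace with a scalar or another trace, pointwise
#'
#' Elementwise subtract/divide/multiply/assign; used e.g. to subtract a
#' fitted artifact template point-by-point, or to convert current to
#' conductance by dividing by the driving force (pA / mV yields nS).
#'
#' @param tr an `ek_trace`.
#' @param other a scalar or an `ek_trace` of the same length.
#' @param op one of `"subtract"`, `"divide"`, `"multiply"`, `"assign"`.
#' @param units optional unit string for the result; for `"divide"` the
#'   pA/mV -> nS conversion is applied automatically when units are carried.
#' @export
pointwise_combine <- function(tr, other,
                              op = c("subtract", "divide", "multiply", "assign"),
                              units = NULL) {
  stopifnot(inherits(tr, "ek_trace"))
  op <- match.arg(op)
  if (inherits(other, "ek_trace")) {
    if (length(other$samples) != length(tr$samples))
      stop("traces have different lengths")
    y <- other$samples
    o_units <- other$units
    desc <- sprintf("trace '%s'", other$label)
  } else {
    stopifnot(is.numeric(other), length(other) == 1)
    y <- other
    o_units <- ""
    desc <- format(other)
  }
  if (op == "divide" && any(y == 0))
    stop("division by zero in pointwise_combine")
  tr$samples <- switch(op,
    subtract = tr$samples - y,
    divide   = tr$samples / y,
    multiply = tr$samples * y,
    assign   = rep_len(y, length(tr$samples)))
  if (!is.null(units)) {
    tr$units <- units
  } else if (op == "divide" && nzchar(o_units)) {
    tr$units <- unit_divide(tr$units, o_units)
  }
  add_note(tr, "pointwise_combine", sprintf("op=%s;other=%s", op, desc))
}

#' Replace intervals by linear interpolation (clip events)
#'
#' Replaces samples inside each interval with the straight line joining the
#' samples just outside its boundaries. Used to remove stimulus artifacts
#' before averaging or conductance conversion.
#'
#' @param tr an `ek_trace`.
#' @param intervals list of windows (each a [window_spec()] or `c(xbgn,xend)`).
#' @export
clip_segments <- function(tr, intervals) {
  stopifnot(inherits(tr, "ek_trace"))
  if (length(intervals) == 0) return(tr)
  ws <- lapply(intervals, as_window)
  ord <- order(vapply(ws, function(w) w$xbgn, 0))
  ws <- ws[ord]
  tt <- trace_times(tr)
  prev_end <- -Inf
  for (w in ws) {
    if (w$xbgn <= prev_end) stop("clip intervals overlap")
    if (w$xbgn < tr$t_start || w$xend > trace_t_end(tr))
      stop("clip interval out of trace range")
    prev_end <- w$xend
    idx <- which(tt >= w$xbgn & tt <= w$xend)
    if (length(idx) == 0) next
    i0 <- max(min(idx) - 1, 1)
    i1 <- min(max(idx) + 1, length(tt))
    tr$samples[idx] <- stats::approx(c(tt[i0], tt[i1]),
                                     c(tr$samples[i0], tr$samples[i1]),
                                     xout = tt[idx])$y
  }
  add_note(tr, "clip_segments",
           paste(vapply(ws, function(w) sprintf("[%g,%g]", w$xbgn, w$xend), ""),
                 collapse = ";"))
}

#' Concatenate sweeps into one continuous trace
#'
#' @param ss an `ek_sweepset` whose sweeps share `dt` and units.
#' @return one `ek_trace` with the samples appended in sweep order and
#'   `t_start` taken from the first sweep.
#' @export
concatenate_sweeps <- function(ss) {
  stopifnot(inherits(ss, "ek_sweepset"), n_sweeps(ss) >= 1)
  dts <- vapply(ss$traces, function(tr) tr$dt, 0)
  if (diff(range(dts)) > 1e-12 * max(dts)) stop("dt mismatch across sweeps")
  us <- unique(vapply(ss$traces, function(tr) tr$units, ""))
  if (length(us) != 1) stop("unit mismatch across sweeps")
  tr1 <- ss$traces[[1]]
  out <- trace(unlist(lapply(ss$traces, function(tr) tr$samples)),
               dt = tr1$dt, t_start = tr1$t_start, units = us,
               label = paste0("C_", ss$prefix))
  add_note(out, "concatenate", sprintf("n=%d", n_sweeps(ss)))
}

#' Fixed-width histogram with left-closed bins
#'
#' Bin edges are `origin + k * bin_width`; bins are left-closed, right-open,
#' so counts always sum to the number of finite values.
#'
#' @param values numeric vector (non-finite values dropped).
#' @param bin_width bin width (> 0).
#' @param origin left edge of the bin lattice.
#' @return data.frame with columns `center` and `count`.
#' @export
histogram_counts <- function(values, bin_width, origin = 0) {
  stopifnot(bin_width > 0)
  values <- values[is.finite(values)]
  if (length(values) == 0)
    return(data.frame(center = numeric(), count = integer()))
  k <- floor((values - origin) / bin_width)
  tab <- table(k)
  kk <- as.integer(names(tab))
  full <- seq(min(kk), max(kk))
  counts <- integer(length(full))
  counts[match(kk, full)] <- as.integer(tab)
  data.frame(center = origin + (full + 0.5) * bin_width, count = counts)
}

#' Min-max normalize a trace on a window
#'
#' Maps the samples to `(x - min) / (max - min)` using the extrema within
#' `window` (default: whole trace). A display/analysis convention, not tied
#' to any acquisition semantics.
#' @param tr an `ek_trace`.
#' @param window optional window restricting where min/max are taken.
#' @export
normalize_trace <- function(tr, window = NULL) {
  stopifnot(inherits(tr, "ek_trace"))
  idx <- if (is.null(window)) seq_along(tr$samples) else window_index(tr, window)
  lo <- min(tr$samples[idx]); hi <- max(tr$samples[idx])
  if (hi == lo) stop("cannot normalize a constant window")
  tr$samples <- (tr$samples - lo) / (hi - lo)
  tr$units <- ""
  add_note(tr, "normalize", sprintf("min=%g;max=%g", lo, hi))
}

#' Differentiate a trace by central differences
#'
#' Interior samples use `(x[i+1] - x[i-1]) / (2 dt)`; the end points use
#' one-sided differences. Length is preserved.
#' @param tr an `ek_trace`.
#' @export
differentiate_trace <- function(tr) {
  stopifnot(inherits(tr, "ek_trace"))
  x <- tr$samples; n <- length(x)
  if (n < 2) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / tr$dt
  d[n] <- (x[n] - x[n - 1]) / tr$dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * tr$dt)
  tr$samples <- d
  tr$units <- paste0(tr$units, "/ms")
  add_note(tr, "differentiate", "central")
}
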