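#' Multi-exponential synaptic waveform parameters
#'
#' Parameterizes the product-form synaptic waveform
#' \deqn{Y(t) = [1 - e^{-(t-t_0)/\tau_r}]^n \, [a_{d1} e^{-(t-t_0)/\tau_{d1}}
#'   + a_{d2} e^{-(t-t_0)/\tau_{d2}}]}
#' for `t >= t0` and 0 before onset: a sigmoid-like rise raised to exponent
#' `n` times a sum of one or two decaying exponentials. This family describes
#' AMPA-receptor EPSC time courses well and is the quantal waveform used by
#' the release simulator.
#'
#' @param t0 onset time (ms).
#' @param tau_r rise time constant (ms, > 0).
#' @param n rise exponent (>= 1).
#' @param a_d1,tau_d1 amplitude and time constant (ms) of the fast decay.
#' @param a_d2,tau_d2 amplitude and time constant (ms) of the slow decay;
#'   `a_d2 = 0` disables the second component.
#' @return An object of class `ek_synexp`.
#' @export
synexp_params <- function(t0 = 0, tau_r = 0.2, n = 1,
                          a_d1 = 1, tau_d1 = 1, a_d2 = 0, tau_d2 = 1) {
  stopifnot(tau_r > 0, tau_d1 > 0, n >= 1)
  if (a_d2 != 0 && tau_d2 <= 0) stop("tau_d2 must be > 0 when a_d2 != 0")
  structure(list(t0 = t0, tau_r = tau_r, n = n, a_d1 = a_d1,
                 tau_d1 = tau_d1, a_d2 = a_d2, tau_d2 = tau_d2),
            class = "ek_synexp")
}

#' Evaluate the synaptic waveform
#'
#' @param params an [synexp_params()] object.
#' @param t numeric vector of times (ms); values before `t0` give 0.
#' @return numeric vector `Y(t)`.
#' @export
synexp_eval <- function(params, t) {
  p <- params
  u <- t - p$t0
  y <- numeric(length(t))
  pos <- u >= 0
  if (any(pos)) {
    up <- u[pos]
    rise <- (1 - exp(-up / p$tau_r))^p$n
    dec <- p$a_d1 * exp(-up / p$tau_d1)
    if (p$a_d2 != 0) dec <- dec + p$a_d2 * exp(-up / p$tau_d2)
    y[pos] <- rise * dec
  }
  y
}

#' Rescale a synaptic waveform to unit peak
#'
#' Finds the extremum of `|Y|` by golden-section search (tolerance 1e-6 ms)
#' and rescales both decay amplitudes by a common factor so the peak
#' magnitude is exactly 1. Needed so per-site quantal amplitudes scale a
#' unit-peak waveform.
#'
#' @param params an [synexp_params()] object.
#' @return list with `params` (rescaled), `peak_time` (ms), `scale` (the
#'   factor applied) and `peak_value` (signed peak of the input waveform).
#' @export
synexp_unit_peak <- function(params) {
  p <- params
  span <- 20 * max(p$tau_d1, if (p$a_d2 != 0) p$tau_d2 else 0, p$tau_r)
  opt <- stats::optimize(function(t) abs(synexp_eval(p, t)),
                         interval = c(p$t0, p$t0 + span),
                         maximum = TRUE, tol = 1e-6)
  peak_abs <- opt$objective
  if (peak_abs == 0) stop("degenerate waveform: peak is zero")
  peak_val <- synexp_eval(p, opt$maximum)
  scale <- 1 / peak_abs
  p$a_d1 <- p$a_d1 * scale
  p$a_d2 <- p$a_d2 * scale
  list(params = p, peak_time = opt$maximum, scale = scale,
       peak_value = peak_val)
}

#' Square-pulse protocol specification
#'
#' @param amp amplitude of sweep 0 (signal units).
#' @param delta per-sweep amplitude increment.
#' @param onset pulse onset (ms).
#' @param width pulse width (ms, > 0).
#' @param sweeps `"all"` or an integer vector of 0-based sweep indices.
#' @export
pulse_spec <- function(amp = 0, delta = 0, onset = 0, width = 1,
                       sweeps = "all") {
  stopifnot(width > 0)
  structure(list(shape = "square", amp = amp, delta = delta, onset = onset,
                 width = width, sweeps = sweeps), class = "ek_pulse")
}

#' Parse a pulse configuration string
#'
#' Accepts the semicolon-delimited `key = value` notation used in stimulus
#' protocols, e.g. `"wave = all;pulse = square;amp = 0,delta = 5;onset =
#' 50;width = 1,000;"`. Whitespace is ignored; thousands separators inside
#' numbers (`1,000`) are stripped; `amp = 0,delta = 5` style compound fields
#' are understood.
#'
#' @param text configuration string.
#' @return a [pulse_spec()].
#' @export
parse_pulse_config <- function(text) {
  fields <- strsplit(text, ";", fixed = TRUE)[[1]]
  fields <- trimws(fields[nzchar(trimws(fields))])
  kv <- list()
  for (f in fields) {
    eqs <- gregexpr("=", f, fixed = TRUE)[[1]]
    ## a comma followed by a known key starts a new pair ("amp = 0,delta = 5");
    ## a comma between digits is a thousands separator ("width = 1,000")
    parts <- strsplit(f, ",(?=\\s*[A-Za-z])", perl = TRUE)[[1]]
    for (p in parts) {
      p <- trimws(p)
      if (!grepl("=", p)) stop(sprintf("malformed token '%s'", p))
      key <- trimws(sub("=.*", "", p))
      val <- trimws(sub("^[^=]*=", "", p))
      kv[[tolower(key)]] <- val
    }
  }
  num <- function(v) as.numeric(gsub(",", "", v, fixed = TRUE))
  known <- c("wave", "pulse", "amp", "delta", "onset", "width")
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop(sprintf("unknown key '%s'", bad[1]))
  shape <- if (is.null(kv$pulse)) "square" else tolower(kv$pulse)
  if (shape != "square") stop(sprintf("unsupported shape '%s'", shape))
  sweeps <- if (is.null(kv$wave) || tolower(kv$wave) == "all") "all"
            else as.integer(num(strsplit(kv$wave, " ")[[1]]))
  pulse_spec(amp = if (is.null(kv$amp)) 0 else num(kv$amp),
             delta = if (is.null(kv$delta)) 0 else num(kv$delta),
             onset = if (is.null(kv$onset)) 0 else num(kv$onset),
             width = if (is.null(kv$width)) stop("missing width") else num(kv$width),
             sweeps = sweeps)
}

#' Generate a family of square-pulse command sweeps
#'
#' Sweep `k` (0-based) takes the value `amp + k * delta` on
#' `[onset, onset + width)` and 0 elsewhere, reproducing incrementing
#' command families such as current steps for an FI protocol.
#'
#' @param spec a [pulse_spec()].
#' @param n_sweeps number of sweeps (>= 1).
#' @param dt sample interval (ms).
#' @param length_ms sweep duration (ms); must contain the pulse.
#' @param units unit string for the sweeps.
#' @return an `ek_sweepset`.
#' @export
make_pulse_sweeps <- function(spec, n_sweeps, dt, length_ms, units = "pA") {
  stopifnot(inherits(spec, "ek_pulse"), n_sweeps >= 1)
  if (spec$onset + spec$width > length_ms)
    stop("pulse extends past the sweep end")
  n <- round(length_ms / dt)
  tt <- (seq_len(n) - 1) * dt
  on <- tt >= spec$onset & tt < spec$onset + spec$width
  traces <- lapply(seq_len(n_sweeps) - 1, function(k) {
    a <- if (identical(spec$sweeps, "all") || k %in% spec$sweeps)
      spec$amp + k * spec$delta else 0
    tr <- trace(ifelse(on, a, 0), dt = dt, t_start = 0, units = units,
                label = sprintf("pulse_%d", k))
    add_note(tr, "make_pulse",
             sprintf("amp=%g;delta=%g;onset=%g;width=%g;k=%d",
                     spec$amp, spec$delta, spec$onset, spec$width, k))
  })
  sweep_set(traces, prefix = "pulse")
}

#' Poisson event train with a refractory dead time
#'
#' Draws strictly increasing event times in `(0, t_max]` whose inter-event
#' intervals are `dead_ms` plus an exponential. The exponential mean is
#' corrected to `1000/f - dead_ms` so the asymptotic mean rate equals `f`
#' despite the refractory dead time (a plain rejection scheme would bias the
#' rate low).
#'
#' @param f mean event rate (Hz, > 0).
#' @param t_max train duration (ms).
#' @param dead_ms minimum interval between events (ms, default 1).
#' @param seed optional integer seed (set for reproducibility).
#' @return numeric vector of event times (ms).
#' @export
poisson_times <- function(f, t_max, dead_ms = 1, seed = NULL) {
  stopifnot(f > 0, t_max > 0, dead_ms >= 0)
  mean_iei <- 1000 / f
  if (mean_iei <= dead_ms)
    stop(sprintf("infeasible rate: f = %g Hz needs mean interval %g ms <= dead time %g ms",
                 f, mean_iei, dead_ms))
  if (!is.null(seed)) set.seed(seed)
  exp_mean <- mean_iei - dead_ms
  times <- numeric(0)
  t <- 0
  ## draw in blocks to avoid sample-by-sample loops
  repeat {
    k <- max(16, ceiling((t_max - t) / mean_iei * 1.5))
    iv <- dead_ms + stats::rexp(k, rate = 1 / exp_mean)
    cs <- t + cumsum(iv)
    times <- c(times, cs[cs <= t_max])
    t <- cs[length(cs)]
    if (t > t_max) break
  }
  times
}
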