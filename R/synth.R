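#' Synthetic continuous recording with embedded synaptic events
#'
#' Builds a noisy baseline trace with multi-exponential events of known
#' times and amplitudes, for exercising the event detectors against ground
#' truth. Noise is white Gaussian by default; pass `noise_tau_ms` to filter
#' it through a single pole for colored noise closer to real recordings.
#'
#' @param n_events number of events (ignored when `times` is given).
#' @param amp_mean,amp_sd event peak amplitude statistics (pA; negative mean
#'   for inward events).
#' @param kinetics an [synexp_params()]; rescaled to unit peak internally.
#' @param times optional explicit event times (ms); otherwise uniform with
#'   a minimum separation of `min_sep`.
#' @param duration_ms,dt trace duration and sample interval (ms).
#' @param noise_sd Gaussian noise SD (pA).
#' @param drift linear drift over the whole trace (pA; 0 disables).
#' @param min_sep minimum event separation when drawing times (ms).
#' @param noise_tau_ms optional single-pole filter time constant for the
#'   noise (ms; `NULL` keeps it white).
#' @param seed integer seed.
#' @return list with `trace` (an `ek_trace`) and `truth` (data.frame:
#'   `time`, `amplitude`; plus the generator parameters as attributes).
#' @export
synth_event_trace <- function(n_events = 20, amp_mean = -20, amp_sd = 0,
                              kinetics = quantal_kinetics_default(),
                              times = NULL, duration_ms = 1000, dt = 0.02,
                              noise_sd = 2, drift = 0, min_sep = 50,
                              noise_tau_ms = NULL, seed = 0) {
  set.seed(seed)
  if (is.null(times)) {
    if (n_events > 0) {
      lo <- 20; hi <- duration_ms - 35
      slots <- seq(lo, max(hi, lo), length.out = max(n_events, 1))
      g <- if (n_events > 1) diff(slots)[1] else Inf
      if (g < min_sep)
        warning("event density too high for the requested separation")
      ## jittered regular placement; jitter bounded so separation >= min_sep
      jit_amp <- if (is.finite(g)) max(0, (g - min_sep) / 2) else min_sep
      times <- sort(slots + stats::runif(n_events, -1, 1) * jit_amp)
    } else times <- numeric(0)
  } else times <- sort(times)
  amps <- if (length(times)) stats::rnorm(length(times), amp_mean, amp_sd)
          else numeric(0)
  up <- synexp_unit_peak(kinetics)
  n <- round(duration_ms / dt)
  tt <- (seq_len(n) - 1) * dt
  y <- numeric(n)
  for (k in seq_along(times)) {
    i0 <- max(1L, floor(times[k] / dt))
    i1 <- min(n, i0 + round(30 / dt))       # events decay within ~30 ms
    y[i0:i1] <- y[i0:i1] + amps[k] * synexp_eval(up$params, tt[i0:i1] - times[k])
  }
  if (noise_sd > 0) {
    eps <- stats::rnorm(n, 0, noise_sd)
    if (!is.null(noise_tau_ms)) {
      a <- exp(-dt / noise_tau_ms)
      eps <- as.numeric(stats::filter(eps * sqrt(1 - a^2), a,
                                      method = "recursive"))
    }
    y <- y + eps
  }
  if (drift != 0) y <- y + seq(0, drift, length.out = n)
  tr <- trace(y, dt = dt, t_start = 0, units = "pA", label = "synth_events")
  tr <- add_note(tr, "synth_event_trace",
                 sprintf("n=%d;amp=%g;noise=%g;seed=%d",
                         length(times), amp_mean, noise_sd, seed))
  truth <- data.frame(time = times, amplitude = amps)
  attr(truth, "params") <- list(noise_sd = noise_sd, dt = dt, seed = seed,
                                peak_time = up$peak_time)
  list(trace = tr, truth = truth)
}

default_ap_template <- function(dt) {
  ## stylized action potential: fast depolarizing lobe crossing 0 mV,
  ## afterhyperpolarization, total ~4 ms, baseline-relative (mV)
  tt <- seq(0, 4, by = dt)
  up <- 110 * exp(-((tt - 0.8) / 0.25)^2)
  ahp <- -8 * exp(-((tt - 1.6) / 0.8)^2)
  up + ahp
}

#' Synthetic membrane-potential trace with inserted action potentials
#'
#' Places a stereotyped action-potential waveform (peaking well above 0 mV)
#' at the requested spike times on a resting-potential baseline with
#' optional noise, for exercising the spike detector.
#'
#' @param spike_times spike times (ms); APs must not overlap.
#' @param resting_mv resting potential (mV).
#' @param noise_sd Gaussian noise SD (mV).
#' @param duration_ms,dt duration and sample interval (ms).
#' @param ap_template optional numeric AP waveform (mV, baseline-relative)
#'   sampled at `dt`; must cross `0 - resting_mv`.
#' @param seed integer seed.
#' @return list with `trace` and `truth` (data.frame `time`).
#' @export
synth_vm_trace <- function(spike_times, resting_mv = -70, noise_sd = 0.5,
                           duration_ms = 1000, dt = 0.05,
                           ap_template = NULL, seed = 0) {
  set.seed(seed)
  spike_times <- sort(spike_times)
  tmpl <- if (is.null(ap_template)) default_ap_template(dt) else ap_template
  if (max(tmpl) + resting_mv <= 0)
    stop("AP template does not cross 0 mV from the resting potential")
  ap_len <- length(tmpl) * dt
  if (length(spike_times) > 1 && any(diff(spike_times) < ap_len))
    stop("action potentials overlap; increase spike-time separation")
  n <- round(duration_ms / dt)
  y <- rep(resting_mv, n)
  for (ts in spike_times) {
    i0 <- round(ts / dt) + 1
    i1 <- min(i0 + length(tmpl) - 1, n)
    if (i0 < 1 || i0 > n) next
    y[i0:i1] <- y[i0:i1] + tmpl[1:(i1 - i0 + 1)]
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  tr <- trace(y, dt = dt, t_start = 0, units = "mV", label = "synth_vm")
  tr <- add_note(tr, "synth_vm_trace",
                 sprintf("n=%d;rest=%g;noise=%g;seed=%d",
                         length(spike_times), resting_mv, noise_sd, seed))
  list(trace = tr, truth = data.frame(time = spike_times))
}

#' Synthetic MPFA dataset by direct binomial sampling
#'
#' Draws per-trial peak amplitudes straight from the multinomial release
#' model measured at the peak (no waveform kinetics, no latency), plus
#' Gaussian background samples — a fast generator for exercising the
#' variance-mean fit against exact binomial ground truth.
#'
#' @param n_sites,q_p,cv_qs,cv_qii release-model parameters as in
#'   [quantal_config()].
#' @param p_levels release probabilities, one condition each.
#' @param n_per trials per condition.
#' @param background_sd background noise SD (pA).
#' @param precision site-set precision (as [sample_site_amplitudes()]).
#' @param seed integer seed.
#' @return list with `peaks` (list of per-condition vectors), `backgrounds`,
#'   `points` (per-condition `ek_mpfa_point`), `site_amps`, `truth` (the
#'   generating parameters).
#' @export
synth_mpfa_dataset <- function(n_sites = 5, q_p = -20, cv_qs = 0,
                               cv_qii = 0, p_levels = c(0.1, 0.3, 0.5, 0.8, 1),
                               n_per = 150, background_sd = 0,
                               precision = 0.01, seed = 0) {
  set.seed(seed)
  site <- sample_site_amplitudes(n_sites, q_p, cv_qii, precision)
  peaks <- list(); bgs <- list(); points <- list()
  for (i in seq_along(p_levels)) {
    P <- p_levels[i]
    pk <- vapply(seq_len(n_per), function(j) {
      rel <- stats::runif(n_sites) < P
      if (!any(rel)) return(0)
      sum(site$q[rel] * (1 + stats::rnorm(sum(rel), 0, cv_qs)))
    }, 0)
    bg <- if (background_sd > 0) stats::rnorm(n_per, 0, background_sd)
          else rep(0, n_per)
    pk <- pk + if (background_sd > 0) stats::rnorm(n_per, 0, background_sd)
          else 0
    peaks[[i]] <- pk; bgs[[i]] <- bg
    points[[i]] <- mpfa_stats(pk, bg, label = sprintf("P=%g", P))
  }
  list(peaks = peaks, backgrounds = bgs, points = points, site_amps = site,
       truth = list(n_sites = n_sites, q_p = q_p, cv_qs = cv_qs,
                    cv_qii = cv_qii, p_levels = p_levels, seed = seed))
}
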