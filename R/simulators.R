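#' Default quantal waveform kinetics
#'
#' Multi-exponential kinetics representative of fast excitatory miniature
#' currents at a cerebellar mossy-fiber to granule-cell synapse: rise time
#' constant 0.116 ms (exponent 1), biexponential decay with amplitudes
#' 86.72 / 13.28 and time constants 0.36 / 2.034 ms.
#' @param t0 onset time (ms).
#' @return an [synexp_params()] object.
#' @export
quantal_kinetics_default <- function(t0 = 0) {
  synexp_params(t0 = t0, tau_r = 0.116, n = 1, a_d1 = 86.72, tau_d1 = 0.36,
                a_d2 = 13.28, tau_d2 = 2.034)
}

#' Composite within-site quantal CV
#'
#' Amplitude and latency variability at a single site combine in quadrature:
#' `CV_QI = sqrt(CV_QS^2 + CV_QL^2)`.
#' @param cv_qs within-site amplitude CV.
#' @param cv_ql latency-induced amplitude CV.
#' @export
composite_cv_qi <- function(cv_qs, cv_ql) sqrt(cv_qs^2 + cv_ql^2)

#' Configuration of the multinomial quantal release simulator
#'
#' Defaults reproduce the reference study conditions for a 5-site granule
#' cell synapse: `N = 5`, `Q_p = -20` pA, `P = 0.5`, within-site amplitude
#' CV 0.3, latency SD 0.08 ms, across-site CV 0.3 generated at 1% precision,
#' 150 trials, quantal time course from [quantal_kinetics_default()]
#' (rescaled internally to unit peak), 50 kHz sampling.
#'
#' @param n_sites number of release sites N.
#' @param p release probability per site (scalar in `[0, 1]`).
#' @param q_p quantal peak amplitude (pA; negative for inward currents).
#' @param cv_qs within-site CV of the released amplitude.
#' @param sigma_ql SD of the release latency (ms).
#' @param cv_qii across-site CV of the site amplitudes.
#' @param precision relative tolerance for the site-amplitude set (mean and
#'   CV must both land within this fraction of their targets).
#' @param n_trials trials per condition.
#' @param waveform quantal kinetics ([synexp_params()]); unit-peak scaling is
#'   applied internally.
#' @param stim_ms stimulus time within the sweep (ms).
#' @param dt sample interval (ms).
#' @param length_ms sweep length (ms).
#' @param noise_sd additive Gaussian noise SD (pA; 0 disables).
#' @param cv_ql_nominal nominal latency-induced amplitude CV used when fixing
#'   the composite `CV_QI` in a subsequent variance-mean fit (the empirically
#'   induced CV is also reported by the simulator).
#' @return an `ek_quantal_config`.
#' @export
quantal_config <- function(n_sites = 5, p = 0.5, q_p = -20, cv_qs = 0.3,
                           sigma_ql = 0.08, cv_qii = 0.3, precision = 0.01,
                           n_trials = 150,
                           waveform = quantal_kinetics_default(),
                           stim_ms = 2, dt = 0.02, length_ms = 12,
                           noise_sd = 0, cv_ql_nominal = 0.2) {
  stopifnot(n_sites >= 1, p >= 0, p <= 1, cv_qs >= 0, sigma_ql >= 0,
            cv_qii >= 0, precision > 0, n_trials >= 1, dt > 0,
            stim_ms < length_ms)
  structure(list(n_sites = n_sites, p = p, q_p = q_p, cv_qs = cv_qs,
                 sigma_ql = sigma_ql, cv_qii = cv_qii, precision = precision,
                 n_trials = n_trials, waveform = waveform, stim_ms = stim_ms,
                 dt = dt, length_ms = length_ms, noise_sd = noise_sd,
                 cv_ql_nominal = cv_ql_nominal),
            class = "ek_quantal_config")
}

#' Draw a site-amplitude set at fixed precision
#'
#' Repeatedly draws `N` site amplitudes from `Gaussian(Q_p, |Q_p| CV_QII)`
#' until the sample mean and sample CV are both within `precision` (relative)
#' of their targets, so every realization of the synapse matches the entered
#' statistics. Draws whose sign differs from `Q_p` are redrawn. Uses the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param n_sites number of sites (>= 2 when `cv_qii > 0`).
#' @param q_p target mean amplitude (pA).
#' @param cv_qii target across-site CV.
#' @param precision relative tolerance on both mean and CV.
#' @param max_iter iteration cap (default 1e6).
#' @return list with `q` (site amplitudes), `mean`, `cv`, `iterations`.
#' @export
sample_site_amplitudes <- function(n_sites, q_p, cv_qii, precision = 0.01,
                                   max_iter = 1e6) {
  if (cv_qii == 0) {
    return(list(q = rep(q_p, n_sites), mean = q_p, cv = 0, iterations = 1L))
  }
  if (n_sites < 2) stop("need at least 2 sites when cv_qii > 0")
  sdev <- abs(q_p) * cv_qii
  best <- NULL; best_err <- Inf
  for (it in seq_len(max_iter)) {
    q <- stats::rnorm(n_sites, q_p, sdev)
    while (any(sign(q) != sign(q_p)))
      q[sign(q) != sign(q_p)] <- stats::rnorm(sum(sign(q) != sign(q_p)),
                                              q_p, sdev)
    m <- mean(q)
    cv <- stats::sd(q) / abs(m)
    e_m <- abs(m / q_p - 1)
    e_cv <- abs(cv / cv_qii - 1)
    if (max(e_m, e_cv) < best_err) {
      best_err <- max(e_m, e_cv)
      best <- list(q = q, mean = m, cv = cv, iterations = it)
    }
    if (e_m <= precision && e_cv <= precision)
      return(list(q = q, mean = m, cv = cv, iterations = it))
  }
  stop(sprintf(
    "site-amplitude precision %g not reached in %d iterations (closest: %g)",
    precision, max_iter, best_err))
}

#' Monte Carlo simulation of multinomial quantal release
#'
#' For each trial and site, release occurs when a uniform draw on `[0, 1]`
#' falls below the site's `P`. Each successful release contributes its site
#' amplitude perturbed by the within-site CV, placed at the stimulus time
#' plus a Gaussian latency, shaped by the unit-peak quantal waveform; the
#' contributions are summed per trial and optional Gaussian noise is added.
#'
#' @param config an [quantal_config()].
#' @param seed integer seed.
#' @param site_amps optional precomputed site-amplitude set (list as returned
#'   by [sample_site_amplitudes()]), so several probability conditions can
#'   share one synapse realization.
#' @return list with `sweeps` (an `ek_sweepset`, prefix "EPSC"), `truth`
#'   (data.frame: trial, site, amplitude, latency), `site_amps`,
#'   `peak_time` (unit waveform peak, ms after onset) and `cv_ql_induced`
#'   (empirical amplitude CV induced by the latency jitter at the waveform
#'   peak).
#' @export
simulate_quantal <- function(config, seed = 0, site_amps = NULL) {
  stopifnot(inherits(config, "ek_quantal_config"))
  set.seed(seed)
  if (is.null(site_amps))
    site_amps <- sample_site_amplitudes(config$n_sites, config$q_p,
                                        config$cv_qii, config$precision)
  up <- synexp_unit_peak(config$waveform)
  wf <- up$params
  nsamp <- round(config$length_ms / config$dt)
  tt <- (seq_len(nsamp) - 1) * config$dt
  traces <- vector("list", config$n_trials)
  truth <- list()
  for (trial in seq_len(config$n_trials)) {
    y <- numeric(nsamp)
    rel <- stats::runif(config$n_sites) < config$p
    for (s in which(rel)) {
      a <- site_amps$q[s] * (1 + stats::rnorm(1, 0, config$cv_qs))
      lat <- stats::rnorm(1, 0, config$sigma_ql)
      y <- y + a * synexp_eval(wf, tt - config$stim_ms - lat)
      truth[[length(truth) + 1]] <-
        data.frame(trial = trial, site = s, amplitude = a, latency = lat)
    }
    if (config$noise_sd > 0)
      y <- y + stats::rnorm(nsamp, 0, config$noise_sd)
    tr <- trace(y, dt = config$dt, t_start = 0, units = "pA",
                label = sprintf("EPSC%d", trial - 1))
    traces[[trial]] <- add_note(tr, "simulate_quantal",
                                sprintf("P=%g;trial=%d;seed=%d",
                                        config$p, trial - 1, seed))
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(trial = integer(), site = integer(),
                           amplitude = numeric(), latency = numeric())
  ## latency-induced amplitude CV at the waveform peak, reported empirically
  cv_ql_ind <- if (config$sigma_ql > 0) {
    lat <- stats::qnorm(seq(0.005, 0.995, by = 0.01), 0, config$sigma_ql)
    att <- abs(synexp_eval(wf, up$peak_time - lat))
    stats::sd(att) / mean(att)
  } else 0
  list(sweeps = sweep_set(traces, prefix = "EPSC"), truth = truth,
       site_amps = site_amps, peak_time = up$peak_time,
       cv_ql_induced = cv_ql_ind)
}

#' Variance-mean (MPFA) analysis of simulated release
#'
#' Runs [simulate_quantal()] at each release probability with one shared
#' site-amplitude set, measures per-trial peaks in a window of width
#' `peak_win_ms` centered on the grand-average peak (background measured in
#' the window reflected about the midpoint of the pre-stimulus baseline
#' window), computes per-condition MPFA statistics with h-statistic variance
#' errors, and fits the multinomial variance-mean relation with both quantal
#' CVs fixed and weights `1/var_err^2`.
#'
#' @param config an [quantal_config()]; its `p` field is overridden per
#'   condition.
#' @param p_levels release probabilities (default `c(0.1, 0.3, 0.5, 0.8, 1)`).
#' @param seed integer master seed; each condition derives its own.
#' @param peak_win_ms amplitude window width (ms, default 0.1).
#' @param cv_qi_fit composite within-site CV held in the fit; default
#'   `composite_cv_qi(cv_qs, cv_ql_nominal)` from the config.
#' @param cv_qii_fit across-site CV held in the fit; default the config's.
#' @return list with `points` (per-condition `ek_mpfa_point`s), `table`,
#'   `fit` (the `ek_fit` from [fit_multinomial()]), `peak_window`, `sims`.
#' @export
mpfa_from_sim <- function(config = quantal_config(),
                          p_levels = c(0.1, 0.3, 0.5, 0.8, 1.0),
                          seed = 0, peak_win_ms = 0.1,
                          cv_qi_fit = NULL, cv_qii_fit = NULL) {
  stopifnot(length(p_levels) >= 2)
  if (is.null(cv_qi_fit))
    cv_qi_fit <- composite_cv_qi(config$cv_qs, config$cv_ql_nominal)
  if (is.null(cv_qii_fit)) cv_qii_fit <- config$cv_qii
  set.seed(seed)
  site_amps <- sample_site_amplitudes(config$n_sites, config$q_p,
                                      config$cv_qii, config$precision)
  sims <- lapply(seq_along(p_levels), function(i) {
    cfg <- config
    cfg$p <- p_levels[i]
    simulate_quantal(cfg, seed = seed + i, site_amps = site_amps)
  })
  ## grand average over all conditions defines the amplitude window
  all_sweeps <- sweep_set(unlist(lapply(sims, function(s) s$sweeps$traces),
                                 recursive = FALSE), prefix = "EPSC")
  polarity <- if (config$q_p < 0) "neg" else "pos"
  search <- window_spec(config$stim_ms, config$stim_ms + 3)
  pk_win <- peak_window_on_average(all_sweeps, search, width = peak_win_ms,
                                   polarity = polarity)
  ## background: the window reflected about the midpoint of the 1-ms
  ## pre-stimulus baseline window
  bl_mid <- config$stim_ms - 0.5
  pk_center <- (pk_win$xbgn + pk_win$xend) / 2
  bg_center <- 2 * bl_mid - pk_center
  bg_win <- window_spec(bg_center - peak_win_ms / 2,
                        bg_center + peak_win_ms / 2)
  bl_win <- window_spec(config$stim_ms - 1, config$stim_ms)
  points <- lapply(seq_along(p_levels), function(i) {
    ss <- sims[[i]]$sweeps
    peaks <- window_measure(ss, "avg", pk_win, baseline_window = bl_win)$value
    bgs <- window_measure(ss, "avg", bg_win, baseline_window = bl_win)$value
    mpfa_stats(peaks, bgs, label = sprintf("P=%g", p_levels[i]))
  })
  fit <- fit_multinomial(points, cv_qi = cv_qi_fit, cv_qii = cv_qii_fit)
  list(points = points, table = mpfa_table(points), fit = fit,
       peak_window = pk_win, background_window = bg_win, sims = sims,
       site_amps = site_amps)
}

#' Resource-probability short-term plasticity parameters
#'
#' The R*P model: at each presynaptic event the response scales with the
#' product `R * P`; immediately after, the resource depletes
#' (`R -> R - R * P`) and the release fraction facilitates
#' (`P -> P + Delta (1 - P)`). Between events both relax exponentially back
#' to `R_inf` and `P_inf` with time constants `tau_r` and `tau_p`.
#'
#' @param r_inf,p_inf resting values (`0 <= p_inf <= 1`).
#' @param delta facilitation increment in `[0, 1]` (0 disables facilitation).
#' @param tau_r,tau_p recovery time constants (ms, > 0).
#' @return an `ek_rp_params`.
#' @export
rp_params <- function(r_inf = 1, p_inf = 0.5, delta = 0, tau_r = 100,
                      tau_p = tau_r) {
  stopifnot(delta >= 0, delta <= 1, tau_r > 0, tau_p > 0,
            p_inf >= 0, p_inf <= 1)
  structure(list(r_inf = r_inf, p_inf = p_inf, delta = delta,
                 tau_r = tau_r, tau_p = tau_p), class = "ek_rp_params")
}

#' Event-driven evaluation of the R*P plasticity model
#'
#' Exact event-driven update: starting from `(R_inf, P_inf)`, each event
#' records the pre-event `(R, P, R*P)`, applies the jump rules, and relaxes
#' both variables in closed form over the interval to the next event.
#'
#' @param event_times strictly increasing event times (ms).
#' @param params an [rp_params()].
#' @return data.frame with columns `t`, `R`, `P`, `RP` (pre-event values).
#' @export
rp_event_values <- function(event_times, params) {
  stopifnot(inherits(params, "ek_rp_params"))
  if (length(event_times) == 0)
    return(data.frame(t = numeric(), R = numeric(), P = numeric(),
                      RP = numeric()))
  if (any(diff(event_times) <= 0)) stop("event times must strictly increase")
  R <- params$r_inf; P <- params$p_inf
  t_prev <- event_times[1]
  out <- matrix(NA_real_, length(event_times), 3)
  for (k in seq_along(event_times)) {
    dt <- event_times[k] - t_prev
    R <- params$r_inf + (R - params$r_inf) * exp(-dt / params$tau_r)
    P <- params$p_inf + (P - params$p_inf) * exp(-dt / params$tau_p)
    out[k, ] <- c(R, P, R * P)
    R <- R - R * P
    P <- P + params$delta * (1 - P)
    t_prev <- event_times[k]
  }
  data.frame(t = event_times, R = out[, 1], P = out[, 2], RP = out[, 3])
}

#' Build a plasticity-scaled conductance train
#'
#' For each input train and each component (direct, and optionally
#' spillover, each with independent `R` and `P` dynamics), every event adds
#' its pre-event `R * P` times the component's maximal-conductance waveform
#' at the event time; all inputs and components sum into one conductance
#' trace.
#'
#' @param event_trains list of event-time vectors (ms), one per input.
#' @param direct list with `rp` (an [rp_params()]) and `waveform` (an
#'   [synexp_params()], the G_max time course in nS).
#' @param spillover optional second component in the same format.
#' @param dt sample interval (ms).
#' @param length_ms output duration (ms).
#' @return an `ek_trace` in nS.
#' @export
stp_conductance_train <- function(event_trains, direct, spillover = NULL,
                                  dt, length_ms) {
  if (is.numeric(event_trains)) event_trains <- list(event_trains)
  nsamp <- round(length_ms / dt)
  tt <- (seq_len(nsamp) - 1) * dt
  y <- numeric(nsamp)
  comps <- c(list(direct), if (!is.null(spillover)) list(spillover))
  for (train in event_trains) {
    for (comp in comps) {
      rp <- rp_event_values(train, comp$rp)
      for (k in seq_len(nrow(rp)))
        y <- y + rp$RP[k] * synexp_eval(comp$waveform, tt - rp$t[k])
    }
  }
  tr <- trace(y, dt = dt, t_start = 0, units = "nS", label = "G_train")
  add_note(tr, "stp_conductance_train",
           sprintf("inputs=%d;components=%d", length(event_trains),
                   length(comps)))
}

#' Integrate-and-fire neuron parameters
#'
#' Single-compartment leaky integrate-and-fire neuron with conductance
#' inputs. Defaults are representative of a cerebellar granule cell
#' (capacitance ~3 pF, input resistance ~1 GOhm).
#'
#' @param c_m membrane capacitance (pF).
#' @param g_leak leak conductance (nS).
#' @param e_leak leak reversal / resting potential (mV).
#' @param v_thresh spike threshold (mV).
#' @param v_peak cosmetic spike peak painted into the voltage trace (mV).
#' @param v_reset post-spike reset potential (mV); must satisfy
#'   `v_reset < v_thresh < v_peak`.
#' @param t_refrac absolute refractory period (ms); the membrane is clamped
#'   at `v_reset` for its duration.
#' @param v_init initial potential (mV; default `e_leak`).
#' @export
iaf_params <- function(c_m = 3, g_leak = 1, e_leak = -75, v_thresh = -40,
                       v_peak = 20, v_reset = -65, t_refrac = 2,
                       v_init = e_leak) {
  stopifnot(c_m > 0, g_leak > 0, t_refrac >= 0)
  if (!(v_reset < v_thresh && v_thresh < v_peak))
    stop("require v_reset < v_thresh < v_peak")
  structure(list(c_m = c_m, g_leak = g_leak, e_leak = e_leak,
                 v_thresh = v_thresh, v_peak = v_peak, v_reset = v_reset,
                 t_refrac = t_refrac, v_init = v_init),
            class = "ek_iaf_params")
}

#' Simulate a conductance-driven integrate-and-fire neuron
#'
#' Integrates `C_m dV/dt = g_leak (E_leak - V) + sum_i g_i(t) (E_i - V) +
#' I_inj(t)` with the exponential Euler scheme (exact for conductances held
#' constant over a step). When `V` reaches threshold a spike time is
#' recorded, the output sample is painted at `v_peak` (cosmetic; excluded
#' from any voltage statistics), and `V` is clamped at `v_reset` for the
#' refractory period. Units: pF, nS, mV, pA, ms (pF/nS = ms; pA/nS = mV).
#'
#' @param params an [iaf_params()].
#' @param syn_inputs list of synaptic inputs, each
#'   `list(g = <ek_trace in nS>, e_rev = <mV>)`; a scalar `g` is treated as
#'   a tonic conductance.
#' @param i_inj optional injected-current `ek_trace` (pA) or scalar.
#' @param dt sample interval (ms); required when every input is scalar.
#' @param n_samples duration in samples when every input is scalar.
#' @return list with `v` (membrane-potential `ek_trace`, mV) and
#'   `spike_times` (ms).
#' @export
iaf_simulate <- function(params, syn_inputs = list(), i_inj = NULL,
                         dt = NULL, n_samples = NULL) {
  stopifnot(inherits(params, "ek_iaf_params"))
  g_traces <- lapply(syn_inputs, `[[`, "g")
  tr_like <- Filter(function(x) inherits(x, "ek_trace"),
                    c(g_traces, list(i_inj)))
  if (length(tr_like) > 0) {
    dt0 <- tr_like[[1]]$dt; n0 <- length(tr_like[[1]]$samples)
    for (tr in tr_like)
      if (abs(tr$dt - dt0) > 1e-12 || length(tr$samples) != n0)
        stop("all input traces must share dt and length")
    dt <- dt0; n_samples <- n0
  }
  if (is.null(dt) || is.null(n_samples))
    stop("dt and n_samples required when no trace inputs are given")
  G <- matrix(0, nrow = n_samples, ncol = max(length(syn_inputs), 1))
  E <- numeric(max(length(syn_inputs), 1))
  for (i in seq_along(syn_inputs)) {
    g <- syn_inputs[[i]]$g
    G[, i] <- if (inherits(g, "ek_trace")) g$samples else rep(g, n_samples)
    E[i] <- syn_inputs[[i]]$e_rev
  }
  if (length(syn_inputs) == 0) G[] <- 0
  Ii <- if (is.null(i_inj)) rep(0, n_samples)
        else if (inherits(i_inj, "ek_trace")) i_inj$samples
        else rep(i_inj, n_samples)
  v <- numeric(n_samples)
  V <- params$v_init
  refrac_left <- 0
  spikes <- numeric(0)
  refrac_n <- params$t_refrac / dt
  for (k in seq_len(n_samples)) {
    if (refrac_left > 0) {
      V <- params$v_reset
      v[k] <- V
      refrac_left <- refrac_left - 1
      next
    }
    g_tot <- params$g_leak + sum(G[k, ])
    v_inf <- (params$g_leak * params$e_leak + sum(G[k, ] * E) + Ii[k]) / g_tot
    V_prev <- V
    V <- v_inf + (V - v_inf) * exp(-dt * g_tot / params$c_m)
    if (!is.finite(V))
      stop(sprintf("non-finite membrane potential at step %d", k))
    if (V >= params$v_thresh) {
      ## sub-step crossing time from the exponential solution over the step
      num <- V_prev - v_inf
      den <- params$v_thresh - v_inf
      theta <- if (num < 0 && den < 0 && den > num)
        (params$c_m / g_tot / dt) * log(num / den) else 1
      spikes <- c(spikes, ((k - 2) + min(max(theta, 0), 1)) * dt)
      v[k] <- params$v_peak
      V <- params$v_reset
      refrac_left <- refrac_n
    } else {
      v[k] <- V
    }
  }
  vt <- trace(v, dt = dt, t_start = 0, units = "mV", label = "V_iaf")
  list(v = add_note(vt, "iaf_simulate",
                    sprintf("spikes=%d;dt=%g", length(spikes), dt)),
       spike_times = spikes)
}
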