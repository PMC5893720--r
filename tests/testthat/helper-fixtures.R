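## Shared fixtures, built in code at load time.

## canonical quantal kinetics used across detection/fitting fixtures
fix_kinetics <- quantal_kinetics_default()
fix_unit <- synexp_unit_peak(fix_kinetics)

## the standard 20-event detection fixture: unit-peak kinetics scaled to
## -20 pA on 2 pA white noise (SNR 10), events >= 50 ms apart, 50 kHz
make_event_fixture <- function(seed = 42) {
  synth_event_trace(n_events = 20, amp_mean = -20, amp_sd = 0,
                    kinetics = fix_kinetics, duration_ms = 1500,
                    dt = 0.02, noise_sd = 2, min_sep = 50, seed = seed)
}

fix_events <- make_event_fixture()

## detection settings matching the fixture (absolute level 6 pA, 5 ms
## baseline, 2.5 ms forward offset, 1 kHz detection-time low-pass)
fix_detcfg <- detection_config(polarity = "neg", level = 6,
                               baseline_win = 5, offset = 2.5,
                               lowpass_khz = 1, min_sep = 5)

## unit-peak template sampled at the fixture dt: 3 ms with 0.2 ms baseline
make_fix_template <- function(dt = 0.02, length_ms = 3, baseline_ms = 0.2) {
  tt <- seq(0, length_ms - baseline_ms, by = dt)
  c(rep(0, round(baseline_ms / dt)), synexp_eval(fix_unit$params, tt))
}

## recall/precision of detected against true event times
match_events <- function(t_detected, t_true, tol_ms = 1) {
  hits <- vapply(t_true, function(t0) any(abs(t_detected - t0) <= tol_ms),
                 logical(1))
  spurious <- vapply(t_detected,
                     function(td) all(abs(t_true - td) > tol_ms), logical(1))
  list(recall = mean(hits), n_spurious = sum(spurious),
       precision = if (length(t_detected)) 1 - mean(spurious) else NA_real_)
}
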