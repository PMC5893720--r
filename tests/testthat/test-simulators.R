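test_that("site-amplitude sets honor the precision contract", {
  set.seed(71)
  exact <- sample_site_amplitudes(5, -20, 0)
  expect_equal(exact$q, rep(-20, 5))
  expect_equal(exact$iterations, 1L)

  s <- sample_site_amplitudes(5, -20, 0.3, precision = 0.01)
  expect_gte(s$mean, -20.2); expect_lte(s$mean, -19.8)
  expect_gte(s$cv, 0.297); expect_lte(s$cv, 0.303)
  expect_true(all(s$q < 0))

  ## tightening the precision does not reduce the median iteration count
  iters <- sapply(1:15, function(sd) {
    set.seed(sd)
    a <- sample_site_amplitudes(5, -20, 0.3, 0.02)$iterations
    set.seed(sd)
    b <- sample_site_amplitudes(5, -20, 0.3, 0.005)$iterations
    c(a, b)
  })
  expect_lte(median(iters[1, ]), median(iters[2, ]))
  expect_error(sample_site_amplitudes(1, -20, 0.3), "at least 2 sites")
})

test_that("quantal simulator obeys degenerate limits", {
  cfg0 <- quantal_config(p = 0, n_trials = 10, length_ms = 5)
  sim0 <- simulate_quantal(cfg0, seed = 1)
  expect_true(all(vapply(sim0$sweeps$traces,
                         function(tr) all(tr$samples == 0), TRUE)))
  expect_equal(nrow(sim0$truth), 0)

  ## P = 1, no variability: every sweep identical, peak N*Q_p
  cfg1 <- quantal_config(p = 1, cv_qs = 0, sigma_ql = 0, cv_qii = 0,
                         n_trials = 5, length_ms = 6)
  sim1 <- simulate_quantal(cfg1, seed = 2)
  s1 <- sim1$sweeps$traces
  for (k in 2:5) expect_identical(s1[[k]]$samples, s1[[1]]$samples)
  ## sampled peak: N * Q_p times the maximum of the sampled unit waveform
  wf_max <- max(synexp_eval(synexp_unit_peak(cfg1$waveform)$params,
                            seq(0, 6, by = cfg1$dt) - cfg1$stim_ms))
  expect_equal(min(s1[[1]]$samples), 5 * -20 * wf_max, tolerance = 1e-9)
  expect_lt(abs(min(s1[[1]]$samples) - (-100)), 0.05)
})

test_that("release counts follow the binomial closed forms", {
  ## fraction of trials with >= 1 release: 1 - (1-P)^N
  cfg <- quantal_config(n_trials = 150, length_ms = 5)
  sim <- simulate_quantal(cfg, seed = 3)
  frac <- length(unique(sim$truth$trial)) / 150
  p_any <- 1 - (1 - 0.5)^5
  se <- sqrt(p_any * (1 - p_any) / 150)
  expect_lt(abs(frac - p_any), 4 * se)

  ## peak variance with no quantal variability: N P (1-P) Q_p^2
  cfg2 <- quantal_config(cv_qs = 0, sigma_ql = 0, cv_qii = 0,
                         n_trials = 1e4, dt = 0.05, length_ms = 4,
                         stim_ms = 1)
  sim2 <- simulate_quantal(cfg2, seed = 4)
  pk_t <- 1 + sim2$peak_time
  peaks <- vapply(sim2$sweeps$traces, function(tr)
    tr$samples[round(pk_t / 0.05) + 1], 0)
  true_var <- 5 * 0.5 * 0.5 * 400
  ve <- sqrt(ephyskit:::var_of_variance(peaks))
  expect_lt(abs(var(peaks) - true_var), 4 * ve)
  expect_lt(abs(mean(peaks) - 5 * 0.5 * -20), 4 * sd(peaks) / 100)
})

test_that("variance-mean analysis of the simulation recovers N and Q_p", {
  ## idealized generator (no kinetics): large-sample recovery
  ds <- synth_mpfa_dataset(n_sites = 5, q_p = -20, cv_qs = 0, cv_qii = 0,
                           n_per = 2000, background_sd = 0.5, seed = 72)
  fit <- fit_multinomial(ds$points, cv_qi = 0, cv_qii = 0)
  expect_lt(abs(fit$estimates["N"] - 5), 0.6)
  expect_lt(abs(fit$estimates["Q_p"] - (-20)), 1)
})

test_that("R*P dynamics match closed forms", {
  prm <- rp_params(r_inf = 1, p_inf = 0.14, delta = 0, tau_r = 131)
  ## first event: R*P = R_inf * P_inf
  r1 <- rp_event_values(10, prm)
  expect_equal(r1$RP, 0.14)

  ## Delta = 0: P pinned at P_inf
  tr <- cumsum(runif(50, 2, 30))
  rv <- rp_event_values(tr, prm)
  expect_true(all(rv$P == 0.14))

  ## steady state under a regular train matches the fixed point to 1e-10
  TT <- 10
  times <- seq(0, by = TT, length.out = 200)
  rv2 <- rp_event_values(times, prm)
  e <- exp(-TT / prm$tau_r)
  r_star <- (1 - e) / (1 - (1 - prm$p_inf) * e)
  expect_equal(rv2$R[200], r_star, tolerance = 1e-10)

  ## bounds hold on random trains with facilitation
  prm2 <- rp_params(r_inf = 1, p_inf = 0.1, delta = 0.3, tau_r = 50,
                    tau_p = 80)
  set.seed(73)
  for (i in 1:5) {
    times <- sort(runif(100, 0, 1000))
    times <- times[c(TRUE, diff(times) > 0)]
    rv3 <- rp_event_values(times, prm2)
    expect_true(all(rv3$R >= 0 & rv3$R <= 1))
    expect_true(all(rv3$P >= 0 & rv3$P <= 1))
  }
  expect_error(rp_event_values(c(5, 5), prm), "strictly increase")
})

test_that("conductance trains sum linearly over inputs and depress", {
  gmax <- synexp_params(0, 0.2, 1, 1, 2)     # ~1 nS peak waveform
  direct <- list(rp = rp_params(1, 0.14, 0, 131), waveform = gmax)
  one <- stp_conductance_train(list(50), direct, dt = 0.1, length_ms = 100)
  expect_equal(max(one$samples),
               0.14 * max(synexp_eval(gmax, seq(0, 50, by = 0.1))),
               tolerance = 1e-6)

  two <- stp_conductance_train(list(50, 50), direct, dt = 0.1,
                               length_ms = 100)
  expect_equal(two$samples, 2 * one$samples, tolerance = 1e-12)

  ## high-frequency burst: depression-only direct amplitudes non-increasing
  spill <- list(rp = rp_params(1, 0.68, 0, 14.85), waveform = gmax)
  burst <- seq(10, 110, by = 11.7)          # ~85 Hz
  rv <- rp_event_values(burst, direct$rp)
  expect_true(all(diff(rv$RP) <= 1e-12))
  g <- stp_conductance_train(list(burst), direct, spillover = spill,
                             dt = 0.1, length_ms = 300)
  expect_true(all(g$samples >= -1e-12))
})

test_that("integrate-and-fire matches leaky-integrator closed forms", {
  prm <- iaf_params(c_m = 3, g_leak = 1, e_leak = -75, v_thresh = -40,
                    v_peak = 20, v_reset = -65, t_refrac = 2)
  ## no input: stays at rest
  out0 <- iaf_simulate(prm, dt = 0.05, n_samples = 2000)
  expect_true(all(out0$v$samples == -75))

  ## subthreshold constant current: V -> E_leak + I/g_leak
  out1 <- iaf_simulate(prm, i_inj = 20, dt = 0.05, n_samples = 20000)
  expect_equal(out1$v$samples[20000], -75 + 20, tolerance = 1e-6)
  expect_length(out1$spike_times, 0)

  ## suprathreshold current: ISI = t_ref + tau_m ln[(Einf-Vr)/(Einf-Vth)]
  I <- 50
  out2 <- iaf_simulate(prm, i_inj = I, dt = 0.01, n_samples = 100000)
  einf <- -75 + I / 1
  tau_m <- 3 / 1
  isi_true <- 2 + tau_m * log((einf - (-65)) / (einf - (-40)))
  isis <- diff(out2$spike_times)
  expect_lt(max(abs(isis - isi_true)), 0.02 + 0.01)

  expect_error(iaf_simulate(prm, syn_inputs = list(
    list(g = trace(rep(1, 10), 0.05), e_rev = 0),
    list(g = trace(rep(1, 10), 0.1), e_rev = 0))), "share dt")
})

test_that("integrate-and-fire converges under step halving", {
  ## plasticity-train drive, dt vs dt/10: spike count is unchanged and
  ## spike times converge (typical deviation well below the coarse step;
  ## worst case bounded by 2 dt -- near-grazing threshold crossings have
  ## O(1) sensitivity to any perturbation, so strict O(dt) agreement is
  ## only attainable for steep crossings)
  set.seed(74)
  ev <- round(poisson_times(30, 500, dead_ms = 5), 1)  # clock-locked stimuli
  gmax <- synexp_params(0, 0.2, 1, 16, 2)
  direct <- list(rp = rp_params(1, 0.5, 0, 50), waveform = gmax)
  prm <- iaf_params(c_m = 3, g_leak = 1, e_leak = -75, v_thresh = -50,
                    v_peak = 20, v_reset = -65, t_refrac = 2)
  run <- function(dt) {
    g <- stp_conductance_train(list(ev), direct, dt = dt, length_ms = 500)
    iaf_simulate(prm, syn_inputs = list(list(g = g, e_rev = 0)))
  }
  a <- run(0.1)
  b <- run(0.01)
  expect_gt(length(a$spike_times), 3)
  expect_equal(length(a$spike_times), length(b$spike_times))
  dev <- abs(a$spike_times - b$spike_times)
  expect_lt(median(dev), 0.05)
  expect_lt(max(dev), 0.2)
})

test_that("simulated events run back through detection and fitting", {
  ## whole-pipeline recursion: simulate -> detect -> fit kinetics
  cfg <- quantal_config(p = 1, cv_qs = 0.05, sigma_ql = 0, cv_qii = 0,
                        n_trials = 20, noise_sd = 1, length_ms = 12)
  sim <- simulate_quantal(cfg, seed = 75)
  cat_tr <- concatenate_sweeps(sim$sweeps)
  ev <- detect_threshold(cat_tr, detection_config(level = 20,
                                                  baseline_win = 1,
                                                  offset = 0.3,
                                                  peak_win = 1.5,
                                                  min_sep = 5))
  expect_equal(sum(ev$accepted), 20)
  ss <- events_to_waves(cat_tr, ev, pre_ms = 1.5, post_ms = 8)
  avg <- average_sweeps(ss)$mean
  fit <- fit_synexp(avg, c(0.3, 9), hold = "n")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["tau_d1"]), 0.36, tolerance = 0.1)
})
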