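test_that("set algebra selects the expected sweeps and honors SetX", {
  ss <- sweep_set(list(trace(0, 1), trace(1, 1), trace(2, 1)),
                  sets = list(Fast = c(TRUE, FALSE, TRUE),
                              Fast2 = c(FALSE, TRUE, FALSE)))
  expect_equal(n_sweeps(select_sweeps(ss, "Fast OR Fast2")), 3)
  expect_equal(n_sweeps(select_sweeps(ss, "Fast AND Fast2")), 0)
  expect_error(select_sweeps(ss, "Nope"), "unknown set name")

  ss <- define_set(ss, "SetX", c(FALSE, FALSE, TRUE))
  expect_equal(n_sweeps(select_sweeps(ss, "All")), 2)
  ss2 <- define_set(ss, "Set1", c(TRUE, TRUE, TRUE))
  expect_equal(n_sweeps(select_sweeps(ss2, "Set1 AND NOT Set1")), 0)
})

test_that("baseline subtraction removes the window mean and is idempotent", {
  tr <- trace(rep(5, 10), dt = 1)
  expect_equal(baseline_subtract(tr, c(0, 3))$samples, rep(0, 10))

  tr2 <- trace(c(1, 2, 3, 4), dt = 1)
  expect_equal(baseline_subtract(tr2, c(0, 1))$samples, c(-0.5, 0.5, 1.5, 2.5))

  ## synthetic EPSC riding on a 10 pA offset: pre-stimulus mean ~ 0 after
  fx <- synth_event_trace(times = 50, amp_mean = -20, noise_sd = 2,
                          duration_ms = 100, seed = 3)
  tr3 <- fx$trace
  tr3$samples <- tr3$samples + 10
  out <- baseline_subtract(tr3, c(49, 50))
  n_in_win <- length(window_index(out, c(49, 50)))
  expect_lt(abs(mean(out$samples[window_index(out, c(49, 50))])),
            4 * 2 / sqrt(n_in_win))
  ## idempotent on the window mean
  out2 <- baseline_subtract(out, c(49, 50))
  expect_equal(out2$samples, out$samples)
  expect_error(baseline_subtract(tr, c(100, 110)), "does not intersect")
})

test_that("binomial smoothing equals n-fold kernel convolution", {
  imp <- trace(c(0, 0, 1, 0, 0), dt = 1)
  expect_equal(smooth_binomial(imp, 0)$samples, imp$samples)
  expect_equal(smooth_binomial(imp, 1)$samples, c(0, 0.25, 0.5, 0.25, 0))
  imp7 <- trace(c(0, 0, 0, 1, 0, 0, 0), dt = 1)
  expect_equal(smooth_binomial(imp7, 2)$samples,
               c(0, 1, 4, 6, 4, 1, 0) / 16, tolerance = 1e-12)
  ## oracle: direct convolution on a short random array (interior samples)
  set.seed(1)
  x <- rnorm(64)
  direct <- x
  for (i in 1:3) {
    padded <- c(direct[2], direct, direct[63])
    direct <- 0.25 * padded[1:64] + 0.5 * padded[2:65] + 0.25 * padded[3:66]
  }
  expect_equal(smooth_binomial(trace(x, 1), 3)$samples, direct,
               tolerance = 1e-12)
})

test_that("Gaussian low-pass has unit DC gain and -3 dB at f_c", {
  dc <- trace(rep(7, 2000), dt = 0.02)
  expect_equal(lowpass(dc, 1)$samples, rep(7, 2000), tolerance = 1e-9)

  tt <- seq(0, 400, by = 0.02)
  sine <- trace(sin(2 * pi * 1 * tt), dt = 0.02)
  out <- lowpass(sine, 1)
  mid <- 5000:15000
  ratio <- max(abs(out$samples[mid]))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.02)

  set.seed(2)
  wn <- trace(rnorm(50000, 0, 2), dt = 0.02)
  expect_lt(var(lowpass(wn, 1)$samples), var(wn$samples))
  expect_error(lowpass(dc, 30), "Nyquist")
})

test_that("alignment shifts t_start so the reference lands at zero", {
  ss <- sweep_set(list(trace(1:5, 1, t_start = 0)))
  expect_equal(align_sweeps(ss, 0)$traces[[1]]$t_start, 0)
  expect_equal(align_sweeps(ss, 5)$traces[[1]]$t_start, -5)
  expect_error(align_sweeps(ss, c(1, 2)), "one offset per sweep")

  ## fit-then-align round trip: two events with onsets 4.1 and 4.3 ms
  tt <- seq(0, 10, by = 0.02)
  mk <- function(t0) trace(-20 * synexp_eval(
    synexp_params(t0, 0.116, 1, fix_unit$params$a_d1, 0.36,
                  fix_unit$params$a_d2, 2.034), tt), dt = 0.02)
  ss2 <- sweep_set(list(mk(4.1), mk(4.3)))
  t0s <- vapply(ss2$traces, function(tr)
    fit_synexp(tr, c(3.5, 7), hold = "n")$estimates["t0"], 0)
  expect_equal(unname(t0s), c(4.1, 4.3), tolerance = 1e-3)
  al <- align_sweeps(ss2, t0s)
  onsets <- vapply(al$traces, function(tr) tr$t_start, 0)
  ## both onsets now coincide at -t0 relative origin: fitted onset maps to 0
  expect_equal(onsets + t0s, c(0, 0), tolerance = 1e-9)
})

test_that("interpolation onto a common grid is exact on lines", {
  tr <- trace(seq(0, 9), dt = 1)      # y = t
  ss <- interpolate_common(sweep_set(list(tr)), 0.25)
  expect_equal(ss$traces[[1]]$samples, trace_times(ss$traces[[1]]),
               tolerance = 1e-12)
  ## identity when already on the target grid
  ss2 <- interpolate_common(sweep_set(list(trace(sin(0:20), 1))), 1)
  expect_equal(ss2$traces[[1]]$samples, sin(0:20), tolerance = 1e-12)
  ## sinusoid: linear-interp error bounded by h^2 max|f''| / 8
  tt <- seq(0, 50, by = 0.06)
  s <- trace(sin(2 * pi * 0.2 * tt), dt = 0.06)
  out <- interpolate_common(sweep_set(list(s)), 0.02)$traces[[1]]
  truth <- sin(2 * pi * 0.2 * trace_times(out))
  bound <- 0.06^2 * (2 * pi * 0.2)^2 / 8
  expect_lt(max(abs(out$samples - truth)), bound)
  expect_error(interpolate_common(
    sweep_set(list(trace(1:5, 1, t_start = 0), trace(1:5, 1, t_start = 100))),
    1), "empty intersection")
})

test_that("averaging returns pointwise mean and SD with provenance", {
  one <- average_sweeps(sweep_set(list(trace(c(1, 2), 1))))
  expect_equal(one$mean$samples, c(1, 2))
  expect_equal(one$stdv$samples, c(0, 0))

  two <- average_sweeps(sweep_set(list(trace(c(0, 0), 1), trace(c(2, 2), 1))))
  expect_equal(two$mean$samples, c(1, 1))
  expect_equal(two$stdv$samples, c(sqrt(2), sqrt(2)))
  expect_match(two$mean$notes$op[nrow(two$mean$notes)], "average")
  expect_error(average_sweeps(sweep_set(list(trace(1:3, 1), trace(1:4, 1)))),
               "interpolate_common")

  ## subtracting the mean from each sweep leaves a zero-mean ensemble
  set.seed(4)
  ss <- sweep_set(lapply(1:8, function(i) trace(rnorm(50), 1)))
  mu <- average_sweeps(ss)$mean
  resid <- lapply(ss$traces, pointwise_combine, other = mu, op = "subtract")
  rmean <- rowMeans(do.call(cbind, lapply(resid, `[[`, "samples")))
  expect_equal(rmean, rep(0, 50), tolerance = 1e-12)
})

test_that("Monte Carlo mean peak agrees with ground truth within SE", {
  set.seed(9)
  n <- 199
  amps <- rnorm(n, -20, 2)
  tt <- seq(0, 8, by = 0.02)
  ss <- sweep_set(lapply(amps, function(a)
    trace(a * synexp_eval(fix_unit$params, tt - 2) + rnorm(length(tt), 0, 2),
          dt = 0.02)))
  avg <- average_sweeps(ss)$mean
  pk <- min(avg$samples)
  se <- sqrt(2^2 / n + var(amps) / n)
  expect_lt(abs(pk - mean(amps)), 4 * se)
})

test_that("pointwise combination handles traces, scalars, units and zeros", {
  tr <- trace(c(1, 2, 3), 1, units = "pA")
  expect_equal(pointwise_combine(tr, tr, "subtract")$samples, c(0, 0, 0))
  g <- pointwise_combine(tr, trace(rep(60, 3), 1, units = "mV"), "divide")
  expect_equal(g$units, "nS")
  expect_equal(g$samples, c(1, 2, 3) / 60)
  expect_error(pointwise_combine(tr, 0, "divide"), "zero")
  expect_error(pointwise_combine(tr, trace(c(1, 0, 1), 1), "divide"), "zero")

  ## artifact-template subtraction removes >95% of the artifact
  tt <- seq(0, 10, by = 0.02)
  artifact <- 50 * exp(-tt / 0.3) - 30 * exp(-tt / 0.1)
  epsc <- -20 * synexp_eval(fix_unit$params, tt - 4)
  mixed <- trace(artifact + epsc, 0.02)
  resid <- pointwise_combine(mixed, trace(artifact, 0.02), "subtract")
  art_win <- which(tt < 2)
  expect_lt(max(abs(resid$samples[art_win] - epsc[art_win])),
            0.05 * max(abs(artifact)))
})

test_that("clipping replaces intervals by a straight line", {
  flat <- trace(rep(3, 100), 1)
  expect_equal(clip_segments(flat, list(c(10, 20)))$samples, rep(3, 100))
  expect_equal(clip_segments(flat, list())$samples, rep(3, 100))

  set.seed(5)
  noise_sd <- 0.5
  y <- rnorm(500, 0, noise_sd)
  y[200:210] <- y[200:210] + 80          # artifact spike
  tr <- trace(y, 0.02)
  out <- clip_segments(tr, list(window_spec(199 * 0.02, 211 * 0.02)))
  expect_lt(max(abs(out$samples[200:210])), 4 * noise_sd)
  expect_error(clip_segments(tr, list(c(1, 3), c(2, 4))), "overlap")
  expect_error(clip_segments(tr, list(c(-5, 1))), "out of trace range")
})

test_that("concatenation appends sweeps in order", {
  ss <- sweep_set(list(trace(c(1, 2), 1), trace(3, 1)))
  expect_equal(concatenate_sweeps(ss)$samples, c(1, 2, 3))
  one <- concatenate_sweeps(sweep_set(list(trace(1:4, 1))))
  expect_equal(one$samples, 1:4)
  expect_error(concatenate_sweeps(
    sweep_set(list(trace(1, 1), trace(1, 2)))), "dt mismatch")
  ## 170 sweeps x 1 s at 50 kHz
  ss3 <- sweep_set(lapply(1:170, function(i) trace(numeric(50000), 0.02)))
  expect_equal(length(concatenate_sweeps(ss3)$samples), 8.5e6)
})

test_that("histogram bins are left-closed with counts preserved", {
  h <- histogram_counts(0.005, 0.01, 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$center, 0.005)
  expect_equal(h$count, 1L)

  set.seed(6)
  u <- runif(1000)
  h2 <- histogram_counts(u, 0.1, 0)
  expect_equal(sum(h2$count), 1000L)
  expect_equal(nrow(h2), 10)

  ## Gaussian sample versus analytic density: chi-squared not rejected
  x <- rnorm(5000)
  h3 <- histogram_counts(x, 0.25, -4)
  p_bins <- pnorm(h3$center + 0.125) - pnorm(h3$center - 0.125)
  keep <- p_bins * 5000 >= 5
  chi2 <- sum((h3$count[keep] - 5000 * p_bins[keep])^2 /
                (5000 * p_bins[keep]))
  expect_gt(pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("every transform appends exactly one provenance note", {
  tr <- trace(sin(seq(0, 6, by = 0.02)), 0.02)
  n0 <- nrow(tr$notes)
  expect_equal(nrow(baseline_subtract(tr, c(0, 1))$notes), n0 + 1)
  expect_equal(nrow(smooth_binomial(tr, 2)$notes), n0 + 1)
  expect_equal(nrow(lowpass(tr, 5)$notes), n0 + 1)
  expect_equal(nrow(clip_segments(tr, list(c(1, 2)))$notes), n0 + 1)
  expect_equal(nrow(pointwise_combine(tr, 2, "multiply")$notes), n0 + 1)
  ## and preserves length
  for (f in list(function(x) baseline_subtract(x, c(0, 1)),
                 function(x) smooth_binomial(x, 3),
                 function(x) lowpass(x, 5),
                 function(x) clip_segments(x, list(c(1, 2)))))
    expect_length(f(tr)$samples, length(tr$samples))
})

test_that("cyclic group assignment follows index mod n", {
  ss <- sweep_set(lapply(1:7, function(i) trace(0, 1)))
  g <- assign_groups(ss, 3)$groups
  expect_equal(g, as.integer((0:6) %% 3))
  g2 <- assign_groups(ss, c(1, 1, 1, 2, 2, 2, 2))$groups
  expect_equal(g2, as.integer(c(1, 1, 1, 2, 2, 2, 2)))
})
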