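## Shared least-squares driver: Levenberg-Marquardt on the free parameters,
## held parameters pinned at their start values and excluded from the
## Jacobian (their reported SE is 0).
ls_fit <- function(resid_fn, start, hold = character(), lower = NULL,
                   upper = NULL, jac_fn = NULL, maxiter = 200,
                   ftol = 1e-10, ptol = 1e-10) {
  pnames <- names(start)
  free <- setdiff(pnames, hold)
  if (length(free) == 0) stop("all parameters held; nothing to fit")
  full <- function(pf) {
    p <- start
    p[free] <- pf
    p
  }
  rf <- function(pf) resid_fn(full(pf))
  jf <- if (is.null(jac_fn)) NULL else function(pf) jac_fn(full(pf))[, free, drop = FALSE]
  lw <- if (is.null(lower)) rep(-Inf, length(free)) else lower[free]
  up <- if (is.null(upper)) rep(Inf, length(free)) else upper[free]
  fit <- minpack.lm::nls.lm(par = start[free], fn = rf, jac = jf,
                            lower = lw, upper = up,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = ftol, ptol = ptol))
  est <- full(fit$par)
  nres <- length(fit$fvec)
  dof <- max(nres - length(free), 1)
  se <- stats::setNames(rep(0, length(pnames)), pnames)
  cv <- tryCatch(solve(fit$hessian) * fit$deviance / dof,
                 error = function(e) NULL)
  if (!is.null(cv)) se[free] <- sqrt(pmax(diag(cv), 0))
  list(estimates = est, se = se, rss = fit$deviance,
       converged = fit$info %in% 1:4, iterations = fit$niter,
       info = fit$message, held = hold)
}

#' Fit the multi-exponential synaptic waveform to a trace
#'
#' Least-squares fit of the [synexp_params()] waveform (zero before onset)
#' over a window containing the event onset, peak and initial decay.
#' Starting values default to heuristics: `t0` from the 20% crossing of the
#' extremum, `tau_d1` from a log-linear fit to the decay. Parameters listed
#' in `hold` are pinned to their start values (e.g. `hold = "a_d2"` with
#' `a_d2 = 0` for a single-exponential decay).
#'
#' @param tr an `ek_trace`.
#' @param window fit window (ms).
#' @param start optional named list/vector overriding the start values
#'   (names among `t0, tau_r, n, a_d1, tau_d1, a_d2, tau_d2`).
#' @param hold character vector of parameter names to hold.
#' @return an `ek_fit` list: `estimates`, `se` (0 for held parameters),
#'   `rss`, `fitted` (an `ek_trace` over the window), `converged`,
#'   `iterations`.
#' @export
fit_synexp <- function(tr, window, start = NULL, hold = c("n", "a_d2", "tau_d2")) {
  stopifnot(inherits(tr, "ek_trace"))
  idx <- window_index(tr, window)
  tt <- trace_times(tr)[idx]
  y_raw <- tr$samples[idx]
  ## start-value heuristics run on a smoothed copy so noise cannot derail
  ## them; the fit itself uses the raw samples
  y <- y_raw
  for (i in 1:8) y <- conv_same(y, c(1, 2, 1) / 4)
  ipk <- which.max(abs(y - stats::median(y)))
  pk <- y[ipk] - stats::median(y[1:max(ipk %/% 4, 1)])
  base <- stats::median(y[1:max(ipk %/% 4, 1)])
  z <- (y - base) / ifelse(pk == 0, 1, pk)      # ~0..1, peak 1
  i20 <- which(z[1:ipk] >= 0.2)
  t0_0 <- if (length(i20)) tt[min(i20)] - 0.1 else tt[1]
  dec <- which(seq_along(y) > ipk & sign(pk) * (y - base) > 0.1 * abs(pk))
  tau_d0 <- if (length(dec) > 3) {
    cf <- stats::coef(stats::lm(log(abs(y[dec] - base)) ~ tt[dec]))
    td <- -1 / unname(cf[2])
    if (is.finite(td) && td > 0) td else 1
  } else 1
  s0 <- c(t0 = t0_0, tau_r = max(tau_d0 / 5, 0.02), n = 1,
          a_d1 = pk * 1.2, tau_d1 = tau_d0, a_d2 = 0, tau_d2 = 4 * tau_d0)
  if (!is.null(start)) s0[names(start)] <- unlist(start)
  ## the onset must lie inside the fit window (precondition of the fit)
  lower <- c(t0 = tt[1], tau_r = 1e-4, n = 1, a_d1 = -Inf, tau_d1 = 1e-4,
             a_d2 = -Inf, tau_d2 = 1e-4)
  upper <- c(t0 = tt[length(tt)], tau_r = Inf, n = Inf, a_d1 = Inf,
             tau_d1 = Inf, a_d2 = Inf, tau_d2 = Inf)
  ## clamp shape parameters during trial steps of the optimizer
  model <- function(p, t) synexp_eval(
    synexp_params(p["t0"], max(p["tau_r"], 1e-4), max(p["n"], 1),
                  p["a_d1"], max(p["tau_d1"], 1e-4),
                  p["a_d2"], max(p["tau_d2"], 1e-4)), t)
  fit <- ls_fit(function(p) y_raw - model(p, tt), s0, hold = hold,
                lower = lower, upper = upper)
  fitted_tr <- trace(model(fit$estimates, tt), dt = tr$dt, t_start = tt[1],
                     units = tr$units, label = "fit_synexp")
  c(fit, list(fitted = fitted_tr, model = "synexp"))
}

## closed-form weighted parabola through the origin on the design {Ip, Ip^2}:
## sigma2 = alpha Ip + beta Ip^2; used for start values (and, in tests, as
## the independent oracle for the CVs-fixed multinomial fit)
mpfa_parabola_solve <- function(Ip, sigma2, w) {
  X <- cbind(Ip, Ip^2)
  A <- crossprod(X * sqrt(w))
  b <- crossprod(X, w * sigma2)
  sol <- solve(A, b)
  c(alpha = sol[1], beta = sol[2])
}

#' Fit the multinomial variance-mean relation
#'
#' Weighted least-squares fit of
#' \deqn{\sigma_I^2 = [Q_p I_p - I_p^2/N]\,[1 + CV_{QII}^2] + Q_p I_p CV_{QI}^2}
#' to a set of MPFA points, estimating `N` (release sites) and `Q_p`
#' (quantal peak) with the quantal CVs fixed. Weights default to
#' `1 / var_err^2`. Start values come from the closed-form weighted parabola
#' solve; the reported estimates and standard errors come from the
#' Levenberg-Marquardt fit with its analytic Jacobian.
#'
#' @param points list of `ek_mpfa_point` (or a data.frame with columns
#'   `Ip`, `sigma2`, `var_err`).
#' @param cv_qi within-site quantal CV, held fixed.
#' @param cv_qii across-site quantal CV, held fixed.
#' @param weights optional per-point weights (default `1/var_err^2`).
#' @return an `ek_fit` list with `estimates["N"]`, `estimates["Q_p"]`, SEs,
#'   `rss`, `fitted` (data.frame `Ip`, `sigma2_hat`), `converged`.
#' @export
fit_multinomial <- function(points, cv_qi = 0, cv_qii = 0, weights = NULL) {
  tab <- if (is.data.frame(points)) points else mpfa_table(points)
  if (nrow(tab) < 2) stop("need at least 2 MPFA points")
  if (length(unique(tab$Ip)) < 2)
    stop("all I_p values are equal; the design is singular")
  w <- if (is.null(weights)) 1 / tab$var_err^2 else weights
  if (any(!is.finite(w) | w <= 0)) stop("weights must be finite and positive")
  kII <- 1 + cv_qii^2
  kI <- cv_qi^2
  ## start from the parabola solve: alpha = Qp (kII + kI), beta = -kII / N
  ab <- mpfa_parabola_solve(tab$Ip, tab$sigma2, w)
  qp0 <- ab["alpha"] / (kII + kI)
  n0 <- -kII / ab["beta"]
  if (!is.finite(n0) || n0 <= 0) n0 <- max(abs(tab$Ip)) / max(abs(qp0), 1e-9)
  model <- function(p) (p["Q_p"] * tab$Ip - tab$Ip^2 / p["N"]) * kII +
    p["Q_p"] * tab$Ip * kI
  jac <- function(p) {
    cbind(N = -sqrt(w) * tab$Ip^2 / p["N"]^2 * kII,
          Q_p = -sqrt(w) * (tab$Ip * kII + tab$Ip * kI))
  }
  start <- c(N = unname(n0), Q_p = unname(qp0))
  fit <- ls_fit(function(p) sqrt(w) * (tab$sigma2 - model(p)), start,
                jac_fn = jac, lower = c(N = 1e-6, Q_p = -Inf))
  fitted <- data.frame(Ip = tab$Ip,
                       sigma2_hat = model(fit$estimates))
  c(fit, list(fitted = fitted, model = "multinomial",
              cv_qi = cv_qi, cv_qii = cv_qii))
}

#' Fit a Gaussian to a histogram or a sample
#'
#' Fits `a * exp(-(x - center)^2 / (2 sd^2))` to histogram counts. When raw
#' values are supplied they are binned first with [histogram_counts()].
#'
#' @param x either a histogram data.frame (`center`, `count`) or a numeric
#'   sample.
#' @param bin_width bin width used when `x` is a raw sample.
#' @return an `ek_fit` with `estimates["amp"]`, `["center"]`, `["sd"]`.
#' @export
fit_gaussian <- function(x, bin_width = NULL) {
  h <- if (is.data.frame(x)) x else {
    if (is.null(bin_width)) stop("bin_width required for raw values")
    histogram_counts(x, bin_width)
  }
  if (nrow(h) < 4) stop("need at least 4 histogram bins")
  xs <- h$center; ys <- h$count
  mu0 <- sum(xs * ys) / sum(ys)
  sd0 <- sqrt(max(sum(ys * (xs - mu0)^2) / sum(ys), 1e-12))
  start <- c(amp = max(ys), center = mu0, sd = sd0)
  model <- function(p) p["amp"] * exp(-(xs - p["center"])^2 / (2 * p["sd"]^2))
  fit <- ls_fit(function(p) ys - model(p), start,
                lower = c(amp = 0, center = -Inf, sd = 1e-12))
  c(fit, list(fitted = data.frame(center = xs, count_hat = model(fit$estimates)),
              model = "gaussian"))
}

#' Outlier cut from a Gaussian fit
#'
#' Returns `center + k * sd`, e.g. the "peak center plus 5 SDs" rule used to
#' split slow from fast rise times.
#' @param fit an `ek_fit` from [fit_gaussian()].
#' @param k number of SDs (default 5).
#' @export
gaussian_cut <- function(fit, k = 5) {
  unname(fit$estimates["center"] + k * fit$estimates["sd"])
}

#' Fit a double exponential decay
#'
#' Fits `a1 exp(-(t - t_ref)/tau1) + a2 exp(-(t - t_ref)/tau2) + y0` over a
#' window on a decaying segment (`t_ref` is the window start). Used e.g. to
#' model the final decay of an averaged stimulus artifact before
#' point-by-point subtraction.
#'
#' @param tr an `ek_trace`.
#' @param window fit window (ms).
#' @param start optional named overrides (`a1, tau1, a2, tau2, y0`).
#' @param hold parameter names to hold (e.g. `c("a2")` with `a2 = 0` for a
#'   single exponential, or `"y0"`).
#' @return an `ek_fit`; degenerate tau pairs are flagged via
#'   `converged = FALSE`, not an exception.
#' @export
fit_doubleexp <- function(tr, window, start = NULL, hold = character()) {
  stopifnot(inherits(tr, "ek_trace"))
  idx <- window_index(tr, window)
  tt <- trace_times(tr)[idx]
  y <- tr$samples[idx]
  t_ref <- tt[1]
  u <- tt - t_ref
  span <- max(u[length(u)], 1e-3)
  n_tail <- max(3L, length(y) %/% 20)
  y0_0 <- mean(y[(length(y) - n_tail + 1):length(y)])
  a0 <- y[1] - y0_0
  ## exponential peeling for start values: slow component from the late
  ## segment, fast component from the early residual
  s0 <- c(a1 = a0 * 0.7, tau1 = span / 20, a2 = a0 * 0.3, tau2 = span / 3,
          y0 = y0_0)
  z <- (y - y0_0) * sign(a0)
  late <- u > span / 3 & z > 0
  if (sum(late) > 5) {
    cf2 <- stats::coef(stats::lm(log(z[late]) ~ u[late]))
    if (is.finite(cf2[2]) && cf2[2] < 0) {
      s0["tau2"] <- min(-1 / unname(cf2[2]), 10 * span)
      s0["a2"] <- sign(a0) * exp(unname(cf2[1]))
      r <- z - exp(unname(cf2[1])) * exp(-u / unname(s0["tau2"]))
      early <- u < span / 4 & r > max(z) * 0.01
      if (sum(early) > 5) {
        cf1 <- stats::coef(stats::lm(log(r[early]) ~ u[early]))
        if (is.finite(cf1[2]) && cf1[2] < 0) {
          s0["tau1"] <- min(-1 / unname(cf1[2]), s0["tau2"])
          s0["a1"] <- sign(a0) * exp(unname(cf1[1]))
        }
      }
    }
  }
  if (!is.null(start)) s0[names(start)] <- unlist(start)
  model <- function(p) p["a1"] * exp(-u / p["tau1"]) +
    p["a2"] * exp(-u / p["tau2"]) + p["y0"]
  fit <- ls_fit(function(p) y - model(p), s0, hold = hold,
                lower = c(a1 = -Inf, tau1 = 1e-5, a2 = -Inf, tau2 = 1e-5,
                          y0 = -Inf))
  ## tau degeneracy: the two components collapsed onto each other
  if (!("tau2" %in% hold) && !("tau1" %in% hold)) {
    r <- fit$estimates["tau2"] / fit$estimates["tau1"]
    if (is.finite(r) && abs(log(r)) < 0.05 && fit$estimates["a2"] != 0)
      fit$converged <- FALSE
  }
  fitted_tr <- trace(model(fit$estimates), dt = tr$dt, t_start = t_ref,
                     units = tr$units, label = "fit_doubleexp")
  c(fit, list(fitted = fitted_tr, t_ref = t_ref, model = "doubleexp"))
}
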