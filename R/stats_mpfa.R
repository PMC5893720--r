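#' Windowed per-sweep measures
#'
#' Computes, for each sweep, the average/minimum/maximum of the
#' baseline-subtracted signal within a window. For `min`/`max` the extremum
#' time is also returned. Failed measures give `NaN` and a reason.
#'
#' @param ss an `ek_sweepset`.
#' @param type `"avg"`, `"min"` or `"max"`.
#' @param window measurement window (ms).
#' @param baseline_window optional baseline window; its mean is subtracted
#'   from the measure (omit for raw values).
#' @return data.frame with columns `sweep`, `value`, `t_at` (extremum time,
#'   `NA` for `"avg"`), `baseline`.
#' @export
window_measure <- function(ss, type = c("avg", "min", "max"), window,
                           baseline_window = NULL) {
  stopifnot(inherits(ss, "ek_sweepset"))
  type <- match.arg(type)
  rows <- lapply(seq_len(n_sweeps(ss)), function(k) {
    tr <- ss$traces[[k]]
    b <- if (is.null(baseline_window)) 0
         else mean(tr$samples[window_index(tr, baseline_window)])
    idx <- tryCatch(window_index(tr, window), error = function(e) integer(0))
    if (length(idx) == 0)
      return(data.frame(sweep = k - 1L, value = NaN, t_at = NA_real_,
                        baseline = b))
    y <- tr$samples[idx] - b
    tt <- trace_times(tr)[idx]
    v <- switch(type, avg = mean(y), min = min(y), max = max(y))
    t_at <- switch(type, avg = NA_real_, min = tt[which.min(y)],
                   max = tt[which.max(y)])
    data.frame(sweep = k - 1L, value = v, t_at = t_at, baseline = b)
  })
  do.call(rbind, rows)
}

#' Fractional rise time of a waveform
#'
#' Locates the polarity extremum within `peak_window`, then finds the last
#' linear-interpolated crossings of `baseline + p * (peak - baseline)` before
#' the peak for `p = p_low` and `p = p_high`. The 10-90% rise time uses
#' `p_low = 0.1, p_high = 0.9`; 20-80% uses 0.2/0.8.
#'
#' @param tr an `ek_trace`.
#' @param p_low,p_high fractions with `0 < p_low < p_high < 1`.
#' @param baseline_window window whose mean defines the baseline.
#' @param peak_window window searched for the extremum.
#' @return list with `t_low`, `t_high`, `rt` (ms), `peak` (signed,
#'   baseline-relative) and `t_peak`; `rt` is `NaN` with a `reason` element
#'   when a crossing cannot be found.
#' @export
rise_time <- function(tr, p_low = 0.1, p_high = 0.9, baseline_window,
                      peak_window) {
  stopifnot(inherits(tr, "ek_trace"), p_low > 0, p_low < p_high, p_high < 1)
  b <- mean(tr$samples[window_index(tr, baseline_window)])
  idx <- window_index(tr, peak_window)
  y <- tr$samples - b
  tt <- trace_times(tr)
  ipk <- idx[which.max(abs(y[idx]))]
  peak <- y[ipk]
  if (peak == 0)
    return(list(t_low = NaN, t_high = NaN, rt = NaN, peak = 0,
                t_peak = tt[ipk], reason = "flat peak"))
  cross_before <- function(p) {
    lvl <- p * peak
    ## last crossing of lvl before the peak (search the signed excursion)
    z <- y[1:ipk] / sign(peak)       # positive-going
    lv <- lvl / sign(peak)
    below <- which(z[-length(z)] < lv & z[-1] >= lv)
    if (length(below) == 0) return(NA_real_)
    i <- below[length(below)]
    frac <- (lv - z[i]) / (z[i + 1] - z[i])
    tt[i] + frac * (tt[i + 1] - tt[i])
  }
  t_low <- cross_before(p_low)
  t_high <- cross_before(p_high)
  if (is.na(t_low) || is.na(t_high))
    return(list(t_low = t_low, t_high = t_high, rt = NaN, peak = peak,
                t_peak = tt[ipk], reason = "crossing not found"))
  list(t_low = t_low, t_high = t_high, rt = t_high - t_low, peak = peak,
       t_peak = tt[ipk])
}

#' Rise-time slope
#'
#' Slope of the chord between the low- and high-fraction crossings,
#' `(y_high - y_low) / (t_high - t_low)` in signal units per ms (e.g.
#' pA/ms). Scales linearly with amplitude while the rise time itself does
#' not, which is what makes it useful as a fast-versus-slow classifier.
#'
#' @inheritParams rise_time
#' @return list as [rise_time()] plus `slope`.
#' @export
rt_slope <- function(tr, p_low = 0.2, p_high = 0.8, baseline_window,
                     peak_window) {
  r <- rise_time(tr, p_low, p_high, baseline_window, peak_window)
  r$slope <- if (is.nan(r$rt) || r$rt == 0) NaN
             else (p_high - p_low) * r$peak / r$rt
  r
}

#' Select a stable run of consecutive responses (Spearman test)
#'
#' Finds the longest window `[i, n]` of consecutive per-sweep values whose
#' Spearman rank correlation with sweep order is not significant (two-sided
#' `p >= alpha`), scanning `i` upward from the start so the first hit is the
#' largest such suffix window. This is the usual drift screen applied before
#' fluctuation analysis.
#'
#' @param values per-sweep measure (e.g. peak amplitudes), length >= 10.
#' @param alpha significance level for the trend test (default 0.05).
#' @param min_len smallest acceptable window (default 10).
#' @return list with `i_begin`, `i_end` (1-based, inclusive), `rho`, `p`.
#' @export
stability_range <- function(values, alpha = 0.05, min_len = 10) {
  n <- length(values)
  if (n < min_len) stop("need at least min_len values")
  for (i in 1:(n - min_len + 1)) {
    v <- values[i:n]
    ct <- suppressWarnings(
      stats::cor.test(seq_along(v), v, method = "spearman", exact = FALSE))
    if (ct$p.value >= alpha)
      return(list(i_begin = i, i_end = n, rho = unname(ct$estimate),
                  p = ct$p.value))
  }
  stop("no stable region of length >= min_len found")
}

#' Classify values against an inequality criterion
#'
#' Boolean membership usable with [define_set()]/[select_sweeps()], e.g.
#' "Success if the 1-ms post-stimulus average exceeds 3 SDs of background".
#'
#' @param values numeric vector (NaN/NA never match).
#' @param op one of `">"`, `"<"`, `">="`, `"<="`.
#' @param threshold finite threshold.
#' @return logical vector; attribute `n_true` holds the match count.
#' @export
classify_inequality <- function(values, op = c(">", "<", ">=", "<="),
                                threshold) {
  op <- match.arg(op)
  stopifnot(is.finite(threshold))
  ok <- is.finite(values)
  if (!any(ok)) warning("all values are non-finite; empty classification")
  res <- rep(FALSE, length(values))
  res[ok] <- switch(op,
                    ">" = values[ok] > threshold,
                    "<" = values[ok] < threshold,
                    ">=" = values[ok] >= threshold,
                    "<=" = values[ok] <= threshold)
  attr(res, "n_true") <- sum(res)
  res
}

## h-statistics: unbiased fourth central moment and unbiased sigma^4
h4_moment <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  n * ((n^2 - 2 * n + 3) * m4 - 3 * (2 * n - 3) * m2^2) /
    ((n - 1) * (n - 2) * (n - 3))
}

sigma4_unbiased <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  n * (n^2 - 3 * n + 3) / ((n - 1) * (n - 2) * (n - 3)) * m2^2 -
    n / ((n - 2) * (n - 3)) * m4
}

## unbiased estimate of Var(s^2) = (mu4 - sigma^4 (n-3)/(n-1)) / n
var_of_variance <- function(x) {
  n <- length(x)
  (h4_moment(x) - sigma4_unbiased(x) * (n - 3) / (n - 1)) / n
}

#' MPFA summary statistics for one probability condition
#'
#' Computes the mean peak current `I_p`, the peak variance `sigma2`
#' (unbiased, with the background-window variance subtracted by default) and
#' the standard error of the variance from h-statistics: the unbiased
#' estimator of `Var(s^2) = (mu4 - sigma^4 (n-3)/(n-1)) / n`, with `mu4`
#' estimated by the unbiased fourth central moment (h-statistic) and
#' `sigma^4` by its unbiased polykay. These variance errors are the fit
#' weights for the variance-mean relation.
#'
#' @param peaks per-trial peak measures (pA), `n >= 4`.
#' @param backgrounds per-trial background measures from the reflected
#'   window (pA), `n >= 4`.
#' @param label condition label.
#' @param subtract_background subtract the background variance from the peak
#'   variance (default TRUE; standard practice, switchable).
#' @return an `ek_mpfa_point`: list with `label`, `Ip`, `sigma2`, `var_err`,
#'   `n`, `bg_var`.
#' @export
mpfa_stats <- function(peaks, backgrounds, label = "",
                       subtract_background = TRUE) {
  n <- length(peaks)
  if (n < 4 || length(backgrounds) < 4)
    stop("h-statistics need at least 4 trials")
  bg_var <- stats::var(backgrounds)
  sigma2 <- stats::var(peaks) - if (subtract_background) bg_var else 0
  if (sigma2 < 0) {
    warning("background variance exceeds peak variance; sigma2 floored at 0")
    sigma2 <- 0
  }
  ve2 <- var_of_variance(peaks)
  if (!is.finite(ve2) || ve2 <= 0) {
    ## pathological 4th-moment draw: fall back to the Gaussian form
    warning("non-positive Var(s^2) estimate; using Gaussian 2 s^4/(n-1)")
    ve2 <- 2 * stats::var(peaks)^2 / (n - 1)
  }
  ## degenerate (constant) samples still need a usable fit weight
  ve2 <- max(ve2, 1e-12)
  structure(list(label = label, Ip = mean(peaks), sigma2 = sigma2,
                 var_err = sqrt(ve2), n = n, bg_var = bg_var),
            class = "ek_mpfa_point")
}

#' Subtract spillover statistics from an MPFA point
#'
#' The slow spillover component inflates both the mean and the variance of
#' the measured peak; given externally estimated spillover statistics this
#' removes them. The estimates themselves must be supplied by the user.
#'
#' @param point an `ek_mpfa_point`.
#' @param ip_s spillover mean current (pA).
#' @param sigma2_s spillover variance (pA^2).
#' @return the corrected point (negative corrected variance is floored at 0
#'   with a warning).
#' @export
spillover_subtract <- function(point, ip_s, sigma2_s) {
  stopifnot(inherits(point, "ek_mpfa_point"))
  point$Ip <- point$Ip - ip_s
  s2 <- point$sigma2 - sigma2_s
  if (s2 < 0) {
    warning("spillover variance exceeds point variance; floored at 0")
    s2 <- 0
  }
  point$sigma2 <- s2
  point$label <- paste0(point$label, " (spillover-corrected)")
  point
}

#' Bind MPFA points into a data frame
#' @param points list of `ek_mpfa_point`.
#' @return data.frame with columns `label`, `Ip`, `sigma2`, `var_err`, `n`.
#' @export
mpfa_table <- function(points) {
  do.call(rbind, lapply(points, function(p)
    data.frame(label = p$label, Ip = p$Ip, sigma2 = p$sigma2,
               var_err = p$var_err, n = p$n, stringsAsFactors = FALSE)))
}

#' Peak measurement window centered on the average extremum
#'
#' Averages the sweeps, finds the polarity extremum of the average within
#' `search_window`, and returns a window of width `width` centered on it
#' (the usual 0.1 ms amplitude window for fluctuation analysis).
#'
#' @param ss an `ek_sweepset`.
#' @param search_window window within which the extremum is sought.
#' @param width window width (ms, default 0.1).
#' @param polarity `"neg"` or `"pos"`.
#' @return a [window_spec()].
#' @export
peak_window_on_average <- function(ss, search_window, width = 0.1,
                                   polarity = c("neg", "pos")) {
  polarity <- match.arg(polarity)
  avg <- average_sweeps(ss)$mean
  idx <- window_index(avg, search_window)
  y <- avg$samples[idx]
  i <- if (polarity == "neg") which.min(y) else which.max(y)
  t_pk <- trace_times(avg)[idx[i]]
  window_spec(t_pk - width / 2, t_pk + width / 2)
}
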