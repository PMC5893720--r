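#' Uniformly sampled trace with provenance notes
#'
#' A `trace` is one uniformly sampled record (a "sweep" or "wave"): current in
#' pA, voltage in mV, or conductance in nS. Sample `i` (0-based) sits at time
#' `t_start + i * dt`, all times in milliseconds. Every mutating operation in
#' the package appends exactly one provenance note (timestamp, operation name,
#' parameter string), so a trace carries its full processing history.
#'
#' @param samples numeric vector of sample values.
#' @param dt sample interval in ms (must be > 0). 50 kHz sampling is
#'   `dt = 0.02`.
#' @param t_start time of the first sample in ms.
#' @param units unit string, e.g. `"pA"`, `"mV"`, `"nS"`.
#' @param label free-form label.
#' @return An object of class `ek_trace`.
#' @examples
#' tr <- trace(rnorm(100), dt = 0.02, units = "pA")
#' trace_times(tr)[1:3]
#' @export
trace <- function(samples, dt, t_start = 0, units = "pA", label = "") {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ms)")
  structure(
    list(samples = samples, dt = dt, t_start = as.numeric(t_start),
         units = as.character(units), label = as.character(label),
         notes = empty_notes()),
    class = "ek_trace")
}

empty_notes <- function() {
  data.frame(timestamp = character(), op = character(),
             params = character(), stringsAsFactors = FALSE)
}

#' @export
print.ek_trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples, dt = %g ms, t = [%g, %g] ms, units = %s%s\n",
              length(x$samples), x$dt, x$t_start, trace_t_end(x), x$units,
              if (nzchar(x$label)) paste0(", label = ", x$label) else ""))
  if (nrow(x$notes) > 0)
    cat(sprintf("  %d provenance note(s); last: %s(%s)\n",
                nrow(x$notes), x$notes$op[nrow(x$notes)],
                x$notes$params[nrow(x$notes)]))
  invisible(x)
}

#' Sample times of a trace
#' @param tr an `ek_trace`.
#' @return numeric vector of times (ms), one per sample.
#' @export
trace_times <- function(tr) tr$t_start + (seq_along(tr$samples) - 1) * tr$dt

trace_t_end <- function(tr) tr$t_start + (length(tr$samples) - 1) * tr$dt

#' Append a provenance note to a trace
#'
#' Used by every mutating operation; exposed so user code can annotate its
#' own processing steps the same way.
#' @param tr an `ek_trace`.
#' @param op operation name.
#' @param params single parameter string.
#' @return the trace with one more note row.
#' @export
add_note <- function(tr, op, params = "") {
  stopifnot(inherits(tr, "ek_trace"))
  tr$notes <- rbind(tr$notes, data.frame(
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
    op = as.character(op), params = as.character(params),
    stringsAsFactors = FALSE))
  tr
}

#' Analysis window in trace time
#'
#' Closed interval `[xbgn, xend]` on sample times, both in ms.
#' @param xbgn,xend window begin/end times (ms), `xbgn < xend`.
#' @return an `ek_window` object.
#' @export
window_spec <- function(xbgn, xend) {
  if (!(is.finite(xbgn) && is.finite(xend) && xbgn < xend))
    stop("window requires finite xbgn < xend")
  structure(list(xbgn = xbgn, xend = xend), class = "ek_window")
}

as_window <- function(w) {
  if (inherits(w, "ek_window")) return(w)
  if (is.numeric(w) && length(w) == 2) return(window_spec(w[1], w[2]))
  stop("expected a window_spec() or numeric length-2 vector")
}

## indices of samples whose time falls in [xbgn, xend]; errors if empty
window_index <- function(tr, window) {
  w <- as_window(window)
  tt <- trace_times(tr)
  idx <- which(tt >= w$xbgn - 1e-9 & tt <= w$xend + 1e-9)
  if (length(idx) == 0)
    stop(sprintf("window [%g, %g] ms does not intersect trace time range [%g, %g] ms",
                 w$xbgn, w$xend, tr$t_start, trace_t_end(tr)))
  idx
}

#' Ordered collection of sweeps sharing a prefix and channel
#'
#' A `sweep_set` groups traces acquired as repeated episodes. Named sets
#' (logical membership per sweep, edited via [define_set()]) support the
#' select/exclude workflow; the reserved set `"SetX"` marks sweeps excluded
#' from every selection. Groups tag sweeps acquired in a repeating sequence.
#'
#' @param traces list of `ek_trace` objects.
#' @param prefix sweep-name prefix (e.g. `"Record"`).
#' @param channel channel id (e.g. `"A"`).
#' @param sets named list of logical vectors, one element per sweep.
#' @param groups optional integer vector (group id per sweep) or `NA`s.
#' @return An object of class `ek_sweepset`.
#' @export
sweep_set <- function(traces, prefix = "Record", channel = "A",
                      sets = list(), groups = NULL) {
  stopifnot(is.list(traces), all(vapply(traces, inherits, TRUE, "ek_trace")))
  n <- length(traces)
  for (nm in names(sets)) {
    if (length(sets[[nm]]) != n)
      stop(sprintf("set '%s' has length %d but there are %d sweeps",
                   nm, length(sets[[nm]]), n))
    sets[[nm]] <- as.logical(sets[[nm]])
  }
  if (is.null(groups)) groups <- rep(NA_integer_, n)
  stopifnot(length(groups) == n)
  structure(list(traces = traces, prefix = prefix, channel = channel,
                 sets = sets, groups = as.integer(groups)),
            class = "ek_sweepset")
}

#' @export
print.ek_sweepset <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweep(s), prefix '%s', channel '%s'",
              n_sweeps(x), x$prefix, x$channel))
  if (length(x$sets)) cat(", sets:", paste(names(x$sets), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Number of sweeps in a sweep set
#' @param ss an `ek_sweepset`.
#' @export
n_sweeps <- function(ss) length(ss$traces)

#' Define or replace a named set
#' @param ss an `ek_sweepset`.
#' @param name set name. `"SetX"` marks sweeps excluded from all selections.
#' @param membership logical vector, one per sweep.
#' @export
define_set <- function(ss, name, membership) {
  stopifnot(inherits(ss, "ek_sweepset"))
  if (length(membership) != n_sweeps(ss))
    stop("membership length must equal the number of sweeps")
  ss$sets[[name]] <- as.logical(membership)
  ss
}

#' Assign sweeps to groups cyclically
#'
#' Cyclic assignment (`sweep index mod n_groups`) matches data acquired in a
#' repeating stimulus sequence; pass an explicit vector to override.
#' @param ss an `ek_sweepset`.
#' @param n_groups number of groups, or an explicit per-sweep vector.
#' @export
assign_groups <- function(ss, n_groups) {
  stopifnot(inherits(ss, "ek_sweepset"))
  if (length(n_groups) == 1) {
    ss$groups <- as.integer((seq_len(n_sweeps(ss)) - 1) %% n_groups)
  } else {
    stopifnot(length(n_groups) == n_sweeps(ss))
    ss$groups <- as.integer(n_groups)
  }
  ss
}

subset_sweeps <- function(ss, keep) {
  idx <- which(keep)
  sweep_set(ss$traces[idx], prefix = ss$prefix, channel = ss$channel,
            sets = lapply(ss$sets, `[`, idx), groups = ss$groups[idx])
}

#' Select sweeps by set algebra
#'
#' Evaluates a set expression over the named sets of a sweep set. Supported
#' tokens: set names, `OR`, `AND`, `NOT`, parentheses, and `All` (every
#' sweep). Sweeps belonging to the reserved exclusion set `"SetX"` are never
#' returned, whatever the expression.
#'
#' @param ss an `ek_sweepset`.
#' @param set_expr expression string, e.g. `"Fast OR Fast2"`.
#' @return a new `ek_sweepset` holding the matching sweeps (sets and groups
#'   subset accordingly).
#' @examples
#' ss <- sweep_set(list(trace(0, 1), trace(1, 1), trace(2, 1)),
#'                 sets = list(Fast = c(TRUE, FALSE, TRUE),
#'                             Fast2 = c(FALSE, TRUE, FALSE)))
#' n_sweeps(select_sweeps(ss, "Fast OR Fast2"))  # 3
#' @export
select_sweeps <- function(ss, set_expr) {
  stopifnot(inherits(ss, "ek_sweepset"))
  n <- n_sweeps(ss)
  toks <- regmatches(set_expr,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*|\\(|\\)", set_expr))[[1]]
  if (length(toks) == 0) stop("empty set expression")
  env <- new.env(parent = baseenv())
  assign("All", rep(TRUE, n), envir = env)
  for (nm in names(ss$sets)) assign(nm, ss$sets[[nm]], envir = env)
  rexpr <- vapply(toks, function(tk) {
    switch(tk,
           "OR" = "|", "AND" = "&", "NOT" = "!", "(" = "(", ")" = ")",
           {
             if (!exists(tk, envir = env, inherits = FALSE))
               stop(sprintf("unknown set name '%s'", tk))
             tk
           })
  }, character(1))
  keep <- eval(parse(text = paste(rexpr, collapse = " ")), envir = env)
  if (!is.logical(keep) || length(keep) != n)
    stop("set expression did not evaluate to a per-sweep logical vector")
  if (!is.null(ss$sets[["SetX"]])) keep <- keep & !ss$sets[["SetX"]]
  keep[is.na(keep)] <- FALSE
  subset_sweeps(ss, keep)
}
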