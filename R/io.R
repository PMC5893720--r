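## Plain-text data-folder store.
##
## Layout on disk (one directory per data folder):
##   folder.json                      -- name, prefixes, channels, set tables
##   <prefix>_<channel>_sweep<k>.csv  -- header comments (dt, t_start, units,
##                                        label) + one sample per line at 17
##                                        significant digits (exact double
##                                        round-trip)
##   log.csv                          -- append-only command log
## The folder -> prefix -> channel -> sweep hierarchy plus set-membership
## tables and the command log are the content; the container is plain text.

fmt17 <- function(x) sprintf("%.17g", x)

write_trace_csv <- function(tr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt=%s", fmt17(tr$dt)),
               sprintf("# t_start=%s", fmt17(tr$t_start)),
               sprintf("# units=%s", tr$units),
               sprintf("# label=%s", tr$label),
               "samples"), con)
  writeLines(fmt17(tr$samples), con)
  invisible(path)
}

read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m) == 0)
      stop(sprintf("missing required attribute '%s' in %s", key, path))
    sub(paste0("^# ", key, "="), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "samples" & nzchar(body)]
  trace(as.numeric(body), dt = as.numeric(get("dt")),
        t_start = as.numeric(get("t_start")), units = get("units"),
        label = get("label"))
}

#' Write a sweep set to a plain-text data folder
#'
#' Persists the folder -> prefix -> channel -> sweep hierarchy, the named
#' set-membership tables and an optional command log as a directory of
#' plain-text files. Samples are written at 17 significant digits so a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param ss an `ek_sweepset` (or a list of them for multiple prefixes).
#' @param path directory to create/overwrite.
#' @param name folder name stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_folder <- function(ss, path, name = basename(path)) {
  if (inherits(ss, "ek_sweepset")) ss <- list(ss)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(name = name, prefixes = list())
  for (s in ss) {
    key <- paste0(s$prefix, "_", s$channel)
    files <- character(n_sweeps(s))
    for (k in seq_len(n_sweeps(s))) {
      files[k] <- sprintf("%s_sweep%d.csv", key, k - 1)
      write_trace_csv(s$traces[[k]], file.path(path, files[k]))
    }
    meta$prefixes[[key]] <- list(prefix = s$prefix, channel = s$channel,
                                 n = n_sweeps(s), files = files,
                                 sets = s$sets,
                                 groups = as.integer(s$groups))
  }
  jsonlite::write_json(meta, file.path(path, "folder.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a plain-text data folder
#'
#' Exact inverse of [write_folder()].
#' @param path folder directory.
#' @return named list of `ek_sweepset` (one per prefix/channel pair);
#'   attribute `name` carries the folder name.
#' @export
read_folder <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "folder.json"),
                              simplifyVector = TRUE)
  out <- list()
  ## read_json may simplify a single-prefix list differently; normalize
  pxs <- meta$prefixes
  for (key in names(pxs)) {
    p <- pxs[[key]]
    traces <- lapply(p$files, function(f) read_trace_csv(file.path(path, f)))
    sets <- lapply(p$sets, as.logical)
    groups <- if (length(p$groups)) as.integer(p$groups) else NULL
    out[[key]] <- sweep_set(traces, prefix = p$prefix, channel = p$channel,
                            sets = sets, groups = groups)
  }
  attr(out, "name") <- meta$name
  out
}

#' Read sweeps from a delimited text file
#'
#' Accepts either a two-column file (time, value: one sweep, `dt` inferred
#' from the time column, which must be uniform within 1 ppm) or an n-column
#' file (one column per sweep, `dt` supplied).
#'
#' @param path CSV path (RFC-4180, "." decimal; a header row is detected and
#'   skipped).
#' @param dt sample interval (ms); required unless a time column is present.
#' @param units unit string for the sweeps.
#' @param time_column `TRUE` to treat the first of two columns as time (ms).
#' @return an `ek_sweepset`.
#' @export
read_sweeps_csv <- function(path, dt = NULL, units = "pA",
                            time_column = NULL) {
  df <- utils::read.csv(path, header = looks_like_header(path),
                        comment.char = "#")
  if (ncol(df) == 2 && (isTRUE(time_column) || is.null(dt))) {
    tcol <- df[[1]]
    d <- diff(tcol)
    dt_inf <- stats::median(d)
    dev <- max(abs(d - dt_inf))
    if (dev > 1e-6 * dt_inf)
      stop(sprintf("time column is not uniform: max deviation %g ms", dev))
    tr <- trace(df[[2]], dt = dt_inf, t_start = tcol[1], units = units,
                label = basename(path))
    return(sweep_set(list(add_note(tr, "read_csv", path))))
  }
  if (is.null(dt)) stop("dt required for files without a time column")
  traces <- lapply(seq_len(ncol(df)), function(j) {
    tr <- trace(df[[j]], dt = dt, t_start = 0, units = units,
                label = sprintf("%s[%d]", basename(path), j - 1))
    add_note(tr, "read_csv", path)
  })
  sweep_set(traces)
}

looks_like_header <- function(path) {
  first <- readLines(path, n = 1)
  first <- sub("^#.*", "", first)
  any(is.na(suppressWarnings(as.numeric(
    strsplit(first, ",", fixed = TRUE)[[1]]))))
}

#' Write sweeps to a delimited text file
#'
#' One column per sweep, 17 significant digits (values round-trip within
#' double formatting precision).
#' @param ss an `ek_sweepset` on a common grid.
#' @param path output path.
#' @export
write_sweeps_csv <- function(ss, path) {
  check_common_grid(ss)
  m <- do.call(cbind, lapply(ss$traces, function(tr) tr$samples))
  colnames(m) <- sprintf("%s%d", ss$prefix, seq_len(ncol(m)) - 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = ","), con)
  writeLines(apply(m, 1, function(r) paste(fmt17(r), collapse = ",")), con)
  invisible(path)
}

#' Import an Axon Binary Format (ABF) recording
#'
#' ABF import needs an ABF reader, which is not part of this package's
#' dependencies. This stub reports the actionable alternatives.
#' @param path ABF file path.
#' @export
import_abf <- function(path) {
  stop(paste0(
    "ABF import requires an ABF reader, which is not installed. ",
    "Convert '", basename(path), "' to delimited text (e.g. with the Python ",
    "package 'pyabf': pyabf.ABF(path).data) and load it with ",
    "read_sweeps_csv()."), call. = FALSE)
}

#' Export an event table to CSV
#'
#' @param events an `ek_events` table (accepted and rejected rows alike).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_event_table <- function(events, path) {
  cols <- c("sweep", "t_cross", "t_onset", "t_peak", "peak_amp",
            "baseline", "accepted", "reason")
  df <- as.data.frame(events)[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [export_event_table()]
#' @param path CSV path.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$reason[is.na(df$reason)] <- ""
  class(df) <- c("ek_events", "data.frame")
  df
}

#' Append an entry to a command log
#'
#' The log is an append-only CSV mirroring an acquisition-style command
#' history: timestamp, operation, parameter string, output identifiers.
#' @param log_path log file (created with a header on first use).
#' @param op operation name.
#' @param params parameter string.
#' @param outputs output identifier string.
#' @export
log_command <- function(log_path, op, params = "", outputs = "") {
  new <- !file.exists(log_path)
  line <- sprintf("%s,%s,\"%s\",\"%s\"",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), op,
                  gsub("\"", "'", params), gsub("\"", "'", outputs))
  con <- file(log_path, "a")
  on.exit(close(con))
  if (new) writeLines("timestamp,op,params,outputs", con)
  writeLines(line, con)
  invisible(log_path)
}

#' Read a command log
#' @param log_path log file path.
#' @return data.frame with columns timestamp, op, params, outputs.
#' @export
read_command_log <- function(log_path) {
  utils::read.csv(log_path, stringsAsFactors = FALSE)
}
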