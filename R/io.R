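# Reading annotation-file dialects into the canonical recording model,
# and writing marks / results tables back out.

stop_parse <- function(...) stop(..., call. = FALSE)

#' Read a Stylet+-style annotation file
#'
#' Each non-blank line holds one mark: an integer waveform code and the
#' time at which the waveform began, separated by whitespace, `;` or `,`
#' (auto-detected per file). Times are converted to minutes internally
#' (acquisition software typically exports seconds).
#'
#' @param path Path to the annotation text file.
#' @param code_map An [epg_code_map()].
#' @param time_unit Unit of the time column in the file.
#' @return A data.frame of class `epg_marks` with columns `code`, `label`
#'   and `time` (minutes), in file order.
#' @export
read_stylet_marks <- function(path, code_map = default_code_map(),
                              time_unit = c("seconds", "minutes")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_parse("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop_parse("parse error: '", basename(path),
                                "' contains no annotation marks")
  body <- paste(lines[keep], collapse = "\n")
  sep <- if (grepl(";", body, fixed = TRUE)) ";"
         else if (grepl(",", body, fixed = TRUE)) ","
         else NULL
  codes <- numeric(length(keep)); times <- numeric(length(keep))
  for (j in seq_along(keep)) {
    ln <- trimws(lines[keep[j]])
    parts <- if (is.null(sep)) strsplit(ln, "[[:space:]]+")[[1]]
             else trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    code <- suppressWarnings(as.numeric(parts[1]))
    time <- suppressWarnings(as.numeric(parts[2]))
    if (length(parts) < 2 || is.na(code) || is.na(time) || code != round(code))
      stop_parse("parse error at line ", keep[j], " of '", basename(path),
                 "': expected <integer code><sep><time>, got: ", lines[keep[j]])
    codes[j] <- code; times[j] <- time
  }
  if (time_unit == "seconds") times <- times / 60
  marks_from_codes(codes, times, code_map, path, lines = keep)
}

#' Read a Windaq-style CSV event export
#'
#' Expects a CSV with a time column (seconds) and an event column whose
#' entries are either numeric waveform codes or label text resolvable
#' through the code map. Column names containing "time" and one of
#' "event"/"label"/"code"/"mark" are used when present; otherwise the
#' first two columns are taken as time and event.
#'
#' @inheritParams read_stylet_marks
#' @return A data.frame of class `epg_marks` (times in minutes).
#' @export
read_windaq_marks <- function(path, code_map = default_code_map()) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_parse("parse error in '",
                   basename(path), "': ", conditionMessage(e)))
  if (!nrow(df) || ncol(df) < 2)
    stop_parse("parse error: '", basename(path),
               "' has no usable time/event columns")
  nms <- tolower(names(df))
  tcol <- which(grepl("time|sec", nms))[1]
  ecol <- which(grepl("event|label|code|mark", nms))[1]
  if (is.na(tcol)) tcol <- 1L
  if (is.na(ecol)) ecol <- setdiff(seq_len(ncol(df)), tcol)[1]
  times <- suppressWarnings(as.numeric(df[[tcol]]))
  if (anyNA(times))
    stop_parse("parse error in '", basename(path), "': non-numeric time at row ",
               which(is.na(times))[1])
  ev <- trimws(as.character(df[[ecol]]))
  codes <- suppressWarnings(as.numeric(ev))
  txt <- which(is.na(codes))
  if (length(txt)) {  # label text rather than numeric codes
    codes[txt] <- map_label_to_code(ev[txt], code_map)
    bad <- txt[is.na(codes[txt])]
    if (length(bad))
      stop_parse("parse error in '", basename(path),
                 "': unresolvable event label(s): ",
                 paste(unique(ev[bad]), collapse = ", "))
  }
  marks_from_codes(codes, times / 60, code_map, path,
                   lines = seq_along(codes) + 1L)
}

# Shared contract checks for both dialects: codes resolve, times strictly
# increase, exactly one terminal mark (code 99) and it is last.
marks_from_codes <- function(codes, times_min, code_map, path, lines) {
  labels <- map_code_to_label(codes, code_map)
  if (anyNA(labels)) {
    i <- which(is.na(labels))[1]
    stop_parse("parse error at line ", lines[i], " of '", basename(path),
               "': code ", codes[i], " is not in the code map")
  }
  if (any(times_min < 0))
    stop_parse("format error in '", basename(path), "': negative time")
  if (any(diff(times_min) <= 0)) {
    i <- which(diff(times_min) <= 0)[1] + 1L
    stop_parse("format error at line ", lines[i], " of '", basename(path),
               "': times must be strictly increasing")
  }
  term <- which(codes == 99L)
  if (length(term) != 1L || term != length(codes))
    stop_parse("format error in '", basename(path),
               "': The end of each recording must be marked (T, code 99), ",
               "exactly once and last")
  structure(
    data.frame(code = as.integer(codes), label = labels, time = times_min,
               stringsAsFactors = FALSE),
    class = c("epg_marks", "data.frame")
  )
}

#' Build a recording from a mark sequence
#'
#' One period per non-terminal mark; durations by successive differencing
#' (the terminal mark closes the final period, which is therefore always
#' truncated by the end of the recording). Probe indices (a probe is a
#' maximal run of non-Np periods) and the cumulative waveform duration
#' within each probe are filled in.
#'
#' @param marks An `epg_marks` data.frame from [read_stylet_marks()] or
#'   [read_windaq_marks()].
#' @param code_map The [epg_code_map()] used to read the marks (records
#'   the code-11 mode on the recording).
#' @param file_name,treatment Metadata attached to the recording.
#' @return An object of class `epg_recording`: list with elements
#'   `periods` (data.frame: `label`, `code`, `start`, `duration`,
#'   `probe`, `cum_probe`), `total_duration`, `file_name`, `treatment`,
#'   `code11_mode`, `terminated` and `last_truncated`.
#' @export
marks_to_recording <- function(marks, code_map = default_code_map(),
                               file_name = "", treatment = NA_integer_) {
  if (nrow(marks) < 2L)
    stop_parse("format error: fewer than 2 marks in '", file_name, "'")
  n <- nrow(marks) - 1L  # drop terminal mark
  label <- marks$label[seq_len(n)]
  start <- marks$time[seq_len(n)]
  duration <- diff(marks$time)
  probing <- label != "Np"
  # probe index: increments at each start of a maximal non-Np run
  newp <- probing & !c(FALSE, probing[-n])
  probe <- ifelse(probing, cumsum(newp), NA_integer_)
  cum <- rep(NA_real_, n)
  if (any(probing)) {
    sp <- split(seq_len(n)[probing], probe[probing])
    for (rows in sp) cum[rows] <- cumsum(duration[rows])
  }
  periods <- data.frame(label = label, code = marks$code[seq_len(n)],
                        start = start, duration = duration,
                        probe = as.integer(probe), cum_probe = cum,
                        stringsAsFactors = FALSE)
  structure(list(
    periods = periods,
    total_duration = marks$time[n + 1L] - marks$time[1L],
    file_name = file_name,
    treatment = treatment,
    code11_mode = code_map$code11,
    terminated = TRUE,
    last_truncated = TRUE
  ), class = "epg_recording")
}

#' Read one annotation file into a recording
#'
#' Convenience wrapper: dialect dispatch plus [marks_to_recording()].
#'
#' @inheritParams read_stylet_marks
#' @param dialect `"stylet"` (two-column text) or `"windaq"` (CSV export).
#' @param treatment Integer treatment code.
#' @return An `epg_recording`.
#' @export
read_epg_file <- function(path, dialect = c("stylet", "windaq"),
                          code_map = default_code_map(),
                          time_unit = c("seconds", "minutes"),
                          treatment = NA_integer_) {
  dialect <- match.arg(dialect)
  marks <- switch(dialect,
    stylet = read_stylet_marks(path, code_map, time_unit),
    windaq = read_windaq_marks(path, code_map))
  marks_to_recording(marks, code_map, file_name = basename(path),
                     treatment = treatment)
}

#' Load all annotation files of one treatment
#'
#' All files are parsed with the same options and tagged with the
#' treatment code. Per-file errors are collected rather than fail-fast,
#' keyed by file position and name.
#'
#' @param paths Character vector of file paths (at least one).
#' @inheritParams read_epg_file
#' @return List with `recordings` (list of `epg_recording`) and `errors`
#'   (data.frame: `position`, `file`, `message`).
#' @export
load_treatment_files <- function(paths, treatment = 1L,
                                 dialect = c("stylet", "windaq"),
                                 code_map = default_code_map(),
                                 time_unit = c("seconds", "minutes")) {
  if (!length(paths)) stop("usage error: no input files given", call. = FALSE)
  dialect <- match.arg(dialect); time_unit <- match.arg(time_unit)
  recs <- list()
  errs <- data.frame(position = integer(), file = character(),
                     message = character(), stringsAsFactors = FALSE)
  for (i in seq_along(paths)) {
    r <- tryCatch(read_epg_file(paths[i], dialect, code_map, time_unit,
                                treatment = treatment),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errs <- rbind(errs, data.frame(position = i, file = basename(paths[i]),
                                     message = conditionMessage(r),
                                     stringsAsFactors = FALSE))
    } else {
      recs[[length(recs) + 1L]] <- r
    }
  }
  list(recordings = recs, errors = errs)
}

#' @export
print.epg_recording <- function(x, ...) {
  cat("EPG recording '", x$file_name, "' (treatment ",
      x$treatment, ")\n", sep = "")
  cat("  ", nrow(x$periods), " periods over ",
      format(x$total_duration), " min; code 11 = ", x$code11_mode,
      "\n", sep = "")
  wf <- sort(table(x$periods$label), decreasing = TRUE)
  cat("  waveforms:", paste(names(wf), wf, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Write a recording's marks to a Stylet+-style text file
#'
#' Inverse of [read_stylet_marks()]: re-emits the code/time mark list
#' (including the terminal mark) at full precision, so a written file
#' re-reads to the identical period table.
#'
#' @param recording An `epg_recording`.
#' @param path Output path.
#' @param time_unit Unit for the written time column.
#' @param sep Separator between code and time.
#' @export
write_stylet_file <- function(recording, path,
                              time_unit = c("seconds", "minutes"),
                              sep = " ") {
  time_unit <- match.arg(time_unit)
  m <- recording_marks(recording)
  t <- if (time_unit == "seconds") m$time * 60 else m$time
  writeLines(paste(m$code, sprintf("%.10f", t), sep = sep), path)
  invisible(path)
}

#' Write a recording's marks as a Windaq-style CSV event export
#'
#' @inheritParams write_stylet_file
#' @export
write_windaq_file <- function(recording, path) {
  m <- recording_marks(recording)
  utils::write.csv(
    data.frame(time = sprintf("%.10f", m$time * 60), event = m$code),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# marks (code, time in minutes) including terminal, from a recording
recording_marks <- function(recording) {
  p <- recording$periods
  data.frame(code = c(p$code, 99L),
             time = c(p$start, p$start[nrow(p)] + p$duration[nrow(p)]))
}

#' Assemble per-recording variable results into a wide table
#'
#' @param results Named list of variable-result data.frames as returned by
#'   [compute_variables()]; names identify the recordings.
#' @return Data.frame, one row per recording, one column per variable
#'   acronym (plus a leading `recording` column).
#' @export
results_table <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  acr <- results[[1]]$acronym
  vals <- do.call(rbind, lapply(results, function(r) {
    stopifnot(identical(r$acronym, acr))
    r$value
  }))
  out <- data.frame(recording = names(results), vals,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("recording", acr)
  out
}

#' Write a results table to CSV
#'
#' Default layout is one row per recording and one column per variable in
#' the configured order; `transpose = TRUE` swaps the axes (the "Results
#' T" layout). Acronyms listed in `order` come first; any registry
#' acronyms not listed are appended in canonical registry order.
#'
#' @param results Named list of variable-result data.frames
#'   (see [results_table()]).
#' @param path Output CSV path.
#' @param transpose Swap rows and columns.
#' @param order Optional character vector of acronyms to put first.
#' @param missing Token written for missing values (`""` or `"NA"`).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, transpose = FALSE, order = NULL,
                          missing = "") {
  stopifnot(missing %in% c("", "NA"))
  tab <- results_table(results)
  acr <- names(tab)[-1]
  if (!is.null(order)) {
    unknown <- setdiff(order, acr)
    if (length(unknown))
      stop("config error: unknown acronym(s) in order: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    acr <- c(order, setdiff(acr, order))
    tab <- tab[, c("recording", acr)]
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  store <- ifelse(is.na(m), missing, format(m, trim = TRUE, digits = 10))
  if (transpose) {
    out <- data.frame(variable = acr, t(store), stringsAsFactors = FALSE,
                      check.names = FALSE)
    names(out) <- c("variable", tab$recording)
  } else {
    out <- data.frame(recording = tab$recording, store,
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(out) <- c("recording", acr)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
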