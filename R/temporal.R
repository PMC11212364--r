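# Per-hour and cumulative recomputation of the variable registry, and
# per-event (WDE) / per-event-per-insect (WDEI) tables.

#' Restrict a recording to a time window
#'
#' Periods are clipped to `[lo, hi)`: a period spanning a boundary is
#' split and its in-window part retained. A final period cut at `hi` is
#' flagged as truncated by the window (`window_cut`), which is distinct
#' from end-of-recording truncation. Probe indices and cumulative
#' durations are recomputed on the slice.
#'
#' @param recording An `epg_recording`.
#' @param lo,hi Window bounds in minutes (half-open interval).
#' @return An `epg_recording` covering the window; attribute
#'   `window_cut` records whether the final period was cut at `hi`.
#' @export
slice_recording <- function(recording, lo, hi) {
  stopifnot(hi > lo)
  if (lo >= recording$total_duration)
    stop("empty window: lo is past the end of the recording", call. = FALSE)
  p <- recording$periods
  t0 <- p$start[1]
  end <- p$start + p$duration
  keep <- which(end > t0 + lo & p$start < t0 + hi)
  q <- p[keep, , drop = FALSE]
  q$duration <- pmin(end[keep], t0 + hi) - pmax(q$start, t0 + lo)
  q$start <- pmax(q$start, t0 + lo)
  cut_hi <- end[keep[length(keep)]] > t0 + hi
  marks <- data.frame(code = c(q$code, 99L),
                      time = c(q$start, q$start[nrow(q)] +
                                 q$duration[nrow(q)]))
  cm_codes <- unique(rbind(data.frame(code = q$code, label = q$label),
                           data.frame(code = 99L, label = "T")))
  cm <- epg_code_map(cm_codes$code, cm_codes$label,
                     code11 = recording$code11_mode)
  mk <- structure(data.frame(code = marks$code,
                             label = c(q$label, "T"),
                             time = marks$time, stringsAsFactors = FALSE),
                  class = c("epg_marks", "data.frame"))
  out <- marks_to_recording(mk, cm, file_name = recording$file_name,
                            treatment = recording$treatment)
  out$code11_mode <- recording$code11_mode
  # end-of-recording truncation survives only if the window reaches it
  out$last_truncated <- !cut_hi && isTRUE(recording$last_truncated)
  out$window_cut <- cut_hi
  out
}

#' Temporal (by-hour / cumulative) variable tables
#'
#' Recomputes the full registry per time window. `"by-hour"` windows are
#' `[60(h-1), 60h)`; `"cumulative"` windows are `[0, 60h)`. The final
#' window may be a partial hour. By default each window counts its own
#' fragment of a boundary-spanning period (so by-hour counts can sum to
#' more than the full-recording count while durations partition
#' exactly); `attribute = "start"` instead assigns whole periods to the
#' window containing their start. The truncated wave criterion is
#' applied to window-created cuts only when `extend_truncation = TRUE`
#' (it targets end-of-recording truncation); the true final period of
#' the recording is treated per `truncated_criterion` whenever the
#' window reaches it.
#'
#' @param recording A validated `epg_recording`.
#' @param mode `"by-hour"` or `"cumulative"`.
#' @param hours Integer vector of hour indices (default: every hour up
#'   to the recording end, final partial hour included).
#' @param attribute `"fragment"` (split periods at boundaries) or
#'   `"start"`.
#' @param extend_truncation Apply the truncated wave criterion to
#'   window-created cuts.
#' @param ... Passed to [compute_variables()].
#' @return Data.frame: window descriptors (`mode`, `hour`, `lo`, `hi`)
#'   plus one column per registry acronym.
#' @export
compute_temporal <- function(recording, mode = c("by-hour", "cumulative"),
                             hours = NULL,
                             attribute = c("fragment", "start"),
                             extend_truncation = FALSE,
                             truncated_criterion = TRUE, ...) {
  mode <- match.arg(mode); attribute <- match.arg(attribute)
  total <- recording$total_duration
  if (is.null(hours)) hours <- seq_len(ceiling(total / 60))
  stopifnot(all(hours >= 1), all(60 * (hours - 1) < total))
  rows <- lapply(hours, function(h) {
    lo <- if (mode == "by-hour") 60 * (h - 1) else 0
    hi <- min(60 * h, total)
    sl <- if (attribute == "start") start_attributed_slice(recording, lo, hi)
          else slice_recording(recording, lo, hi)
    if (is.null(sl)) {  # start attribution: no period starts in window
      acr <- epg_variable_registry()$acronym
      vals <- as.data.frame(t(stats::setNames(rep(NA_real_, length(acr)),
                                              acr)), check.names = FALSE)
      return(cbind(data.frame(mode = mode, hour = h, lo = lo, hi = hi),
                   vals))
    }
    crit <- if (isTRUE(sl$window_cut)) extend_truncation
            else truncated_criterion
    res <- compute_variables(sl, truncated_criterion = crit, force = TRUE,
                             ...)
    cbind(data.frame(mode = mode, hour = h, lo = lo, hi = hi),
          as.data.frame(t(stats::setNames(res$value, res$acronym)),
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# whole periods attributed to the window containing their start
start_attributed_slice <- function(recording, lo, hi) {
  p <- recording$periods
  t0 <- p$start[1]
  keep <- which(p$start >= t0 + lo & p$start < t0 + hi)
  if (!length(keep)) return(NULL)
  q <- p[keep, , drop = FALSE]
  # contiguous re-timing so the original whole-period durations survive
  mk <- structure(data.frame(
    code = c(q$code, 99L), label = c(q$label, "T"),
    time = q$start[1] + cumsum(c(0, q$duration)),
    stringsAsFactors = FALSE), class = c("epg_marks", "data.frame"))
  cm_codes <- unique(rbind(data.frame(code = q$code, label = q$label),
                           data.frame(code = 99L, label = "T")))
  cm <- epg_code_map(cm_codes$code, cm_codes$label,
                     code11 = recording$code11_mode)
  out <- marks_to_recording(mk, cm, file_name = recording$file_name,
                            treatment = recording$treatment)
  out$code11_mode <- recording$code11_mode
  out$last_truncated <- FALSE
  out$window_cut <- TRUE
  out
}

#' Per-event table for one waveform across a treatment
#'
#' Lists every period of the waveform across the given recordings, one
#' row per event, with provenance — the "Events" layout used to compute
#' waveform duration per event (WDE). Events pooled across insects are
#' pseudo-replicates; prefer [wdei()] for statistics.
#'
#' @param recordings List of `epg_recording`.
#' @param waveform A label from [epg_labels()].
#' @return Data.frame: `treatment`, `recording`, `waveform`, `event`,
#'   `start`, `duration`.
#' @export
events_table <- function(recordings, waveform) {
  stopifnot(is.list(recordings), length(recordings) >= 1L,
            waveform %in% epg_labels())
  rows <- lapply(recordings, function(r) {
    i <- which(r$periods$label == waveform)
    if (!length(i)) return(NULL)
    data.frame(treatment = r$treatment, recording = r$file_name,
               waveform = waveform, event = seq_along(i),
               start = r$periods$start[i], duration = r$periods$duration[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(treatment = integer(), recording = character(),
                      waveform = character(), event = integer(),
                      start = numeric(), duration = numeric())
  rownames(out) <- NULL
  out
}

#' Waveform duration per event and per insect (WDEI)
#'
#' Mean duration of the waveform's periods within one recording — the
#' per-insect summary that makes the individual recording the
#' statistical replicate. Equals the registry's `a_` variable for the
#' same recording and options.
#'
#' @param recording An `epg_recording`.
#' @param waveform A label from [epg_labels()].
#' @param truncated_criterion,mean_policy As in [compute_variables()].
#' @return Mean duration in minutes, or `NA` when the waveform is
#'   absent.
#' @export
wdei <- function(recording, waveform, truncated_criterion = FALSE,
                 mean_policy = "longest-include") {
  stopifnot(waveform %in% epg_labels())
  p <- recording$periods
  rows <- which(p$label == waveform)
  if (!length(rows)) return(NA_real_)
  n <- nrow(p)
  if (truncated_criterion && isTRUE(recording$last_truncated) && n %in% rows)
    truncated_wave_stats(p$duration[rows[rows != n]], p$duration[n],
                         TRUE, mean_policy)$a
  else mean(p$duration[rows])
}
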