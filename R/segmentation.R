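# Higher-order structure on top of the period sequence: probes, pd
# groups, phloem phases, and derived period classes.

#' Find probes in a recording
#'
#' A probe is a maximal run of non-Np periods; every Np period separates
#' probes. A probe shorter than `brief_threshold` minutes is flagged
#' brief (the "short probe" class of the variable registry).
#'
#' @param recording An `epg_recording`.
#' @param brief_threshold Brief-probe threshold in minutes (strict `<`).
#' @return Data.frame with one row per probe: `probe`, `start`,
#'   `duration`, `n_periods`, `first_row`, `last_row`, `brief`.
#' @export
find_probes <- function(recording, brief_threshold = 3) {
  p <- recording$periods
  rows <- which(!is.na(p$probe))
  if (!length(rows))
    return(data.frame(probe = integer(), start = numeric(),
                      duration = numeric(), n_periods = integer(),
                      first_row = integer(), last_row = integer(),
                      brief = logical()))
  idx <- p$probe[rows]
  out <- data.frame(
    probe = sort(unique(idx)),
    start = as.numeric(tapply(p$start[rows], idx, min)),
    duration = as.numeric(tapply(p$duration[rows], idx, sum)),
    n_periods = as.integer(tapply(rows, idx, length)),
    first_row = as.integer(tapply(rows, idx, min)),
    last_row = as.integer(tapply(rows, idx, max))
  )
  out$brief <- out$duration < brief_threshold
  out
}

#' Group potential-drop subphases
#'
#' One group per pd onset (subphase II-1), with the II-2 / II-3 subphase
#' durations taken from the following period triplet. In p-pd mode each
#' code-11 period forms its own group of kind `"p-pd"` (no subphases
#' marked). Incomplete groups (validation already reports them under G5)
#' are emitted with the absent subphases as `NA` and `complete = FALSE`.
#'
#' @param recording An `epg_recording`.
#' @return Data.frame: `group`, `kind` (`"standard-pd"` or `"p-pd"`),
#'   `probe`, `start`, `dur_II1`, `dur_II2`, `dur_II3`, `total`,
#'   `onset_row`, `end_row`, `complete`.
#' @export
find_pd_groups <- function(recording) {
  p <- recording$periods
  lab <- p$label
  n <- length(lab)
  prev <- c(NA_character_, lab[-n])
  rows_list <- list()
  onsets <- which(lab == "pd" & (is.na(prev) | !(prev %in% pd_sub)))
  for (o in onsets) {
    i2 <- if (o + 1L <= n && lab[o + 1L] == "pdII-2") o + 1L else NA_integer_
    i3 <- if (!is.na(i2) && i2 + 1L <= n && lab[i2 + 1L] == "pdII-3")
      i2 + 1L else NA_integer_
    d1 <- p$duration[o]
    d2 <- if (is.na(i2)) NA_real_ else p$duration[i2]
    d3 <- if (is.na(i3)) NA_real_ else p$duration[i3]
    end <- max(c(o, i2, i3), na.rm = TRUE)
    rows_list[[length(rows_list) + 1L]] <- data.frame(
      kind = "standard-pd", probe = p$probe[o], start = p$start[o],
      dur_II1 = d1, dur_II2 = d2, dur_II3 = d3,
      total = sum(c(d1, d2, d3), na.rm = TRUE),
      onset_row = o, end_row = end,
      complete = !is.na(i2) && !is.na(i3), stringsAsFactors = FALSE)
  }
  for (o in which(lab == "p-pd")) {
    rows_list[[length(rows_list) + 1L]] <- data.frame(
      kind = "p-pd", probe = p$probe[o], start = p$start[o],
      dur_II1 = NA_real_, dur_II2 = NA_real_, dur_II3 = NA_real_,
      total = p$duration[o], onset_row = o, end_row = o,
      complete = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(rows_list))
    return(data.frame(group = integer(), kind = character(),
                      probe = integer(), start = numeric(),
                      dur_II1 = numeric(), dur_II2 = numeric(),
                      dur_II3 = numeric(), total = numeric(),
                      onset_row = integer(), end_row = integer(),
                      complete = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows_list)
  out <- out[order(out$onset_row), , drop = FALSE]
  out <- cbind(group = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Find phloem phases
#'
#' A phloem phase is a maximal contiguous run of E1/E2 periods. Phases
#' never span probes (any other label, including Np, pd, D or E1e,
#' breaks the run). A phase reaches E2 when at least one E2 period lies
#' inside it.
#'
#' @param recording An `epg_recording`.
#' @return Data.frame: `phase`, `probe`, `start`, `duration`,
#'   `n_periods`, `first_row`, `last_row`, `reaches_E2`, `e1_total`,
#'   `e2_total`.
#' @export
find_phloem_phases <- function(recording) {
  p <- recording$periods
  inph <- p$label %in% c("E1", "E2")
  if (!any(inph))
    return(data.frame(phase = integer(), probe = integer(),
                      start = numeric(), duration = numeric(),
                      n_periods = integer(), first_row = integer(),
                      last_row = integer(), reaches_E2 = logical(),
                      e1_total = numeric(), e2_total = numeric()))
  run <- cumsum(inph & !c(FALSE, inph[-length(inph)]))
  run[!inph] <- NA
  ids <- sort(unique(run[!is.na(run)]))
  rows <- lapply(ids, function(k) {
    r <- which(!is.na(run) & run == k)
    data.frame(probe = p$probe[r[1]], start = p$start[r[1]],
               duration = sum(p$duration[r]), n_periods = length(r),
               first_row = r[1], last_row = r[length(r)],
               reaches_E2 = any(p$label[r] == "E2"),
               e1_total = sum(p$duration[r][p$label[r] == "E1"]),
               e2_total = sum(p$duration[r][p$label[r] == "E2"]))
  })
  out <- cbind(phase = seq_along(ids), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Classify periods into derived behavioral classes
#'
#' Per-period flags: `sE2` (sustained E2, duration strictly greater than
#' `sE2_threshold`); `sgE1` (E1 belonging to a phloem phase that never
#' reaches E2); `frE1` (E1 strictly between two E2 periods of the same
#' phase); `first_E1_E2` (the initial E1 of a phase that reaches E2);
#' `sgD` (a D period not followed by E1). Thresholds are strict
#' inequalities, so boundary durations fall outside the class. The
#' truncated final period is classified on its observed duration.
#'
#' @param recording An `epg_recording`.
#' @param phases Result of [find_phloem_phases()]; computed if missing.
#' @param sE2_threshold Sustained-E2 threshold in minutes (strict `>`).
#' @param frE1_both_sides If `TRUE` (default) frE1 requires an E2
#'   neighbour on both sides within the phase; if `FALSE` a preceding E2
#'   suffices.
#' @return Data.frame of logical flags, one row per period: `sE2`,
#'   `sgE1`, `frE1`, `first_E1_E2`, `sgD`.
#' @export
classify_periods <- function(recording, phases = NULL, sE2_threshold = 10,
                             frE1_both_sides = TRUE) {
  p <- recording$periods
  n <- nrow(p)
  if (is.null(phases)) phases <- find_phloem_phases(recording)
  tags <- data.frame(sE2 = p$label == "E2" & p$duration > sE2_threshold,
                     sgE1 = logical(n), frE1 = logical(n),
                     first_E1_E2 = logical(n), sgD = logical(n))
  if (nrow(phases)) for (k in seq_len(nrow(phases))) {
    r <- phases$first_row[k]:phases$last_row[k]
    lab <- p$label[r]
    if (!phases$reaches_E2[k]) {
      tags$sgE1[r[lab == "E1"]] <- TRUE
    } else {
      if (lab[1] == "E1") tags$first_E1_E2[r[1]] <- TRUE
      e1 <- which(lab == "E1")
      for (j in e1) {
        left <- j > 1 && lab[j - 1] == "E2"
        right <- j < length(lab) && lab[j + 1] == "E2"
        tags$frE1[r[j]] <- if (frE1_both_sides) left && right else left
      }
    }
  }
  dd <- which(p$label == "D")
  tags$sgD[dd] <- dd == n | c(p$label[-1], "")[dd] != "E1"
  tags
}
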