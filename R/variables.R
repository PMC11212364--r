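# Computation of the full per-recording variable registry, with the
# standard missing-data conventions and the truncated wave criterion.

# mean/median/max that return NA on empty input without warnings
mean0 <- function(x) if (length(x)) mean(x) else NA_real_
med0  <- function(x) if (length(x)) stats::median(x) else NA_real_
max0  <- function(x) if (length(x)) max(x) else NA_real_
min0  <- function(x) if (length(x)) min(x) else NA_real_

#' Compute the 127 registry variables for one recording
#'
#' Runs segmentation (probes, pd groups, phloem phases, derived period
#' classes) and evaluates every variable of [epg_variable_registry()],
#' applying the standard missing-data conventions: absent waveform gives
#' count and sum 0 but missing mean/median; recording-start-based times
#' with no reference event are set to the total recording duration;
#' first-probe-based times to the time from first-probe start to the end
#' of the recording; within-probe times, after-counts and sequential
#' durations become missing; before-counts are set to the total count.
#' With `truncated_criterion = TRUE` the mean and median of the waveform
#' whose final period is cut by the end-of-recording mark are estimated
#' with the truncated wave criterion ([true_median_estimate()],
#' [mean_with_truncation()]); all other waveforms are unaffected.
#'
#' @param recording A validated `epg_recording`.
#' @param truncated_criterion Apply the truncated wave criterion.
#' @param mean_policy Mean policy under truncation
#'   (see [mean_with_truncation()]).
#' @param sE2_threshold,brief_threshold Class thresholds in minutes
#'   (strict inequalities: sustained E2 `>`, brief probe `<`).
#' @param e1_index Definition used for the E1 index: `"mirror"` (the E2
#'   index formula with E1 in place of E2) or `"share"`
#'   (`100 * s_E1 / (s_E1 + s_E2)`).
#' @param frE1_both_sides Passed to [classify_periods()].
#' @param guidelines,force Validation gate: unless `force = TRUE`, any
#'   validation issue aborts the computation with a pointer to the
#'   error report.
#' @return Data.frame of class `epg_variables`: `acronym`, `value`,
#'   `missing_reason` (`NA`, `"waveform-absent"`, `"rule-applied"` or
#'   `"undefined-denominator"`), `flag` (truncation method or rule
#'   note), in registry order. Exactly one row per registry acronym.
#' @export
compute_variables <- function(recording, truncated_criterion = TRUE,
                              mean_policy = "longest-include",
                              sE2_threshold = 10, brief_threshold = 3,
                              e1_index = c("mirror", "share"),
                              frE1_both_sides = TRUE,
                              guidelines = guideline_set(), force = FALSE) {
  e1_index <- match.arg(e1_index)
  if (!force) {
    iss <- validate_recording(recording, guidelines)
    if (nrow(iss))
      stop("validation failed for '", recording$file_name, "': ",
           nrow(iss), " wrong marks; run validate_recording() / ",
           "error_report() for details, or use force = TRUE", call. = FALSE)
  }
  p <- recording$periods
  n <- nrow(p)
  total <- recording$total_duration
  probes <- find_probes(recording, brief_threshold)
  phases <- find_phloem_phases(recording)
  pdg <- find_pd_groups(recording)
  tags <- classify_periods(recording, phases, sE2_threshold, frE1_both_sides)

  v <- list(); fl <- list()
  setv <- function(acr, value, flag = NA_character_) {
    v[[acr]] <<- as.numeric(value)
    if (!is.na(flag)) fl[[acr]] <<- flag
  }

  last_label <- p$label[n]
  trunc_on <- isTRUE(truncated_criterion) && isTRUE(recording$last_truncated)

  # non-sequential block for a set of member durations; `rows` are the
  # period rows of the class so the truncated final period is recognised
  nonseq <- function(suffix, durs, rows = integer(), mx = FALSE) {
    k <- length(durs)
    setv(paste0("n_", suffix), k)
    setv(paste0("s_", suffix), if (k) sum(durs) else 0)
    if (k == 0L) {
      setv(paste0("a_", suffix), NA); setv(paste0("m_", suffix), NA)
      if (mx) setv(paste0("mx_", suffix), NA)
      return()
    }
    if (trunc_on && length(rows) && n %in% rows) {
      untr <- durs[rows != n]
      st <- truncated_wave_stats(untr, p$duration[n], TRUE, mean_policy)
      setv(paste0("a_", suffix), st$a, st$a_flag)
      setv(paste0("m_", suffix), st$m, st$m_flag)
    } else {
      setv(paste0("a_", suffix), mean(durs))
      setv(paste0("m_", suffix), stats::median(durs))
    }
    if (mx)
      setv(paste0("mx_", suffix), max(durs),
           if (length(rows) && n %in% rows &&
               which.max(durs) == match(n, rows)) "max-is-truncated"
           else NA_character_)
  }

  rows_of <- function(lbl) which(p$label == lbl)
  dur_of <- function(rows) p$duration[rows]

  # --- plain waveform classes -------------------------------------------
  nonseq("Np", dur_of(rows_of("Np")), rows_of("Np"), mx = TRUE)
  nonseq("C", dur_of(rows_of("C")), rows_of("C"))
  nonseq("F", dur_of(rows_of("F")), rows_of("F"))
  nonseq("G", dur_of(rows_of("G")), rows_of("G"))
  nonseq("E1e", dur_of(rows_of("E1e")), rows_of("E1e"))
  nonseq("D", dur_of(rows_of("D")), rows_of("D"))
  nonseq("E1", dur_of(rows_of("E1")), rows_of("E1"), mx = TRUE)
  nonseq("E2", dur_of(rows_of("E2")), rows_of("E2"))
  setv("mx_E2", max0(dur_of(rows_of("E2"))),
       if (length(rows_of("E2")) && last_label == "E2" &&
           which.max(dur_of(rows_of("E2"))) == match(n, rows_of("E2")))
         "max-is-truncated" else NA_character_)
  nonseq("p-pd", dur_of(rows_of("p-pd")), rows_of("p-pd"))
  setv("n_sgD", sum(tags$sgD))

  np_rows <- rows_of("Np")
  setv("d_2Np", if (length(np_rows) >= 2L) p$duration[np_rows[2]] else NA)

  # --- probes ------------------------------------------------------------
  npr <- nrow(probes)
  nonseq("Pr", probes$duration)  # probe durations; criterion not applied
  setv("d_1Pr", if (npr) probes$duration[1] else NA)
  setv("n_bPr", sum(probes$brief))

  # --- derived phloem classes -------------------------------------------
  sg_rows <- which(tags$sgE1)
  nonseq("sgE1", dur_of(sg_rows), sg_rows, mx = TRUE)
  fr_rows <- which(tags$frE1)
  nonseq("frE1", dur_of(fr_rows), fr_rows, mx = TRUE)
  e12 <- phases[phases$reaches_E2, , drop = FALSE]
  nonseq("E12", e12$duration, mx = TRUE)
  se2_rows <- which(tags$sE2)
  nonseq("sE2", dur_of(se2_rows), se2_rows)
  setv("d_1st_E", if (nrow(phases)) phases$duration[1] else NA)
  e2_rows <- rows_of("E2")
  setv("d_1st_E2", if (length(e2_rows)) p$duration[e2_rows[1]] else NA)
  first_e1 <- which(tags$first_E1_E2)
  setv("a_1st E1_followed_E2", mean0(dur_of(first_e1)))
  setv("a_s_E2/phloem_ph",
       if (nrow(e12)) mean(e12$e2_total) else NA)

  # --- sequential times --------------------------------------------------
  t0 <- p$start[1]
  end_time <- t0 + total
  first_probe_start <- if (npr) probes$start[1] else NA_real_
  setv("t > 1Pr", if (npr) first_probe_start - t0 else total,
       if (!npr) "set-total-duration" else NA_character_)

  first_start_of <- function(rows) if (length(rows)) p$start[rows[1]] else NA
  # first phloem activity = first E1 or E2 period
  e_rows <- which(p$label %in% c("E1", "E2"))
  firstE <- first_start_of(e_rows)
  firstE12 <- if (nrow(e12)) e12$start[1] else NA
  firstE2 <- first_start_of(e2_rows)
  firstsE2 <- first_start_of(se2_rows)

  probe_time <- function(event_start, acr) {
    if (is.na(first_probe_start)) {
      setv(acr, NA)
    } else if (is.na(event_start)) {
      setv(acr, end_time - first_probe_start, "set-first-probe-to-end")
    } else setv(acr, event_start - first_probe_start)
  }
  probe_time(firstE, "t > 1E")
  probe_time(firstE12, "t > 1E12")
  probe_time(firstE2, "t > 1E2")
  probe_time(firstsE2, "t > 1sE2")

  # time from the start of the containing probe to the event
  within_probe_time <- function(rows, acr) {
    if (!length(rows)) { setv(acr, NA); return() }
    pr <- p$probe[rows[1]]
    setv(acr, p$start[rows[1]] - probes$start[probes$probe == pr])
  }
  within_probe_time(e_rows, "tPr > 1E/1Pr")
  within_probe_time(e2_rows, "tPr > 1E2/1Pr")
  within_probe_time(se2_rows, "tPr > 1sE2/1Pr")

  # C time (pd excluded) within the containing probe before the event
  c_time_before <- function(event_row) {
    pr <- p$probe[event_row]
    rows <- which(!is.na(p$probe) & p$probe == pr & p$label == "C" &
                    seq_len(n) < event_row)
    sum(p$duration[rows])
  }
  setv("tC > 1E/1Pr", if (length(e_rows)) c_time_before(e_rows[1]) else NA)
  setv("tC > 1sE2/1Pr",
       if (length(se2_rows)) c_time_before(se2_rows[1]) else NA)
  # per-probe C time before the first E of each probe containing E
  probes_with_E <- unique(p$probe[e_rows])
  ctimes <- vapply(probes_with_E, function(pr) {
    first_in_probe <- min(e_rows[p$probe[e_rows] == pr])
    c_time_before(first_in_probe)
  }, numeric(1))
  setv("atC > 1E/Pr", mean0(ctimes))
  setv("mntC > 1E/Pr", min0(ctimes))
  setv("s_np.1E",
       if (length(e_rows))
         sum(p$duration[p$label == "Np" & seq_len(n) < e_rows[1]])
       else NA)

  # --- sequential counts -------------------------------------------------
  # probes strictly before the probe containing the first occurrence
  before_counts <- function(rows, acr, brief_acr = NULL) {
    if (!length(rows)) {
      setv(acr, npr, "set-total-count")
      if (!is.null(brief_acr)) setv(brief_acr, sum(probes$brief),
                                    "set-total-count")
    } else {
      pr <- p$probe[rows[1]]
      setv(acr, sum(probes$probe < pr))
      if (!is.null(brief_acr))
        setv(brief_acr, sum(probes$brief[probes$probe < pr]))
    }
  }
  before_counts(e_rows, "n_Pr > 1E", "n_brPr > 1E")
  before_counts(e2_rows, "n_Pr > 1E2")
  before_counts(se2_rows, "n_Pr > 1sE2")
  setv("n_E2 > 1sE2",
       if (length(se2_rows)) sum(e2_rows < se2_rows[1])
       else length(e2_rows),
       if (!length(se2_rows)) "set-total-count" else NA_character_)
  after_counts <- function(rows, acr, brief = FALSE) {
    if (!length(rows)) { setv(acr, NA); return() }
    pr <- p$probe[rows[1]]
    keep <- probes$probe > pr
    setv(acr, if (brief) sum(probes$brief[keep]) else sum(keep))
  }
  after_counts(e_rows, "n_Pr.after1E")
  after_counts(e_rows, "n_bPr.after1E", brief = TRUE)
  after_counts(se2_rows, "n_Pr < 1sE2")

  # --- E1 followed by E2 -------------------------------------------------
  nxt <- c(p$label[-1], NA)
  e1_before_e2 <- which(p$label == "E1" & !is.na(nxt) & nxt == "E2")
  setv("d_E1followedbyE2",
       if (length(e1_before_e2)) sum(p$duration[e1_before_e2]) else NA)
  e1_before_se2 <- e1_before_e2[(e1_before_e2 + 1L) %in% se2_rows]
  setv("d_E1followedbysE2",
       if (length(e1_before_se2)) sum(p$duration[e1_before_se2]) else NA)

  # --- potential indices -------------------------------------------------
  s_pr <- if (npr) sum(probes$duration) else 0
  s_c <- sum(p$duration[p$label == "C"])
  s_e1 <- sum(p$duration[p$label == "E1"])
  s_e2 <- sum(p$duration[p$label == "E2"])
  for (w in c("C", "F", "G", "E1", "E2")) {
    sw <- sum(p$duration[p$label == w])
    setv(paste0("%probtimein", w), if (s_pr > 0) 100 * sw / s_pr else NA)
  }
  setv("E2/C_ratio", if (s_c > 0) s_e2 / s_c else NA)
  index_from_first <- function(rows, s_w) {
    if (!length(rows)) return(NA_real_)
    onset <- p$start[rows[1]]
    denom <- end_time - onset
    if (denom <= 0) return(NA_real_)
    100 * s_w / denom
  }
  setv("E2_index", index_from_first(e2_rows, s_e2))
  setv("E1_index",
       if (e1_index == "mirror") index_from_first(rows_of("E1"), s_e1)
       else if (s_e1 + s_e2 > 0) 100 * s_e1 / (s_e1 + s_e2) else NA)
  n_e1 <- length(rows_of("E1"))
  setv("frE1_ratio", if (n_e1 > 0) length(fr_rows) / n_e1 else NA)
  n_e2 <- length(e2_rows)
  setv("%_sE2", if (n_e2 > 0) 100 * length(se2_rows) / n_e2 else NA)
  setv("%Phloem_ph_fail",
       if (nrow(phases)) 100 * sum(!phases$reaches_E2) / nrow(phases) else NA)

  # --- potential drops ---------------------------------------------------
  std <- pdg[pdg$kind == "standard-pd", , drop = FALSE]
  npd <- nrow(std)
  # group-duration statistics; the truncated wave criterion applies at
  # the subphase (label) level, not to group totals
  setv("n_pd", npd)
  setv("s_pd", if (npd) sum(std$total) else 0)
  setv("a_pd", mean0(std$total))
  setv("m_pd", med0(std$total))
  sub_map <- c("pd II-1" = "pd", "pd II-2" = "pdII-2", "pd II-3" = "pdII-3")
  for (s in names(sub_map)) {
    rows <- rows_of(sub_map[[s]])
    nonseq_sub <- dur_of(rows)
    setv(paste0("s_", s), if (length(rows)) sum(nonseq_sub) else 0)
    if (trunc_on && length(rows) && n %in% rows) {
      st <- truncated_wave_stats(nonseq_sub[rows != n], p$duration[n],
                                 TRUE, mean_policy)
      setv(paste0("a_", s), st$a, st$a_flag)
      setv(paste0("m_", s), st$m, st$m_flag)
    } else {
      setv(paste0("a_", s), mean0(nonseq_sub))
      setv(paste0("m_", s), med0(nonseq_sub))
    }
  }
  setv("n_pd/minC", if (s_c > 0) npd / s_c else NA)
  setv("t > 1pd", if (npd) std$start[1] - t0 else total,
       if (!npd) "set-total-duration" else NA_character_)
  first_probe_pds <- if (npr) std[!is.na(std$probe) & std$probe == probes$probe[1], ,
                                  drop = FALSE] else std[0, ]
  setv("t > 1pd/1Pr",
       if (nrow(first_probe_pds))
         first_probe_pds$start[1] - first_probe_start else NA)
  probes_with_pd <- unique(std$probe[!is.na(std$probe)])
  tpd <- vapply(probes_with_pd, function(pr) {
    min(std$start[!is.na(std$probe) & std$probe == pr]) -
      probes$start[probes$probe == pr]
  }, numeric(1))
  setv("at > 1pd/Pr", mean0(tpd))
  setv("m_Pr > 1pd", med0(tpd))
  setv("mnt_1pd/1pd", min0(tpd))
  setv("n_pd/1Pr", if (npr) nrow(first_probe_pds) else NA)
  setv("%_Pr_pd", if (npr) 100 * length(probes_with_pd) / npr else NA)
  before_counts(std$onset_row, "n_Pr > 1pd")
  first5 <- utils::head(std, 5L)
  setv("s_pdII-3/5pd", sum(first5$dur_II3, na.rm = TRUE),
       if (npd > 0 && npd < 5) "fewer-than-5-pds" else NA_character_)

  # --- assemble in registry order ---------------------------------------
  reg <- epg_variable_registry()
  missing_acr <- setdiff(reg$acronym, names(v))
  if (length(missing_acr))
    stop("internal error: registry variables not computed: ",
         paste(missing_acr, collapse = ", "))
  value <- vapply(reg$acronym, function(a) v[[a]], numeric(1))
  flag <- vapply(reg$acronym, function(a) {
    f <- fl[[a]]; if (is.null(f)) NA_character_ else f
  }, character(1))
  missing_reason <- ifelse(!is.na(value), NA_character_,
    ifelse(reg$missing_rule == "undefined-denominator",
           "undefined-denominator",
    ifelse(reg$missing_rule == "waveform-absent", "waveform-absent",
           "rule-applied")))
  # rule flags on non-missing values
  out <- data.frame(acronym = reg$acronym, value = unname(value),
                    missing_reason = unname(missing_reason),
                    flag = unname(flag),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("epg_variables", "data.frame")
  out
}

#' Treatment-level percentage variables
#'
#' Percent of recordings (insects) of a treatment that show at least one
#' E2 period, and at least one sustained E2 period. The experimental
#' unit in EPG work is the individual recording, so these are the only
#' variables pooled across insects.
#'
#' @param recordings List of `epg_recording` objects (one treatment).
#' @param sE2_threshold Sustained-E2 threshold in minutes (strict `>`).
#' @return Data.frame with rows `%_E2/Tr` and `%_sE2/Tr`.
#' @export
treatment_percentages <- function(recordings, sE2_threshold = 10) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  has_e2 <- vapply(recordings, function(r) any(r$periods$label == "E2"),
                   logical(1))
  has_se2 <- vapply(recordings, function(r)
    any(r$periods$label == "E2" & r$periods$duration > sE2_threshold),
    logical(1))
  data.frame(acronym = c("%_E2/Tr", "%_sE2/Tr"),
             value = c(100 * mean(has_e2), 100 * mean(has_se2)),
             n_recordings = length(recordings),
             stringsAsFactors = FALSE)
}

#' @export
print.epg_variables <- function(x, ...) {
  cat("EPG variables:", nrow(x), "registry entries,",
      sum(is.na(x$value)), "missing\n")
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...", nrow(x) - 12, "more rows\n")
  invisible(x)
}
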