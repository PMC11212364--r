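# Marking-guideline rule engine. Rules G1-G11 mirror the published
# waveform-marking guidelines; DUP flags duplicated adjacent labels and
# G4b covers the code-11 waveforms (D / p-pd), whose grammar is not part
# of the printed guideline table and can therefore be disabled.

rule_messages <- c(
  G1  = "The recording always starts with Np",
  G2  = "Np is always followed by C",
  G3  = "E2 is always preceded by E1",
  G4  = "pd waveform is always preceded by C and followed by C or Np",
  G4b = "D / p-pd is always preceded by C",
  G5  = "The subphase sequence after pd (pdII-1) should be II-2, II-3",
  G6  = "F is always preceded by C",
  G7  = "F is always followed by Np or C",
  G8  = "G is always preceded by C",
  G9  = "G is always followed by Np or C",
  G10 = "E1 is always followed by E1e, E2, C, or Np",
  G11 = "The end of each recording must be marked (T, code 99)",
  DUP = "waveform duplication: identical adjacent labels"
)

#' Guideline rule identifiers
#' @return Character vector of all rule ids.
#' @export
guideline_rules <- function() names(rule_messages)

#' Select the enabled marking guidelines
#'
#' Rules G2-G11 and the duplication check are always enforced. G1 (the
#' recording starts with Np) may be disabled for insects already probing
#' at recording start (e.g. whitefly nymphs, mealybugs); G4b (grammar of
#' the code-11 waveforms D and p-pd, not covered by the printed
#' guidelines) may also be disabled.
#'
#' @param g1,g4b Logical; enable the optional rules.
#' @return Character vector of enabled rule ids, class `epg_guidelines`.
#' @export
guideline_set <- function(g1 = TRUE, g4b = TRUE) {
  rules <- guideline_rules()
  if (!g1) rules <- setdiff(rules, "G1")
  if (!g4b) rules <- setdiff(rules, "G4b")
  structure(rules, class = "epg_guidelines")
}

pd_sub <- c("pd", "pdII-2", "pdII-3")

issue_df <- function(rule = character(), row = integer(),
                     previous = character(), current = character()) {
  data.frame(rule = rule, row = as.integer(row), previous = previous,
             current = current,
             message = unname(rule_messages[rule]),
             stringsAsFactors = FALSE)
}

#' Validate a recording against the marking guidelines
#'
#' Scans the period label sequence and reports one issue per violated
#' rule instance. Validation never throws on content; an empty result
#' means the sequence is grammatical. `row` is the 1-based index into the
#' period sequence of the second element of the offending transition
#' (row 1 for G1; the last row for a missing terminal mark, G11). A
#' single bad transition may violate several rules; all are reported.
#'
#' @param recording An `epg_recording`.
#' @param guidelines A [guideline_set()].
#' @return Data.frame of class `epg_issues` with columns `rule`, `row`,
#'   `previous`, `current`, `message`, ordered by row then rule.
#' @export
validate_recording <- function(recording, guidelines = guideline_set()) {
  lab <- recording$periods$label
  n <- length(lab)
  prev <- c(NA_character_, lab[-n])
  iss <- issue_df()
  add <- function(rule, rows) {
    if (!length(rows) || !(rule %in% guidelines)) return()
    iss <<- rbind(iss, issue_df(rep(rule, length(rows)), rows,
                                ifelse(rows > 1, lab[rows - 1], "<start>"),
                                lab[rows]))
  }
  add("G1", if (lab[1] != "Np") 1L else integer())
  add("G2", which(prev == "Np" & lab != "C"))
  add("G3", which(lab == "E2" & (is.na(prev) | prev != "E1")))
  # G4: group onset preceded by C; end of the pd subphase group followed
  # by C or Np (the internal subphase order is G5's business)
  onset <- which(lab == "pd" & (is.na(prev) | !(prev %in% pd_sub)))
  add("G4", onset[is.na(prev[onset]) | prev[onset] != "C"])
  in_group <- lab %in% pd_sub
  group_end <- which(in_group & !c(in_group[-1], FALSE))
  after <- group_end + 1L
  keep <- after <= n & !(lab[pmin(after, n)] %in% c("C", "Np"))
  add("G4", after[keep])
  # G5: II-2 must follow II-1 (pd), II-3 must follow II-2; and a group
  # must not stop short of II-3
  add("G5", which(lab == "pdII-2" & (is.na(prev) | prev != "pd")))
  add("G5", which(lab == "pdII-3" & (is.na(prev) | prev != "pdII-2")))
  # incomplete group; a group cut short by the end of the recording
  # (truncated final period) is not a marking error
  add("G5", group_end[lab[group_end] != "pdII-3" & group_end != n])
  add("G6", which(lab == "F" & (is.na(prev) | prev != "C")))
  add("G7", which(prev == "F" & !(lab %in% c("Np", "C"))))
  add("G8", which(lab == "G" & (is.na(prev) | prev != "C")))
  add("G9", which(prev == "G" & !(lab %in% c("Np", "C"))))
  add("G10", which(prev == "E1" & !(lab %in% c("E1e", "E2", "C", "Np"))))
  add("G11", if (!isTRUE(recording$terminated)) n else integer())
  add("G4b", which(lab %in% c("D", "p-pd") & (is.na(prev) | prev != "C")))
  add("DUP", which(!is.na(prev) & lab == prev))
  iss <- iss[!duplicated(iss[c("rule", "row")]), , drop = FALSE]
  iss <- iss[order(iss$row, iss$rule), , drop = FALSE]
  rownames(iss) <- NULL
  class(iss) <- c("epg_issues", "data.frame")
  iss
}

#' Human-readable validation report for a set of files
#'
#' The headline counts all wrong marks across files; a per-file block
#' lists each issue's row and rule. Files without issues are omitted.
#'
#' @param issues_by_file Named list of `epg_issues` data.frames (names
#'   are file names, in load order).
#' @return Character vector of report lines.
#' @export
error_report <- function(issues_by_file) {
  stopifnot(is.list(issues_by_file))
  total <- sum(vapply(issues_by_file, nrow, integer(1)))
  if (total == 0L)
    return("All files passed sequence validation: 0 wrong marks were detected.")
  out <- sprintf("You must review the sequence: '%d' wrong marks were detected",
                 total)
  for (i in seq_along(issues_by_file)) {
    iss <- issues_by_file[[i]]
    if (!nrow(iss)) next
    out <- c(out, sprintf("File %d: %s (%d issue%s)", i,
                          names(issues_by_file)[i] %||% "<unnamed>",
                          nrow(iss), if (nrow(iss) == 1) "" else "s"))
    out <- c(out, sprintf("  row %d: %s (%s -> %s) %s",
                          iss$row, iss$rule, iss$previous, iss$current,
                          iss$message))
  }
  out
}

#' Export validation issues as a machine-readable CSV
#'
#' @inheritParams error_report
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
issues_csv <- function(issues_by_file, path) {
  rows <- lapply(seq_along(issues_by_file), function(i) {
    iss <- issues_by_file[[i]]
    if (!nrow(iss)) return(NULL)
    cbind(data.frame(file = names(issues_by_file)[i],
                     stringsAsFactors = FALSE),
          iss[, c("row", "rule", "previous", "current")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(file = character(), row = integer(), rule = character(),
                      previous = character(), current = character())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) != 1L || is.na(a) || !nzchar(a)) b else a
}
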