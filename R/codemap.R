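# Waveform code maps: integer annotation codes <-> waveform labels.

#' Waveform labels recognised by the package
#'
#' Canonical label strings used throughout: `"Np"` (non-probing), `"C"`
#' (pathway), `"E1e"` (extracellular salivation), `"E1"` (sieve-element
#' salivation), `"E2"` (phloem ingestion), `"F"` (derailed stylet
#' mechanics), `"G"` (xylem ingestion), `"pd"` (potential-drop subphase
#' II-1, the group onset), `"pdII-2"`, `"pdII-3"`, `"D"` (psyllid first
#' phloem contact), `"p-pd"` (aphid phloem potential drop) and `"T"`
#' (terminal mark).
#'
#' @return Character vector of all label strings.
#' @export
epg_labels <- function() {
  c("Np", "C", "E1e", "E1", "E2", "F", "G",
    "pd", "pdII-2", "pdII-3", "D", "p-pd", "T")
}

#' Construct a waveform code map
#'
#' Maps integer annotation codes to waveform labels. Code 11 is shared by
#' the psyllid waveform D and the aphid phloem potential drop (p-pd); the
#' `code11` mode decides which of the two it denotes for a given dataset.
#' Code 99 is always the terminal mark `"T"`.
#'
#' @param codes Integer vector of annotation codes.
#' @param labels Character vector of waveform labels, same length as
#'   `codes`, drawn from [epg_labels()].
#' @param code11 Either `"p-pd"` (aphids) or `"D"` (psyllids); applied to
#'   code 11 if present.
#' @return An object of class `epg_code_map`.
#' @export
epg_code_map <- function(codes, labels, code11 = c("p-pd", "D")) {
  code11 <- match.arg(code11)
  codes <- as.integer(codes)
  stopifnot(length(codes) == length(labels), !anyNA(codes))
  labels[codes == 11L] <- code11
  if (anyDuplicated(codes))
    stop("code map: duplicated codes", call. = FALSE)
  if (anyDuplicated(labels))
    stop("code map: mapping must be injective over enabled codes", call. = FALSE)
  bad <- setdiff(labels, epg_labels())
  if (length(bad))
    stop("code map: unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!any(codes == 99L) || labels[codes == 99L] != "T")
    stop("code map: code 99 must map to the terminal mark T", call. = FALSE)
  structure(list(codes = codes, labels = labels, code11 = code11),
            class = "epg_code_map")
}

#' Default waveform code map
#'
#' Codes 11 (D or p-pd) and 99 (terminal mark) are fixed by convention;
#' the remaining assignments follow common acquisition-software exports
#' and can be overridden with [epg_code_map()] or a configuration file.
#'
#' @inheritParams epg_code_map
#' @return An `epg_code_map`.
#' @examples
#' default_code_map()
#' default_code_map("D")  # psyllid datasets
#' @export
default_code_map <- function(code11 = c("p-pd", "D")) {
  code11 <- match.arg(code11)
  epg_code_map(
    codes  = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 99L),
    labels = c("Np", "C", "E1e", "E1", "E2", "F", "G",
               "pd", "pdII-2", "pdII-3", "p-pd", "T"),
    code11 = code11
  )
}

#' @export
print.epg_code_map <- function(x, ...) {
  cat("EPG waveform code map (code 11 = ", x$code11, "):\n", sep = "")
  print(stats::setNames(x$labels, x$codes))
  invisible(x)
}

map_code_to_label <- function(code, map) {
  i <- match(as.integer(code), map$codes)
  map$labels[i]
}

map_label_to_code <- function(label, map) {
  i <- match(label, map$labels)
  map$codes[i]
}
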