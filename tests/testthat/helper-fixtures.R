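# Build a recording directly from label/duration vectors (terminal mark
# appended), for hand-constructed test cases.
make_rec <- function(labels, durations, file_name = "fixture.ana",
                     treatment = 1L) {
  stopifnot(length(labels) == length(durations))
  code11 <- if ("D" %in% labels) "D" else "p-pd"
  cm <- default_code_map(code11)
  codes <- cm$codes[match(labels, cm$labels)]
  stopifnot(!anyNA(codes))
  mk <- structure(
    data.frame(code = c(codes, 99L), label = c(labels, "T"),
               time = cumsum(c(0, durations)), stringsAsFactors = FALSE),
    class = c("epg_marks", "data.frame"))
  marks_to_recording(mk, cm, file_name = file_name, treatment = treatment)
}

var_value <- function(vars, acronym) {
  stopifnot(acronym %in% vars$acronym)
  vars$value[vars$acronym == acronym]
}
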