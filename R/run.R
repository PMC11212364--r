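# Batch workflow: configuration, the run pipeline behind the command
# line front end (validate -> compute -> write), and logging. Every
# invocation is stateless: outputs depend only on the inputs and
# options of that run.

#' Read a run configuration file
#'
#' YAML with any of: `code_map` (mapping code -> label), `code11_mode`
#' (`"p-pd"`/`"D"`), `dialect`, `time_unit`, `sE2_threshold`,
#' `brief_threshold`, `truncated_criterion`, `mean_policy`,
#' `transpose`, `missing_token`, `order` (list of acronyms first in the
#' output), `guidelines` (`g1`, `g4b` toggles). Absent fields fall back
#' to package defaults.
#'
#' @param path Path to a YAML configuration file, or `NULL` for all
#'   defaults.
#' @return List of run options, class `epg_config`.
#' @export
read_epg_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(code11_mode = "p-pd", dialect = "stylet",
                   time_unit = "seconds", sE2_threshold = 10,
                   brief_threshold = 3, truncated_criterion = TRUE,
                   mean_policy = "longest-include", transpose = FALSE,
                   missing_token = "", order = NULL,
                   guidelines = list(g1 = TRUE, g4b = TRUE))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!is.null(cfg$code_map)) {
    codes <- as.integer(names(cfg$code_map))
    cfg$map <- epg_code_map(codes, unlist(cfg$code_map, use.names = FALSE),
                            code11 = cfg$code11_mode)
  } else cfg$map <- default_code_map(cfg$code11_mode)
  class(cfg) <- "epg_config"
  cfg
}

#' Run the full calculation pipeline on a batch of files
#'
#' Parses all files, validates every sequence, and (when all are valid,
#' or `force = TRUE`) computes the variable registry per recording and
#' writes the results table, the per-treatment percentages, the error
#' report and a run log. Exit status: 0 success, 1 usage error, 2 parse
#' error, 3 validation failure.
#'
#' @param files Character vector of annotation files, or a data.frame
#'   manifest with columns `file` and `treatment`.
#' @param treatment Integer treatment code applied to all `files` when
#'   no manifest is given.
#' @param out_dir Output directory (created if needed).
#' @param config An `epg_config` from [read_epg_config()].
#' @param force Compute even when validation issues exist.
#' @return Invisibly, a list: `status`, `results` (named list of
#'   variable tables), `issues`, `treatment_summary`, `paths` of the
#'   written artifacts.
#' @export
run_epg <- function(files, treatment = 1L, out_dir = ".",
                    config = read_epg_config(), force = FALSE) {
  if (is.data.frame(files)) {
    manifest <- files
    stopifnot(all(c("file", "treatment") %in% names(manifest)))
  } else {
    if (!length(files)) {
      message("usage error: no input files")
      return(invisible(list(status = 1L)))
    }
    manifest <- data.frame(file = files, treatment = treatment,
                           stringsAsFactors = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("run: %d file(s), dialect=%s, code11=%s, truncated_criterion=%s",
                         nrow(manifest), config$dialect, config$code11_mode,
                         config$truncated_criterion))
  recs <- list(); parse_errors <- character(0)
  for (i in seq_len(nrow(manifest))) {
    r <- tryCatch(read_epg_file(manifest$file[i], config$dialect, config$map,
                                config$time_unit,
                                treatment = manifest$treatment[i]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      parse_errors <- c(parse_errors,
                        sprintf("file %d (%s): %s", i,
                                basename(manifest$file[i]),
                                conditionMessage(r)))
    } else recs[[basename(manifest$file[i])]] <- r
  }
  log_lines <- c(log_lines, parse_errors)
  if (length(parse_errors)) {
    writeLines(c(log_lines, "status: parse error"),
               file.path(out_dir, "run.log"))
    message(paste(parse_errors, collapse = "\n"))
    return(invisible(list(status = 2L, parse_errors = parse_errors)))
  }
  gl <- guideline_set(g1 = isTRUE(config$guidelines$g1),
                      g4b = isTRUE(config$guidelines$g4b))
  issues <- lapply(recs, validate_recording, guidelines = gl)
  report <- error_report(issues)
  writeLines(report, file.path(out_dir, "validation_report.txt"))
  issues_csv(issues, file.path(out_dir, "validation_issues.csv"))
  n_issues <- sum(vapply(issues, nrow, integer(1)))
  log_lines <- c(log_lines, sprintf("validation: %d issue(s)", n_issues))
  if (n_issues > 0 && !force) {
    writeLines(c(log_lines, "status: validation failure"),
               file.path(out_dir, "run.log"))
    message(report[1])
    return(invisible(list(status = 3L, issues = issues,
                          paths = file.path(out_dir,
                            c("validation_report.txt",
                              "validation_issues.csv")))))
  }
  results <- lapply(recs, compute_variables,
                    truncated_criterion = config$truncated_criterion,
                    mean_policy = config$mean_policy,
                    sE2_threshold = config$sE2_threshold,
                    brief_threshold = config$brief_threshold,
                    guidelines = gl, force = force)
  paths <- file.path(out_dir, "results.csv")
  write_results(results, paths, transpose = FALSE, order = config$order,
                missing = if (identical(config$missing_token, "NA")) "NA"
                          else "")
  if (isTRUE(config$transpose)) {
    pt <- file.path(out_dir, "results_t.csv")
    write_results(results, pt, transpose = TRUE, order = config$order,
                  missing = if (identical(config$missing_token, "NA")) "NA"
                            else "")
    paths <- c(paths, pt)
  }
  tr_summary <- do.call(rbind, lapply(split(seq_along(recs),
      vapply(recs, function(r) r$treatment, numeric(1))),
    function(ix) {
      tp <- treatment_percentages(recs[ix], config$sE2_threshold)
      cbind(treatment = recs[[ix[1]]]$treatment, tp)
    }))
  utils::write.csv(tr_summary, file.path(out_dir, "treatment_summary.csv"),
                   row.names = FALSE)
  paths <- c(paths, file.path(out_dir, "treatment_summary.csv"))
  log_lines <- c(log_lines,
                 sprintf("computed %d variables for %d recording(s)",
                         nrow(results[[1]]), length(results)),
                 "status: ok")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(status = 0L, results = results, issues = issues,
                 treatment_summary = tr_summary,
                 paths = c(paths, file.path(out_dir, "run.log"))))
}
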