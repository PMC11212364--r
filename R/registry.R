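# The declarative registry of the 127 per-recording variables. Keeping
# the registry data-driven (one table, not one function per variable)
# means a contested definition can be corrected in a single place.

reg_row <- function(acronym, description, category, shared,
                    missing_rule = "missing") {
  data.frame(acronym = acronym, description = description,
             category = category, shared_with_sarria = shared,
             missing_rule = missing_rule, stringsAsFactors = FALSE)
}

# n/a/m/s (+ mx) block for one waveform class
nams_block <- function(suffix, noun, shared = c(n = FALSE, a = FALSE,
                                                m = FALSE, s = FALSE),
                       mx = FALSE, mx_shared = FALSE) {
  out <- rbind(
    reg_row(paste0("n_", suffix), paste("Number of periods of", noun),
            "nonsequential", shared[["n"]], "zero"),
    reg_row(paste0("a_", suffix), paste("Average duration of", noun, "periods"),
            "nonsequential", shared[["a"]], "waveform-absent"),
    reg_row(paste0("m_", suffix), paste("Median duration of", noun, "periods"),
            "nonsequential", shared[["m"]], "waveform-absent"),
    reg_row(paste0("s_", suffix), paste("Sum duration of all periods of", noun),
            "nonsequential", shared[["s"]], "zero"))
  if (mx)
    out <- rbind(out, reg_row(paste0("mx_", suffix),
                              paste("Longest period of", noun),
                              "nonsequential", mx_shared, "waveform-absent"))
  out
}

sh <- function(n = FALSE, a = FALSE, m = FALSE, s = FALSE)
  c(n = n, a = a, m = m, s = s)

#' The standardized per-recording variable registry
#'
#' Returns the declarative table of the 127 feeding-behavior variables
#' computed per recording: acronym, descriptive name, category, whether
#' the variable is also calculated by the Sarria workbook (53 are), and
#' the rule applied when the reference waveform or event is absent
#' (`"zero"`, `"missing"`, `"set-total-duration"`,
#' `"set-first-probe-to-end"`, `"set-total-count"`,
#' `"undefined-denominator"`). The two treatment-level percentages (%
#' insects with E2 / with sustained E2) are computed across recordings
#' by [treatment_percentages()] and are not part of this per-recording
#' registry.
#'
#' @return Data.frame with 127 rows and columns `acronym`,
#'   `description`, `category`, `shared_with_sarria`, `missing_rule`.
#' @examples
#' reg <- epg_variable_registry()
#' nrow(reg)                        # 127
#' sum(reg$shared_with_sarria)      # 53
#' @export
epg_variable_registry <- function() {
  reg <- rbind(
    # --- non-probing ---
    nams_block("Np", "non-probing (Np)", sh(TRUE, TRUE, FALSE, TRUE),
               mx = TRUE),
    reg_row("d_2Np", "Duration of the second non-probe period",
            "sequential-duration", TRUE),
    # --- probes ---
    nams_block("Pr", "probes (Pr)", sh(TRUE, FALSE, FALSE, TRUE)),
    reg_row("d_1Pr", "Duration of 1st probe", "sequential-duration", TRUE),
    reg_row("n_bPr", "Number of short probes (< 3 min)", "nonsequential",
            TRUE, "zero"),
    # --- pathway, xylem, derailment, extracellular salivation ---
    nams_block("C", "C", sh(TRUE, TRUE, FALSE, TRUE)),
    nams_block("F", "F", sh(TRUE, TRUE, FALSE, TRUE)),
    nams_block("G", "G", sh(TRUE, TRUE, FALSE, TRUE)),
    nams_block("E1e", "E1e", sh(TRUE, TRUE, FALSE, TRUE)),
    # --- psyllid D ---
    nams_block("D", "D", sh()),
    reg_row("n_sgD", "Number of periods of single D", "nonsequential",
            FALSE, "zero"),
    # --- phloem phase structure ---
    reg_row("d_1st_E", "Duration of the first phloem phase",
            "sequential-duration", TRUE),
    nams_block("sgE1", "single E1 (sgE1)", sh(TRUE, FALSE, FALSE, TRUE),
               mx = TRUE),
    nams_block("frE1", "fractionated E1 (frE1)", sh(), mx = TRUE),
    nams_block("E1", "E1", sh(TRUE, TRUE, FALSE, TRUE), mx = TRUE),
    reg_row("a_1st E1_followed_E2",
            "Mean duration of initial E1 in phloem phase",
            "sequential-duration", FALSE),
    nams_block("E12", "E12 (phloem phase reaching E2)", sh(), mx = TRUE),
    nams_block("E2", "E2", sh(TRUE, TRUE, FALSE, TRUE)),
    reg_row("a_s_E2/phloem_ph", "Mean duration of E2 per phloem phase",
            "sequential-duration", FALSE),
    reg_row("mx_E2", "Longest period of E2", "nonsequential", TRUE,
            "waveform-absent"),
    reg_row("d_1st_E2", "Duration of the 1st E2 in the recording",
            "sequential-duration", TRUE),
    nams_block("sE2", "sustained E2 (sE2, > 10 min)", sh(n = TRUE)),
    # --- sequential times ---
    reg_row("t > 1Pr", "Time to 1st probe from start of recording",
            "sequential-time", TRUE, "set-total-duration"),
    reg_row("t > 1E", "Time to 1st E from start of 1st probe",
            "sequential-time", TRUE, "set-first-probe-to-end"),
    reg_row("t > 1E12", "Time to the 1st E12 from start of 1st probe",
            "sequential-time", FALSE, "set-first-probe-to-end"),
    reg_row("t > 1E2", "Time to the 1st E2 from start of 1st probe",
            "sequential-time", TRUE, "set-first-probe-to-end"),
    reg_row("t > 1sE2", "Time to 1st sE2 from start of 1st probe",
            "sequential-time", FALSE, "set-first-probe-to-end"),
    reg_row("tPr > 1E/1Pr", "Time from the beginning of that probe to 1st E",
            "sequential-time", TRUE),
    reg_row("tPr > 1E2/1Pr", "Time from the beginning of that probe to 1st E2",
            "sequential-time", TRUE),
    reg_row("tPr > 1sE2/1Pr",
            "Time from the beginning of that probe to 1st sE2",
            "sequential-time", TRUE),
    reg_row("tC > 1E/1Pr", "Time in C to 1st E in 1st probe with E",
            "sequential-duration", FALSE),
    reg_row("tC > 1sE2/1Pr", "Time in C to 1st sE2 in 1st probe with sE2",
            "sequential-duration", FALSE),
    reg_row("atC > 1E/Pr", "Average time in C to 1st E in probes with E",
            "sequential-duration", FALSE),
    reg_row("mntC > 1E/Pr", "Minimum time in C to 1st E in probes with E",
            "sequential-duration", TRUE),
    reg_row("s_np.1E",
            "Total duration of non-probing before the 1st E in the recording",
            "sequential-duration", TRUE),
    # --- sequential counts ---
    reg_row("n_Pr > 1E", "Number of probes before 1st E in the recording",
            "sequential-count", TRUE, "set-total-count"),
    reg_row("n_brPr > 1E",
            "Number of brief probes (< 3 min) before 1st E in the recording",
            "sequential-count", TRUE, "set-total-count"),
    reg_row("n_Pr > 1E2", "Number of probes before 1st E2 in the recording",
            "sequential-count", FALSE, "set-total-count"),
    reg_row("n_Pr > 1sE2", "Number of probes before 1st sE2 in the recording",
            "sequential-count", FALSE, "set-total-count"),
    reg_row("n_E2 > 1sE2", "Number of E2 before 1st sE2 in the recording",
            "sequential-count", FALSE, "set-total-count"),
    reg_row("n_Pr.after1E", "Number of probes after 1st E in the recording",
            "sequential-count", TRUE),
    reg_row("n_bPr.after1E",
            "Number of brief probes (< 3 min) after 1st E in the recording",
            "sequential-count", FALSE),
    reg_row("n_Pr < 1sE2", "Number of probes after 1st sE2 in the recording",
            "sequential-count", FALSE),
    # --- sequential durations around phloem events ---
    reg_row("d_E1followedbyE2", "Duration of E1 followed by E2",
            "sequential-duration", FALSE),
    reg_row("d_E1followedbysE2", "Duration of E1 followed by sE2",
            "sequential-duration", FALSE),
    # --- potential indices ---
    reg_row("E2/C_ratio", "E2/C ratio", "potential-index", FALSE,
            "undefined-denominator"),
    reg_row("E1_index", "E1 index", "potential-index", FALSE),
    reg_row("frE1_ratio", "E fractioning ratio", "potential-index", FALSE,
            "undefined-denominator"),
    reg_row("E2_index", "E2 index", "potential-index", TRUE),
    reg_row("%probtimeinC", "% of probing time spent in C",
            "potential-index", TRUE, "undefined-denominator"),
    reg_row("%probtimeinF", "% of probing time spent in F",
            "potential-index", TRUE, "undefined-denominator"),
    reg_row("%probtimeinG", "% of probing time spent in G",
            "potential-index", TRUE, "undefined-denominator"),
    reg_row("%probtimeinE1", "% of probing time spent in E1",
            "potential-index", TRUE, "undefined-denominator"),
    reg_row("%probtimeinE2", "% of probing time spent in E2",
            "potential-index", TRUE, "undefined-denominator"),
    reg_row("%_sE2", "% of E2s that are sustained E2s (> 10 min)",
            "potential-index", TRUE),
    reg_row("%Phloem_ph_fail",
            "% of phloem phases that fail to achieve ingestion",
            "potential-index", FALSE),
    # --- potential drops ---
    reg_row("n_pd", "Number of pds", "pd", TRUE, "zero"),
    reg_row("n_pd/minC", "Number of pds per minute of pathway phase",
            "pd", FALSE, "undefined-denominator"),
    reg_row("a_pd", "Average duration of pds", "pd", TRUE, "waveform-absent"),
    reg_row("m_pd", "Median duration of pds", "pd", FALSE, "waveform-absent"),
    reg_row("s_pd", "Sum duration of all pds", "pd", TRUE, "zero"),
    reg_row("a_pd II-1", "Average pd II-1 duration", "pd", FALSE,
            "waveform-absent"),
    reg_row("m_pd II-1", "Median pd II-1 duration", "pd", FALSE,
            "waveform-absent"),
    reg_row("s_pd II-1", "Sum of time pd II-1 periods", "pd", FALSE, "zero"),
    reg_row("a_pd II-2", "Average pd II-2 duration", "pd", FALSE,
            "waveform-absent"),
    reg_row("m_pd II-2", "Median pd II-2 duration", "pd", FALSE,
            "waveform-absent"),
    reg_row("s_pd II-2", "Sum of time pd II-2 periods", "pd", FALSE, "zero"),
    reg_row("a_pd II-3", "Average pd II-3 duration", "pd", FALSE,
            "waveform-absent"),
    reg_row("m_pd II-3", "Median pd II-3 duration", "pd", FALSE,
            "waveform-absent"),
    reg_row("s_pd II-3", "Sum of time pd II-3 periods", "pd", FALSE, "zero"),
    reg_row("t > 1pd", "Time to 1st pd", "pd", FALSE, "set-total-duration"),
    reg_row("t > 1pd/1Pr", "Time to 1st pd in 1st probe", "pd", FALSE),
    reg_row("at > 1pd/Pr",
            "Average time to 1st pd in a probe for all probes with pds",
            "pd", FALSE),
    reg_row("m_Pr > 1pd",
            "Median time to 1st pd in a probe for all probes with pds",
            "pd", FALSE),
    reg_row("mnt_1pd/1pd",
            "Minimum time to 1st pd in a probe among all probes with pds",
            "pd", FALSE),
    reg_row("n_pd/1Pr", "Number of pds in 1st probe", "pd", FALSE),
    reg_row("%_Pr_pd", "% probes with at least one pd", "pd", FALSE,
            "undefined-denominator"),
    reg_row("n_Pr > 1pd", "Number of probes before 1st pd", "pd", FALSE,
            "set-total-count"),
    reg_row("s_pdII-3/5pd", "Sum duration of II-3 in 1st 5 pds", "pd",
            FALSE, "zero"),
    # --- phloem potential drops (aphid code-11 mode) ---
    nams_block("p-pd", "phloem pd (p-pd)", sh())
  )
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 127L, !anyDuplicated(reg$acronym),
            sum(reg$shared_with_sarria) == 53L)
  reg
}

#' Treatment-level variable registry
#'
#' The two percentages computed across the recordings of a treatment
#' rather than per recording.
#'
#' @return Data.frame with 2 rows (`%_E2/Tr`, `%_sE2/Tr`).
#' @export
treatment_variable_registry <- function() {
  rbind(reg_row("%_E2/Tr", "% insects with E2", "treatment-level", FALSE),
        reg_row("%_sE2/Tr", "% insects with sE2", "treatment-level", FALSE))
}
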