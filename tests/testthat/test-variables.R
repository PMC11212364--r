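# The variable registry and per-recording computation.

test_that("the registry is complete, unique and correctly partitioned", {
  reg <- epg_variable_registry()
  expect_equal(nrow(reg), 127L)
  expect_false(anyDuplicated(reg$acronym) > 0)
  expect_equal(sum(reg$shared_with_sarria), 53L)
  expect_equal(sum(!reg$shared_with_sarria), 74L)
  expect_equal(nrow(treatment_variable_registry()), 2L)
})

test_that("non-sequential statistics match hand arithmetic", {
  # Np durations 10, 5, 30 (criterion off so the final Np is included
  # as observed)
  rec <- make_rec(c("Np", "C", "Np", "C", "Np"), c(10, 7, 5, 3, 30))
  v <- compute_variables(rec, truncated_criterion = FALSE)
  expect_equal(var_value(v, "n_Np"), 3)
  expect_equal(var_value(v, "a_Np"), 15)
  expect_equal(var_value(v, "m_Np"), 10)
  expect_equal(var_value(v, "s_Np"), 45)
  expect_equal(var_value(v, "mx_Np"), 30)
  expect_equal(var_value(v, "d_2Np"), 5)
  # absent waveform: zero count and sum, missing mean/median
  expect_equal(var_value(v, "n_G"), 0)
  expect_equal(var_value(v, "s_G"), 0)
  expect_true(is.na(var_value(v, "a_G")))
  expect_true(is.na(var_value(v, "m_G")))
  expect_equal(v$missing_reason[v$acronym == "a_G"], "waveform-absent")
  # singleton E2 of 12.5 min (> 10 so also sustained)
  rec2 <- make_rec(c("Np", "C", "E1", "E2", "C", "Np"),
                   c(5, 5, 1, 12.5, 5, 451))
  v2 <- compute_variables(rec2, truncated_criterion = FALSE)
  for (a in c("a_E2", "m_E2", "s_E2", "mx_E2", "d_1st_E2"))
    expect_equal(var_value(v2, a), 12.5)
  expect_equal(var_value(v2, "n_E2"), 1)
  expect_equal(var_value(v2, "n_sE2"), 1)
})

test_that("sequential times use the three starting points", {
  # first probe at 7 min; E1 at 30 min within the second probe
  rec <- make_rec(c("Np", "C", "Np", "C", "E1", "E2", "C", "Np"),
                  c(7, 3, 5, 15, 2, 40, 5, 403))
  v <- compute_variables(rec, truncated_criterion = FALSE)
  expect_equal(var_value(v, "t > 1Pr"), 7)
  expect_equal(var_value(v, "t > 1E"), 23)       # 30 - 7
  expect_equal(var_value(v, "t > 1E2"), 25)
  expect_equal(var_value(v, "tPr > 1E/1Pr"), 15) # within its probe
  expect_equal(var_value(v, "tC > 1E/1Pr"), 15)
  expect_equal(var_value(v, "s_np.1E"), 12)      # 7 + 5
  expect_equal(var_value(v, "n_Pr > 1E"), 1)
  expect_equal(var_value(v, "n_Pr.after1E"), 0)
})

test_that("missing-data conventions for absent phloem activity", {
  # 6 probes, 2 brief, no E anywhere; first probe at 7 min, total 480
  lab <- c("Np", "C", "Np", "C", "Np", "C", "Np", "C", "Np", "C",
           "Np", "C")
  durs <- c(7, 2, 10, 50, 10, 2.5, 10, 60, 10, 100, 10, 208.5)
  rec <- make_rec(lab, durs)
  v <- compute_variables(rec, truncated_criterion = FALSE)
  expect_equal(var_value(v, "t > 1Pr"), 7)
  # recording-start-based phloem times: from first probe start to end
  expect_equal(var_value(v, "t > 1E"), 473)
  expect_equal(v$flag[v$acronym == "t > 1E"], "set-first-probe-to-end")
  # within-probe times: missing
  expect_true(is.na(var_value(v, "tPr > 1E/1Pr")))
  # before-counts: total counts
  expect_equal(var_value(v, "n_Pr > 1E"), 6)
  expect_equal(var_value(v, "n_brPr > 1E"), 2)
  # after-counts and sequential durations: missing
  expect_true(is.na(var_value(v, "n_Pr.after1E")))
  expect_true(is.na(var_value(v, "s_np.1E")))
  expect_true(is.na(var_value(v, "d_1st_E")))
})

test_that("potential indices follow their defining ratios", {
  # one probe: C 100, E1 4, E2 296 -> s_Pr 400, plus Np tail
  rec <- make_rec(c("Np", "C", "E1", "E2", "Np"), c(10, 100, 4, 296, 70))
  v <- compute_variables(rec, truncated_criterion = FALSE)
  expect_equal(var_value(v, "%probtimeinC"), 25)
  expect_equal(var_value(v, "%probtimeinE2"), 100 * 296 / 400)
  expect_equal(var_value(v, "E2/C_ratio"), 2.96)
  expect_equal(var_value(v, "%_sE2"), 100)
  expect_equal(var_value(v, "%Phloem_ph_fail"), 0)
  # E2 index: first E2 onset at 400 of 480 min, 60 min of E2 after it
  rec2 <- make_rec(c("Np", "C", "E1", "E2", "E1", "E2", "C"),
                   c(5, 394, 1, 30, 10, 30, 10))
  v2 <- compute_variables(rec2, truncated_criterion = FALSE)
  expect_equal(var_value(v2, "E2_index"), 75)   # 100 * 60 / 80
  # 1 of 3 phloem phases fails to reach ingestion
  rec3 <- make_rec(c("Np", "C", "E1", "E2", "C", "E1", "C", "E1", "E2",
                     "Np"),
                   c(5, 5, 1, 30, 5, 2, 5, 1, 30, 396))
  v3 <- compute_variables(rec3, truncated_criterion = FALSE)
  expect_equal(var_value(v3, "%Phloem_ph_fail"), 100 / 3)
  expect_equal(var_value(v3, "n_sgE1"), 1)
  expect_equal(var_value(v3, "n_E12"), 2)
})

test_that("pd variables: rates, first-probe times, first-five II-3 sum", {
  lab <- c("Np", "C", "pd", "pdII-2", "pdII-3", "C", "pd", "pdII-2",
           "pdII-3", "C", "Np", "C", "Np")
  durs <- c(5, 1, .05, .03, .02, 1, .04, .02, .01, 1.83, 5, 4, 462)
  rec <- make_rec(lab, durs)
  v <- compute_variables(rec, truncated_criterion = FALSE)
  expect_equal(var_value(v, "n_pd"), 2)
  expect_equal(var_value(v, "s_pd"), 0.17)
  expect_equal(var_value(v, "a_pd"), 0.085)
  expect_equal(var_value(v, "s_pd II-3"), 0.03)
  expect_equal(var_value(v, "s_pdII-3/5pd"), 0.03)
  expect_equal(v$flag[v$acronym == "s_pdII-3/5pd"], "fewer-than-5-pds")
  expect_equal(var_value(v, "t > 1pd"), 6)
  expect_equal(var_value(v, "t > 1pd/1Pr"), 1)
  expect_equal(var_value(v, "mnt_1pd/1pd"), 1)
  expect_equal(var_value(v, "n_pd/1Pr"), 2)
  expect_equal(var_value(v, "%_Pr_pd"), 50)    # 1 of 2 probes
  s_C <- sum(durs[lab == "C"])
  expect_equal(var_value(v, "n_pd/minC"), 2 / s_C)
  expect_equal(var_value(v, "n_Pr > 1pd"), 0)
})

test_that("compute_variables is complete, deterministic and gated", {
  g <- generate_recording(generator_profile(ensure_all = TRUE), seed = 3)
  v1 <- compute_variables(g$recording)
  v2 <- compute_variables(g$recording)
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 127L)
  expect_setequal(v1$acronym, epg_variable_registry()$acronym)
  reg <- epg_variable_registry()
  expect_equal(sum(v1$acronym %in% reg$acronym[reg$shared_with_sarria]), 53L)
  # values and missing reasons are mutually exclusive
  expect_true(all(is.na(v1$value) != is.na(v1$missing_reason)))
  # validation gate
  bad <- make_rec(c("Np", "E1", "C", "Np"), c(5, 5, 5, 465))
  expect_error(compute_variables(bad), "validation failed")
  expect_s3_class(compute_variables(bad, force = TRUE), "epg_variables")
})

test_that("percentages stay in [0,100] and durations within the recording", {
  for (s in 1:5) {
    rec <- generate_recording(generator_profile(), seed = 200 + s)$recording
    v <- compute_variables(rec)
    pct <- v$value[grepl("^%", v$acronym)]
    expect_true(all(pct >= 0 & pct <= 100, na.rm = TRUE))
    durs <- v$value[grepl("^(s_|a_|m_|mx_|d_|t )", v$acronym)]
    expect_true(all(durs >= 0 & durs <= rec$total_duration + 1e-9,
                    na.rm = TRUE))
  }
})

test_that("treatment percentages count insects with E2 and sustained E2", {
  with_e2 <- make_rec(c("Np", "C", "E1", "E2", "Np"), c(5, 5, 1, 30, 439))
  no_e2 <- make_rec(c("Np", "C", "Np"), c(5, 5, 470))
  short_e2 <- make_rec(c("Np", "C", "E1", "E2", "C", "Np"),
                       c(5, 5, 1, 4, 5, 460))
  tp <- treatment_percentages(list(with_e2, with_e2, with_e2, short_e2,
                                   no_e2))
  expect_equal(tp$value[tp$acronym == "%_E2/Tr"], 80)
  expect_equal(tp$value[tp$acronym == "%_sE2/Tr"], 60)
  tp0 <- treatment_percentages(list(no_e2, no_e2))
  expect_equal(tp0$value, c(0, 0))
  tp1 <- treatment_percentages(list(with_e2))
  expect_equal(tp1$value[1], 100)
})
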