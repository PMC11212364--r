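# Probes, pd groups, phloem phases, derived period classes.

test_that("probes are maximal non-Np runs with brief flags", {
  r <- make_rec(c("Np", "C", "Np", "C", "E1", "E2", "Np"),
                c(5, 2.9, 5, 20, 40, 60, 347.1))
  pr <- find_probes(r)
  expect_equal(nrow(pr), 2L)
  expect_equal(pr$n_periods, c(1L, 3L))
  expect_equal(pr$duration, c(2.9, 120))
  expect_equal(pr$brief, c(TRUE, FALSE))   # strict < 3 min
  # boundary: exactly 3 min is not brief
  r3 <- make_rec(c("Np", "C", "Np"), c(5, 3, 472))
  expect_false(find_probes(r3)$brief)
  # no probes at all
  expect_equal(nrow(find_probes(make_rec("Np", 480))), 0L)
})

test_that("pd subphase groups are assembled from the period triplet", {
  r <- make_rec(c("Np", "C", "pd", "pdII-2", "pdII-3", "C", "Np"),
                c(5, 5, 0.05, 0.03, 0.02, 5, 464.9))
  g <- find_pd_groups(r)
  expect_equal(nrow(g), 1L)
  expect_equal(g$dur_II1, 0.05)
  expect_equal(g$dur_II2, 0.03)
  expect_equal(g$dur_II3, 0.02)
  expect_equal(g$total, 0.10)
  expect_true(g$complete)
  expect_equal(g$kind, "standard-pd")
  # p-pd periods form their own single-period groups
  r2 <- make_rec(c("Np", "C", "p-pd", "C", "Np"), c(5, 5, 0.08, 5, 464.9))
  g2 <- find_pd_groups(r2)
  expect_equal(g2$kind, "p-pd")
  expect_equal(g2$total, 0.08)
  # several groups
  lab <- c("Np", rep(c("C", "pd", "pdII-2", "pdII-3"), 5), "C", "Np")
  r5 <- make_rec(lab, c(5, rep(c(1, .05, .03, .02), 5), 1, 400))
  expect_equal(sum(find_pd_groups(r5)$kind == "standard-pd"), 5L)
})

test_that("phloem phases are maximal E1/E2 runs that never span probes", {
  r <- make_rec(c("Np", "C", "E1", "E2", "E1", "E2", "C", "Np"),
                c(5, 5, 2, 30, 1, 20, 5, 412))
  ph <- find_phloem_phases(r)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$n_periods, 4L)
  expect_true(ph$reaches_E2)
  expect_equal(ph$duration, 53)
  r2 <- make_rec(c("Np", "C", "E1", "C", "E1", "E2", "Np"),
                 c(5, 5, 2, 5, 3, 30, 430))
  ph2 <- find_phloem_phases(r2)
  expect_equal(ph2$reaches_E2, c(FALSE, TRUE))
  expect_equal(nrow(find_phloem_phases(make_rec(c("Np", "C", "Np"),
                                                c(5, 5, 470)))), 0L)
})

test_that("derived period classes follow strict thresholds and neighbours", {
  r <- make_rec(c("Np", "C", "E1", "E2", "E1", "E2", "C",
                  "E1", "C", "E2"),
                c(5, 5, 2, 9.9, 1, 10.1, 5, 3, 5, 200))
  # last E2 invalid grammar-wise (C before E2) but classification is
  # grammar-agnostic; use only the flags of interest
  tags <- classify_periods(r)
  expect_equal(which(tags$sE2), c(6L, 10L))           # > 10 strict
  expect_equal(which(tags$first_E1_E2), 3L)
  expect_equal(which(tags$frE1), 5L)
  r2 <- make_rec(c("Np", "C", "E1", "C", "Np"), c(5, 5, 3, 5, 462))
  expect_equal(which(classify_periods(r2)$sgE1), 3L)
  # frE1 one-sided option
  r3 <- make_rec(c("Np", "C", "E1", "E2", "E1", "C", "Np"),
                 c(5, 5, 2, 30, 4, 5, 429))
  expect_false(any(classify_periods(r3)$frE1))
  expect_equal(which(classify_periods(r3, frE1_both_sides = FALSE)$frE1), 5L)
  # single D: not followed by E1
  r4 <- make_rec(c("Np", "C", "D", "C", "D", "E1", "E2", "Np"),
                 c(5, 5, 8, 5, 8, 2, 40, 407))
  expect_equal(which(classify_periods(r4)$sgD), 3L)
})

test_that("segmentation invariants hold on generated recordings", {
  for (s in 1:10) {
    rec <- generate_recording(generator_profile(), seed = 100 + s)$recording
    pr <- find_probes(rec)
    np_total <- sum(rec$periods$duration[rec$periods$label == "Np"])
    expect_equal(sum(pr$duration) + np_total, rec$total_duration)
    ph <- find_phloem_phases(rec)
    if (nrow(ph)) {
      # every phase lies within one probe
      expect_true(all(!is.na(ph$probe)))
      same <- mapply(function(a, b)
        length(unique(rec$periods$probe[a:b])) == 1L,
        ph$first_row, ph$last_row)
      expect_true(all(same))
    }
    tags <- classify_periods(rec, ph)
    expect_false(any(tags$sgE1 & tags$frE1))
    # phases without E2 are exactly the sgE1 phases
    expect_equal(sum(!ph$reaches_E2) + sum(ph$reaches_E2), nrow(ph))
    expect_equal(sum(tags$sgE1), sum(!ph$reaches_E2))
  }
})
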