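# The marking-guideline rule engine.

test_that("classic mis-markings are caught with rule and row", {
  # Np followed by E1 breaks the Np->C rule
  r <- make_rec(c("Np", "E1", "C", "Np"), c(5, 5, 5, 465))
  iss <- validate_recording(r)
  expect_true(any(iss$rule == "G2" & iss$row == 2))
  expect_equal(iss$previous[iss$rule == "G2"], "Np")
  expect_equal(iss$current[iss$rule == "G2"], "E1")
  # Np followed by another Np is a duplication error
  r2 <- make_rec(c("Np", "C", "Np", "Np"), c(5, 5, 5, 465))
  iss2 <- validate_recording(r2)
  expect_true(any(iss2$rule == "DUP" & iss2$row == 4))
})

test_that("a grammatical sequence yields no issues", {
  r <- make_rec(c("Np", "C", "pd", "pdII-2", "pdII-3", "C", "Np"),
                c(5, 5, 0.05, 0.03, 0.02, 5, 464.9))
  expect_equal(nrow(validate_recording(r)), 0L)
})

test_that("the first-label rule can be disabled for probing starts", {
  r <- make_rec(c("C", "Np"), c(20, 460))
  iss <- validate_recording(r)
  expect_true(any(iss$rule == "G1" & iss$row == 1))
  expect_equal(nrow(validate_recording(r, guideline_set(g1 = FALSE))), 0L)
})

test_that("each guideline rule fires on its canonical violation", {
  cases <- list(
    G3  = list(c("Np", "C", "E2", "Np"), "E2 preceded by C"),
    G4  = list(c("Np", "C", "E1e", "pd", "pdII-2", "pdII-3", "C", "Np"),
               "pd preceded by E1e"),
    G4b = list(c("Np", "C", "E1e", "p-pd", "C", "Np"), "p-pd after E1e"),
    G5  = list(c("Np", "C", "pd", "pdII-3", "pdII-2", "C", "Np"),
               "subphases out of order"),
    G6  = list(c("Np", "C", "E1e", "F", "C", "Np"), "F preceded by E1e"),
    G7  = list(c("Np", "C", "F", "G", "C", "Np"), "F followed by G"),
    G8  = list(c("Np", "C", "E1e", "G", "C", "Np"), "G preceded by E1e"),
    G9  = list(c("Np", "C", "G", "F", "C", "Np"), "G followed by F"),
    G10 = list(c("Np", "C", "E1", "F", "C", "Np"), "E1 followed by F"))
  for (rule in names(cases)) {
    lab <- cases[[rule]][[1]]
    r <- make_rec(lab, rep(2, length(lab)))
    iss <- validate_recording(r)
    expect_true(any(iss$rule == rule), label = cases[[rule]][[2]])
  }
  # incomplete pd subphase group
  r <- make_rec(c("Np", "C", "pd", "C", "Np"), c(5, 5, 0.05, 5, 465))
  expect_true(any(validate_recording(r)$rule == "G5"))
  # missing terminal mark (simulated on the recording object)
  r2 <- make_rec(c("Np", "C", "Np"), c(5, 5, 470))
  r2$terminated <- FALSE
  iss2 <- validate_recording(r2)
  expect_true(any(iss2$rule == "G11" & iss2$row == 3))
})

test_that("one bad transition can be reported under several rules", {
  # E2 straight after Np violates both the Np->C rule and E1-precedes-E2
  r <- make_rec(c("Np", "E2", "C", "Np"), c(5, 5, 5, 465))
  rules <- validate_recording(r)$rule
  expect_true(all(c("G2", "G3") %in% rules))
})

test_that("validation is deterministic and ordered by row", {
  r <- make_rec(c("C", "E2", "F", "G", "Np"), c(5, 5, 5, 5, 460))
  i1 <- validate_recording(r); i2 <- validate_recording(r)
  expect_identical(i1, i2)
  expect_true(!is.unsorted(i1$row))
})

test_that("the error report uses the review-sequence headline", {
  r_bad <- make_rec(c("Np", "E1", "C", "E2", "Np"), c(5, 5, 5, 5, 460))
  r_ok <- make_rec(c("Np", "C", "Np"), c(5, 5, 470))
  issues <- list(ok.ana = validate_recording(r_ok),
                 bad.ana = validate_recording(r_bad))
  rep <- error_report(issues)
  n <- nrow(issues$bad.ana)
  expect_match(rep[1], sprintf(
    "You must review the sequence: '%d' wrong marks were detected", n),
    fixed = TRUE)
  # only the offending file gets a block
  expect_true(any(grepl("File 2: bad.ana", rep, fixed = TRUE)))
  expect_false(any(grepl("ok.ana", rep, fixed = TRUE)))
  expect_match(error_report(list(a = validate_recording(r_ok))),
               "0 wrong marks")
  # machine-readable export
  f <- tempfile(fileext = ".csv")
  issues_csv(issues, f)
  csv <- read.csv(f)
  expect_equal(nrow(csv), n)
  expect_equal(unique(csv$file), "bad.ana")
})
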