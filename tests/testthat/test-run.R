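# The batch pipeline behind the command-line front end.

make_batch <- function(dir, seeds = 1:3, profile = generator_profile()) {
  dir.create(dir, showWarnings = FALSE)
  vapply(seeds, function(s) {
    g <- generate_recording(profile, seed = s,
                            file_name = sprintf("rec%02d.ana", s))
    f <- file.path(dir, g$recording$file_name)
    write_stylet_file(g$recording, f)
    f
  }, character(1))
}

test_that("a valid batch computes results, summary and log", {
  d <- tempfile(); files <- make_batch(d)
  out <- file.path(d, "out")
  r <- run_epg(files, treatment = 1L, out_dir = out)
  expect_equal(r$status, 0L)
  res <- read.csv(file.path(out, "results.csv"), check.names = FALSE)
  expect_equal(dim(res), c(3L, 128L))
  expect_true(file.exists(file.path(out, "run.log")))
  expect_true(file.exists(file.path(out, "treatment_summary.csv")))
  expect_true(all(c("%_E2/Tr", "%_sE2/Tr") %in%
                  read.csv(file.path(out, "treatment_summary.csv"),
                           check.names = FALSE)$acronym))
})

test_that("validation failures stop the run unless forced", {
  d <- tempfile(); dir.create(d)
  g <- generate_recording(generator_profile(), seed = 2)
  inj <- inject_violation(g$recording, "G2", seed = 3)
  f <- file.path(d, "bad.ana")
  write_stylet_file(inj$recording, f)
  out <- file.path(d, "out")
  expect_message(r <- run_epg(f, out_dir = out),
                 "You must review the sequence")
  expect_equal(r$status, 3L)
  expect_false(file.exists(file.path(out, "results.csv")))
  report <- readLines(file.path(out, "validation_report.txt"))
  expect_match(report[1], "wrong marks were detected")
  r2 <- run_epg(f, out_dir = out, force = TRUE)
  expect_equal(r2$status, 0L)
  expect_true(file.exists(file.path(out, "results.csv")))
})

test_that("parse errors and empty input get distinct statuses", {
  d <- tempfile(); dir.create(d)
  f <- file.path(d, "broken.ana")
  writeLines(c("1 0.0", "2 30.0"), f)   # no terminal mark
  expect_message(r <- run_epg(f, out_dir = file.path(d, "o")), "format error")
  expect_equal(r$status, 2L)
  expect_message(r0 <- run_epg(character(0)), "usage error")
  expect_equal(r0$status, 1L)
})

test_that("runs are stateless: re-running reproduces outputs byte for byte", {
  d <- tempfile(); files <- make_batch(d, seeds = 4:5)
  o1 <- file.path(d, "o1"); o2 <- file.path(d, "o2")
  run_epg(files, out_dir = o1)
  # an unrelated run in between must not contaminate the next one
  run_epg(make_batch(file.path(d, "other"), seeds = 9),
          out_dir = file.path(d, "o_other"))
  run_epg(files, out_dir = o2)
  expect_identical(readLines(file.path(o1, "results.csv")),
                   readLines(file.path(o2, "results.csv")))
})

test_that("configuration controls code map, order and transposition", {
  cfgf <- tempfile(fileext = ".yaml")
  writeLines(c("transpose: true",
               "order: ['s_E2', 'n_Pr']",
               "code_map:",
               "  1: 'Np'", "  2: 'C'", "  4: 'E1'", "  5: 'E2'",
               "  99: 'T'"), cfgf)
  cfg <- read_epg_config(cfgf)
  expect_true(cfg$transpose)
  expect_equal(cfg$order, c("s_E2", "n_Pr"))
  d <- tempfile(); dir.create(d)
  rec <- make_rec(c("Np", "C", "E1", "E2", "Np"), c(5, 5, 1, 30, 439))
  f <- file.path(d, "r.ana")
  write_stylet_file(rec, f)
  out <- file.path(d, "out")
  r <- run_epg(f, out_dir = out, config = cfg)
  expect_equal(r$status, 0L)
  res <- read.csv(file.path(out, "results.csv"), check.names = FALSE)
  expect_equal(names(res)[2:3], c("s_E2", "n_Pr"))
  rt <- read.csv(file.path(out, "results_t.csv"), check.names = FALSE)
  expect_equal(nrow(rt), 127L)
  # defaults when no file is given
  expect_equal(read_epg_config()$dialect, "stylet")
})
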