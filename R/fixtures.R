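# Synthetic-recording generator: grammatical mark sequences with known
# composition, targeted grammar-violation injection, and the truncation
# validation suite. The generator exists so that every other module is
# testable without laboratory recordings; its duration distributions are
# log-normal with order-of-magnitude-realistic presets (pd subphases a
# few seconds, E2 up to hours) and make no quantitative biological claim.

#' Generator profile for synthetic recordings
#'
#' The profile fixes the study conditions a generated dataset emulates:
#' an 8-h recording, probes separated by non-probing, pathway activity
#' carrying potential drops, occasional xylem (G) / derailment (F)
#' periods, and phloem phases that reach sustained ingestion with a set
#' probability. The `insect` preset selects the code-11 waveform: aphids
#' mark phloem potential drops (p-pd), psyllids mark D.
#'
#' @param insect `"aphid"` or `"psyllid"`.
#' @param total_duration Recording length in minutes.
#' @param p_phloem Probability that a (non-brief) probe contains a
#'   phloem phase.
#' @param p_E2 Probability that a phloem phase reaches E2.
#' @param p_brief Probability that a probe is a brief pathway-only probe.
#' @param p_F,p_G Probability that a probe contains an F / G period.
#' @param p_E1e Probability that a phloem phase is preceded by E1e.
#' @param p_code11 Probability that a probe contains a code-11 period
#'   (p-pd or D according to the preset).
#' @param pd_rate Expected number of pd groups per minute of pathway C.
#' @param mean_extra_E2 Mean number of extra E1-E2 cycles within a
#'   phloem phase (produces fractionated E1).
#' @param lognorm Named list of `c(meanlog, sdlog)` duration parameters
#'   (minutes) per waveform.
#' @param ensure_all Deterministically include every waveform of the
#'   preset at least once (first probe is a fixed full-feature probe).
#' @return List of class `epg_profile`.
#' @export
generator_profile <- function(insect = c("aphid", "psyllid"),
                              total_duration = 480,
                              p_phloem = 0.6, p_E2 = 0.7, p_brief = 0.25,
                              p_F = 0.12, p_G = 0.08, p_E1e = 0.3,
                              p_code11 = 0.25, pd_rate = 0.8,
                              mean_extra_E2 = 0.6,
                              lognorm = NULL, ensure_all = FALSE) {
  insect <- match.arg(insect)
  stopifnot(total_duration > 0)
  defaults <- list(
    Np = c(log(1.5), 0.9), C = c(log(2.5), 0.8),
    F = c(log(18), 0.7), G = c(log(12), 0.7),
    E1e = c(log(0.8), 0.5), E1 = c(log(1.5), 0.7),
    E2 = c(log(22), 1.0),
    pd = c(log(0.030), 0.3), `pdII-2` = c(log(0.020), 0.3),
    `pdII-3` = c(log(0.015), 0.3),
    D = c(log(8), 0.5), `p-pd` = c(log(0.08), 0.4))
  if (!is.null(lognorm)) defaults[names(lognorm)] <- lognorm
  structure(list(insect = insect, total_duration = total_duration,
                 p_phloem = p_phloem, p_E2 = p_E2, p_brief = p_brief,
                 p_F = p_F, p_G = p_G, p_E1e = p_E1e,
                 p_code11 = p_code11, pd_rate = pd_rate,
                 mean_extra_E2 = mean_extra_E2,
                 lognorm = defaults, ensure_all = ensure_all),
            class = "epg_profile")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

#' Generate a grammatical synthetic recording
#'
#' Emits a mark sequence that satisfies the marking guidelines by
#' construction, cut at `total_duration` so the final period is
#' truncated by the terminal mark exactly as in a real recording.
#' Deterministic for a fixed seed.
#'
#' @param profile A [generator_profile()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param file_name,treatment Metadata for the recording.
#' @return List: `recording` (an `epg_recording`) and `composition`
#'   (data.frame `label`, `duration` of the periods actually emitted,
#'   the ground truth for recovery tests).
#' @export
generate_recording <- function(profile = generator_profile(), seed = NULL,
                               file_name = "synthetic.ana", treatment = 1L) {
  with_seed(seed, {
    lab <- character(0); dur <- numeric(0)
    emit <- function(l, d) { lab <<- c(lab, l); dur <<- c(dur, d) }
    rl <- function(w, k = 1L) {
      p <- profile$lognorm[[w]]
      stats::rlnorm(k, p[1], p[2])
    }
    code11_label <- if (profile$insect == "aphid") "p-pd" else "D"
    emit_pd_group <- function() {
      emit("pd", rl("pd")); emit("pdII-2", rl("pdII-2"))
      emit("pdII-3", rl("pdII-3"))
    }
    emit_C_with_pds <- function() {
      d <- rl("C")
      k <- stats::rpois(1, profile$pd_rate * d)
      segs <- d * as.vector(stats::rmultinom(1, 1000, rep(1, k + 1))) / 1000
      segs[segs <= 0] <- d / (1000 * (k + 1))
      for (j in seq_len(k)) { emit("C", segs[j]); emit_pd_group() }
      emit("C", segs[k + 1])
    }
    emit_phase <- function(reaches) {
      if (stats::runif(1) < profile$p_E1e) emit("E1e", rl("E1e"))
      emit("E1", rl("E1"))
      if (reaches) {
        emit("E2", rl("E2"))
        extra <- stats::rpois(1, profile$mean_extra_E2)
        for (j in seq_len(extra)) { emit("E1", rl("E1")); emit("E2", rl("E2")) }
      }
    }
    emit_full_probe <- function() {  # deterministic, every waveform once
      emit("C", 2); emit_pd_group(); emit("C", 1.5)
      emit(code11_label, rl(code11_label))
      if (code11_label == "D") { emit("E1", 2); emit("E2", 15); emit("C", 1) }
      else emit("C", 1)
      emit("F", 4); emit("C", 1); emit("G", 3); emit("C", 2)
      emit("E1e", 0.5); emit("E1", 1.5); emit("E2", 15)
      emit("E1", 0.8); emit("E2", 2); emit("C", 1)
    }
    emit_probe <- function() {
      if (stats::runif(1) < profile$p_brief) { emit("C", stats::runif(1, 0.3, 2.5)); return() }
      emit_C_with_pds()
      if (stats::runif(1) < profile$p_F) { emit("F", rl("F")); emit("C", rl("C")) }
      if (stats::runif(1) < profile$p_G) { emit("G", rl("G")); emit("C", rl("C")) }
      if (stats::runif(1) < profile$p_code11) {
        emit(code11_label, rl(code11_label))
        if (code11_label == "D") {
          emit_phase(stats::runif(1) < profile$p_E2); emit("C", rl("C"))
        } else emit("C", rl("C"))
      }
      if (stats::runif(1) < profile$p_phloem) {
        emit_phase(stats::runif(1) < profile$p_E2)
        if (stats::runif(1) < 0.5) emit("C", rl("C"))
      }
    }
    emit("Np", rl("Np"))
    first <- TRUE
    while (sum(dur) < profile$total_duration) {
      if (first && profile$ensure_all) emit_full_probe() else emit_probe()
      first <- FALSE
      emit("Np", rl("Np"))
    }
    # cut at total_duration: the period spanning it becomes the
    # truncated final period
    ends <- cumsum(dur)
    cut <- which(ends >= profile$total_duration)[1]
    lab <- lab[seq_len(cut)]; dur <- dur[seq_len(cut)]
    dur[cut] <- profile$total_duration - (ends[cut] - dur[cut])
    comp <- data.frame(label = lab, duration = dur, stringsAsFactors = FALSE)
    cm <- default_code_map(code11 = if (profile$insect == "aphid") "p-pd"
                           else "D")
    mk <- structure(data.frame(
      code = c(map_label_to_code(lab, cm), 99L),
      label = c(lab, "T"),
      time = cumsum(c(0, dur)), stringsAsFactors = FALSE),
      class = c("epg_marks", "data.frame"))
    rec <- marks_to_recording(mk, cm, file_name = file_name,
                              treatment = treatment)
    list(recording = rec, composition = comp)
  })
}

# per-rule minimal edits; each returns list(rows, fun) applied to labels
violable_sites <- function(lab, terminated, rule) {
  n <- length(lab)
  prev <- c(NA_character_, lab[-n])
  nxt <- c(lab[-1], NA_character_)
  switch(rule,
    G1  = if (lab[1] == "Np") 1L else integer(),
    G2  = which(lab == "Np" & !is.na(nxt)),
    G3  = which(lab == "E2" & prev == "E1"),
    G4  = which(lab == "pd" & prev == "C"),
    G4b = which(lab %in% c("D", "p-pd") & prev == "C"),
    G5  = which(lab == "pdII-2" & prev == "pd" & nxt == "pdII-3"),
    G6  = which(lab == "F" & prev == "C"),
    G7  = which(lab == "F" & !is.na(nxt)),
    G8  = which(lab == "G" & prev == "C"),
    G9  = which(lab == "G" & !is.na(nxt)),
    G10 = which(lab == "E1" & !is.na(nxt)),
    G11 = if (terminated) 1L else integer(),
    DUP = seq_len(n)[-1],
    stop("unknown rule id: ", rule, call. = FALSE))
}

#' Inject a single grammar violation into a valid recording
#'
#' Applies a minimal seeded edit that violates the named rule at a
#' random eligible position. The edit may, as in real mis-marked files,
#' additionally trigger neighbouring rules; the named rule's issue is
#' guaranteed at the returned row. Returns `NULL` (skip signal) when the
#' rule cannot be violated on this recording (e.g. no pd to corrupt).
#'
#' @param recording A valid `epg_recording`.
#' @param rule A rule id from [guideline_rules()].
#' @param seed Integer seed for the site choice.
#' @return List: `recording` (edited), `rule`, `row` (1-based period row
#'   where the issue is expected); or `NULL` if not violable.
#' @export
inject_violation <- function(recording, rule, seed = NULL) {
  with_seed(seed, {
    lab <- recording$periods$label
    sites <- violable_sites(lab, isTRUE(recording$terminated), rule)
    if (!length(sites)) return(NULL)
    i <- if (length(sites) == 1L) sites else sample(sites, 1L)
    row <- i
    out <- recording
    switch(rule,
      G1  = { lab[1] <- "C"; row <- 1L },
      G2  = { lab[i + 1L] <- "E1"; row <- i + 1L },
      G3  = { lab[i - 1L] <- "C"; row <- i },
      G4  = { lab[i - 1L] <- "E1e"; row <- i },
      G4b = { lab[i - 1L] <- "E1e"; row <- i },
      G5  = { tmp <- lab[i]; lab[i] <- lab[i + 1L]; lab[i + 1L] <- tmp
              row <- i },
      G6  = { lab[i - 1L] <- "E1e"; row <- i },
      G7  = { lab[i + 1L] <- "E1e"; row <- i + 1L },
      G8  = { lab[i - 1L] <- "E1e"; row <- i },
      G9  = { lab[i + 1L] <- "E1e"; row <- i + 1L },
      G10 = { lab[i + 1L] <- "F"; row <- i + 1L },
      G11 = { out$terminated <- FALSE; row <- length(lab) },
      DUP = { lab[i] <- lab[i - 1L]; row <- i })
    out$periods$label <- lab
    # keep annotation codes in step with the edited labels so the edit
    # survives a round trip through the on-disk dialects
    cm <- default_code_map(recording$code11_mode)
    out$periods$code <- map_label_to_code(lab, cm)
    list(recording = out, rule = rule, row = row)
  })
}

#' Truncation validation suite
#'
#' Small cases mirroring artificially modified recordings with 1, 2 or 3
#' complete E1-E2 cycles plus a final truncated E2, each paired with the
#' brute-force range of attainable true medians (enumerated over a dense
#' grid of hypothetical true durations) as an oracle.
#'
#' @param seed Integer seed.
#' @param n_cases Number of cases (cycled over 1, 2, 3 prior periods;
#'   default 5, alternating truncated-longest and not).
#' @return List of cases: `untruncated`, `truncated_obs`,
#'   `oracle_range` (`c(lo, hi)`, `hi` may be `Inf`), `k`.
#' @export
generate_truncation_suite <- function(seed = 1L, n_cases = 5L) {
  with_seed(seed, {
    ks <- rep_len(c(1L, 2L, 2L, 3L, 3L), n_cases)
    lapply(seq_len(n_cases), function(i) {
      k <- ks[i]
      u <- round(stats::rlnorm(k, log(15), 0.8), 3)
      t_obs <- if (i %% 2 == 0) round(max(u) * stats::runif(1, 1.1, 2), 3)
               else round(min(u) * stats::runif(1, 0.3, 0.9), 3)
      list(untruncated = u, truncated_obs = t_obs,
           oracle_range = brute_median_range(u, t_obs), k = k)
    })
  })
}

#' Brute-force range of attainable true medians
#'
#' Enumerates `median(untruncated + {T})` over a dense grid of
#' hypothetical true durations `T >= truncated_obs` (the median is
#' non-decreasing and saturates once `T` exceeds every untruncated
#' duration, so a grid reaching far beyond them recovers the exact
#' range). Used as an independent check of [true_median_estimate()].
#'
#' @inheritParams true_median_estimate
#' @param grid_max Upper end of the enumeration grid.
#' @param n_grid Number of grid points.
#' @return `c(lo, hi)`; `hi` is `Inf` when the median grows without
#'   bound (fewer than 2 untruncated periods).
#' @export
brute_median_range <- function(untruncated, truncated_obs,
                               grid_max = 1e6, n_grid = 512L) {
  grid <- unique(c(truncated_obs,
                   exp(seq(log(truncated_obs), log(grid_max),
                           length.out = n_grid)),
                   untruncated[untruncated >= truncated_obs], grid_max))
  meds <- vapply(grid, function(T)
    stats::median(c(untruncated, T)), numeric(1))
  hi <- max(meds)
  # unbounded when the median still tracks T at the top of the grid
  unbounded <- length(untruncated) < 2L
  c(min(meds), if (unbounded) Inf else hi)
}
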