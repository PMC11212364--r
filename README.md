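# epgvars

Calculation of electrical penetration graph (EPG) feeding-behavior
variables from waveform annotation files.

The EPG technique records voltage waveforms while a piercing-sucking
insect (aphid, psyllid, whitefly, ...) penetrates plant tissue; each
waveform corresponds to a behavior — `Np` non-probing, `C` pathway,
`pd` intracellular punctures (subphases II-1/II-2/II-3), `E1` sieve
element salivation, `E2` phloem ingestion, `F` derailed stylet
mechanics, `G` xylem ingestion. Turning an annotated 8-h recording into
the standardized behavioral variables used across the field (times to
first phloem phase, probe counts, potential indices, pd statistics, ...)
is tedious and error-prone by hand. `epgvars` does it programmatically,
for entomologists and plant-resistance researchers who analyse EPG
datasets in R:

* parses Stylet+-style text and Windaq-style CSV annotation exports
  into a canonical period table (one period per mark, durations by
  successive differencing, minutes throughout);
* validates the mark sequence against the standard waveform-marking
  guidelines (G1–G11 plus duplication), reporting each violation with
  its rule and row;
* computes a registry of **127 variables per recording** (53 of them
  shared with the widely used Sarria workbook), with the field's
  missing-data conventions, plus per-treatment percentages, by-hour and
  cumulative temporal tables, per-event (WDE) tables and per-insect
  means (WDEI);
* implements the **truncated wave criterion** for the final period cut
  by the end of the recording.

## The truncated wave criterion

The last period of every recording is artificially terminated by the
terminal mark, so its true duration `T` is only known to satisfy
`T >= t_obs`. The median of the waveform's durations is a
non-decreasing function of `T`, so the attainable true medians form an
interval `[median(u + {t_obs}), lim_{T->inf} median(u + {T})]` where
`u` are the complete-period durations. When at least two complete
periods exist and the truncated one is the longest, the interval
collapses and the median is recovered *exactly*; otherwise the interval
midpoint is a least-biased estimate (with flagged fallbacks for 0 or 1
complete periods). Means are handled by policy — by default the
truncated observation is included only when it is the longest period,
since including it always underestimates the mean but excluding a very
long one often underestimates it more.

```r
library(epgvars)
true_median_estimate(c(2, 10), 5)
#> Truncated-period median estimate: 7.5 (midpoint)
#>   possible true medians: [5, 10]
```

## Worked example

```r
library(epgvars)

g <- generate_recording(generator_profile("aphid", ensure_all = TRUE),
                        seed = 42, file_name = "aphid_01.ana")
g$recording
#> EPG recording 'aphid_01.ana' (treatment 1)
#>   240 periods over 480 min; code 11 = p-pd
#>   waveforms: C:68 pd:38 pdII-2:38 pdII-3:38 E1:16 Np:15 E2:12 p-pd:6 F:4 E1e:3 G:2

validate_recording(g$recording)   # 0 rows: the sequence is grammatical

v <- compute_variables(g$recording)           # all 127 registry variables
v[match(c("n_Pr", "n_bPr", "s_E2", "a_E2", "m_E2", "n_sE2",
          "t > 1E", "E2_index", "%probtimeinE2", "n_pd"), v$acronym), 1:2]
#>          acronym   value
#>             n_Pr  15.000
#>            n_bPr   3.000
#>             s_E2 249.499
#>             a_E2  17.741
#>             m_E2  12.495
#>            n_sE2   8.000
#>           t > 1E  15.160
#>         E2_index  54.453
#>    %probtimeinE2  57.598
#>             n_pd  38.000
```

The insect probed 15 times (3 of them brief), spent 249.5 min ingesting
phloem sap across 12 E2 periods (8 sustained), reached the phloem
15.2 min after its first probe began, and performed 38 potential drops.
`m_E2` and `a_E2` already account for the recording ending mid-E2 via
the truncated wave criterion (the applied branch is in the `flag`
column). For whole workflows use `run_epg()` (or the script in
`inst/cli/epgvars.R` from a shell): it validates a batch, writes
`results.csv` (optionally transposed), a per-treatment summary, the
validation report and a run log, with distinct exit statuses for usage,
parse and validation failures.

## Documentation

The methods vignette (`vignettes/epg-variable-calculation.Rmd`) gives
the full account: the data model and sequence grammar, the
truncated-median mathematics, every registry convention and
configurable definition, the temporal-analysis semantics, and what the
synthetic generator does and does not emulate.
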