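---
title: "Calculating EPG feeding-behavior variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculating EPG feeding-behavior variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgvars)
```

## The data model

The electrical penetration graph (EPG) technique records voltage
waveforms while a piercing-sucking insect (an aphid, psyllid, whitefly,
...) penetrates plant tissue with its stylets. Each waveform corresponds
to a behavior: `Np` non-probing, `C` intercellular pathway, `pd` a brief
intracellular puncture (with subphases II-1, II-2, II-3), `E1`
salivation into a sieve element, `E2` passive phloem ingestion, `F`
derailed stylet mechanics, `G` xylem ingestion, `E1e` extracellular
salivation. Aphids additionally mark phloem potential drops (`p-pd`) and
psyllids a first phloem contact (`D`); both conventionally share
annotation code 11, so a dataset-level mode decides which one code 11
denotes. Code 99 is the terminal mark that closes every file.

Acquisition software exports an annotation file per recording: an
ordered list of (code, time) marks. `epgvars` reads two dialects — a
two-column text format (whitespace/semicolon/comma separated) and a CSV
event export — converts times to minutes, and turns marks into
*periods* by successive differencing: each mark opens a period that the
next mark closes. The terminal mark closes the final period, which is
therefore always artificially truncated: its true duration is unknown
but at least the observed one. Durations telescope, so the period table
tiles the recording exactly (`s_Np + s_Pr` equals the total duration to
machine precision; the test suite asserts this on every generated
recording).

A *probe* is a maximal run of non-`Np` periods; a *phloem phase* is a
maximal run of `E1`/`E2` periods. Derived classes refine these: brief
probes (duration strictly `< 3` min), sustained E2 (`sE2`, strictly
`> 10` min), single E1 (`sgE1`, an E1 whose phase never reaches E2),
fractionated E1 (`frE1`, an E1 between two E2 periods of the same
phase), `E12` (a phase that reaches E2, its duration the whole phase),
and single D (a `D` not followed by `E1`). Both thresholds are strict
inequalities, so a probe of exactly 3 min is not brief and an E2 of
exactly 10 min is not sustained; boundary values fall outside the
class by design.

## Sequence validation

Correct variable values require correctly ordered marks, so computation
is gated on a rule engine that checks the standard waveform-marking
guidelines: recordings start with `Np` (rule G1, optional — insects such
as whitefly nymphs may already be probing at recording start); `Np` is
always followed by `C` (G2); `E2` is always preceded by `E1` (G3); `pd`
is preceded by `C` and the subphase group is followed by `C` or `Np`
(G4); subphases run II-1, II-2, II-3 (G5); `F` and `G` are preceded by
`C` and followed by `Np` or `C` (G6–G9); `E1` is followed by `E1e`,
`E2`, `C`, or `Np` (G10); the terminal mark is present (G11); adjacent
identical labels are duplication errors (DUP).

Three design points deserve a note:

* G4's "followed by `C` or `Np`" applies after the *complete* subphase
  group, since G5 already mandates the internal order — reading it
  per-period would contradict G5.
* The code-11 waveforms (`D`, `p-pd`) are not covered by the printed
  guidelines; the engine checks "preceded by `C`" for them under a
  separate rule id `G4b` so users can disable it independently.
* A single bad transition may violate several rules (`Np → E2` breaks
  both G2 and G3); all are reported, each with the 1-based row of the
  second element of the offending pair. A subphase group cut short by
  the end of the recording is *not* flagged: truncation is not a
  marking error.

Validation never throws on content; it returns a located issue table,
and `compute_variables()` refuses to run on an invalid sequence unless
forced, mirroring a fix-then-run workflow.

## The truncated wave criterion

The final period of a recording is cut by the terminal mark, so for the
waveform it belongs to, plain means and medians are biased. Writing $u$
for the durations of the complete periods of that waveform and
$t_{obs}$ for the observed truncated duration, the true duration $T$
satisfies $T \ge t_{obs}$, and the median of $u \cup \{T\}$ is a
non-decreasing step function of $T$. The attainable true medians
therefore form an interval $[m_{low}, m_{high}]$ with
$m_{low} = \mathrm{median}(u \cup \{t_{obs}\})$ and $m_{high}$ the
limit as $T \to \infty$ (the median with the truncated period ranked
above all others). The estimator is:

* **exact** when $m_{low} = m_{high}$ — which holds whenever
  $|u| \ge 2$ and the truncated period is the longest: how much longer
  it really was cannot move the median;
* the **midpoint** $(m_{low} + m_{high})/2$ when the interval is a
  proper finite interval, as a least-biased estimate;
* with $|u| = 1$ the interval is unbounded above and the single
  complete duration is returned, flagged `fallback`;
* with $|u| = 0$ the observed duration itself is returned, flagged
  `lower-bound`.

Medians of an even number of values are the mean of the two middle
values (the standard convention). Every branch is reported in the
output metadata, and the whole estimator is checked against brute-force
enumeration of $\mathrm{median}(u \cup \{T\})$ over a dense grid of
$T$ (`brute_median_range()`), including the invariance of the exact
branch under random substituted true durations.

Means have no analogous rank argument — they are computed from actual
values, and including a truncated period always underestimates the
mean. Excluding a very long truncated period, however, often
underestimates it even more. The default policy `longest-include`
operationalizes this: the truncated observation enters the mean exactly
when it is the longest (or only) period. `include` and `exclude` are
available, and every result carries the branch taken.

The criterion applies to the classes that contain the physically
truncated period (the label classes and the derived `sgE1`/`frE1`/`sE2`
classes). Aggregate structures — probe durations, `E12` phase
durations, pd group totals — use observed durations; a maximum (`mx_`)
cannot be corrected without the unknown true value and is reported as
observed, flagged when the maximum is the truncated period. Counts and
sums always include the observed truncated duration.

## The variable registry

`epg_variable_registry()` is a declarative table of the 127 variables
computed per recording — non-sequential statistics (`n_`, `a_`, `m_`,
`s_`, `mx_`) per waveform class, sequential times measured from the
three standard starting points (recording start, first-probe start,
start of the containing probe), sequential counts and durations around
the first phloem events, potential indices, and the pd family. Keeping
the registry data-driven means any contested definition can be
corrected in one place. 53 of the 127 are also calculated by the widely
used Sarria workbook, recorded in the `shared_with_sarria` flag; the
remaining 74 are unique to this registry. The two percentages that pool
insects (`%_E2/Tr`, `%_sE2/Tr`) are treatment-level quantities — the
replicate in EPG work is the individual recording — so they are
computed across recordings by `treatment_percentages()` and sit outside
the per-recording registry.

Missing-data conventions follow the standard sequential-variable rules:

* absent waveform: count and sum are 0, mean/median/max are missing;
* recording-start-based times with no reference event are set to the
  total recording duration;
* first-probe-based times to the time from first-probe start to the
  end of the recording;
* within-probe times, after-counts, and sequential durations (including
  `s_np.1E`) become missing;
* before-counts are set to the total count;
* ratios with a zero denominator are missing
  (`undefined-denominator`).

The same conventions are extended to the pd family by starting point
(`t > 1pd` falls back to the total duration, `n_Pr > 1pd` to the total
probe count, within-probe pd times to missing).

A few definitions are not fixed by any published formula and are
explicit package choices, kept configurable:

* **E1 index**: mirrored from the E2 index (share of time in E1 from
  the first E1 onset to the end of the recording); the alternative
  $100\,s_{E1}/(s_{E1}+s_{E2})$ is available via `e1_index = "share"`.
* **E fractioning ratio**: `n_frE1 / n_E1`, missing when no E1; `frE1`
  requires an E2 neighbour on both sides by default
  (`frE1_both_sides = FALSE` relaxes to a preceding E2 only).
* **Duration of the first phloem phase** (`d_1st_E`) is the whole
  contiguous E1/E2 phase, not the first E1 period alone.
* `d_2Np` is the duration of the second non-probing period, missing
  with fewer than two `Np` periods.
* A `C` interrupted by a pd group counts as two `C` periods
  (mark-based counting, one period per marked row), and pd time is not
  part of `s_C`.

## Temporal analyses, events, WDEI

`compute_temporal()` recomputes the registry per window: by-hour
windows $[60(h{-}1), 60h)$ or cumulative windows $[0, 60h)$, with a
final partial hour permitted. By default a period spanning a boundary
is split and each window counts its own fragment — durations then
partition exactly (by-hour sums equal full-recording totals, and the
final cumulative window reproduces the full results verbatim), at the
cost of by-hour counts possibly exceeding the full count. The
alternative (`attribute = "start"`) assigns whole periods to the window
containing their start, which preserves counts but not the duration
partition; a window containing no period start is reported as all
missing. The truncated wave criterion targets end-of-recording
truncation, so window-created cuts are left as observed unless
`extend_truncation = TRUE`.

`events_table()` lists every period of a waveform across a treatment
(the per-event WDE layout); since pooled events are pseudo-replicates,
`wdei()` provides the per-insect mean that treatment statistics should
use — definitionally equal to the registry's `a_` variable for the same
options.

## The synthetic generator

Laboratory EPG recordings are not shipped with the package; the
generator (`generate_recording()`) provides study-condition stand-ins:
8-h recordings (480 min), probes separated by non-probing, pathway
segments carrying pd groups at a set rate (0.8 groups per minute of C),
occasional F (p = 0.12) and G (p = 0.08) periods, phloem phases in 60%
of standard probes, reaching E2 with probability 0.7, brief probes at
rate 0.25, and an aphid/psyllid preset for the code-11 waveform.
Durations are log-normal per waveform with order-of-magnitude-realistic
medians (Np ≈ 1.5 min, C ≈ 2.5 min, E2 ≈ 22 min, pd subphases a few
seconds); these parameters shape plausible sequences and make **no
quantitative biological claim**. Sequences are grammatical by
construction, the recording is cut at the nominal duration so the final
period is genuinely truncated, and the generator returns the exact
composition it emitted, so count/sum variables can be checked for exact
recovery. `inject_violation()` makes a minimal seeded edit violating a
named rule for validator completeness tests, and
`generate_truncation_suite()` reproduces the 1/2/3-prior-period
truncated-E2 validation design with enumeration oracles attached.

What passing tests on generated data do *not* show: that real
recordings of a given species follow these rates or durations, or that
waveform identification from voltage traces is correct — the package
starts at the annotation file, and signal processing is out of scope.

## Numerical choices and problem sizes

Times are real minutes over half-open intervals; the terminal mark is a
boundary, not a period. File writers emit full precision so a written
recording re-reads to the identical period table (round-trip agreement
within $10^{-9}$ min is asserted in the tests). Variable equality
against an independent per-variable rescan implementation is checked at
$10^{-9}$ min on 100 generated recordings (240-min recordings keep the
suite fast; the identities are length-invariant); validator soundness
uses 1000 generated recordings and 100 seeded injections per rule;
truncation-estimator checks use 500 random cases against brute-force
enumeration over a grid up to $10^6$ min. Known limitations: only the
single final period is treated as censored (no multi-censoring, no
Kaplan–Meier machinery — deliberate non-goals), psyllid-specific
E(pd)-style waveform variants are not modelled, and the exact column
grammar of acquisition exports varies by setup, which is why the code
map, dialect and time unit are configuration rather than assumptions.
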