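# The truncated wave criterion: least-biased estimation of the median
# (and policy-driven mean) waveform-period duration when the final
# period of a waveform is artificially terminated by the end of the
# recording, so that its true duration is unknown but at least the
# observed one.

#' Least-biased estimate of the true median period duration
#'
#' The final period of a waveform is truncated: its true duration `T` is
#' unknown but `T >= truncated_obs`. The median of the full set
#' `untruncated + {T}` is a non-decreasing function of `T`, so the set
#' of possible true medians is the interval from `median_low` (the
#' median computed with `T = truncated_obs`) to `median_high` (the limit
#' as `T -> Inf`, i.e. the median with the truncated period ranked above
#' all others). When the interval collapses to a point — which happens
#' whenever there are at least 2 untruncated periods and the truncated
#' one is the longest — the estimate is exact: how much longer the
#' truncated period really was cannot move the median. Otherwise, the
#' midpoint of the interval is used as a least-biased estimate. With
#' only 1 untruncated period the interval is unbounded above and the
#' single untruncated duration is returned (`method = "fallback"`); with
#' none, the observed truncated duration is returned as a lower bound.
#'
#' Medians of an even number of values are the mean of the two middle
#' values.
#'
#' @param untruncated Durations (minutes, > 0) of the complete periods of
#'   the waveform; may be empty.
#' @param truncated_obs Observed duration (> 0) of the truncated period.
#' @return List of class `truncation_estimate`: `median_low`,
#'   `median_high` (possibly `Inf`), `estimate`, `exact`, `method`
#'   (one of `"include-exact"`, `"midpoint"`, `"fallback"`,
#'   `"lower-bound"`).
#' @examples
#' true_median_estimate(c(2, 4), 9)    # exact: 4
#' true_median_estimate(c(2, 10), 5)   # midpoint of [5, 10]: 7.5
#' @export
true_median_estimate <- function(untruncated, truncated_obs) {
  untruncated <- as.numeric(untruncated)
  if (length(truncated_obs) != 1L || is.na(truncated_obs) || truncated_obs <= 0)
    stop("truncated_obs must be a single positive duration", call. = FALSE)
  if (anyNA(untruncated) || any(untruncated <= 0))
    stop("untruncated durations must be positive", call. = FALSE)
  k <- length(untruncated)
  median_low <- stats::median(c(untruncated, truncated_obs))
  median_high <- median_with_infinite(untruncated)
  if (median_low == median_high) {
    est <- median_low; exact <- TRUE; method <- "include-exact"
  } else if (is.finite(median_high)) {
    est <- (median_low + median_high) / 2; exact <- FALSE; method <- "midpoint"
  } else if (k == 1L) {
    est <- untruncated; exact <- FALSE; method <- "fallback"
  } else {  # k == 0
    est <- truncated_obs; exact <- FALSE; method <- "lower-bound"
  }
  structure(list(median_low = median_low, median_high = median_high,
                 estimate = est, exact = exact, method = method),
            class = "truncation_estimate")
}

# median of sort(u) with one extra value ranked above everything
median_with_infinite <- function(u) {
  v <- sort(u)
  n <- length(u) + 1L
  if (n %% 2L == 1L) {
    m <- (n + 1L) %/% 2L
    if (m <= length(v)) v[m] else Inf
  } else {
    a <- v[n %/% 2L]
    b <- if (n %/% 2L + 1L <= length(v)) v[n %/% 2L + 1L] else Inf
    (a + b) / 2
  }
}

#' @export
print.truncation_estimate <- function(x, ...) {
  cat("Truncated-period median estimate: ", format(x$estimate),
      " (", x$method, if (x$exact) ", exact" else "", ")\n", sep = "")
  cat("  possible true medians: [", format(x$median_low), ", ",
      format(x$median_high), "]\n", sep = "")
  invisible(x)
}

#' Mean period duration under truncation
#'
#' Means are computed from actual values only, so the ranking argument
#' that makes medians exactly recoverable does not apply: including a
#' truncated period always underestimates the mean, while excluding a
#' very long truncated period often underestimates it even more. The
#' default policy `"longest-include"` operationalizes that trade-off:
#' the truncated observation is included exactly when it is the longest
#' period (or the only one), otherwise excluded.
#'
#' @inheritParams true_median_estimate
#' @param policy `"include"`, `"exclude"`, or `"longest-include"`.
#' @return List: `value` (minutes, `NA` when no value is computable) and
#'   `flag` describing the branch taken.
#' @export
mean_with_truncation <- function(untruncated, truncated_obs,
                                 policy = c("longest-include", "include",
                                            "exclude")) {
  policy <- match.arg(policy)
  untruncated <- as.numeric(untruncated)
  if (length(truncated_obs) != 1L || is.na(truncated_obs) || truncated_obs <= 0)
    stop("truncated_obs must be a single positive duration", call. = FALSE)
  if (anyNA(untruncated) || any(untruncated <= 0))
    stop("untruncated durations must be positive", call. = FALSE)
  k <- length(untruncated)
  switch(policy,
    include = list(value = mean(c(untruncated, truncated_obs)),
                   flag = "included-underestimate"),
    exclude = if (k == 0L) list(value = NA_real_, flag = "excluded-no-data")
              else list(value = mean(untruncated), flag = "excluded"),
    `longest-include` =
      if (k == 0L || truncated_obs > max(untruncated))
        list(value = mean(c(untruncated, truncated_obs)),
             flag = "included-longest")
      else
        list(value = mean(untruncated), flag = "excluded-not-longest")
  )
}

#' Adjusted mean/median for the waveform truncated at end of recording
#'
#' Helper applying the criterion to one waveform class: the durations of
#' its complete periods and the observed duration of its final,
#' truncated period. With `enabled = FALSE` the truncated period is
#' simply included in a plain mean and median.
#'
#' @inheritParams true_median_estimate
#' @param enabled Apply the truncated wave criterion?
#' @param mean_policy Passed to [mean_with_truncation()].
#' @return List: `a` (mean), `m` (median), `a_flag`, `m_flag`.
#' @export
truncated_wave_stats <- function(untruncated, truncated_obs, enabled = TRUE,
                                 mean_policy = "longest-include") {
  if (!enabled) {
    all <- c(untruncated, truncated_obs)
    return(list(a = mean(all), m = stats::median(all),
                a_flag = "truncated-included", m_flag = "truncated-included"))
  }
  med <- true_median_estimate(untruncated, truncated_obs)
  avg <- mean_with_truncation(untruncated, truncated_obs, mean_policy)
  list(a = avg$value, m = med$estimate,
       a_flag = avg$flag, m_flag = med$method)
}
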