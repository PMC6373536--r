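#' Trim response times to the analysable range
#'
#' Removes trials with response times strictly below `lo_ms` or strictly
#' above `hi_ms` (times exactly at a bound are kept). The removed
#' proportion is reported over main-block trials, the only trials that
#' enter any analysis.
#'
#' @param trials Trial tibble with at least `rt_ms` (and `block` for the
#'   removal proportion; rows without a `block` column are all treated as
#'   main trials).
#' @param lo_ms,hi_ms Inclusive bounds in milliseconds.
#' @return A list with `trials` (kept rows) and `removed_proportion`
#'   (proportion of main-block trials removed; 0 for empty input).
#' @examples
#' filter_rts(tibble::tibble(rt_ms = c(150, 500, 2600)))
#' @export
filter_rts <- function(trials, lo_ms = 200, hi_ms = 2500) {
  if (nrow(trials) == 0) {
    return(list(trials = trials, removed_proportion = 0))
  }
  stopifnot("rt_ms" %in% names(trials), !anyNA(trials$rt_ms))
  keep <- trials$rt_ms >= lo_ms & trials$rt_ms <= hi_ms
  is_main <- if ("block" %in% names(trials)) {
    trials$block != "practice"
  } else {
    rep(TRUE, nrow(trials))
  }
  removed <- if (any(is_main)) sum(!keep & is_main) / sum(is_main) else 0
  list(trials = trials[keep, ], removed_proportion = removed)
}

#' Exclude participants with excessive error rates
#'
#' Drops all trials of participants whose main-block error proportion is
#' strictly greater than `error_threshold` (a participant at exactly the
#' threshold is retained). Intended to run on unfiltered trials, before
#' response-time trimming.
#'
#' @param trials Trial tibble with `participant_id`, `correct` and
#'   (optionally) `block`.
#' @param error_threshold Exclusion threshold on the error proportion.
#' @return A list with `trials` (kept rows) and `excluded` (character
#'   vector of excluded participant ids, possibly empty).
#' @export
exclude_participants <- function(trials, error_threshold = 0.45) {
  stopifnot(all(c("participant_id", "correct") %in% names(trials)))
  main <- if ("block" %in% names(trials)) {
    dplyr::filter(trials, .data$block != "practice")
  } else {
    trials
  }
  rates <- main |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(error_rate = mean(!.data$correct), .groups = "drop")
  excluded <- rates$participant_id[rates$error_rate > error_threshold]
  list(trials = dplyr::filter(trials,
                              !.data$participant_id %in% excluded),
       excluded = excluded)
}

#' Reduce trials to per-participant, per-cell summary statistics
#'
#' Computes, for each participant and each combination of the requested
#' design factors, the trial counts, proportion correct, and the mean,
#' variance (n-1 denominator) and median of the *correct* response times.
#' Mean and variance are returned in seconds (the units of the EZ
#' estimator); the median stays in milliseconds. Practice trials are always
#' excluded; pass already-trimmed trials.
#'
#' Cells with fewer than two correct trials have undefined variance and are
#' flagged `degenerate = TRUE`; they are kept so that downstream estimation
#' can report them rather than silently drop them.
#'
#' @param trials Trimmed trial tibble.
#' @param factors Subset of `c("expression", "required_response",
#'   "face_gender")` defining the cells.
#' @return A tibble with one row per participant x cell: the factor
#'   columns, `n_total`, `n_correct`, `pc`, `mrt_s`, `vrt_s2`,
#'   `median_rt_ms`, `degenerate`.
#' @export
summarize_cells <- function(trials,
                            factors = c("expression", "required_response",
                                        "face_gender")) {
  stopifnot(all(factors %in% c("expression", "required_response",
                               "face_gender")),
            length(factors) >= 1,
            all(c("participant_id", "correct", "rt_ms") %in% names(trials)))
  main <- if ("block" %in% names(trials)) {
    dplyr::filter(trials, .data$block != "practice")
  } else {
    trials
  }
  id_cols <- intersect(c("participant_id", "participant_gender"),
                       names(main))
  main |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_cols, factors)))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_correct = sum(.data$correct),
      pc = .data$n_correct / .data$n_total,
      mrt_s = mean(.data$rt_ms[.data$correct]) / 1000,
      vrt_s2 = var(.data$rt_ms[.data$correct] / 1000),
      median_rt_ms = median(.data$rt_ms[.data$correct]),
      .groups = "drop"
    ) |>
    dplyr::mutate(degenerate = .data$n_correct < 2 |
                    !is.finite(.data$vrt_s2) | .data$vrt_s2 <= 0)
}
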