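#' Posterior-predictive simulation from fitted EZ parameters
#'
#' For every non-degenerate participant-by-cell estimate, simulates
#' `n_sim` Wiener trials from the fitted (v, a, ter) via [simulate_rts()].
#' Upper-boundary absorptions form the predicted correct-response stream,
#' lower-boundary absorptions the predicted error stream.
#'
#' @param estimates Estimate tibble from [estimate_all()].
#' @param n_sim Simulated trials per estimate.
#' @param seed Optional integer seed (one stream for the whole table, so
#'   the result is reproducible as a unit).
#' @param dt Integrator step, seconds.
#' @return A tibble with the identifying columns of `estimates` plus
#'   `rt_ms` and `correct` (one row per simulated trial). Degenerate
#'   estimates are skipped; their ids are in the `skipped` attribute.
#' @export
posterior_predict <- function(estimates, n_sim = 10000, seed = NULL,
                              dt = 5e-4) {
  stopifnot(all(c("v", "a", "ter", "s") %in% names(estimates)))
  if (!is.null(seed)) set.seed(seed)
  usable <- !estimates$degenerate & is.finite(estimates$v)
  id_cols <- setdiff(names(estimates),
                     c("v", "a", "ter", "s", "edge_corrected", "degenerate",
                       "n_basis"))
  sims <- purrr::map(which(usable), function(i) {
    sim <- simulate_rts(list(v = estimates$v[i], a = estimates$a[i],
                             ter = estimates$ter[i], s = estimates$s[i]),
                        n_trials = n_sim, dt = dt)
    dplyr::bind_cols(estimates[rep(i, n_sim), id_cols],
                     tibble::tibble(rt_ms = sim$rt_ms,
                                    correct = sim$hit_upper))
  })
  out <- dplyr::bind_rows(sims)
  attr(out, "skipped") <- estimates[!usable, id_cols]
  attr(out, "n_sim") <- n_sim
  out
}

stream_quantiles <- function(rt, probs = c(0.05, 0.5, 0.95)) {
  # linear interpolation between order statistics (type 7)
  quantile(rt, probs = probs, type = 7, names = FALSE)
}

#' Compare observed and posterior-predictive response-time summaries
#'
#' Per participant-by-cell and response stream (correct / error), computes
#' the observed median and 5th/95th percentiles and the same summaries of
#' the predictive simulation, and checks whether the observed median falls
#' inside the predicted 5-95% band. Cells with no observed responses in a
#' stream are flagged `assessable = FALSE` for that stream (typical for
#' error responses in accurate cells) rather than dropped.
#'
#' @param observed Trimmed main-block trial tibble.
#' @param simulated Output of [posterior_predict()].
#' @param factors Cell-defining factor columns present in both tables.
#' @return A tibble of class `pp_fit_summary`, one row per cell x stream:
#'   observed and predicted medians and percentiles (ms), `n_observed`,
#'   `n_simulated`, `within_band`, `assessable`. The proportion of
#'   assessable correct-stream cells with the observed median inside the
#'   predicted band is in the `coverage` attribute (also via
#'   [fit_coverage()]).
#' @export
fit_summary <- function(observed, simulated,
                        factors = c("expression", "required_response",
                                    "face_gender")) {
  keys <- c("participant_id", factors)
  stopifnot(all(keys %in% names(observed)),
            all(keys %in% names(simulated)))
  obs_main <- if ("block" %in% names(observed)) {
    dplyr::filter(observed, .data$block != "practice")
  } else {
    observed
  }
  summarise_streams <- function(d, prefix) {
    d |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys)),
                      stream = ifelse(.data$correct, "correct", "error")) |>
      dplyr::summarise(
        n = dplyr::n(),
        p5 = stream_quantiles(.data$rt_ms)[1],
        median = stream_quantiles(.data$rt_ms)[2],
        p95 = stream_quantiles(.data$rt_ms)[3],
        .groups = "drop"
      ) |>
      dplyr::rename_with(~ paste0(prefix, "_", .x),
                         c("n", "p5", "median", "p95"))
  }
  obs <- summarise_streams(obs_main, "observed")
  pred <- summarise_streams(simulated, "predicted")
  streams <- tidyr::expand_grid(
    dplyr::distinct(simulated[keys]), stream = c("correct", "error"))
  out <- streams |>
    dplyr::left_join(obs, by = c(keys, "stream")) |>
    dplyr::left_join(pred, by = c(keys, "stream")) |>
    dplyr::mutate(
      observed_n = tidyr::replace_na(.data$observed_n, 0L),
      predicted_n = tidyr::replace_na(.data$predicted_n, 0L),
      assessable = .data$observed_n > 0 & .data$predicted_n > 0,
      within_band = .data$assessable &
        .data$observed_median >= .data$predicted_p5 &
        .data$observed_median <= .data$predicted_p95
    ) |>
    dplyr::rename(n_observed = "observed_n", n_simulated = "predicted_n")
  coverage <- out |>
    dplyr::filter(.data$stream == "correct", .data$assessable) |>
    dplyr::summarise(coverage = mean(.data$within_band)) |>
    dplyr::pull(.data$coverage)
  attr(out, "coverage") <- coverage
  class(out) <- c("pp_fit_summary", class(out))
  out
}

#' Aggregate band coverage of a fit summary
#'
#' @param x A [fit_summary()] table.
#' @param stream Response stream to assess.
#' @return Proportion of assessable cells whose observed median lies inside
#'   the predicted 5-95% band.
#' @export
fit_coverage <- function(x, stream = "correct") {
  rows <- x$stream == stream & x$assessable
  if (!any(rows)) return(NA_real_)
  mean(x$within_band[rows])
}

#' Plot observed vs posterior-predictive medians
#'
#' Design-cell means (across participants) of observed medians (circles)
#' and predicted medians (crosses), with bars spanning the cell-mean 5th to
#' 95th observed percentiles, faceted by response stream and participant
#' gender when available.
#'
#' @param object A [fit_summary()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pp_fit_summary <- function(object, ...) {
  factors <- intersect(c("expression", "required_response", "face_gender"),
                       names(object))
  has_pg <- "participant_gender" %in% names(object)
  grp <- c(factors, "stream", if (has_pg) "participant_gender")
  cellmeans <- object |>
    dplyr::filter(.data$assessable) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      observed = mean(.data$observed_median),
      predicted = mean(.data$predicted_median),
      lo = mean(.data$observed_p5),
      hi = mean(.data$observed_p95),
      .groups = "drop"
    ) |>
    dplyr::mutate(cell = interaction(
      !!!rlang::syms(factors), sep = "\n", lex.order = TRUE))
  p <- ggplot2::ggplot(cellmeans, ggplot2::aes(x = .data$cell)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), shape = 1,
                        size = 2.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted), shape = 4,
                        size = 2.5, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "median RT (ms)",
                  caption = "circles: observed; crosses: predicted; bars: observed 5th-95th percentile") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
  if (has_pg) {
    p + ggplot2::facet_grid(stream ~ participant_gender, scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(~stream, scales = "free_y")
  }
}

#' Plot condition means of a per-participant cell statistic
#'
#' Group means with bootstrap-free normal-approximation standard-error
#' bars, in the layout standard for this task: expression on the x axis,
#' one line per level of `trace`, faceted by participant gender.
#'
#' @param stat_table Per-participant cell-statistic tibble.
#' @param dv Statistic column name.
#' @param trace Factor drawn as separate lines
#'   (`"required_response"` or `"face_gender"`).
#' @return A ggplot object.
#' @export
plot_condition_means <- function(stat_table, dv,
                                 trace = "required_response") {
  means <- stat_table |>
    dplyr::group_by(.data$participant_gender, .data$expression,
                    .data[[trace]]) |>
    dplyr::summarise(
      m = mean(.data[[dv]]),
      se = sd(.data[[dv]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(means, ggplot2::aes(
    x = .data$expression, y = .data$m, group = .data[[trace]],
    colour = .data[[trace]])) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$se,
                                          ymax = .data$m + .data$se)) +
    ggplot2::facet_wrap(~participant_gender) +
    ggplot2::labs(y = dv, x = "expression")
}
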