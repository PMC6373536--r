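#' Label a Bayes factor with its Jeffreys evidence band
#'
#' Bands for `bf10 > 1` (evidence against the null): (1, 3.2] anecdotal,
#' (3.2, 10] moderate, (10, 100] strong, (100, Inf) decisive — boundary
#' points fall in the lower band. A `bf10 < 1` favours the null and is
#' labelled by banding its reciprocal with a `"null-"` prefix; `bf10 = 1`
#' is `"no evidence"`.
#'
#' @param bf10 Positive Bayes factor(s) for the alternative over the null.
#' @return Character vector of labels.
#' @examples
#' classify_bf(c(8.72, 17, 3.66, 0.26))
#' @export
classify_bf <- function(bf10) {
  if (any(is.na(bf10)) || any(bf10 <= 0)) {
    stop("`bf10` must be positive.", call. = FALSE)
  }
  band <- function(b) {
    dplyr::case_when(
      b <= 3.2 ~ "anecdotal",
      b <= 10 ~ "moderate",
      b <= 100 ~ "strong",
      TRUE ~ "decisive"
    )
  }
  dplyr::case_when(
    bf10 > 1 ~ band(bf10),
    bf10 < 1 ~ paste0("null-", band(1 / bf10)),
    TRUE ~ "no evidence"
  )
}

#' One-sample JZS Bayes factor
#'
#' Bayes factor for a non-zero mean of `differences` against the point
#' null, under the Jeffreys-Zellner-Siow prior: a Cauchy(0, `rscale`)
#' prior on the standardised effect and Jeffreys prior on the variance.
#' Computed by one-dimensional adaptive quadrature (relative tolerance
#' 1e-8) of the marginal likelihood in the inverse-gamma mixture
#' representation of the Cauchy prior.
#'
#' @param differences Numeric vector (e.g. paired differences), `n >= 2`,
#'   non-zero variance.
#' @param rscale Cauchy prior scale on the standardised effect; the
#'   conventional default is `sqrt(2)/2`.
#' @return The Bayes factor `bf10` (alternative over null).
#' @examples
#' jzs_ttest_bf(c(0.3, 0.5, 0.2, 0.4, 0.6, 0.1, 0.35, 0.45))
#' @export
jzs_ttest_bf <- function(differences, rscale = sqrt(2) / 2) {
  x <- differences[is.finite(differences)]
  n <- length(x)
  if (n < 2) stop("Need at least two observations.", call. = FALSE)
  sdx <- sd(x)
  if (sdx == 0) stop("Zero-variance input: t statistic undefined.",
                     call. = FALSE)
  tstat <- mean(x) / (sdx / sqrt(n))
  nu <- n - 1
  # delta | g ~ N(0, g rscale^2), g ~ InvGamma(1/2, 1/2)
  integrand <- function(g) {
    q <- 1 + n * g * rscale^2
    exp(-0.5 * log(q) -
          (nu + 1) / 2 * log1p(tstat^2 / (q * nu)) -
          0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g))
  }
  num <- integrate(integrand, 0, Inf, rel.tol = 1e-8,
                   abs.tol = 0)$value
  den <- exp(-(nu + 1) / 2 * log1p(tstat^2 / nu))
  num / den
}

#' Narrowest interval containing a given posterior mass
#'
#' Highest-density interval of a unimodal sample by the sorted-window scan:
#' among all windows containing `cred` of the sorted draws, the shortest.
#'
#' @param draws Numeric vector of posterior draws.
#' @param cred Credibility mass, default 0.95.
#' @return Numeric length-2 `(lower, upper)`.
#' @export
hdi <- function(draws, cred = 0.95) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  k <- max(1L, ceiling(cred * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Standardised paired effect size with highest-density interval
#'
#' The point estimate is `dz = mean(differences) / sd(differences)`. The
#' posterior of `dz = mu/sigma` under a normal likelihood with the Jeffreys
#' reference prior on `(mu, sigma^2)` is sampled analytically:
#' `sigma^2 | data ~ (n-1) s^2 / chisq(n-1)` and
#' `mu | sigma^2, data ~ N(xbar, sigma^2/n)`. The HDI is the narrowest
#' interval containing `cred` of the `mu/sigma` draws.
#'
#' @inheritParams jzs_ttest_bf
#' @param cred Credibility mass of the interval.
#' @param draws Number of analytic posterior draws.
#' @param seed Optional integer seed (the draws are seed-deterministic).
#' @return A one-row tibble: `dz`, `hdi_low`, `hdi_high`, `bf10` (the JZS
#'   Bayes factor of the same differences).
#' @export
effect_size_hdi <- function(differences, cred = 0.95, draws = 1e5,
                            seed = NULL) {
  x <- differences[is.finite(differences)]
  n <- length(x)
  if (n < 2) stop("Need at least two observations.", call. = FALSE)
  s2 <- var(x)
  if (s2 == 0) stop("Zero-variance input.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sig2 <- (n - 1) * s2 / rchisq(draws, n - 1)
  mu <- rnorm(draws, mean(x), sqrt(sig2 / n))
  dz_draws <- mu / sqrt(sig2)
  h <- hdi(dz_draws, cred)
  tibble::tibble(dz = mean(x) / sqrt(s2), hdi_low = h[1], hdi_high = h[2],
                 bf10 = jzs_ttest_bf(x))
}

sum_col <- function(data, f) {
  # +1 for the alphabetically first level, -1 for the second
  lv <- sort(unique(as.character(data[[f]])))
  if (length(lv) != 2) {
    stop("Factor `", f, "` must have exactly 2 levels.", call. = FALSE)
  }
  ifelse(data[[f]] == lv[1], 1, -1)
}

#' Bayes-factor ANOVA over all design terms of a cell-statistic table
#'
#' For a per-participant, per-cell statistic (median RT, drift rate,
#' boundary separation, non-decision time, ...), quantifies the evidence
#' for every main effect and interaction of the mixed
#' 2 (expression) x 2 (response) x 2 (face-gender) x 2 (participant-gender)
#' design. Each term is compared on its own against a null model containing
#' only a participant random intercept: both models are fitted by maximum
#' likelihood ([lme4::lmer()]) and the Bayes factor is the BIC
#' approximation `bf10 = exp((BIC_null - BIC_term) / 2)`. With sum-coded
#' two-level factors every term is a single column, so "null + term" is
#' well defined without marginality constraints.
#'
#' @param stat_table Tibble with columns `participant_id`,
#'   `participant_gender`, the within factors and the statistic; must be
#'   balanced (exactly one value per participant x within-cell).
#' @param dv Name of the statistic column.
#' @param between Between-participant factor name.
#' @param within Character vector of within-participant factor names.
#' @return A tibble sorted by decreasing `bf10`: `dv`, `term`, `bf10`,
#'   `label`, `method`.
#' @export
run_bayes_anova <- function(stat_table, dv,
                            between = "participant_gender",
                            within = c("expression", "required_response",
                                       "face_gender")) {
  factors <- c(within, between)
  stopifnot(all(c("participant_id", factors, dv) %in% names(stat_table)))
  counts <- stat_table |>
    dplyr::count(.data$participant_id,
                 dplyr::across(dplyr::all_of(within)))
  cells_per <- stat_table |>
    dplyr::count(.data$participant_id)
  expected <- prod(purrr::map_int(within,
                                  ~ length(unique(stat_table[[.x]]))))
  if (any(counts$n != 1) || any(cells_per$n != expected)) {
    offenders <- unique(c(
      counts$participant_id[counts$n != 1],
      cells_per$participant_id[cells_per$n != expected]))
    stop("Unbalanced cell table for participants: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  if (anyNA(stat_table[[dv]])) {
    stop("Missing values in `", dv, "`.", call. = FALSE)
  }

  codes <- purrr::map(setNames(factors, factors),
                      ~ sum_col(stat_table, .x))
  terms <- unlist(purrr::map(seq_along(factors),
                             ~ utils::combn(factors, .x, simplify = FALSE)),
                  recursive = FALSE)

  df <- tibble::tibble(value = stat_table[[dv]],
                       participant_id = stat_table$participant_id)
  null_fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | participant_id), data = df, REML = FALSE)))
  bic0 <- stats::BIC(null_fit)

  res <- purrr::map_dfr(terms, function(tm) {
    df$x <- Reduce(`*`, codes[tm])
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ x + (1 | participant_id), data = df,
                 REML = FALSE)))
    tibble::tibble(term = paste(tm, collapse = ":"),
                   bf10 = exp((bic0 - stats::BIC(fit)) / 2))
  })
  res |>
    dplyr::mutate(dv = dv, label = classify_bf(.data$bf10),
                  method = "bic-approx", .before = 1) |>
    dplyr::select("dv", "term", "bf10", "label", "method") |>
    dplyr::arrange(dplyr::desc(.data$bf10))
}

#' Simple-interaction follow-up within one participant-gender group
#'
#' Restricts a cell-statistic table to one gender group, collapses to the
#' 2 x 2 expression-by-`pair_factor` means per participant, and computes
#' (a) the within-subject interaction Bayes factor — a JZS one-sample test
#' on the per-participant double-difference contrast — and (b) the paired
#' per-expression contrasts (first level minus second level of
#' `pair_factor`) with standardised effect sizes and HDIs.
#'
#' @inheritParams run_bayes_anova
#' @param group Level of `participant_gender` to analyse.
#' @param pair_factor The second factor of the 2 x 2: `required_response`
#'   (push minus pull) or `face_gender` (male minus female).
#' @param seed Optional seed for the HDI draws.
#' @return A list with `interaction` (one-row tibble: `bf10`, `label`,
#'   `method`) and `contrasts` (one row per expression: `contrast`, `dz`,
#'   `hdi_low`, `hdi_high`, `bf10`, `label`).
#' @export
simple_interaction_followup <- function(stat_table, group, dv,
                                        pair_factor = "required_response",
                                        seed = NULL) {
  stopifnot(pair_factor %in% c("required_response", "face_gender"))
  if (!group %in% stat_table$participant_gender) {
    stop("Group `", group, "` not present in the table.", call. = FALSE)
  }
  lv <- if (pair_factor == "required_response") c("push", "pull")
        else c("male", "female")
  cells <- stat_table |>
    dplyr::filter(.data$participant_gender == group) |>
    dplyr::group_by(.data$participant_id, .data$expression,
                    .data[[pair_factor]]) |>
    dplyr::summarise(value = mean(.data[[dv]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(c("expression",
                                                    pair_factor)),
                       values_from = "value")

  first <- function(expr) cells[[paste(expr, lv[1], sep = "_")]]
  second <- function(expr) cells[[paste(expr, lv[2], sep = "_")]]
  d_angry <- first("angry") - second("angry")
  d_happy <- first("happy") - second("happy")
  inter <- d_angry - d_happy
  if (sd(inter) == 0 || sd(d_angry) == 0 || sd(d_happy) == 0) {
    stop("Zero-variance contrast in group `", group,
         "`: all cell values identical.", call. = FALSE)
  }

  bf_int <- jzs_ttest_bf(inter)
  contrasts <- dplyr::bind_rows(
    dplyr::mutate(effect_size_hdi(d_angry, seed = seed),
                  contrast = paste0("angry: ", lv[1], " - ", lv[2]),
                  .before = 1),
    dplyr::mutate(effect_size_hdi(d_happy, seed = seed),
                  contrast = paste0("happy: ", lv[1], " - ", lv[2]),
                  .before = 1)
  ) |>
    dplyr::mutate(label = classify_bf(.data$bf10))

  list(
    interaction = tibble::tibble(
      dv = dv, group = group,
      term = paste0("expression:", pair_factor),
      bf10 = bf_int, label = classify_bf(bf_int), method = "jzs-ttest"),
    contrasts = contrasts
  )
}

#' One-way comparison of group means with partial eta squared
#'
#' Classical one-way ANOVA for a between-group comparison (used for the
#' BIS/BAS gender comparisons): F statistic, partial eta squared
#' `SS_effect / (SS_effect + SS_error)` and the F-test p value.
#'
#' @param values Numeric outcome vector.
#' @param groups Group membership vector (2+ levels, each with n >= 2).
#' @return One-row tibble: `f`, `df1`, `df2`, `eta_p_sq`, `p`.
#' @export
compare_group_means <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("Need at least two groups.", call. = FALSE)
  if (any(table(g) < 2)) stop("Each group needs n >= 2.", call. = FALSE)
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  ss_eff <- tab["g", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  f <- tab["g", "F value"]
  tibble::tibble(
    f = f,
    df1 = tab["g", "Df"],
    df2 = tab["Residuals", "Df"],
    eta_p_sq = ss_eff / (ss_eff + ss_err),
    p = tab["g", "Pr(>F)"]
  )
}
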