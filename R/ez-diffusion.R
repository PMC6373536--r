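#' EZ-diffusion forward map: parameters to observable moments
#'
#' Maps drift rate, boundary separation and non-decision time to the three
#' population summary statistics of the symmetric-start Wiener process:
#' proportion correct `pc`, mean of correct response times `mrt_s` (seconds)
#' and variance of correct response times `vrt_s2` (seconds squared). With
#' an unbiased start and no trial-to-trial parameter variability the correct
#' and error decision-time distributions coincide, so the moments apply to
#' either response stream.
#'
#' Writing `y = exp(-v a / s^2)`:
#' `pc = 1/(1+y)`; mean decision time `MDT = (a/(2v)) (1-y)/(1+y)`;
#' `mrt = ter + MDT`; and with `w = -v a / s^2`,
#' `vrt = (a s^2 / (2 v^3)) (2 w e^w - e^{2w} + 1) / (e^w + 1)^2`.
#'
#' @param v Drift rate; must be non-zero (at `v = 0` the moments are
#'   undefined and `pc` would be exactly 0.5).
#' @param a Boundary separation (> 0).
#' @param ter Non-decision time, seconds.
#' @param s Noise scaling (> 0).
#' @return A tibble with columns `pc`, `mrt_s`, `vrt_s2`. Vectorised over
#'   parameters.
#' @examples
#' ez_forward(v = 2.16, a = 1.2, ter = 0.3)
#' @seealso [ez_inverse()] for the exact algebraic inverse.
#' @export
ez_forward <- function(v, a, ter, s = 1) {
  n <- max(length(v), length(a), length(ter), length(s))
  v <- rep_len(v, n); a <- rep_len(a, n)
  ter <- rep_len(ter, n); s <- rep_len(s, n)
  if (any(v == 0)) {
    stop("Moments are undefined at v = 0 (pc would be exactly 0.5).",
         call. = FALSE)
  }
  if (any(a <= 0) || any(s <= 0)) {
    stop("`a` and `s` must be positive.", call. = FALSE)
  }
  w <- -v * a / s^2
  y <- exp(w)
  pc <- 1 / (1 + y)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  vrt <- (a * s^2 / (2 * v^3)) * (2 * w * y - y^2 + 1) / (y + 1)^2
  tibble::tibble(pc = pc, mrt_s = ter + mdt, vrt_s2 = vrt)
}

#' Edge-correct an observed proportion correct
#'
#' The EZ inverse is undefined at `pc` of exactly 0, 0.5 or 1. Observed
#' cells regularly produce `pc = 1` (a perfect 32-trial cell), so these
#' edge values are nudged by the minimal-perturbation convention `1/(2n)`:
#' `pc = 1` becomes `1 - 1/(2n)`, `pc = 0` becomes `1/(2n)` and `pc = 0.5`
#' becomes `0.5 + 1/(2n)`.
#'
#' @param pc Observed proportion(s) correct in \[0, 1\].
#' @param n Number of trials behind each proportion.
#' @return A tibble with the corrected `pc` and a logical `corrected` flag.
#'   Vectorised.
#' @examples
#' edge_correct(1, 32)   # 1 - 1/64
#' edge_correct(0.93, 32)
#' @export
edge_correct <- function(pc, n) {
  k <- max(length(pc), length(n))
  pc <- rep_len(pc, k); n <- rep_len(n, k)
  stopifnot(all(pc >= 0 & pc <= 1), all(n >= 1))
  corrected <- pc == 0 | pc == 0.5 | pc == 1
  out <- pc
  out[pc == 1] <- 1 - 1 / (2 * n[pc == 1])
  out[pc == 0] <- 1 / (2 * n[pc == 0])
  out[pc == 0.5] <- 0.5 + 1 / (2 * n[pc == 0.5])
  tibble::tibble(pc = out, corrected = corrected)
}

#' EZ-diffusion inverse: observed moments to parameter estimates
#'
#' Exact algebraic inverse of [ez_forward()]. With `L = logit(pc)`:
#' `v = sign(pc - 1/2) s ((L (L pc^2 - L pc + pc - 1/2)) / vrt)^{1/4}`,
#' `a = s^2 L / v`, and `ter = mrt - MDT(v, a)`.
#'
#' @param pc Proportion correct, strictly inside (0, 1) and not equal to
#'   0.5; apply [edge_correct()] first for observed edge cells.
#' @param mrt_s Mean of correct response times, seconds.
#' @param vrt_s2 Variance of correct response times, seconds squared
#'   (> 0).
#' @param s Noise scaling used for the estimates.
#' @return A tibble with columns `v`, `a`, `ter`. Vectorised.
#' @examples
#' m <- ez_forward(1.85, 1.2, 0.3)
#' ez_inverse(m$pc, m$mrt_s, m$vrt_s2)  # recovers (1.85, 1.2, 0.3)
#' @export
ez_inverse <- function(pc, mrt_s, vrt_s2, s = 1) {
  k <- max(length(pc), length(mrt_s), length(vrt_s2), length(s))
  pc <- rep_len(pc, k); mrt_s <- rep_len(mrt_s, k)
  vrt_s2 <- rep_len(vrt_s2, k); s <- rep_len(s, k)
  if (any(pc <= 0 | pc >= 1 | pc == 0.5)) {
    stop("`pc` must lie strictly inside (0, 1) and differ from 0.5; ",
         "apply edge_correct() to observed edge cells first.",
         call. = FALSE)
  }
  if (any(vrt_s2 <= 0)) {
    stop("`vrt_s2` must be positive.", call. = FALSE)
  }
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt_s2
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  tibble::tibble(v = v, a = a, ter = mrt_s - mdt)
}

#' Estimate EZ-diffusion parameters for every participant-by-cell summary
#'
#' Applies [edge_correct()] then [ez_inverse()] to each row of a
#' cell-summary table (see [summarize_cells()]). Degenerate cells — fewer
#' than two correct trials, zero response-time variance, or a proportion
#' correct that is still 0.5 after correction — are kept in the output with
#' `NA` parameters and `degenerate = TRUE` rather than dropped.
#'
#' Negative `ter` estimates (possible in small cells) are retained and
#' flagged via `ter < 0`, never clamped: clamping would bias the
#' downstream ANOVAs.
#'
#' @param summaries Cell-summary tibble from [summarize_cells()].
#' @param s Noise scaling threaded through all estimates.
#' @return A tibble with the identifying columns of `summaries` plus `v`,
#'   `a`, `ter`, `s`, `edge_corrected`, `degenerate` and `n_basis` (number
#'   of trials behind the estimate).
#' @examples
#' sc <- default_scenario(n_participants_per_gender = 2, seed = 7)
#' d <- generate_dataset(sc)
#' cells <- summarize_cells(filter_rts(d$trials)$trials)
#' estimate_all(cells)
#' @export
estimate_all <- function(summaries, s = 1) {
  stopifnot(all(c("pc", "mrt_s", "vrt_s2", "n_total") %in% names(summaries)))
  ec <- edge_correct(summaries$pc, summaries$n_total)
  pc <- ec$pc
  bad <- summaries$n_correct < 2 | !is.finite(summaries$vrt_s2) |
    summaries$vrt_s2 <= 0 | pc == 0.5 | pc <= 0 | pc >= 1
  est <- tibble::tibble(v = rep(NA_real_, nrow(summaries)),
                        a = NA_real_, ter = NA_real_)
  if (any(!bad)) {
    est[!bad, ] <- ez_inverse(pc[!bad], summaries$mrt_s[!bad],
                              summaries$vrt_s2[!bad], s = s)
  }
  id_cols <- setdiff(names(summaries),
                     c("pc", "mrt_s", "vrt_s2", "median_rt_ms",
                       "n_total", "n_correct", "degenerate"))
  dplyr::bind_cols(
    summaries[id_cols],
    est,
    tibble::tibble(s = s,
                   edge_corrected = ec$corrected,
                   degenerate = bad,
                   n_basis = summaries$n_total)
  )
}
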