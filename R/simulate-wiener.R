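#' Construct a set of Wiener diffusion parameters
#'
#' Bundles the three free parameters of the simplified (EZ) diffusion
#' decision model with the noise scaling `s`. The starting point is always
#' the unbiased `z = a/2`; it is never a free parameter here.
#'
#' @param v Drift rate (evidence units per second). Positive drift favours
#'   the upper ("correct") boundary.
#' @param a Boundary separation (evidence units); must be positive.
#' @param ter Non-decision time in seconds (stimulus encoding plus motor
#'   execution); must be non-negative.
#' @param s Within-trial noise standard deviation (evidence per sqrt-second).
#'   The conventional scaling here is `s = 1`.
#'
#' @return A list of class `diffusion_params` with elements `v`, `a`, `ter`,
#'   `s` and the implied starting point `z = a/2`.
#' @examples
#' diffusion_params(v = 2.16, a = 1.2, ter = 0.3)
#' @export
diffusion_params <- function(v, a, ter, s = 1) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    stop("`a` (boundary separation) must be a single positive number.",
         call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s <= 0) {
    stop("`s` (noise scaling) must be a single positive number.",
         call. = FALSE)
  }
  if (!is.numeric(ter) || length(ter) != 1 || !is.finite(ter) || ter < 0) {
    stop("`ter` (non-decision time) must be a single non-negative number.",
         call. = FALSE)
  }
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
    stop("`v` (drift rate) must be a single finite number.", call. = FALSE)
  }
  structure(list(v = v, a = a, ter = ter, s = s, z = a / 2),
            class = "diffusion_params")
}

#' Simulate first-passage times of the two-boundary Wiener process
#'
#' Draws choice/response-time pairs from a symmetric-start diffusion process
#' `dX = v dt + s sqrt(dt) N(0,1)` starting at `z = a/2`, absorbed at 0 or
#' `a`. The response time is the first-passage time plus the non-decision
#' time `ter`. Sampling uses an Euler-Maruyama scheme with the
#' Brownian-bridge within-step crossing correction, so hitting probabilities
#' and passage-time moments agree with the closed forms of [ez_forward()]
#' to well within Monte-Carlo error at the default step size.
#'
#' @param params A [diffusion_params()] object (or a list with elements
#'   `v`, `a`, `ter`, `s`).
#' @param n_trials Number of trials to simulate (positive integer).
#' @param seed Optional integer seed set before sampling.
#' @param dt Time step of the integrator, seconds.
#' @param max_time Maximum decision time simulated per trial, seconds;
#'   rarely-hit censoring guard.
#'
#' @return A tibble with one row per trial: `rt_ms` (response time in
#'   milliseconds, including non-decision time) and `hit_upper` (logical;
#'   `TRUE` when the process was absorbed at the upper boundary, which is
#'   the "correct" boundary when `v > 0`).
#' @examples
#' simulate_rts(diffusion_params(2.16, 1.2, 0.3), n_trials = 10, seed = 1)
#' @export
simulate_rts <- function(params, n_trials, seed = NULL, dt = 5e-4,
                         max_time = 10) {
  if (!is.list(params) || !all(c("v", "a", "ter", "s") %in% names(params))) {
    stop("`params` must contain elements v, a, ter and s.", call. = FALSE)
  }
  if (params$a <= 0 || params$s <= 0) {
    stop("Invalid diffusion parameters: `a` and `s` must be positive.",
         call. = FALSE)
  }
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1) {
    stop("`n_trials` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) {
    stop("`dt` must be positive.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_wiener_cpp(as.integer(n_trials), params$v, params$a,
                        params$a / 2, params$ter, params$s, dt, max_time)
  tibble::tibble(rt_ms = sim$rt_s * 1000, hit_upper = sim$hit_upper)
}

#' Closed-form probability of absorption at the upper boundary
#'
#' For a symmetric start (`z = a/2`) the probability that the diffusion is
#' absorbed at the upper boundary is `1 / (1 + exp(-v a / s^2))`.
#'
#' @inheritParams diffusion_params
#' @return Probability in (0, 1).
#' @keywords internal
wiener_upper_prob <- function(v, a, s = 1) {
  plogis(v * a / s^2)
}
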