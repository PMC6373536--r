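# shared fixtures, generated once per test run

.fixture_env <- new.env(parent = emptyenv())

# moderate synthetic experiment reused by several files (16 + 16
# participants keeps every within-cell at the design's 32 trials while
# staying fast)
shared_dataset <- function() {
  if (is.null(.fixture_env$dataset)) {
    .fixture_env$dataset <- generate_dataset(
      default_scenario(n_participants_per_gender = 16, seed = 20))
  }
  .fixture_env$dataset
}

shared_estimates <- function() {
  if (is.null(.fixture_env$estimates)) {
    d <- shared_dataset()
    kept <- filter_rts(exclude_participants(d$trials)$trials)$trials
    .fixture_env$kept_trials <- kept
    .fixture_env$estimates <- estimate_all(summarize_cells(kept))
  }
  .fixture_env$estimates
}

shared_kept_trials <- function() {
  shared_estimates()
  .fixture_env$kept_trials
}

# hand-built toy trial table: one participant, explicit RTs/correctness
toy_trials <- function(rt_ms, correct = TRUE, participant_id = "P01",
                       block = "main1") {
  n <- length(rt_ms)
  tibble::tibble(
    participant_id = rep_len(participant_id, n),
    participant_gender = "female",
    block = rep_len(block, n),
    mapping = "push-angry/pull-happy",
    trial_index = seq_len(n),
    stimulus_id = "m1_angry",
    expression = "angry",
    face_gender = "male",
    required_response = "push",
    observed_response = ifelse(rep_len(correct, n), "push", "pull"),
    rt_ms = rt_ms,
    correct = rep_len(correct, n)
  )
}

# independent JZS oracle: direct quadrature over the Cauchy effect-size
# prior using the noncentral-t sampling density (a different route from
# the package's inverse-gamma mixture integral)
jzs_oracle <- function(x, rscale = sqrt(2) / 2) {
  n <- length(x)
  tstat <- mean(x) / (sd(x) / sqrt(n))
  nu <- n - 1
  num <- suppressWarnings(integrate(function(delta) {
    dt(tstat, nu, ncp = sqrt(n) * delta) * dcauchy(delta, 0, rscale)
  }, -Inf, Inf, rel.tol = 1e-10)$value)
  num / dt(tstat, nu)
}
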