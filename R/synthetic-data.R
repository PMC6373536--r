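#' Generate the trial skeleton of an approach-avoidance joystick experiment
#'
#' Builds the full trial list (without responses or response times) for a
#' 2 (expression: angry/happy) x 2 (face gender) x 2 (required response:
#' push/pull) within-participant design with participant gender between.
#' Each participant receives a 16-trial practice block (one presentation of
#' each of the 16 unique face stimuli: 8 identities x 2 expressions) and two
#' 128-trial main blocks (8 repetitions of the 16 stimuli each). The
#' response mapping (push-for-angry vs push-for-happy) alternates between
#' the two main blocks; which mapping comes first is randomised per
#' participant, as is trial order within each block. The practice block uses
#' the first main block's mapping.
#'
#' @param n_participants_per_gender Number of participants in each gender
#'   group (>= 1).
#' @param seed Optional integer seed; identical seeds give identical trial
#'   lists.
#' @return A tibble with one row per trial and columns `participant_id`,
#'   `participant_gender`, `block` (practice/main1/main2), `mapping`,
#'   `trial_index`, `stimulus_id`, `expression`, `face_gender` and
#'   `required_response`.
#' @examples
#' d <- generate_design(1, seed = 1)
#' table(d$block)
#' @export
generate_design <- function(n_participants_per_gender, seed = NULL) {
  if (!is.numeric(n_participants_per_gender) ||
      length(n_participants_per_gender) != 1 ||
      n_participants_per_gender < 1) {
    stop("`n_participants_per_gender` must be a positive integer.",
         call. = FALSE)
  }
  n_per <- as.integer(n_participants_per_gender)
  if (!is.null(seed)) set.seed(seed)

  stimuli <- tidyr::expand_grid(
    identity = c(paste0("m", 1:4), paste0("f", 1:4)),
    expression = c("angry", "happy")
  ) |>
    dplyr::mutate(
      face_gender = ifelse(startsWith(.data$identity, "m"), "male", "female"),
      stimulus_id = paste(.data$identity, .data$expression, sep = "_")
    )

  ids <- c(sprintf("F%02d", seq_len(n_per)), sprintf("M%02d", seq_len(n_per)))
  genders <- rep(c("female", "male"), each = n_per)
  mappings <- c("push-angry/pull-happy", "push-happy/pull-angry")

  purrr::map2(ids, genders, function(id, pg) {
    first <- mappings[sample.int(2, 1)]
    second <- setdiff(mappings, first)
    one_block <- function(block, mapping, reps) {
      b <- stimuli[rep(seq_len(nrow(stimuli)), reps), ]
      b <- b[sample.int(nrow(b)), ]
      dplyr::mutate(b,
        participant_id = id, participant_gender = pg,
        block = block, mapping = mapping,
        trial_index = dplyr::row_number(),
        required_response = required_response_for(.data$expression, mapping)
      )
    }
    dplyr::bind_rows(
      one_block("practice", first, 1L),
      one_block("main1", first, 8L),
      one_block("main2", second, 8L)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("participant_id", "participant_gender", "block", "mapping",
                  "trial_index", "stimulus_id", "expression", "face_gender",
                  "required_response")
}

#' Required response implied by expression and block mapping
#'
#' @param expression Character vector of "angry"/"happy".
#' @param mapping Block mapping string ("push-angry/pull-happy" or
#'   "push-happy/pull-angry").
#' @return Character vector of "push"/"pull".
#' @keywords internal
required_response_for <- function(expression, mapping) {
  push_angry <- mapping == "push-angry/pull-happy"
  ifelse(xor(expression == "angry", !push_angry), "push", "pull")
}

#' Default synthetic-experiment scenario
#'
#' Ground truth for the synthetic generator, chosen so that the generated
#' data carry the qualitative structure the analysis is designed to detect:
#'
#' * Female participants show the approach-avoidance drift pattern —
#'   higher drift for angry/push (2.16) than angry/pull (1.85) and higher
#'   for happy/pull (2.31) than happy/push (2.12); the four values are the
#'   printed female condition means.
#' * Female non-decision times are lower for angry/push responses and for
#'   gender-congruent faces (angry-male, happy-female); female boundary
#'   separation is raised for angry-male faces.
#' * Male participants show only a happy > angry drift difference, with no
#'   response or face-gender modulation.
#'
#' Between-participant heterogeneity is additive on `v`, `a` and `ter`
#' (shared across that participant's cells), and BIS/BAS questionnaire
#' totals are drawn from gender-specific truncated normals whose truncated
#' means equal the printed group means.
#'
#' @param n_participants_per_gender Participants per gender group.
#' @param contaminant_rate Proportion of trials replaced by out-of-range
#'   response times (uniform on 50-199 ms or 2501-4000 ms, half each), to
#'   exercise the trimming filters; must be < 0.1.
#' @param seed Integer seed stored in the scenario and used by
#'   [generate_dataset()].
#' @return A list of class `pp_scenario`: `truth` (16-row tibble mapping
#'   participant_gender x expression x required_response x face_gender to
#'   `v`, `a`, `ter`), between-participant SDs `sd_v`, `sd_a`, `sd_ter`,
#'   noise scaling `s`, contaminant settings, `bisbas` distribution
#'   settings and `seed`.
#' @examples
#' default_scenario(seed = 1)$truth
#' @export
default_scenario <- function(n_participants_per_gender = 32,
                             contaminant_rate = 0.03, seed = NULL) {
  truth <- tidyr::expand_grid(
    participant_gender = c("female", "male"),
    expression = c("angry", "happy"),
    required_response = c("push", "pull"),
    face_gender = c("male", "female")
  ) |>
    dplyr::mutate(
      v = dplyr::case_when(
        .data$participant_gender == "female" &
          .data$expression == "angry" & .data$required_response == "push" ~ 2.16,
        .data$participant_gender == "female" &
          .data$expression == "angry" & .data$required_response == "pull" ~ 1.85,
        .data$participant_gender == "female" &
          .data$expression == "happy" & .data$required_response == "pull" ~ 2.31,
        .data$participant_gender == "female" &
          .data$expression == "happy" & .data$required_response == "push" ~ 2.12,
        .data$expression == "angry" ~ 1.90,
        TRUE ~ 2.10
      ),
      a = 1.2 + ifelse(.data$participant_gender == "female" &
                         .data$expression == "angry" &
                         .data$face_gender == "male", 0.15, 0),
      ter = 0.35 -
        ifelse(.data$participant_gender == "female" &
                 .data$expression == "angry" &
                 .data$required_response == "push", 0.03, 0) -
        ifelse(.data$participant_gender == "female" &
                 ((.data$expression == "angry" & .data$face_gender == "male") |
                  (.data$expression == "happy" & .data$face_gender == "female")),
               0.03, 0)
    )
  scenario_config(
    n_participants_per_gender = n_participants_per_gender,
    truth = truth,
    sd_v = 0.40, sd_a = 0.12, sd_ter = 0.04, s = 1,
    contaminant_rate = contaminant_rate,
    contaminant_bounds_ms = c(50, 199, 2501, 4000),
    bisbas = list(
      bis = list(female = c(mean = 23.32, sd = 3.09),
                 male = c(mean = 19.29, sd = 4.21),
                 range = c(7, 28)),
      bas = list(female = c(mean = 12.48, sd = 2.33),
                 male = c(mean = 13.30, sd = 2.33),
                 range = c(4, 28))
    ),
    seed = seed
  )
}

#' Assemble and validate a synthetic-experiment scenario
#'
#' @inheritParams default_scenario
#' @param truth Tibble with one row per
#'   participant_gender x expression x required_response x face_gender
#'   combination (16 rows) and columns `v`, `a`, `ter`.
#' @param sd_v,sd_a,sd_ter Between-participant SDs of additive offsets on
#'   the condition parameters.
#' @param s Noise scaling of the diffusion process.
#' @param contaminant_bounds_ms Numeric length-4: low tail (min, max) and
#'   high tail (min, max) of the contaminant response-time ranges, ms.
#' @param bisbas Gender-specific mean/sd/range settings for the BIS and BAS
#'   questionnaire totals.
#' @return A validated list of class `pp_scenario`.
#' @export
scenario_config <- function(n_participants_per_gender, truth,
                            sd_v = 0.4, sd_a = 0.12, sd_ter = 0.04, s = 1,
                            contaminant_rate = 0.03,
                            contaminant_bounds_ms = c(50, 199, 2501, 4000),
                            bisbas = NULL, seed = NULL) {
  needed <- tidyr::expand_grid(
    participant_gender = c("female", "male"),
    expression = c("angry", "happy"),
    required_response = c("push", "pull"),
    face_gender = c("male", "female")
  )
  found <- dplyr::semi_join(
    needed, truth,
    by = c("participant_gender", "expression", "required_response",
           "face_gender"))
  if (nrow(found) < nrow(needed)) {
    missing <- dplyr::anti_join(
      needed, truth,
      by = c("participant_gender", "expression", "required_response",
             "face_gender"))
    stop("Scenario truth table is missing ", nrow(missing),
         " condition combination(s), e.g. ",
         paste(unlist(missing[1, ]), collapse = "/"), call. = FALSE)
  }
  stopifnot(all(truth$a > 0), all(truth$ter >= 0), s > 0)
  if (contaminant_rate < 0 || contaminant_rate >= 0.1) {
    stop("`contaminant_rate` must lie in [0, 0.1).", call. = FALSE)
  }
  structure(list(
    n_participants_per_gender = as.integer(n_participants_per_gender),
    truth = truth, sd_v = sd_v, sd_a = sd_a, sd_ter = sd_ter, s = s,
    contaminant_rate = contaminant_rate,
    contaminant_bounds_ms = contaminant_bounds_ms,
    bisbas = bisbas, seed = seed
  ), class = "pp_scenario")
}

#' Draw from a truncated normal whose *truncated* mean hits a target
#'
#' Questionnaire totals live on a bounded range, so a naive truncated
#' normal undershoots the target mean whenever the target sits near a
#' bound. The underlying (pre-truncation) mean is solved with [uniroot()]
#' so that the mean after truncation equals `mean`; the stated `sd` is used
#' as the underlying scale.
#'
#' @param n Number of draws.
#' @param mean Target mean of the truncated distribution.
#' @param sd Underlying normal standard deviation.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of draws in `[lo, hi]`.
#' @keywords internal
rtruncnorm_calibrated <- function(n, mean, sd, lo, hi) {
  trunc_mean <- function(mu) {
    al <- (lo - mu) / sd; be <- (hi - mu) / sd
    z <- pnorm(be) - pnorm(al)
    if (z < 1e-12) return(if (mu > hi) hi else lo)  # fully truncated tail
    mu + sd * (dnorm(al) - dnorm(be)) / z
  }
  if (mean <= lo || mean >= hi) {
    stop("Target mean must lie strictly inside the truncation range.",
         call. = FALSE)
  }
  mu <- uniroot(function(m) trunc_mean(m) - mean,
                interval = c(lo - 10 * sd, hi + 10 * sd))$root
  p_lo <- pnorm(lo, mu, sd); p_hi <- pnorm(hi, mu, sd)
  qnorm(runif(n, p_lo, p_hi), mu, sd)
}

#' Draw BIS/BAS questionnaire totals for a set of participants
#'
#' BIS totals (7 items, range 7-28) and BAS totals are drawn from
#' gender-specific mean-calibrated truncated normals and rounded to integer
#' scores. The BAS total is split into Drive, Fun-Seeking and Reward
#' subtotals (4/13, 4/13, 5/13 shares, rounded) that sum exactly to the
#' total.
#'
#' @param participant_id,participant_gender Parallel vectors.
#' @param bisbas The `bisbas` settings of a [scenario_config()].
#' @return Tibble with `participant_id`, `participant_gender`, `bis`,
#'   `bas`, `bas_drive`, `bas_fun`, `bas_reward`.
#' @keywords internal
draw_bisbas <- function(participant_id, participant_gender, bisbas) {
  out <- tibble::tibble(participant_id = participant_id,
                        participant_gender = participant_gender,
                        bis = NA_real_, bas = NA_real_)
  for (g in c("female", "male")) {
    idx <- participant_gender == g
    if (!any(idx)) next
    bi <- bisbas$bis; ba <- bisbas$bas
    out$bis[idx] <- round(rtruncnorm_calibrated(
      sum(idx), bi[[g]]["mean"], bi[[g]]["sd"], bi$range[1], bi$range[2]))
    out$bas[idx] <- round(rtruncnorm_calibrated(
      sum(idx), ba[[g]]["mean"], ba[[g]]["sd"], ba$range[1], ba$range[2]))
  }
  out |>
    dplyr::mutate(
      bas_drive = round(.data$bas * 4 / 13),
      bas_fun = round(.data$bas * 4 / 13),
      bas_reward = .data$bas - .data$bas_drive - .data$bas_fun
    )
}

#' Generate a complete synthetic experiment
#'
#' Builds the trial skeleton with [generate_design()], draws per-participant
#' diffusion parameters (condition means from the scenario truth table plus
#' participant-level additive offsets), simulates every trial's response
#' time and choice with [simulate_rts()], maps boundary hits to observed
#' responses (upper boundary = required response), injects contaminant
#' response times outside the trimming range, and draws BIS/BAS totals.
#'
#' @param scenario A [scenario_config()] / [default_scenario()] object.
#' @param dt Integrator step passed to [simulate_rts()].
#' @return A list with `trials` (tibble of trial records, including
#'   `observed_response`, `rt_ms`, `correct`) and `participants` (tibble of
#'   participant profiles with BIS/BAS totals and the participant's drawn
#'   parameter offsets).
#' @examples
#' d <- generate_dataset(default_scenario(n_participants_per_gender = 2,
#'                                        seed = 42))
#' head(d$trials)
#' @export
generate_dataset <- function(scenario, dt = 5e-4) {
  stopifnot(inherits(scenario, "pp_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)

  design <- generate_design(scenario$n_participants_per_gender)
  participants <- design |>
    dplyr::distinct(.data$participant_id, .data$participant_gender)

  profiles <- draw_bisbas(participants$participant_id,
                          participants$participant_gender,
                          scenario$bisbas) |>
    dplyr::mutate(
      offset_v = rnorm(dplyr::n(), 0, scenario$sd_v),
      offset_a = rnorm(dplyr::n(), 0, scenario$sd_a),
      offset_ter = rnorm(dplyr::n(), 0, scenario$sd_ter)
    )

  # participant x condition parameter table; floors keep rare extreme
  # offsets inside the parameter space without shifting typical draws
  partab <- profiles |>
    dplyr::select("participant_id", "participant_gender", "offset_v",
                  "offset_a", "offset_ter") |>
    dplyr::inner_join(scenario$truth, by = "participant_gender",
                      relationship = "many-to-many") |>
    dplyr::mutate(
      v = .data$v + .data$offset_v,
      a = pmax(.data$a + .data$offset_a, 0.3),
      ter = pmax(.data$ter + .data$offset_ter, 0.05)
    )

  keys <- c("participant_id", "expression", "required_response",
            "face_gender")
  design <- dplyr::arrange(design, .data$participant_id, .data$block,
                           .data$trial_index)
  grouped <- design |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split()
  simulated <- purrr::map(grouped, function(g) {
    p <- dplyr::semi_join(partab, g[1, keys], by = keys)
    sim <- simulate_rts(list(v = p$v, a = p$a, ter = p$ter, s = scenario$s),
                        n_trials = nrow(g), dt = dt)
    dplyr::mutate(g,
      observed_response = ifelse(sim$hit_upper, .data$required_response,
                                 ifelse(.data$required_response == "push",
                                        "pull", "push")),
      rt_ms = sim$rt_ms,
      correct = sim$hit_upper
    )
  })
  trials <- dplyr::bind_rows(simulated) |>
    dplyr::arrange(.data$participant_id,
                   factor(.data$block, c("practice", "main1", "main2")),
                   .data$trial_index)

  if (scenario$contaminant_rate > 0) {
    b <- scenario$contaminant_bounds_ms
    is_cont <- runif(nrow(trials)) < scenario$contaminant_rate
    low_tail <- runif(nrow(trials)) < 0.5
    cont_rt <- ifelse(low_tail, runif(nrow(trials), b[1], b[2]),
                      runif(nrow(trials), b[3], b[4]))
    trials$rt_ms[is_cont] <- cont_rt[is_cont]
  }

  list(trials = trials, participants = profiles)
}
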