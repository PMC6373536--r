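trial_csv_cols <- c("participant_id", "participant_gender", "block",
                    "mapping", "trial_index", "stimulus_id", "expression",
                    "face_gender", "required_response", "observed_response",
                    "rt_ms", "correct")

#' Write / read the canonical trial CSV
#'
#' The canonical schema has one row per trial with columns
#' `participant_id, participant_gender, block, mapping, trial_index,
#' stimulus_id, expression, face_gender, required_response,
#' observed_response, rt_ms, correct`. Writing is deterministic
#' (byte-identical files for identical tibbles); reading validates the
#' header, parses `rt_ms` as a positive number and reports malformed rows
#' by line number. Unknown extra columns are preserved.
#'
#' @param trials Trial tibble in the canonical schema.
#' @param path File path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` returns the trial tibble.
#' @export
write_trials_csv <- function(trials, path) {
  missing <- setdiff(trial_csv_cols, names(trials))
  if (length(missing) > 0) {
    stop("Trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ordered <- trials[c(trial_csv_cols,
                      setdiff(names(trials), trial_csv_cols))]
  readr::write_csv(ordered, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  out <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      participant_gender = readr::col_character(),
      block = readr::col_character(),
      mapping = readr::col_character(),
      trial_index = readr::col_integer(),
      stimulus_id = readr::col_character(),
      expression = readr::col_character(),
      face_gender = readr::col_character(),
      required_response = readr::col_character(),
      observed_response = readr::col_character(),
      rt_ms = readr::col_double(),
      correct = readr::col_logical(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE, lazy = FALSE
  ))
  missing <- setdiff(trial_csv_cols, names(out))
  if (length(missing) > 0) {
    stop("File ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("Malformed rows in ", path, " at line(s): ",
         paste(unique(probs$row + 1), collapse = ", "),
         " (e.g. ", probs$expected[1], " got '", probs$actual[1], "')",
         call. = FALSE)
  }
  if (nrow(out) > 0 && any(!is.na(out$rt_ms) & out$rt_ms <= 0)) {
    stop("Non-positive rt_ms values in ", path, call. = FALSE)
  }
  out
}

#' Deterministic stage sub-seed
#'
#' Derives an integer seed below 2^31 from the master seed and a stage
#' name, so that adding a pipeline stage never perturbs the random streams
#' of earlier stages.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @keywords internal
stage_seed <- function(master, stage) {
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Assemble and validate a pipeline configuration
#'
#' @param mode `"synthetic"` (generate data from `scenario`) or `"csv"`
#'   (read `trials_path`/`participants_path`).
#' @param scenario A [scenario_config()] for synthetic mode.
#' @param trials_path,participants_path Input CSV paths for csv mode.
#' @param s Diffusion noise scaling used in estimation.
#' @param lo_ms,hi_ms Response-time trimming bounds, ms.
#' @param error_threshold Participant exclusion threshold.
#' @param n_sim Posterior-predictive trials per cell.
#' @param hdi_draws Posterior draws behind each effect-size HDI.
#' @param seed Master integer seed (mandatory in synthetic mode).
#' @param out_dir Output directory (created if needed).
#' @return A validated list of class `pp_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv"),
                            scenario = default_scenario(),
                            trials_path = NULL, participants_path = NULL,
                            s = 1, lo_ms = 200, hi_ms = 2500,
                            error_threshold = 0.45, n_sim = 10000,
                            hdi_draws = 1e5, seed = NULL,
                            out_dir = tempfile("pushpull-run-")) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    stopifnot(inherits(scenario, "pp_scenario"))
    if (is.null(seed)) {
      stop("`seed` is mandatory in synthetic mode.", call. = FALSE)
    }
  } else {
    if (is.null(trials_path) || !file.exists(trials_path)) {
      stop("`trials_path` must point to an existing file in csv mode.",
           call. = FALSE)
    }
    if (!is.null(participants_path) && !file.exists(participants_path)) {
      stop("`participants_path` does not exist.", call. = FALSE)
    }
    if (is.null(seed)) seed <- 1L
  }
  structure(list(mode = mode, scenario = scenario,
                 trials_path = trials_path,
                 participants_path = participants_path,
                 s = s, lo_ms = lo_ms, hi_ms = hi_ms,
                 error_threshold = error_threshold, n_sim = n_sim,
                 hdi_draws = hdi_draws, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pp_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or CSV
#' reading), participant exclusion (on untrimmed error rates),
#' response-time trimming, cell summarisation, EZ parameter estimation,
#' Bayes-factor ANOVAs for median RT and the three diffusion parameters
#' with gender-specific simple-interaction follow-ups, the binomial GEE
#' accuracy model, ex-Gaussian BIS/BAS regressions (when participant
#' covariates are available) and the posterior-predictive fit assessment.
#' Writes tidy CSVs for every stage product, a JSON run manifest and a
#' markdown report into `out_dir`. Every stochastic stage consumes a
#' sub-seed derived from the master seed and the stage name.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with all stage products (`trials`,
#'   `participants`, `excluded`, `removed_proportion`, `cells`,
#'   `estimates`, `anova` (one tibble per dv), `followups`, `accuracy_gee`,
#'   `bisbas_models`, `fit`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # -- acquire ---------------------------------------------------------
  if (config$mode == "synthetic") {
    scenario <- config$scenario
    scenario$seed <- stage_seed(config$seed, "generate")
    data <- generate_dataset(scenario)
    trials <- data$trials
    participants <- data$participants
  } else {
    trials <- read_trials_csv(config$trials_path)
    participants <- if (!is.null(config$participants_path)) {
      readr::read_csv(config$participants_path, progress = FALSE,
                      show_col_types = FALSE)
    } else {
      NULL
    }
  }
  log_stage("acquire", "%d trials, %d participants", nrow(trials),
            length(unique(trials$participant_id)))

  # -- preprocess ------------------------------------------------------
  excl <- exclude_participants(trials, config$error_threshold)
  filt <- filter_rts(excl$trials, config$lo_ms, config$hi_ms)
  trials_kept <- filt$trials
  log_stage("preprocess", "excluded %d participant(s); trimmed %.2f%% of main trials",
            length(excl$excluded), 100 * filt$removed_proportion)

  cells <- summarize_cells(trials_kept)
  estimates <- estimate_all(cells, s = config$s)
  log_stage("estimate", "%d cell estimates (%d degenerate, %d edge-corrected)",
            nrow(estimates), sum(estimates$degenerate),
            sum(estimates$edge_corrected))

  # -- inference -------------------------------------------------------
  stat_tables <- list(
    median_rt = dplyr::select(cells, dplyr::all_of(
      c("participant_id", "participant_gender", "expression",
        "required_response", "face_gender"))) |>
      dplyr::mutate(value = cells$median_rt_ms),
    v = dplyr::filter(estimates, !.data$degenerate) |>
      dplyr::transmute(.data$participant_id, .data$participant_gender,
                       .data$expression, .data$required_response,
                       .data$face_gender, value = .data$v),
    a = dplyr::filter(estimates, !.data$degenerate) |>
      dplyr::transmute(.data$participant_id, .data$participant_gender,
                       .data$expression, .data$required_response,
                       .data$face_gender, value = .data$a),
    ter = dplyr::filter(estimates, !.data$degenerate) |>
      dplyr::transmute(.data$participant_id, .data$participant_gender,
                       .data$expression, .data$required_response,
                       .data$face_gender, value = .data$ter)
  )
  anova_res <- purrr::imap(stat_tables, function(tab, nm) {
    complete <- tab |>
      dplyr::count(.data$participant_id) |>
      dplyr::filter(.data$n == 8)
    tab <- dplyr::semi_join(tab, complete, by = "participant_id")
    res <- run_bayes_anova(tab, dv = "value")
    dplyr::mutate(res, dv = nm)
  })
  followups <- purrr::imap(stat_tables, function(tab, nm) {
    complete <- tab |>
      dplyr::count(.data$participant_id) |>
      dplyr::filter(.data$n == 8)
    tab <- dplyr::semi_join(tab, complete, by = "participant_id")
    purrr::map(c(female = "female", male = "male"), function(g) {
      simple_interaction_followup(
        tab, group = g, dv = "value",
        seed = stage_seed(config$seed, paste0("hdi-", nm, "-", g)))
    })
  })
  log_stage("infer", "Bayes-factor ANOVAs for %s",
            paste(names(stat_tables), collapse = ", "))

  gee <- fit_gee_binomial(
    dplyr::filter(trials_kept, .data$block != "practice"),
    correct ~ expression * required_response * face_gender *
      participant_gender)
  log_stage("accuracy", "GEE alpha = %.4f, converged = %s", gee$alpha,
            gee$converged)

  bisbas_models <- NULL
  covars <- intersect(c("bis", "bas_reward", "bas_drive", "bas_fun"),
                      names(participants %||% tibble::tibble()))
  if (length(covars) > 0) {
    correct_main <- trials_kept |>
      dplyr::filter(.data$block != "practice", .data$correct)
    bisbas_models <- purrr::map(
      setNames(covars, covars),
      function(cv) {
        tryCatch(
          fit_exgauss_regression(correct_main, participants,
                                 covariate = cv),
          error = function(e) structure(list(covariate = cv,
                                             message = conditionMessage(e)),
                                        class = "pp_exgauss_reg_failure"))
      })
    failed <- purrr::map_lgl(bisbas_models,
                             inherits, "pp_exgauss_reg_failure")
    log_stage("bisbas", "ex-Gaussian regressions for %s%s",
              paste(covars, collapse = ", "),
              if (any(failed)) paste0(" (not estimable: ",
                                      paste(covars[failed],
                                            collapse = ", "), ")")
              else "")
  }

  sims <- posterior_predict(estimates, n_sim = config$n_sim,
                            seed = stage_seed(config$seed, "predict"))
  fit <- fit_summary(trials_kept, sims)
  log_stage("fit", "correct-stream coverage %.3f", fit_coverage(fit))

  # -- outputs ---------------------------------------------------------
  out <- function(name) file.path(config$out_dir, name)
  write_trials_csv(trials, out("trials.csv"))
  if (!is.null(participants)) {
    readr::write_csv(participants, out("participants.csv"),
                     progress = FALSE)
  }
  readr::write_csv(cells, out("cell_summaries.csv"), progress = FALSE)
  readr::write_csv(estimates, out("ez_estimates.csv"), progress = FALSE)
  readr::write_csv(dplyr::bind_rows(anova_res), out("bayes_anova.csv"),
                   progress = FALSE)
  followup_tab <- purrr::imap_dfr(followups, function(by_group, nm) {
    purrr::imap_dfr(by_group, function(fl, g) {
      dplyr::bind_rows(
        dplyr::mutate(fl$interaction, kind = "interaction",
                      contrast = NA_character_, dz = NA_real_,
                      hdi_low = NA_real_, hdi_high = NA_real_),
        dplyr::mutate(fl$contrasts, kind = "contrast", dv = nm, group = g,
                      term = NA_character_, method = "jzs-ttest"))
    })
  })
  readr::write_csv(followup_tab, out("followups.csv"), progress = FALSE)
  readr::write_csv(tidy(gee), out("accuracy_gee.csv"), progress = FALSE)
  if (!is.null(bisbas_models)) {
    ok <- bisbas_models[!purrr::map_lgl(bisbas_models, inherits,
                                        "pp_exgauss_reg_failure")]
    if (length(ok) > 0) {
      readr::write_csv(
        purrr::imap_dfr(ok, ~ dplyr::mutate(tidy(.x), covariate = .y)),
        out("bisbas_exgauss.csv"), progress = FALSE)
    }
  }
  readr::write_csv(tibble::as_tibble(fit), out("fit_summary.csv"),
                   progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pushpull")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = config$mode, seed = config$seed, s = config$s,
    filter_bounds_ms = c(config$lo_ms, config$hi_ms),
    error_threshold = config$error_threshold, n_sim = config$n_sim,
    excluded_participants = excl$excluded,
    removed_proportion = filt$removed_proportion,
    n_trials = nrow(trials), n_trials_kept = nrow(trials_kept)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_report(out("report.md"), anova_res, followups, gee, bisbas_models,
               fit, excl, filt)

  invisible(list(trials = trials, participants = participants,
                 excluded = excl$excluded,
                 removed_proportion = filt$removed_proportion,
                 cells = cells, estimates = estimates, anova = anova_res,
                 followups = followups, accuracy_gee = gee,
                 bisbas_models = bisbas_models, fit = fit,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(path, anova_res, followups, gee, bisbas_models,
                         fit, excl, filt) {
  fmt_bf <- function(tab, n = 5) {
    paste(sprintf("- %s: BF10 = %.3g (%s)", tab$term, tab$bf10, tab$label)[
      seq_len(min(n, nrow(tab)))], collapse = "\n")
  }
  sections <- c(
    "# Approach-avoidance diffusion-model analysis report", "",
    sprintf("Excluded participants (error rate): %s",
            if (length(excl$excluded) == 0) "none"
            else paste(excl$excluded, collapse = ", ")),
    sprintf("Response-time trimming removed %.2f%% of main trials.",
            100 * filt$removed_proportion), "",
    "## Median correct RT (Bayes-factor ANOVA)", fmt_bf(anova_res$median_rt), "",
    "## Drift rates", fmt_bf(anova_res$v), "",
    sprintf("Female expression x response interaction: BF10 = %.3g (%s); male: BF10 = %.3g (%s)",
            followups$v$female$interaction$bf10,
            followups$v$female$interaction$label,
            followups$v$male$interaction$bf10,
            followups$v$male$interaction$label), "",
    "## Non-decision times", fmt_bf(anova_res$ter), "",
    "## Boundary separation", fmt_bf(anova_res$a), "",
    "## Accuracy (binomial GEE, exchangeable)",
    paste(sprintf("- %s: estimate %.4f (z = %.2f, p = %.3g)",
                  gee$coefficients$term, gee$coefficients$estimate,
                  gee$coefficients$statistic, gee$coefficients$p.value),
          collapse = "\n"), "",
    "## BIS/BAS ex-Gaussian regressions",
    if (is.null(bisbas_models)) {
      "No participant covariates available."
    } else {
      paste(purrr::imap_chr(bisbas_models, function(m, nm) {
        if (inherits(m, "pp_exgauss_reg_failure")) {
          return(sprintf("- %s: not estimable (%s)", nm, m$message))
        }
        hl <- m$coefficients[grepl("cov_scaled", m$coefficients$term), ]
        top <- hl[which.max(abs(hl$statistic)), ]
        sprintf("- %s: largest covariate slope %s = %.4f (t = %.2f)",
                nm, top$term, top$estimate, top$statistic)
      }), collapse = "\n")
    }, "",
    "## Posterior-predictive fit",
    sprintf("Observed correct-response medians inside the predicted 5-95%% band for %.1f%% of cells; error stream: %s.",
            100 * fit_coverage(fit, "correct"),
            ifelse(is.na(fit_coverage(fit, "error")), "not assessable",
                   sprintf("%.1f%%", 100 * fit_coverage(fit, "error"))))
  )
  writeLines(sections, path)
  invisible(path)
}

#' Parameter-recovery study over a drift-rate grid
#'
#' For each generating drift rate, simulates `n_trials` Wiener trials at
#' the stated boundary separation and non-decision time, reduces them to
#' (proportion correct, correct-RT mean, correct-RT variance), applies the
#' EZ inverse and reports generating vs recovered parameters.
#'
#' @param v_grid Generating drift rates.
#' @param a,ter,s Generating boundary separation, non-decision time and
#'   scaling (shared across the grid).
#' @param n_trials Simulated trials per grid point.
#' @param seed Optional master seed; each grid point consumes a derived
#'   sub-seed.
#' @param dt Integrator step.
#' @return A tibble with one row per grid point: generating parameters,
#'   observed moments and recovered `v_hat`, `a_hat`, `ter_hat`.
#' @examples
#' recovery_study(c(1.85, 2.16), n_trials = 2000, seed = 1)
#' @export
recovery_study <- function(v_grid, a = 1.2, ter = 0.3, s = 1,
                           n_trials = 50000, seed = NULL, dt = 5e-4) {
  purrr::map_dfr(seq_along(v_grid), function(i) {
    sub_seed <- if (is.null(seed)) NULL else {
      stage_seed(seed, paste0("recover-", i))
    }
    sim <- simulate_rts(list(v = v_grid[i], a = a, ter = ter, s = s),
                        n_trials = n_trials, seed = sub_seed, dt = dt)
    correct_rt_s <- sim$rt_ms[sim$hit_upper] / 1000
    pc <- edge_correct(mean(sim$hit_upper), n_trials)$pc
    est <- ez_inverse(pc, mean(correct_rt_s), var(correct_rt_s), s = s)
    tibble::tibble(v = v_grid[i], a = a, ter = ter, n_trials = n_trials,
                   pc = mean(sim$hit_upper),
                   mrt_s = mean(correct_rt_s), vrt_s2 = var(correct_rt_s),
                   v_hat = est$v, a_hat = est$a, ter_hat = est$ter)
  })
}
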