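test_that("design generator produces the canonical block structure", {
  d <- generate_design(1, seed = 1) |>
    dplyr::filter(participant_id == "F01")
  expect_equal(sum(d$block == "main1"), 128)
  expect_equal(sum(d$block == "main2"), 128)
  practice <- dplyr::filter(d, block == "practice")
  expect_equal(nrow(practice), 16)
  expect_equal(as.vector(sort(table(practice$expression))), c(8, 8))
  expect_equal(length(unique(practice$stimulus_id)), 16)

  # each main block shows each stimulus exactly 8 times
  for (b in c("main1", "main2")) {
    counts <- table(d$stimulus_id[d$block == b])
    expect_equal(length(counts), 16)
    expect_true(all(counts == 8))
  }
  # mapping flips between the main blocks
  expect_equal(length(unique(d$mapping[d$block != "practice"])), 2)
  expect_equal(length(unique(d$mapping[d$block == "main1"])), 1)
})

test_that("design cells are balanced and responses follow the mapping", {
  d <- generate_design(2, seed = 3)
  expect_equal(nrow(d), 2 * 2 * (16 + 2 * 128))
  main <- dplyr::filter(d, block != "practice")
  cells <- main |>
    dplyr::count(participant_id, expression, face_gender,
                 required_response)
  expect_true(all(cells$n == 32))
  # required response is a pure function of (expression, mapping)
  expect_equal(
    d$required_response,
    ifelse(xor(d$expression == "angry",
               d$mapping != "push-angry/pull-happy"), "push", "pull"))
})

test_that("design generation is deterministic under a fixed seed", {
  expect_identical(generate_design(2, seed = 11),
                   generate_design(2, seed = 11))
  expect_error(generate_design(0), "positive")
})

test_that("wiener simulator matches closed-form hitting probability and adds ter", {
  p <- diffusion_params(v = 2, a = 1.2, ter = 0.3)
  sim <- simulate_rts(p, 20000, seed = 5)
  phat <- mean(sim$hit_upper)
  ptrue <- plogis(2 * 1.2)
  se <- sqrt(ptrue * (1 - ptrue) / 20000)
  expect_lt(abs(phat - ptrue), 4 * se)
  expect_gte(min(sim$rt_ms), 300)

  # dominant drift forces the upper boundary
  sim_big <- simulate_rts(diffusion_params(50, 1.2, 0.1), 500, seed = 6)
  expect_true(all(sim_big$hit_upper))

  expect_error(simulate_rts(list(v = 1, a = -1, ter = 0, s = 1), 10),
               "positive")
  expect_error(diffusion_params(1, 0, 0.3), "boundary")
})

test_that("simulated decision-time moments match the EZ closed forms", {
  m <- ez_forward(2.16, 1.2, 0.3)
  sim <- simulate_rts(diffusion_params(2.16, 1.2, 0.3), 50000, seed = 2)
  rt_c <- sim$rt_ms[sim$hit_upper] / 1000
  n_c <- length(rt_c)
  expect_lt(abs(mean(rt_c) - m$mrt_s), 3 * sqrt(m$vrt_s2 / n_c))
  # variance comparison on the MC standard error of a sample variance
  se_var <- m$vrt_s2 * sqrt(2 / (n_c - 1))
  expect_lt(abs(var(rt_c) - m$vrt_s2), 4 * se_var)
})

test_that("default scenario encodes the documented effect directions", {
  sc <- default_scenario(seed = 1)
  tt <- sc$truth
  expect_equal(nrow(tt), 16)
  expect_true(all(tt$a > 0) && all(tt$ter > 0))
  f_angry <- dplyr::filter(tt, participant_gender == "female",
                           expression == "angry")
  expect_true(all(
    f_angry$v[f_angry$required_response == "push"] >
      f_angry$v[f_angry$required_response == "pull"]))
  m <- dplyr::filter(tt, participant_gender == "male")
  by_cell <- tidyr::pivot_wider(m, names_from = "required_response",
                                values_from = "v",
                                id_cols = c("expression", "face_gender"))
  expect_equal(by_cell$push, by_cell$pull)
  expect_error(scenario_config(2, tt[-1, ], seed = 1), "missing")
  expect_error(default_scenario(contaminant_rate = 0.2), "0.1")
})

test_that("generated datasets respect the scenario contract", {
  sc <- default_scenario(n_participants_per_gender = 2, seed = 31,
                         contaminant_rate = 0)
  sc$sd_ter <- 0
  d <- generate_dataset(sc)
  expect_equal(nrow(d$trials), 2 * 2 * 272)
  expect_equal(d$trials$correct,
               d$trials$observed_response == d$trials$required_response)
  # without contaminants and ter >= 0.2 s nothing is trimmed
  expect_gte(min(d$trials$rt_ms), 200)
  expect_equal(filter_rts(d$trials)$removed_proportion, 0)
  # determinism, byte for byte through the CSV writer
  d2 <- generate_dataset(sc)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials_csv(d$trials, f1); write_trials_csv(d2$trials, f2)
  expect_identical(readLines(f1), readLines(f2))

  # contaminants land outside the trimming range
  sc2 <- default_scenario(n_participants_per_gender = 2, seed = 32,
                          contaminant_rate = 0.05)
  d3 <- generate_dataset(sc2)
  trimmed <- filter_rts(d3$trials)
  expect_gt(trimmed$removed_proportion, 0)
  out_of_range <- d3$trials$rt_ms < 200 | d3$trials$rt_ms > 2500
  expect_true(all(d3$trials$rt_ms[out_of_range] >= 50 &
                    d3$trials$rt_ms[out_of_range] <= 4000))
})

test_that("BIS generator reproduces the gender-specific group means", {
  set.seed(77)
  sc <- default_scenario(seed = 1)
  ids <- sprintf("p%05d", 1:20000)
  genders <- rep(c("female", "male"), each = 10000)
  bb <- pushpull:::draw_bisbas(ids, genders, sc$bisbas)
  expect_lt(abs(mean(bb$bis[bb$participant_gender == "female"]) - 23.32),
            0.12)
  expect_lt(abs(mean(bb$bis[bb$participant_gender == "male"]) - 19.29),
            0.15)
  expect_true(all(bb$bis >= 7 & bb$bis <= 28))
  expect_equal(bb$bas, bb$bas_drive + bb$bas_fun + bb$bas_reward)
})
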