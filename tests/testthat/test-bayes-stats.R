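test_that("evidence bands follow the Jeffreys rule with half-open edges", {
  expect_equal(classify_bf(c(8.72, 17, 3.66)),
               c("moderate", "strong", "moderate"))
  # boundary points belong to the lower band
  expect_equal(classify_bf(c(3.2, 10, 100, 101)),
               c("anecdotal", "moderate", "strong", "decisive"))
  expect_equal(classify_bf(2), "anecdotal")
  expect_equal(classify_bf(1), "no evidence")
  expect_equal(classify_bf(1 / 17), "null-strong")
  expect_equal(classify_bf(0.26), "null-moderate")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  set.seed(14)
  vectors <- list(
    rnorm(20, 0.4, 1),
    rnorm(12, 0, 0.5),
    rnorm(40, 0.8, 1.2),
    c(0.3, -0.1, 0.5, 0.2, 0.25, 0.6, -0.05, 0.4, 0.15, 0.3)
  )
  for (x in vectors) {
    bf <- jzs_ttest_bf(x)
    oracle <- jzs_oracle(x)
    expect_equal(bf, oracle, tolerance = 1e-4)
  }
})

test_that("JZS Bayes factor has the right invariances and limits", {
  set.seed(15)
  x <- rnorm(25, 0.5, 1)
  expect_equal(jzs_ttest_bf(3 * x), jzs_ttest_bf(x), tolerance = 1e-8)
  # data with mean exactly zero favour the null
  x0 <- c(x, -x)
  expect_lt(jzs_ttest_bf(x0), 1)
  # evidence grows without bound in |t|
  bfs <- sapply(c(0.2, 0.6, 1.2), function(m) jzs_ttest_bf(x - mean(x) + m))
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_ttest_bf(rep(1, 5)), "variance")
  expect_error(jzs_ttest_bf(1), "two")
})

test_that("effect-size posterior summaries behave analytically", {
  sym <- c(-2, -1, -0.5, 0.5, 1, 2)
  res <- effect_size_hdi(sym, seed = 1)
  expect_equal(res$dz, 0)
  expect_lt(res$hdi_low, 0)
  expect_gt(res$hdi_high, 0)

  # sign reversal negates the effect size and mirrors the interval
  set.seed(21)
  x <- rnorm(30, 0.4, 1)
  a <- effect_size_hdi(x, seed = 5)
  b <- effect_size_hdi(-x, seed = 5)
  expect_equal(b$dz, -a$dz)
  expect_equal(b$hdi_low, -a$hdi_high, tolerance = 0.02)
  expect_equal(b$hdi_high, -a$hdi_low, tolerance = 0.02)

  # large-sample width matches the normal approximation
  set.seed(22)
  big <- rnorm(10000, 0.5, 1)
  r <- effect_size_hdi(big, seed = 2)
  dz <- mean(big) / sd(big)
  se <- sqrt(1 / 10000 + dz^2 / (2 * 10000))
  expect_equal(r$dz, dz)
  expect_equal(r$hdi_low, dz - 1.96 * se, tolerance = 0.02)
  expect_equal(r$hdi_high, dz + 1.96 * se, tolerance = 0.02)
  expect_error(effect_size_hdi(c(1, 1, 1)), "variance")
})

make_stat_table <- function(n_per_gender, effect = function(df) 0) {
  cells <- tidyr::expand_grid(
    participant_id = sprintf("s%02d", seq_len(2 * n_per_gender)),
    expression = c("angry", "happy"),
    required_response = c("push", "pull"),
    face_gender = c("male", "female"))
  cells$participant_gender <- ifelse(
    as.integer(sub("s", "", cells$participant_id)) <= n_per_gender,
    "female", "male")
  intercepts <- rnorm(2 * n_per_gender, 0, 0.5)
  names(intercepts) <- sprintf("s%02d", seq_len(2 * n_per_gender))
  cells$value <- intercepts[cells$participant_id] + effect(cells) +
    rnorm(nrow(cells))
  cells
}

test_that("BIC-approximate ANOVA detects strong effects and stays quiet under the null", {
  set.seed(33)
  # a large expression main effect is decisive in nearly every replicate
  hits <- replicate(10, {
    tab <- make_stat_table(15, effect = function(df) {
      0.5 * ifelse(df$expression == "angry", 1, -1)
    })
    res <- run_bayes_anova(tab, "value")
    res$bf10[res$term == "expression"] > 100
  })
  expect_gte(mean(hits), 0.9)

  # under pure noise, spurious model terms are rare
  set.seed(34)
  null_runs <- replicate(20, {
    res <- run_bayes_anova(make_stat_table(15), "value")
    c(all_quiet = all(res$bf10 < 3.2), exceed = mean(res$bf10 > 3.2))
  })
  expect_gte(mean(null_runs["all_quiet", ]), 0.75)
  expect_lte(mean(null_runs["exceed", ]), 0.05)
})

test_that("BIC-approximate ANOVA is invariant to affine changes of the dv", {
  set.seed(35)
  tab <- make_stat_table(10, effect = function(df) {
    0.3 * ifelse(df$expression == "angry", 1, -1)
  })
  r1 <- run_bayes_anova(tab, "value")
  tab$value <- 5 + 2 * tab$value
  r2 <- run_bayes_anova(tab, "value")
  expect_equal(r2$bf10[order(r2$term)], r1$bf10[order(r1$term)],
               tolerance = 1e-6)
})

test_that("unbalanced tables are rejected with the offending participants", {
  set.seed(36)
  tab <- make_stat_table(4)
  expect_error(run_bayes_anova(tab[-1, ], "value"), "s01")
})

test_that("simple-interaction follow-ups recover the built-in group difference", {
  est <- shared_estimates()
  vtab <- est |>
    dplyr::filter(!degenerate) |>
    dplyr::transmute(participant_id, participant_gender, expression,
                     required_response, face_gender, value = v)
  f <- simple_interaction_followup(vtab, "female", "value", seed = 4)
  m <- simple_interaction_followup(vtab, "male", "value", seed = 4)
  # the angry push-pull drift advantage is a female effect in the generator
  angry <- f$contrasts[grepl("^angry", f$contrasts$contrast), ]
  expect_gt(angry$dz, 0)
  expect_gt(f$interaction$bf10, m$interaction$bf10)
  expect_true(all(f$contrasts$hdi_low <= f$contrasts$dz &
                    f$contrasts$dz <= f$contrasts$hdi_high))

  flat <- vtab |> dplyr::mutate(value = 1)
  expect_error(simple_interaction_followup(flat, "female", "value"),
               "Zero-variance")
  expect_error(simple_interaction_followup(vtab, "child", "value"),
               "not present")
})

test_that("group-mean comparison reports F, partial eta squared and p", {
  g <- rep(c("a", "b"), each = 10)
  same <- c(1:10, 1:10)
  r0 <- compare_group_means(same, g)
  expect_equal(r0$f, 0)
  expect_equal(r0$eta_p_sq, 0)

  set.seed(41)
  x <- rnorm(20, ifelse(g == "a", 0, 1))
  r <- compare_group_means(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(r$f, unname(tt$statistic)^2)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 18)
  expect_error(compare_group_means(x, rep("a", 20)), "two groups")
})

test_that("BIS group separation implies a partial eta squared near 0.24", {
  set.seed(42)
  etas <- replicate(150, {
    x <- c(rnorm(31, 23.32, 3.09), rnorm(32, 19.29, 4.21))
    g <- rep(c("f", "m"), c(31, 32))
    compare_group_means(x, g)$eta_p_sq
  })
  expect_equal(mean(etas), 0.24, tolerance = 0.05)
})
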