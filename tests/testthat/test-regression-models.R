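test_that("sum coding maps two-level factors to +1/-1 with orthogonal products", {
  expect_equal(sum_code(c("angry", "happy", "angry")), c(1, -1, 1))
  expect_error(sum_code(c("a", "b", "c")), "2 levels")

  grid <- tidyr::expand_grid(e = c("angry", "happy"),
                             r = c("push", "pull"),
                             f = c("male", "female"))
  X <- cbind(e = sum_code(grid$e), r = sum_code(grid$r),
             f = sum_code(grid$f))
  X <- cbind(X, er = X[, "e"] * X[, "r"], erf = X[, "e"] * X[, "r"] *
               X[, "f"])
  # balanced design: all columns mean-zero and mutually orthogonal
  expect_true(all(colMeans(X) == 0))
  gram <- crossprod(X)
  expect_equal(gram, diag(diag(gram)), ignore_attr = TRUE)
  # the 3-way column is the elementwise product of the mains
  expect_equal(X[, "erf"], X[, "e"] * X[, "r"] * X[, "f"],
               ignore_attr = TRUE)
})

test_that("GEE with singleton clusters equals ordinary logistic ML", {
  set.seed(51)
  n <- 400
  df <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    expression = sample(c("angry", "happy"), n, TRUE),
    face_gender = sample(c("male", "female"), n, TRUE))
  eta <- 1.2 + 0.5 * sum_code(df$expression) -
    0.3 * sum_code(df$face_gender)
  df$correct <- runif(n) < plogis(eta)
  fit <- fit_gee_binomial(df, correct ~ expression * face_gender)
  ref <- glm(correct ~ I(sum_code(expression)) * I(sum_code(face_gender)),
             binomial, df)
  expect_lt(max(abs(tidy(fit)$estimate - unname(coef(ref)))), 1e-6)
  expect_equal(glance(fit)$alpha, 0)
  expect_true(glance(fit)$converged)
})

test_that("GEE Wald tests are calibrated under cluster correlation", {
  set.seed(52)
  reps <- 100
  hits <- replicate(reps, {
    n_clust <- 30; m <- 8
    u <- rnorm(n_clust, 0, 0.6)   # random intercept -> exchangeable corr
    df <- tibble::tibble(
      participant_id = rep(sprintf("c%02d", 1:n_clust), each = m),
      x = sample(c("angry", "happy"), n_clust * m, TRUE))
    df$correct <- runif(nrow(df)) <
      plogis(0.8 + rep(u, each = m))   # no effect of x
    fit <- fit_gee_binomial(df, correct ~ x)
    abs(tidy(fit)$statistic[2]) < 1.96
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("GEE recovers the generator's accuracy asymmetry on synthetic data", {
  kept <- shared_kept_trials()
  main <- dplyr::filter(kept, block != "practice")
  fit <- fit_gee_binomial(
    main, correct ~ expression * required_response * face_gender)
  expect_true(glance(fit)$converged)
  co <- tidy(fit)
  # angry (+1) drifts are lower -> angry accuracy below happy
  expect_lt(co$estimate[co$term == "expression"], 0)
  # contrasts via linear combinations work
  L <- as.numeric(co$term == "expression")
  ct <- gee_contrast(fit, L)
  expect_equal(ct$estimate, co$estimate[co$term == "expression"])
  expect_equal(ct$std.error, co$std.error[co$term == "expression"])
})

test_that("ex-Gaussian density is normalised and matches a convolution oracle", {
  expect_equal(
    integrate(function(t) exgauss_density(t, 0.45, 0.05, 0.15),
              -Inf, Inf)$value, 1, tolerance = 1e-6)
  # oracle: numerical convolution of the Gaussian and exponential parts
  conv <- function(t, mu, sigma, tau) {
    integrate(function(u) dnorm(t - u, mu, sigma) * dexp(u, 1 / tau),
              0, Inf, rel.tol = 1e-10)$value
  }
  for (t0 in c(0.3, 0.5, 0.9)) {
    expect_equal(exgauss_density(t0, 0.45, 0.05, 0.15),
                 conv(t0, 0.45, 0.05, 0.15), tolerance = 1e-6)
  }
  expect_error(exgauss_density(0.5, 0.4, -1, 0.1), "positive")
  # sampler moments match mu + tau and sigma^2 + tau^2
  set.seed(61)
  x <- rexgauss(50000, 0.45, 0.05, 0.15)
  expect_equal(mean(x), 0.6, tolerance = 0.005)
  expect_equal(var(x), 0.05^2 + 0.15^2, tolerance = 0.01)
})

test_that("ex-Gaussian ML recovers parameters and is location-equivariant", {
  set.seed(62)
  x <- rexgauss(10000, 0.45, 0.05, 0.15)
  fit <- fit_exgauss_ml(x)
  expect_lt(abs(fit$mu - 0.45) / 0.45, 0.05)
  expect_lt(abs(fit$sigma - 0.05) / 0.05, 0.05)
  expect_lt(abs(fit$tau - 0.15) / 0.15, 0.05)
  # the reported log likelihood is the sum of log densities at the MLE
  expect_equal(fit$loglik,
               sum(exgauss_density(x, fit$mu, fit$sigma, fit$tau,
                                   log = TRUE)))
  shifted <- fit_exgauss_ml(x + 0.2)
  expect_equal(shifted$mu, fit$mu + 0.2, tolerance = 1e-4)
  expect_equal(shifted$sigma, fit$sigma, tolerance = 1e-4)
  expect_equal(shifted$tau, fit$tau, tolerance = 1e-4)
  expect_error(fit_exgauss_ml(rep(1, 20)), "Degenerate")
  expect_error(fit_exgauss_ml(c(1, 2)), "at least 10")
})

test_that("ex-Gaussian ML error shrinks with sample size", {
  set.seed(63)
  rmse_at <- function(n, reps = 15) {
    errs <- replicate(reps, {
      fit <- fit_exgauss_ml(rexgauss(n, 0.45, 0.05, 0.15))
      sqrt(mean((c(fit$mu, fit$sigma, fit$tau) -
                   c(0.45, 0.05, 0.15))^2))
    })
    mean(errs)
  }
  r <- sapply(c(500, 2000, 10000), rmse_at)
  expect_true(all(diff(r) < 0))
})

test_that("covariate scaling centres to mean 0 and SD one half", {
  x <- c(1, 2, 3, 4, 5)
  z <- scale_2sd(x)
  expect_equal(z, c(-2, -1, 0, 1, 2) / (2 * sd(x)))
  set.seed(64)
  y <- rnorm(100, 50, 9)
  expect_equal(mean(scale_2sd(y)), 0, tolerance = 1e-12)
  expect_equal(sd(scale_2sd(y)), 0.5, tolerance = 1e-12)
  expect_error(scale_2sd(rep(3, 5)), "zero standard deviation")
})

# builds ex-Gaussian RT data with a known happy x pull x female x covariate
# slope on mu
make_exgauss_experiment <- function(n_per_gender = 8, trials_per_cell = 30,
                                    slope = 0.12) {
  participants <- tibble::tibble(
    participant_id = sprintf("e%02d", seq_len(2 * n_per_gender)),
    participant_gender = rep(c("female", "male"), each = n_per_gender),
    bis = round(c(rnorm(n_per_gender, 23.3, 3.1),
                  rnorm(n_per_gender, 19.3, 4.2))),
    intercept = rnorm(2 * n_per_gender, 0.45, 0.04))
  cov_scaled <- scale_2sd(participants$bis)
  names(cov_scaled) <- participants$participant_id
  cells <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    expression = c("angry", "happy"),
    required_response = c("push", "pull"))
  trials <- cells[rep(seq_len(nrow(cells)), each = trials_per_cell), ] |>
    dplyr::inner_join(participants, by = "participant_id")
  four_way <- with(trials, (expression == "happy") *
                     (required_response == "pull") *
                     (participant_gender == "female") *
                     cov_scaled[participant_id])
  mu <- trials$intercept +
    0.02 * (trials$expression == "happy") -
    0.03 * (trials$required_response == "pull") +
    slope * four_way
  trials$rt_ms <- 1000 * (rnorm(nrow(trials), mu, 0.05) +
                            rexp(nrow(trials), 1 / 0.15))
  trials$block <- "main1"
  list(trials = trials, participants = participants)
}

test_that("ex-Gaussian regression recovers the built-in 4-way covariate slope", {
  set.seed(65)
  term4 <- "expressionhappy:responsepull:genderfemale:cov_scaled"
  signs <- replicate(10, {
    ex <- make_exgauss_experiment(slope = 0.12)
    fit <- fit_exgauss_regression(ex$trials, ex$participants, "bis")
    co <- tidy(fit)
    co$estimate[co$term == term4] > 0
  })
  expect_gte(mean(signs), 0.9)
})

test_that("a null covariate slope is covered by its confidence interval", {
  set.seed(66)
  term4 <- "expressionhappy:responsepull:genderfemale:cov_scaled"
  covered <- replicate(20, {
    ex <- make_exgauss_experiment(slope = 0)
    fit <- fit_exgauss_regression(ex$trials, ex$participants, "bis")
    co <- tidy(fit)
    row <- co[co$term == term4, ]
    abs(row$estimate) < 1.96 * row$std.error
  })
  expect_gte(mean(covered), 0.8)
})

test_that("regression output is invariant to raw covariate rescaling and drops absorbed terms", {
  set.seed(67)
  ex <- make_exgauss_experiment()
  fit1 <- fit_exgauss_regression(ex$trials, ex$participants, "bis")
  rescaled <- dplyr::mutate(ex$participants, bis = 10 * bis + 3)
  fit2 <- fit_exgauss_regression(ex$trials, rescaled, "bis")
  # the covariate enters after 2-SD standardisation, so affine changes of
  # the raw scores change nothing
  expect_equal(tidy(fit2)$estimate, tidy(fit1)$estimate, tolerance = 1e-5)
  # purely participant-level terms are absorbed by the intercepts
  expect_true(all(c("genderfemale", "cov_scaled") %in%
                    fit1$dropped_terms))
  expect_false(any(tidy(fit1)$term %in% fit1$dropped_terms))
  expect_true(fit1$converged)
  expect_gt(fit1$sigma, 0)
  expect_gt(fit1$tau, 0)
})
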