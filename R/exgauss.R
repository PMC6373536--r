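#' Ex-Gaussian density
#'
#' Density of the ex-Gaussian distribution — the convolution of a
#' Normal(`mu`, `sigma`) and an Exponential(rate `1/tau`) — the standard
#' descriptive model for positively skewed response-time distributions:
#' `f(t) = (1/tau) exp(mu/tau + sigma^2/(2 tau^2) - t/tau)
#'   Phi((t - mu)/sigma - sigma/tau)`.
#' Evaluated in log space (with `pnorm(log.p = TRUE)`) so that large
#' `sigma/tau` ratios do not overflow.
#'
#' @param t Evaluation points (same units as `mu`, typically seconds).
#' @param mu,sigma Mean and SD of the Gaussian component; `sigma > 0`.
#' @param tau Mean of the exponential component; `tau > 0`.
#' @param log If `TRUE`, return the log density.
#' @return Numeric vector of (log) densities.
#' @examples
#' exgauss_density(0.5, mu = 0.45, sigma = 0.05, tau = 0.15)
#' @export
exgauss_density <- function(t, mu, sigma, tau, log = FALSE) {
  if (any(sigma <= 0) || any(tau <= 0)) {
    stop("`sigma` and `tau` must be positive.", call. = FALSE)
  }
  k <- max(length(t), length(mu), length(sigma), length(tau))
  t <- rep_len(t, k); mu <- rep_len(mu, k)
  sigma <- rep_len(sigma, k); tau <- rep_len(tau, k)
  w <- (t - mu) / sigma - sigma / tau
  ll <- -base::log(tau) + (mu - t) / tau + sigma^2 / (2 * tau^2) +
    pnorm(w, log.p = TRUE)
  # Gaussian limit: for tau << sigma the exact exponent suffers
  # catastrophic cancellation; the distribution is then numerically a
  # Normal(mu + tau, sqrt(sigma^2 + tau^2))
  lim <- tau < 0.05 * sigma
  if (any(lim)) {
    ll[lim] <- dnorm(t[lim], mu[lim] + tau[lim],
                     sqrt(sigma[lim]^2 + tau[lim]^2), log = TRUE)
  }
  if (log) ll else exp(ll)
}

#' Draw ex-Gaussian samples
#'
#' @param n Number of draws.
#' @inheritParams exgauss_density
#' @return Numeric vector: `rnorm(n, mu, sigma) + rexp(n, 1/tau)`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  rnorm(n, mu, sigma) + rexp(n, 1 / tau)
}

exgauss_negll <- function(par, t) {
  sigma <- exp(par[2]); tau <- exp(par[3])
  if (!all(is.finite(c(par[1], sigma, tau))) ||
      sigma < 1e-4 || tau < 1e-4 || sigma > 10 || tau > 10) {
    return(1e10)  # reject line-search overshoots and degenerate scales
  }
  nll <- -sum(exgauss_density(t, par[1], sigma, tau, log = TRUE))
  if (!is.finite(nll)) 1e10 else nll
}

exgauss_start <- function(t) {
  m <- mean(t); s2 <- var(t)
  sk <- mean((t - m)^3) / s2^1.5
  tau0 <- (max(sk, 0.05) * s2^1.5 / 2)^(1 / 3)
  tau0 <- min(tau0, 0.95 * sqrt(s2) * 1.5)
  sigma0 <- sqrt(max(s2 - tau0^2, 0.05 * s2))
  c(m - tau0, base::log(sigma0), base::log(tau0))
}

#' Maximum-likelihood fit of an ex-Gaussian distribution
#'
#' Fits (`mu`, `sigma`, `tau`) by maximising the exact log likelihood with
#' BFGS from moment-based starting values (`tau` from the sample skewness,
#' `sigma` from the residual variance). Positivity of `sigma` and `tau` is
#' enforced by optimising on the log scale.
#'
#' @param rts_s Numeric vector of response times in seconds, `n >= 10`.
#' @return An object of class `pp_exgauss` with elements `mu`, `sigma`,
#'   `tau`, `loglik`, `n`, `converged`. Use [tidy()] / [glance()] for
#'   tibble views.
#' @examples
#' fit_exgauss_ml(rexgauss(500, 0.45, 0.05, 0.15))
#' @export
fit_exgauss_ml <- function(rts_s) {
  t <- rts_s[is.finite(rts_s)]
  if (length(t) < 10) stop("Need at least 10 observations.", call. = FALSE)
  if (var(t) == 0) stop("Degenerate (zero-variance) input.", call. = FALSE)
  opt <- optim(exgauss_start(t), exgauss_negll, t = t, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  structure(list(mu = opt$par[1], sigma = exp(opt$par[2]),
                 tau = exp(opt$par[3]), loglik = -opt$value,
                 n = length(t), converged = opt$convergence == 0),
            class = "pp_exgauss")
}

#' @export
tidy.pp_exgauss <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "tau"),
                 estimate = c(x$mu, x$sigma, x$tau))
}

#' @export
glance.pp_exgauss <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, converged = x$converged)
}

#' @export
print.pp_exgauss <- function(x, ...) {
  cat(sprintf(
    "Ex-Gaussian ML fit (n = %d): mu = %.4f, sigma = %.4f, tau = %.4f\n",
    x$n, x$mu, x$sigma, x$tau))
  invisible(x)
}

#' @export
autoplot.pp_exgauss <- function(object, data = NULL, bins = 40, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(x = data, y = ggplot2::after_stat(.data$density)),
      bins = bins, fill = "grey80", colour = "grey40")
  }
  rng <- if (is.null(data)) {
    c(object$mu - 3 * object$sigma,
      object$mu + object$tau + 5 * object$tau)
  } else {
    range(data)
  }
  grid <- seq(rng[1], rng[2], length.out = 400)
  p +
    ggplot2::geom_line(ggplot2::aes(
      x = grid,
      y = exgauss_density(grid, object$mu, object$sigma, object$tau)),
      colour = "firebrick") +
    ggplot2::labs(x = "response time (s)", y = "density")
}

#' Centre and scale a covariate to two standard deviations
#'
#' `(x - mean(x)) / (2 sd(x))`; the result has mean 0 and SD 0.5, which
#' puts the slopes of continuous covariates on the same footing as
#' two-level factor contrasts.
#'
#' @param x Numeric vector with non-zero SD.
#' @return Scaled numeric vector.
#' @examples
#' scale_2sd(c(1, 2, 3, 4, 5))
#' @export
scale_2sd <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("`x` has zero standard deviation.", call. = FALSE)
  }
  (x - mean(x)) / (2 * s)
}

#' Ex-Gaussian response-time regression with a questionnaire covariate
#'
#' Models correct-response response times (seconds) as ex-Gaussian with the
#' Gaussian mean `mu` a linear function of treatment-coded
#' expression x response x participant-gender x covariate terms (reference
#' levels: angry, push, male), with a shared `sigma` and `tau` and fixed
#' per-participant intercept offsets. The covariate is centred and scaled
#' to 2 SD ([scale_2sd()]) at the participant level before entering the
#' design.
#'
#' Because the participant offsets absorb everything constant within a
#' participant, the purely participant-level columns (participant gender,
#' the covariate and their product) are not identified and are dropped from
#' the coefficient table; within-participant terms — including the 4-way
#' expression x response x gender x covariate slope — remain identified.
#' Fitting is by maximum likelihood (BFGS with the analytic gradient);
#' Wald standard errors come from the observed information.
#'
#' @param trials Trimmed, correct, main-block trials with `participant_id`,
#'   `participant_gender`, `expression`, `required_response`, `rt_ms`.
#' @param participants Participant table with `participant_id` and the
#'   covariate column.
#' @param covariate Name of the covariate column in `participants`
#'   (e.g. `"bis"`, `"bas_drive"`).
#' @return An object of class `pp_exgauss_reg`: coefficient table
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`), shared
#'   `sigma` and `tau`, participant offsets, `loglik`, `converged`.
#' @export
fit_exgauss_regression <- function(trials, participants, covariate = "bis") {
  stopifnot(covariate %in% names(participants),
            all(c("participant_id", "participant_gender", "expression",
                  "required_response", "rt_ms") %in% names(trials)))
  pt <- participants |>
    dplyr::distinct(.data$participant_id, .data[[covariate]]) |>
    dplyr::mutate(cov_scaled = scale_2sd(.data[[covariate]]))
  d <- trials |>
    dplyr::inner_join(pt, by = "participant_id") |>
    dplyr::mutate(
      expression = factor(.data$expression, c("angry", "happy")),
      response = factor(.data$required_response, c("push", "pull")),
      gender = factor(.data$participant_gender, c("male", "female")),
      rt_s = .data$rt_ms / 1000
    )
  n_per_gender <- d |>
    dplyr::distinct(.data$participant_id, .data$gender) |>
    dplyr::count(.data$gender)
  if (nrow(n_per_gender) < 2 || any(n_per_gender$n < 2)) {
    stop("Need at least 2 participants per gender group.", call. = FALSE)
  }

  X_full <- model.matrix(~ expression * response * gender * cov_scaled, d)
  # drop columns constant within every participant (absorbed by the
  # participant intercepts)
  pid <- d$participant_id
  within_var <- apply(X_full, 2, function(col) {
    any(tapply(col, pid, function(z) max(z) - min(z)) > 0)
  })
  within_var["(Intercept)"] <- TRUE
  X_terms <- X_full[, within_var, drop = FALSE]
  qrX <- qr(X_terms)
  if (qrX$rank < ncol(X_terms)) {
    stop("Collinear design after dropping absorbed columns.",
         call. = FALSE)
  }
  ids <- sort(unique(pid))
  P <- length(ids)
  Z <- matrix(0, nrow(d), P - 1,
              dimnames = list(NULL, paste0("participant:", ids[-1])))
  for (j in seq_len(P - 1)) Z[pid == ids[j + 1], j] <- 1
  X <- cbind(X_terms, Z)
  k <- ncol(X)
  t_obs <- d$rt_s

  negll <- function(par) {
    sigma <- exp(par[k + 1]); tau <- exp(par[k + 2])
    if (!is.finite(sigma) || !is.finite(tau) ||
        sigma < 1e-4 || tau < 1e-4 || sigma > 10 || tau > 10) {
      return(1e10)  # reject line-search overshoots and degenerate scales
    }
    mu <- drop(X %*% par[1:k])
    nll <- -sum(exgauss_density(t_obs, mu, sigma, tau, log = TRUE))
    if (!is.finite(nll)) 1e10 else nll
  }
  grad <- function(par) {
    sigma <- exp(par[k + 1]); tau <- exp(par[k + 2])
    if (!is.finite(sigma) || !is.finite(tau) ||
        sigma < 1e-4 || tau < 1e-4 || sigma > 10 || tau > 10) {
      return(rep(0, k + 2))
    }
    mu <- drop(X %*% par[1:k])
    w <- (t_obs - mu) / sigma - sigma / tau
    r <- exp(dnorm(w, log = TRUE) - pnorm(w, log.p = TRUE))
    dmu <- 1 / tau - r / sigma
    dsig <- sigma / tau^2 + r * (-(t_obs - mu) / sigma^2 - 1 / tau)
    dtau <- -1 / tau - (mu - t_obs) / tau^2 - sigma^2 / tau^3 +
      r * sigma / tau^2
    -c(drop(crossprod(X, dmu)), sum(dsig) * sigma, sum(dtau) * tau)
  }

  marg <- fit_exgauss_ml(t_obs)
  start <- c(marg$mu, rep(0, k - 1), base::log(marg$sigma),
             base::log(marg$tau))
  opt <- optim(start, negll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  H <- optimHess(opt$par, negll, grad)
  se_all <- rep(NA_real_, k + 2)
  cov_ok <- tryCatch({
    Hinv <- solve(H)
    se_all <- sqrt(pmax(diag(Hinv), 0))
    TRUE
  }, error = function(e) FALSE)

  est <- opt$par[1:k]
  se <- se_all[1:k]
  zstat <- est / se
  keep <- seq_len(ncol(X_terms))
  coef_tab <- tibble::tibble(
    term = colnames(X)[keep], estimate = est[keep],
    std.error = se[keep], statistic = zstat[keep],
    p.value = 2 * pnorm(-abs(zstat[keep]))
  )
  dropped <- colnames(X_full)[!within_var]
  structure(list(
    coefficients = coef_tab,
    participant_offsets = tibble::tibble(
      participant_id = ids[-1], offset = est[-keep]),
    sigma = exp(opt$par[k + 1]), tau = exp(opt$par[k + 2]),
    loglik = -opt$value, n_obs = nrow(d), n_participants = P,
    covariate = covariate, dropped_terms = dropped,
    converged = opt$convergence == 0 && cov_ok
  ), class = "pp_exgauss_reg")
}

#' @export
tidy.pp_exgauss_reg <- function(x, ...) x$coefficients

#' @export
glance.pp_exgauss_reg <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, tau = x$tau, logLik = x$loglik,
                 nobs = x$n_obs, n_participants = x$n_participants,
                 converged = x$converged)
}

#' @export
print.pp_exgauss_reg <- function(x, ...) {
  cat(sprintf(
    "Ex-Gaussian regression on mu (covariate: %s)\n", x$covariate))
  cat(sprintf("  shared sigma = %.4f, tau = %.4f; %d participants\n",
              x$sigma, x$tau, x$n_participants))
  print(x$coefficients)
  invisible(x)
}
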