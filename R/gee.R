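#' Sum-code a two-level factor
#'
#' Maps the alphabetically first level to +1 and the second to -1, the
#' coding that makes single-column "terms" comparable to ANOVA effects.
#' Interaction columns are elementwise products of main-effect columns.
#'
#' @param x Factor or character vector with exactly two distinct values.
#' @return Numeric vector of +1/-1.
#' @examples
#' sum_code(c("angry", "happy", "angry"))
#' @export
sum_code <- function(x) {
  lv <- sort(unique(as.character(x)))
  if (length(lv) != 2) {
    stop("sum_code() supports exactly 2 levels; got ", length(lv), ".",
         call. = FALSE)
  }
  ifelse(as.character(x) == lv[1], 1, -1)
}

#' Binomial GEE with exchangeable working correlation
#'
#' Marginal logistic regression for clustered binary outcomes, fitted by
#' iteratively reweighted generalised estimating equations. The working
#' correlation is exchangeable (common within-cluster correlation `alpha`,
#' estimated from Pearson residual cross-products each iteration) and
#' standard errors are robust (sandwich) estimates, so inference is valid
#' even if the working structure is wrong. All two-level factor predictors
#' are sum-coded (+1/-1) to make effects comparable to ANOVA terms.
#'
#' With singleton clusters the exchangeable structure is vacuous and the
#' estimates coincide with ordinary logistic maximum likelihood.
#'
#' @param data Trial-level tibble; the response must be binary (logical or
#'   0/1).
#' @param formula Model formula, e.g.
#'   `correct ~ expression * required_response * face_gender`.
#' @param cluster Name of the clustering column (default
#'   `"participant_id"`).
#' @param max_iter,tol Convergence controls: stop when the maximum relative
#'   coefficient change drops below `tol`.
#' @return An object of class `pp_gee`: coefficient table with robust SEs
#'   and Wald z tests, the working correlation `alpha`, the robust
#'   covariance matrix, cluster counts and convergence information. Use
#'   [tidy()] / [glance()] for tibble views and [gee_contrast()] for linear
#'   combinations.
#' @examples
#' d <- generate_dataset(default_scenario(2, seed = 3))
#' f <- filter_rts(d$trials)$trials
#' fit <- fit_gee_binomial(dplyr::filter(f, block != "practice"),
#'                         correct ~ expression * required_response)
#' tidy(fit)
#' @export
fit_gee_binomial <- function(data, formula, cluster = "participant_id",
                             max_iter = 100, tol = 1e-8) {
  stopifnot(cluster %in% names(data))
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop("The response must be binary.", call. = FALSE)
  }
  # sum-code all character/factor predictors
  vars <- attr(stats::terms(mf), "term.labels")
  base_vars <- unique(unlist(strsplit(vars, ":", fixed = TRUE)))
  coded <- mf
  for (v in base_vars) {
    if (is.character(coded[[v]]) || is.factor(coded[[v]])) {
      coded[[v]] <- sum_code(coded[[v]])
    }
  }
  X <- model.matrix(stats::delete.response(stats::terms(mf)), coded)
  id <- data[[cluster]][as.integer(rownames(mf))]
  if (length(unique(id)) < 2) {
    stop("Need at least 2 clusters.", call. = FALSE)
  }

  # initialise at the ordinary logistic ML solution
  fit0 <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- coef(fit0)
  if (any(!is.finite(beta)) || max(abs(beta)) > 30) {
    stop("Separation detected: logistic estimates diverge.", call. = FALSE)
  }
  p <- ncol(X)
  idx <- split(seq_along(y), id)
  n_clusters <- length(idx)
  alpha <- 0
  converged <- FALSE
  iter <- 0

  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    e <- (y - mu) / sqrt(w)

    # moment estimator of the exchangeable correlation
    npairs <- sum(vapply(idx, function(i) {
      ni <- length(i); ni * (ni - 1) / 2
    }, numeric(1)))
    if (npairs > p) {
      cross <- sum(vapply(idx, function(i) {
        (sum(e[i])^2 - sum(e[i]^2)) / 2
      }, numeric(1)))
      phi <- sum(e^2) / (length(y) - p)
      alpha <- cross / (phi * (npairs - p))
      alpha <- max(min(alpha, 0.99), -0.99)
    } else {
      alpha <- 0
    }

    M <- matrix(0, p, p)
    U <- numeric(p)
    for (i in idx) {
      ni <- length(i)
      Ai <- sqrt(w[i])
      Di <- X[i, , drop = FALSE] * w[i]          # dmu/dbeta
      ri <- y[i] - mu[i]
      # V^{-1} r and V^{-1} D with V = A^{1/2} R A^{1/2},
      # R^{-1} = (I - alpha/(1+(ni-1)alpha) J) / (1-alpha)
      solve_V <- function(Mat) {
        Za <- Mat / Ai                           # A^{-1/2} M
        Ra <- (Za - alpha / (1 + (ni - 1) * alpha) *
                 matrix(colSums(Za), ni, ncol(Mat), byrow = TRUE)) /
          (1 - alpha)
        Ra / Ai
      }
      Vinv_D <- solve_V(Di)
      M <- M + crossprod(Di, Vinv_D)
      U <- U + drop(crossprod(Vinv_D, ri))
    }
    delta <- solve(M, U)
    if (any(!is.finite(delta))) {
      stop("GEE update diverged (possible separation).", call. = FALSE)
    }
    beta_new <- beta + delta
    rel <- max(abs(delta) / pmax(abs(beta_new), 1e-4))
    beta <- beta_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }

  # sandwich covariance at the final beta
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  M <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (i in idx) {
    ni <- length(i)
    Ai <- sqrt(w[i])
    Di <- X[i, , drop = FALSE] * w[i]
    ri <- y[i] - mu[i]
    solve_V <- function(Mat) {
      Za <- Mat / Ai
      Ra <- (Za - alpha / (1 + (ni - 1) * alpha) *
               matrix(colSums(Za), ni, ncol(Mat), byrow = TRUE)) /
        (1 - alpha)
      Ra / Ai
    }
    Vinv_D <- solve_V(Di)
    M <- M + crossprod(Di, Vinv_D)
    g <- drop(crossprod(Vinv_D, ri))
    B <- B + tcrossprod(g)
  }
  Minv <- solve(M)
  vcov_rob <- Minv %*% B %*% Minv
  se <- sqrt(diag(vcov_rob))
  z <- beta / se

  coef_tab <- tibble::tibble(
    term = colnames(X), estimate = unname(beta), std.error = unname(se),
    statistic = unname(z), p.value = 2 * pnorm(-abs(z))
  )
  structure(list(coefficients = coef_tab, alpha = alpha,
                 vcov = vcov_rob, n_clusters = n_clusters,
                 n_obs = length(y), converged = converged,
                 n_iter = iter, formula = formula),
            class = "pp_gee")
}

#' Wald test of a linear combination of GEE coefficients
#'
#' @param fit A [fit_gee_binomial()] object.
#' @param L Numeric vector of weights, one per coefficient (in the order of
#'   `tidy(fit)$term`), defining the contrast `L %*% beta`.
#' @return One-row tibble: `estimate`, `std.error`, `statistic` (Wald z),
#'   `p.value`.
#' @export
gee_contrast <- function(fit, L) {
  stopifnot(inherits(fit, "pp_gee"),
            length(L) == nrow(fit$coefficients))
  est <- sum(L * fit$coefficients$estimate)
  se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  z <- est / se
  tibble::tibble(estimate = est, std.error = se, statistic = z,
                 p.value = 2 * pnorm(-abs(z)))
}

#' @export
tidy.pp_gee <- function(x, ...) x$coefficients

#' @export
glance.pp_gee <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_clusters = x$n_clusters,
                 n_obs = x$n_obs, n_iter = x$n_iter,
                 converged = x$converged)
}

#' @export
print.pp_gee <- function(x, ...) {
  cat("Binomial GEE (exchangeable working correlation)\n")
  cat(sprintf("  clusters: %d  obs: %d  alpha: %.4f  converged: %s\n",
              x$n_clusters, x$n_obs, x$alpha, x$converged))
  print(x$coefficients)
  invisible(x)
}
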