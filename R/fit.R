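#' Log-link count regression with quasi-dispersion correction
#'
#' Fits a Poisson log-link regression by iteratively reweighted least
#' squares (convergence when the relative deviance change drops below 1e-8,
#' at most 100 iterations) and estimates the dispersion
#' \eqn{\phi = \chi^2_{Pearson} / df} from the fit. The reported covariance
#' is the quasi-likelihood one, \eqn{\phi (X^T W X)^{-1}}, so standard
#' errors are scaled by \eqn{\sqrt{\phi}} -- the correction appropriate for
#' the under- and over-dispersion typical of arena and field trap counts.
#' Non-convergence is flagged on the returned object rather than raised.
#'
#' @param data A data.frame (e.g. a capture dataset).
#' @param formula Model formula with the count on the left-hand side, e.g.
#'   `count ~ size_class * factor(distance_or_height_cm)`.
#' @return A `count_model_fit`: list with `coefficients`, `covariance`
#'   (quasi-scaled), `dispersion_phi`, `loglik`, `deviance`, `df_residual`,
#'   `converged`, `fitted`, plus the response and design matrix.
#' @examples
#' d <- data.frame(count = c(1, 2, 3))
#' coef(fit_count_model(d, count ~ 1))  # log(2)
#' @export
fit_count_model <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(y < 0) || any(y != round(y))) {
    stop("response must contain non-negative integer counts", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf("design is rank-deficient (empty or aliased cells): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- .irls_poisson(X, y)
  phi <- sum((y - fit$mu)^2 / fit$mu) / (length(y) - ncol(X))
  structure(
    list(coefficients = fit$beta,
         covariance = phi * fit$unscaled_cov,
         unscaled_covariance = fit$unscaled_cov,
         dispersion_phi = phi,
         loglik = sum(stats::dpois(y, fit$mu, log = TRUE)),
         deviance = fit$deviance,
         df_residual = length(y) - ncol(X),
         converged = fit$converged,
         fitted = fit$mu, y = y, X = X,
         formula = formula),
    class = "count_model_fit"
  )
}

.irls_poisson <- function(X, y, epsilon = 1e-8, maxit = 100L) {
  beta <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    eta <- pmin(eta, 30)  # guard against overflow in early iterations
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    WX <- X * mu
    XtWX <- crossprod(X, WX)
    beta <- drop(solve(XtWX, crossprod(WX, z)))
    mu <- exp(pmin(drop(X %*% beta), 30))
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < epsilon) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- pmin(drop(X %*% beta), 30)
  mu <- exp(eta)
  XtWX <- crossprod(X, X * mu)
  list(beta = stats::setNames(beta, colnames(X)), mu = mu,
       deviance = 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu)),
       unscaled_cov = solve(XtWX), converged = converged)
}

#' @export
coef.count_model_fit <- function(object, ...) object$coefficients

#' @export
vcov.count_model_fit <- function(object, ...) object$covariance

#' @export
logLik.count_model_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat("<count_model_fit>", deparse(x$formula), "\n")
  se <- sqrt(diag(x$covariance))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  cat(sprintf("dispersion phi = %.3f; deviance = %.2f on %d df%s\n",
              x$dispersion_phi, x$deviance, x$df_residual,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Likelihood-ratio test between nested count models
#'
#' Compares a full and a reduced fit of the same response. The default
#' statistic is twice the log-likelihood difference referred to a chi-square
#' distribution. With `quasi = TRUE`, the deviance difference is divided by
#' the full model's dispersion and the degrees-of-freedom difference and
#' referred to an F distribution -- the usual approximation when standard
#' errors have been quasi-corrected.
#'
#' @param fit_full,fit_reduced `count_model_fit` objects; the reduced
#'   model's terms must be a subset of the full model's.
#' @param quasi Use the dispersion-scaled F approximation?
#' @return List with `statistic`, `df`, `p_value` (and `df2` for the F form).
#' @export
lr_test <- function(fit_full, fit_reduced, quasi = FALSE) {
  stopifnot(inherits(fit_full, "count_model_fit"),
            inherits(fit_reduced, "count_model_fit"))
  if (length(fit_full$y) != length(fit_reduced$y) ||
      any(fit_full$y != fit_reduced$y)) {
    stop("models were fitted to different responses", call. = FALSE)
  }
  if (!all(colnames(fit_reduced$X) %in% colnames(fit_full$X)) ||
      ncol(fit_reduced$X) >= ncol(fit_full$X)) {
    stop("`fit_reduced` must be strictly nested in `fit_full`", call. = FALSE)
  }
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  if (quasi) {
    stat <- (fit_reduced$deviance - fit_full$deviance) /
      (df * fit_full$dispersion_phi)
    list(statistic = stat, df = df, df2 = fit_full$df_residual,
         p_value = stats::pf(stat, df, fit_full$df_residual,
                             lower.tail = FALSE))
  } else {
    stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
    list(statistic = stat, df = df,
         p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
  }
}

#' Quadratic attraction-range model
#'
#' Regresses counts (log link) on the maximum resolvable range of the trap
#' pattern and its square, the form under which catch rises to a peak and
#' then declines with increasing resolvable range. Row-within-tunnel
#' grouping labels, when present, are absorbed as jointly estimated fixed
#' offsets -- a deliberately simple stand-in for random effects that leaves
#' the quadratic coefficients interpretable.
#'
#' @param data A capture dataset with columns `count` and
#'   `max_resolvable_range_cm` (and optionally `row_id`).
#' @param group_offsets Absorb `row_id` as fixed offsets when available?
#' @return A `count_model_fit` whose coefficients include `max_range` and
#'   `max_range_sq`.
#' @export
fit_quadratic_range_model <- function(data, group_offsets = TRUE) {
  x <- data$max_resolvable_range_cm
  if (length(unique(x)) < 3) {
    stop("at least 3 distinct resolvable-range values are required",
         call. = FALSE)
  }
  d <- data.frame(count = data$count, max_range = x, max_range_sq = x^2)
  form <- count ~ max_range + max_range_sq
  if (group_offsets && "row_id" %in% names(data) &&
      length(unique(stats::na.omit(data$row_id))) > 1) {
    d$group <- factor(data$row_id)
    form <- count ~ max_range + max_range_sq + group
  }
  fit_count_model(d, form)
}

#' Peak of the quadratic attraction-range response
#'
#' For a fitted quadratic with negative curvature, the catch-maximizing
#' resolvable range is \eqn{-\beta_1 / (2 \beta_2)}. The confidence interval
#' is a parametric bootstrap: coefficient draws from the fit's (quasi-scaled)
#' normal approximation, keeping draws with negative curvature, with the
#' interval taken from percentiles of the implied peaks.
#'
#' @param fit A fit from [fit_quadratic_range_model()].
#' @param level Confidence level.
#' @param n_boot Bootstrap draws.
#' @param seed Seed for the draws.
#' @return List with `peak_cm`, `ci` (length 2) and `n_effective_draws`.
#' @examples
#' # peak of log mu = 0.10 x - 0.0019231 x^2 is at 26 cm
#' @export
peak_range <- function(fit, level = 0.95, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "count_model_fit"))
  b <- fit$coefficients
  if (!all(c("max_range", "max_range_sq") %in% names(b))) {
    stop("fit must contain `max_range` and `max_range_sq` terms", call. = FALSE)
  }
  if (b["max_range_sq"] >= 0) {
    stop("no interior maximum: quadratic coefficient is non-negative",
         call. = FALSE)
  }
  peak <- -b["max_range"] / (2 * b["max_range_sq"])
  idx <- match(c("max_range", "max_range_sq"), names(b))
  draws <- .with_seed(seed,
    MASS::mvrnorm(n_boot, mu = b[idx], Sigma = fit$covariance[idx, idx]))
  keep <- draws[, 2] < 0
  peaks <- -draws[keep, 1] / (2 * draws[keep, 2])
  alpha <- (1 - level) / 2
  list(peak_cm = unname(peak),
       ci = unname(stats::quantile(peaks, c(alpha, 1 - alpha))),
       n_effective_draws = sum(keep))
}
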