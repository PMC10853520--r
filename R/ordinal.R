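# Ordinal calibration of tracing error components against human 5-point
# quality ratings: a proportional-odds (cumulative logit) model with
# per-rater intercepts. Rater intercepts are ridge-penalized maximum
# likelihood, with the penalty re-estimated from the fitted intercept
# variance (a PQL-style update), which approximates random rater intercepts.

# Negative penalized log-likelihood of the proportional-odds model.
# theta = (beta, zeta1, log diff(zeta)[...], u). P(Y <= k) = plogis(zeta_k - eta).
po_nll <- function(theta, X, y, rater_idx, n_lev, lambda) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  zraw <- theta[p + seq_len(n_lev - 1)]
  zeta <- cumsum(c(zraw[1], exp(zraw[-1])))
  u <- if (length(theta) > p + n_lev - 1) theta[-(seq_len(p + n_lev - 1))] else numeric(0)
  eta <- as.vector(X %*% beta)
  if (length(u)) eta <- eta + u[rater_idx]
  upper <- c(zeta, Inf)[y]
  lower <- c(-Inf, zeta)[y]
  pr <- stats::plogis(upper - eta) - stats::plogis(lower - eta)
  -sum(log(pmax(pr, 1e-300))) + lambda / 2 * sum(u^2)
}

fit_proportional_odds <- function(X, y, rater = NULL, lambda = 1,
                                  adapt_penalty = TRUE, maxit = 1000) {
  X <- as.matrix(X)
  levs <- sort(unique(y))
  if (length(levs) < 2) {
    stop("ratings have a single level; ordinal fit degenerate", call. = FALSE)
  }
  yi <- match(y, levs)
  n_lev <- length(levs)
  p <- ncol(X)
  if (!is.null(rater)) {
    rater <- as.factor(rater)
    if (nlevels(rater) < 2) rater <- NULL
  }
  rater_idx <- if (is.null(rater)) integer(0) else as.integer(rater)
  n_u <- if (is.null(rater)) 0L else nlevels(rater)

  # start: zero slopes, thresholds from the marginal rating frequencies
  cum <- cumsum(table(factor(yi, levels = seq_len(n_lev))))[-n_lev] / length(yi)
  z0 <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  z0 <- cummax(z0 + seq_len(n_lev - 1) * 1e-6)  # enforce strict order
  th0 <- c(rep(0, p), z0[1], log(pmax(diff(z0), 1e-4)), rep(0, n_u))

  fit_once <- function(lam, start) {
    stats::optim(start, po_nll, X = X, y = yi,
                 rater_idx = rater_idx, n_lev = n_lev, lambda = lam,
                 method = "BFGS", control = list(maxit = maxit, reltol = 1e-10))
  }
  fit <- fit_once(lambda, th0)
  if (n_u > 0 && adapt_penalty) {
    u <- fit$par[-(seq_len(p + n_lev - 1))]
    sig2 <- max(mean(u^2), 1e-3)
    fit <- fit_once(1 / sig2, fit$par)
    lambda <- 1 / sig2
  }
  if (fit$convergence != 0) {
    stop("proportional-odds fit did not converge (optim code ",
         fit$convergence, ")", call. = FALSE)
  }
  H <- stats::optimHess(fit$par, po_nll, X = X, y = yi,
                        rater_idx = rater_idx, n_lev = n_lev, lambda = lambda)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA, length(fit$par),
                                                      length(fit$par)))
  beta <- fit$par[seq_len(p)]
  names(beta) <- colnames(X)
  zraw <- fit$par[p + seq_len(n_lev - 1)]
  zeta <- cumsum(c(zraw[1], exp(zraw[-1])))
  u <- if (n_u) fit$par[-(seq_len(p + n_lev - 1))] else numeric(0)
  se_beta <- sqrt(pmax(diag(vc)[seq_len(p)], 0))
  names(se_beta) <- colnames(X)
  list(beta = beta, se = se_beta, zeta = zeta, levels = levs,
       rater_intercepts = u,
       rater_levels = if (n_u) levels(rater) else character(0),
       rater_var = if (n_u) mean(u^2) else NA_real_,
       lambda = lambda, logLik = -fit$value, convergence = fit$convergence,
       n_obs = length(yi))
}

#' Calibrate tracing error components against human quality ratings
#'
#' Fits a proportional-odds model predicting 5-point tracing-quality ratings
#' from the four registration error components (shape error, translation,
#' rotation, scaling magnitudes) and target-shape identity, with per-rater
#' intercepts (ridge-penalized, penalty set from the estimated intercept
#' variance). The latent linear predictor of this model is the tracing score.
#'
#' @param errors Tibble with one row per tracing: `tracing_id`,
#'   `shape_error`, `translation_mag`, `rotation_mag`, `scaling_mag`,
#'   `shape_id` (and optionally `session_id`).
#' @param ratings Tibble with `tracing_id`, `rater_id`, `rating` (integers,
#'   >= 2 distinct levels; each tracing rated at least once).
#' @param include_raters Set `FALSE` to drop rater intercepts (plain
#'   proportional-odds maximum likelihood).
#' @return An object of class `"tracing_calibration"` with elements
#'   `coefficients`, `se`, `thresholds`, `rater_var`, `logLik`, `n_obs`.
#' @export
fit_tracing_calibration <- function(errors, ratings, include_raters = TRUE) {
  df <- dplyr::inner_join(ratings, errors, by = "tracing_id")
  if (!nrow(df)) stop("no rated tracings after joining", call. = FALSE)
  X <- cbind(shape_error = df$shape_error,
             translation_mag = df$translation_mag,
             rotation_mag = df$rotation_mag,
             scaling_mag = df$scaling_mag,
             shape_star = as.numeric(df$shape_id ==
                                       sort(unique(df$shape_id))[-1][1] &
                                       length(unique(df$shape_id)) > 1))
  if (length(unique(df$shape_id)) < 2) X <- X[, 1:4, drop = FALSE]
  fit <- fit_proportional_odds(
    X, df$rating, rater = if (include_raters) df$rater_id else NULL)
  structure(list(coefficients = fit$beta, se = fit$se,
                 thresholds = fit$zeta, levels = fit$levels,
                 rater_var = fit$rater_var, logLik = fit$logLik,
                 n_obs = fit$n_obs, shape_levels = sort(unique(df$shape_id))),
            class = "tracing_calibration")
}

#' @export
print.tracing_calibration <- function(x, ...) {
  cat("<tracing_calibration> proportional-odds fit,", x$n_obs, "ratings\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("thresholds:", paste(round(x$thresholds, 3), collapse = ", "), "\n")
  if (!is.na(x$rater_var)) cat("rater intercept variance:",
                               round(x$rater_var, 4), "\n")
  invisible(x)
}

#' Score tracings and sessions with a fitted calibration
#'
#' The per-tracing score is the latent-scale linear predictor of the
#' calibration model (rater effects excluded); since the error coefficients
#' are negative, higher scores mean better tracings. Session scores average
#' the session's tracings; a session with none gets no row.
#'
#' @param errors Tibble as in [fit_tracing_calibration()], with `session_id`.
#' @param calibration A `"tracing_calibration"`.
#' @return Tibble with per-session `tracing_score` and `n_tracings`, plus a
#'   `per_tracing` attribute holding the per-tracing scores.
#' @export
score_tracings <- function(errors, calibration) {
  b <- calibration$coefficients
  X <- cbind(errors$shape_error, errors$translation_mag,
             errors$rotation_mag, errors$scaling_mag)
  eta <- as.vector(X %*% b[1:4])
  if (length(b) > 4) {
    star <- as.numeric(errors$shape_id == calibration$shape_levels[-1][1])
    eta <- eta + b[5] * star
  }
  per <- tibble::tibble(tracing_id = errors$tracing_id,
                        session_id = errors$session_id,
                        score = eta)
  out <- dplyr::summarise(dplyr::group_by(per, session_id),
                          tracing_score = mean(score),
                          n_tracings = dplyr::n(), .groups = "drop")
  attr(out, "per_tracing") <- per
  out
}
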