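# The study's statistical models: production GLMM (binary recognizability),
# conditional-evidence LMM (evidence of correctly classified drawings),
# recognition GLMM (4AFC accuracy ~ evidence x recognizer age), and the
# category-level production-recognition correlation. Fitting is delegated
# to lme4 / lmerTest; this module owns the model specifications, predictor
# scaling, and the tidy ModelFit contract (Wald tests, two-tailed, no
# multiple-comparison correction).

z <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

unit <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

tidy_fixed <- function(coefs, satterthwaite = FALSE) {
  est <- coefs[, 1]; se <- coefs[, 2]
  stat <- coefs[, if (satterthwaite) "t value" else "z value"]
  p <- coefs[, ncol(coefs)]
  tibble::tibble(term = rownames(coefs), estimate = est, se = se,
                 statistic = stat, p = p,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 df = if (satterthwaite) coefs[, "df"] else NA_real_)
}

tidy_ranef <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  tibble::tibble(grouping = vc$grp, term = vc$var1, variance = vc$vcov)
}

new_model_fit <- function(model, satterthwaite = FALSE) {
  coefs <- stats::coef(summary(model))
  conv <- is.null(model@optinfo$conv$lme4$messages)
  structure(list(fixed = tidy_fixed(coefs, satterthwaite),
                 random = tidy_ranef(model),
                 n_obs = stats::nobs(model),
                 converged = conv, model = model),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> n = %d, converged: %s\n", x$n_obs, x$converged))
  print(as.data.frame(
    dplyr::mutate(x$fixed, dplyr::across(dplyr::where(is.numeric),
                                         ~ round(.x, 4)))))
  cat("random-effect variances:\n")
  print(as.data.frame(x$random))
  invisible(x)
}

production_predictors <- function(table, scale) {
  sc <- if (scale == "z") z else unit
  dplyr::transmute(
    table,
    correct = correct,
    evidence = if ("evidence" %in% names(table)) evidence else NA_real_,
    age = sc(age), frequency = sc(draw_frequency),
    tracing = sc(tracing_score), time = sc(draw_time_s),
    ink = sc(ink_proportion), strokes = sc(n_strokes),
    participant = factor(session_id), category = factor(category))
}

check_design <- function(table) {
  if (length(unique(table$category)) < 2 ||
        length(unique(table$session_id)) < 2) {
    stop("need >= 2 categories and >= 2 participants", call. = FALSE)
  }
}

#' Production model: drawing recognizability across development
#'
#' Logistic mixed model predicting each drawing's binary classification
#' score from child age, parent-reported drawing frequency, their
#' interaction, tracing score, and the effort covariates (time, ink,
#' strokes), with random intercepts for participant and category.
#' Predictors are z-scored before fitting so coefficients are standardized;
#' tests are two-tailed Wald.
#'
#' @param table Per-drawing tibble with `correct` (logical), `age`,
#'   `draw_frequency`, `tracing_score`, `draw_time_s`, `ink_proportion`,
#'   `n_strokes`, `session_id`, `category`.
#' @param scale `"z"` (default) or `"unit"` (scale predictors to `[0, 1]`).
#' @return A `model_fit`: tidy fixed effects (estimate, SE, z, p, Wald 95%
#'   CI), random-effect variances, `n_obs`, convergence flag, and the lme4
#'   fit. Singular random effects warn but the fit is retained.
#' @export
fit_production_model <- function(table, scale = c("z", "unit")) {
  scale <- match.arg(scale)
  check_design(table)
  df <- production_predictors(table, scale)
  m <- lme4::glmer(
    correct ~ age * frequency + tracing + time + ink + strokes +
      (1 | participant) + (1 | category),
    data = df, family = stats::binomial())
  if (lme4::isSingular(m)) warning("singular random-effect fit retained")
  new_model_fit(m)
}

#' Conditional evidence model: informativeness of recognizable drawings
#'
#' Linear mixed model on the log-odds classifier evidence of correctly
#' classified drawings, with the production model's predictor set and
#' random intercepts for participant and category. Degrees of freedom and
#' p-values use the Satterthwaite approximation.
#'
#' @param table As in [fit_production_model()], restricted to correctly
#'   classified drawings, plus an `evidence` column.
#' @inheritParams fit_production_model
#' @return A `model_fit` with Satterthwaite `df` on the fixed effects.
#' @export
fit_conditional_evidence_model <- function(table, scale = c("z", "unit")) {
  scale <- match.arg(scale)
  if (!all(table$correct)) {
    stop("conditional evidence model applies to correctly classified drawings only",
         call. = FALSE)
  }
  check_design(table)
  df <- production_predictors(table, scale)
  m <- lmerTest::lmer(
    evidence ~ age * frequency + tracing + time + ink + strokes +
      (1 | participant) + (1 | category),
    data = df)
  if (lme4::isSingular(m)) warning("singular random-effect fit retained")
  new_model_fit(m, satterthwaite = TRUE)
}

#' Recognition model: 4AFC accuracy from evidence and recognizer age
#'
#' Logistic mixed model predicting trial-level recognition accuracy from
#' per-drawing classifier evidence, recognizer age, and their interaction,
#' with random intercepts for recognizer and intended category and a random
#' evidence slope by category.
#'
#' @param trials Retained drawing trials with `correct`,
#'   `recognizer_age_years`, `evidence`, `session_id`, `category`.
#' @param scale `"z"` (default; standardized coefficients as in the model
#'   tables) or `"unit"` (predictors scaled to `[0, 1]`).
#' @return A `model_fit`.
#' @export
fit_recognition_model <- function(trials, scale = c("z", "unit")) {
  scale <- match.arg(scale)
  sc <- if (match.arg(scale) == "z") z else unit
  df <- tibble::tibble(
    correct = trials$correct,
    evidence = sc(trials$evidence),
    age = sc(trials$recognizer_age_years),
    subject = factor(trials$session_id),
    category = factor(trials$category))
  m <- lme4::glmer(
    correct ~ evidence * age + (1 | subject) + (1 + evidence | category),
    data = df, family = stats::binomial())
  if (lme4::isSingular(m)) warning("singular random-effect fit retained")
  new_model_fit(m)
}

#' Category-level production-recognition correlation
#'
#' Relates how recognizable children's drawings of a category are
#' (production side: mean classification accuracy) to how well children
#' recognize drawings of that category in the 4AFC games (recognition
#' side), restricting the recognition side to the `top_fraction` most
#' recognizable drawings per category ranked by classifier evidence (ties
#' broken by drawing id). Pearson correlation across categories aggregated
#' over age, with a two-tailed test and 95% CI; a per-(category, age) table
#' is returned for plotting.
#'
#' @param production Tibble (`category`, `age_years`, `production_score`,
#'   optionally `n_drawings`).
#' @param recognition_trials Retained drawing trials with `category`,
#'   `recognizer_age_years`, `correct`, `drawing_id` and per-drawing
#'   `evidence`.
#' @param top_fraction Fraction of most recognizable drawings kept per
#'   category (default 0.3).
#' @return List with `r`, `ci`, `p`, `df`, `by_category` and
#'   `by_category_age` tibbles.
#' @export
production_recognition_correlation <- function(production,
                                               recognition_trials,
                                               top_fraction = 0.3) {
  cats <- sort(unique(production$category))
  if (length(cats) < 3) stop("need >= 3 categories", call. = FALSE)
  dr <- unique(recognition_trials[, c("drawing_id", "category", "evidence")])
  keep_ids <- unlist(lapply(split(dr, dr$category), function(d) {
    d <- d[order(-d$evidence, d$drawing_id), ]
    utils::head(d$drawing_id, max(1, ceiling(top_fraction * nrow(d))))
  }))
  top <- recognition_trials[recognition_trials$drawing_id %in% keep_ids, ]
  rec_cat <- dplyr::summarise(dplyr::group_by(top, category),
                              recognition_score = mean(correct),
                              n_trials = dplyr::n(), .groups = "drop")
  rec_cat_age <- dplyr::summarise(
    dplyr::group_by(top, category, age_years = recognizer_age_years),
    recognition_score = mean(correct), n_trials = dplyr::n(),
    .groups = "drop")
  prod_cat <- dplyr::summarise(dplyr::group_by(production, category),
                               production_score = mean(production_score),
                               .groups = "drop")
  joint <- dplyr::inner_join(prod_cat, rec_cat, by = "category")
  ct <- stats::cor.test(joint$production_score, joint$recognition_score,
                        method = "pearson")
  list(r = unname(ct$estimate),
       ci = unname(ct$conf.int), p = ct$p.value,
       df = unname(ct$parameter),
       by_category = joint,
       by_category_age = dplyr::left_join(
         rec_cat_age,
         dplyr::select(production, category, age_years, production_score),
         by = c("category", "age_years")))
}
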