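# Mixed-model specifications: recovery, scaling invariance, degenerate
# designs, and the production-recognition correlation.

test_that("production model recovers a planted age effect", {
  d <- simulate_production_data(
    n_participants = 350, n_categories = 12, drawings_per_participant = 8,
    beta = c(intercept = -0.5, age = 0.25, tracing = 0.3), seed = 2)
  fit <- fit_production_model(d)
  fe <- fit$fixed
  b_age <- fe[fe$term == "age", ]
  expect_lt(abs(b_age$estimate - 0.25), 2 * b_age$se)
  b_tr <- fe[fe$term == "tracing", ]
  expect_lt(abs(b_tr$estimate - 0.3), 2 * b_tr$se)
  expect_true(all(c("participant", "category") %in% fit$random$grouping))
  expect_equal(fe$ci_low, fe$estimate - 1.96 * fe$se)
})

test_that("standardized estimates are invariant to predictor rescaling", {
  d <- simulate_production_data(n_participants = 120, n_categories = 8,
                                beta = c(intercept = 0, age = 0.3), seed = 3)
  d2 <- d
  d2$draw_time_s <- d2$draw_time_s * 10 + 100
  d2$n_strokes <- d2$n_strokes * 3
  f1 <- suppressWarnings(fit_production_model(d))
  f2 <- suppressWarnings(fit_production_model(d2))
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-5)
})

test_that("degenerate designs are rejected with clear errors", {
  d <- simulate_production_data(n_participants = 30, n_categories = 1,
                                seed = 4)
  expect_error(fit_production_model(d), ">= 2 categories")
  d2 <- simulate_production_data(n_participants = 30, n_categories = 6,
                                 response = "evidence", seed = 5)
  d2$correct[1] <- FALSE
  expect_error(fit_conditional_evidence_model(d2), "correctly classified")
})

test_that("conditional evidence model recovers with Satterthwaite df", {
  d <- simulate_production_data(
    n_participants = 300, n_categories = 12, drawings_per_participant = 6,
    beta = c(intercept = 0.2, age = 0.111), response = "evidence",
    sigma = 1, seed = 6)
  fit <- fit_conditional_evidence_model(d)
  b <- fit$fixed[fit$fixed$term == "age", ]
  expect_lt(abs(b$estimate - 0.111), 2 * b$se)
  expect_false(is.na(b$df))

  # constant evidence -> all slopes near zero
  d0 <- d; d0$evidence <- 1.7
  f0 <- suppressWarnings(fit_conditional_evidence_model(d0))
  slopes <- f0$fixed$estimate[f0$fixed$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-6))
})

test_that("recognition model recovers planted evidence x age interaction", {
  d <- simulate_recognition_data(
    n_subjects = 250, trials_per_subject = 12,
    beta = c(intercept = 0.1, evidence = 0.5, age = 0.3,
             interaction = 0.12), seed = 7)
  fit <- suppressWarnings(fit_recognition_model(d))
  fe <- fit$fixed
  for (nm in c("evidence", "age")) {
    row <- fe[fe$term == nm, ]
    expect_lt(abs(row$estimate - attr(d, "truth")$beta[[nm]]), 2 * row$se)
  }
  ia <- fe[fe$term == "evidence:age", ]
  expect_gt(ia$estimate, 0)
  expect_lt(abs(ia$estimate - 0.12), 2 * ia$se)
  expect_true("category" %in%
                fit$random$grouping[fit$random$term %in% "evidence"])
})

test_that("production-recognition correlation behaves at its limits", {
  set.seed(9)
  cats <- paste0("c", 1:16)
  prod <- tibble::tibble(category = rep(cats, each = 5),
                         age_years = rep(4:8, 16),
                         production_score = runif(80))
  # recognition trials engineered so category accuracy equals the
  # category's mean production score -> r = 1
  trials <- dplyr::bind_rows(lapply(cats, function(cn) {
    p <- mean(prod$production_score[prod$category == cn])
    n <- 50
    tibble::tibble(session_id = sprintf("%s_s%02d", cn, 1:n),
                   recognizer_age_years = rep(4:8, 10),
                   trial_type = "drawing", category = cn,
                   drawing_id = sprintf("%s_d%02d", cn, rep(1:10, 5)),
                   evidence = rep(seq(-1, 1, length.out = 10), 5),
                   correct = rep(c(TRUE, FALSE),
                                 c(round(p * n), n - round(p * n))))
  }))
  # top-30% filter keeps the highest-evidence drawings; correctness is
  # spread uniformly so accuracy is preserved in expectation, use all
  res <- production_recognition_correlation(prod, trials, top_fraction = 1)
  expect_equal(res$r, cor(res$by_category$production_score,
                          res$by_category$recognition_score))
  expect_gt(res$r, 0.99)

  expect_error(production_recognition_correlation(prod[1:10, ], trials),
               ">= 3")

  # independent scores -> |r| small on average; just check it runs and
  # reports a CI straddling the estimate
  trials$correct <- sample(c(TRUE, FALSE), nrow(trials), replace = TRUE)
  r2 <- production_recognition_correlation(prod, trials, top_fraction = 0.3)
  expect_lt(r2$ci[1], r2$r); expect_gt(r2$ci[2], r2$r)
  # the top-fraction restriction keeps ~30% of each category's drawings
  kept <- unique(r2$by_category_age$category)
  expect_setequal(kept, cats)
})

test_that("shared category difficulty yields a positive correlation", {
  set.seed(10)
  cats <- paste0("c", 1:16)
  diff_c <- rnorm(16, 0, 1)
  prod <- tibble::tibble(category = cats, age_years = 6,
                         production_score = plogis(diff_c + rnorm(16, 0, 0.3)))
  trials <- dplyr::bind_rows(lapply(seq_along(cats), function(i) {
    n <- 80
    tibble::tibble(session_id = sprintf("s%03d", 1:n),
                   recognizer_age_years = sample(4:8, n, TRUE),
                   trial_type = "drawing", category = cats[i],
                   drawing_id = sprintf("%s_d%02d", cats[i], rep(1:20, 4)),
                   evidence = rnorm(n),
                   correct = runif(n) < plogis(diff_c[i]))
  }))
  res <- production_recognition_correlation(prod, trials)
  expect_gt(res$r, 0.3)
  expect_lt(res$p, 0.05)
})
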