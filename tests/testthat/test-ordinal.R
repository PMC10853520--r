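# Ordinal calibration of tracing errors against quality ratings, and
# session-level scoring.

make_errors <- function(n = 400, seed = 31) {
  set.seed(seed)
  tibble::tibble(
    tracing_id = sprintf("t%04d", seq_len(n)),
    session_id = sprintf("s%04d", rep(seq_len(n / 2), each = 2)),
    shape_error = runif(n, 0, 0.8),
    translation_mag = runif(n, 0, 25),
    rotation_mag = runif(n, 0, 0.5),
    scaling_mag = runif(n, 0, 0.6),
    shape_id = rep(c("square", "star"), n / 2))
}

true_beta <- c(-4, -0.08, -3, -2.5, -0.5)
true_th <- c(-4.5, -2.5, -0.8, 1.2)

test_that("calibration fit matches MASS::polr in the fixed-effects mode", {
  errors <- make_errors(300)
  rt <- generate_ratings(errors, true_beta, true_th, rater_sd = 0,
                         n_raters = 1, ratings_per_tracing = 2, seed = 6)
  cal <- fit_tracing_calibration(errors, rt, include_raters = FALSE)
  df <- dplyr::inner_join(rt, errors, by = "tracing_id")
  pol <- MASS::polr(factor(rating) ~ shape_error + translation_mag +
                      rotation_mag + scaling_mag + I(shape_id == "star"),
                    data = df)
  expect_equal(unname(cal$coefficients), unname(coef(pol)), tolerance = 1e-3)
  expect_equal(unname(cal$thresholds), unname(pol$zeta), tolerance = 1e-3)
})

test_that("known coefficients are recovered within 2 SE with rater effects", {
  errors <- make_errors(500, seed = 32)
  rt <- generate_ratings(errors, true_beta, true_th, rater_sd = 0.5,
                         n_raters = 25, ratings_per_tracing = 3, seed = 7)
  cal <- fit_tracing_calibration(errors, rt)
  expect_gte(nrow(rt), 1500)
  expect_true(all(abs(cal$coefficients - true_beta) < 2 * cal$se))
  expect_true(all(diff(cal$thresholds) > 0))
})

test_that("null calibration reproduces marginal rating frequencies", {
  errors <- make_errors(400, seed = 33)
  errors[c("shape_error", "translation_mag", "rotation_mag",
           "scaling_mag")] <- 0
  rt <- generate_ratings(errors, rep(0, 5), true_th, rater_sd = 0,
                         n_raters = 1, ratings_per_tracing = 2, seed = 8)
  cal <- fit_tracing_calibration(errors, rt, include_raters = FALSE)
  # zero-variance predictors are unidentified; their effect on the linear
  # predictor is nil, and thresholds recover the marginal frequencies
  marg <- cumsum(prop.table(table(rt$rating)))[1:4]
  expect_equal(unname(plogis(cal$thresholds)), unname(marg),
               tolerance = 0.02)
})

test_that("duplicating every row leaves point estimates unchanged", {
  errors <- make_errors(200, seed = 34)
  rt <- generate_ratings(errors, true_beta, true_th, rater_sd = 0,
                         n_raters = 1, ratings_per_tracing = 1, seed = 9)
  cal1 <- fit_tracing_calibration(errors, rt, include_raters = FALSE)
  cal2 <- fit_tracing_calibration(errors,
                                  dplyr::bind_rows(rt, rt),
                                  include_raters = FALSE)
  expect_equal(cal1$coefficients, cal2$coefficients, tolerance = 1e-4)
  expect_equal(cal1$thresholds, cal2$thresholds, tolerance = 1e-4)
})

test_that("degenerate ratings error out", {
  errors <- make_errors(50, seed = 35)
  rt <- tibble::tibble(tracing_id = errors$tracing_id,
                       rater_id = "r1", rating = 3L)
  expect_error(fit_tracing_calibration(errors, rt), "single level")
  expect_error(fit_tracing_calibration(errors[0, ], rt[0, ]), "no rated")
})

test_that("session scores average tracings and order by quality", {
  errors <- make_errors(200, seed = 36)
  rt <- generate_ratings(errors, true_beta, true_th, rater_sd = 0.3,
                         n_raters = 10, ratings_per_tracing = 2, seed = 10)
  cal <- fit_tracing_calibration(errors, rt)

  perfect <- errors[1, ]
  perfect[c("shape_error", "translation_mag", "rotation_mag",
            "scaling_mag")] <- 0
  worst <- errors[which.max(errors$shape_error), ]
  both <- dplyr::bind_rows(perfect, worst)
  both$session_id <- c("sA", "sB")
  sc <- score_tracings(both, cal)
  expect_gt(sc$tracing_score[sc$session_id == "sA"],
            sc$tracing_score[sc$session_id == "sB"])

  # two tracings in one session average exactly
  two <- errors[1:2, ]; two$session_id <- "sX"
  sc2 <- score_tracings(two, cal)
  per <- attr(sc2, "per_tracing")
  expect_equal(sc2$tracing_score, mean(per$score))
  expect_equal(sc2$n_tracings, 2L)

  # sessions with zero tracings yield no row (missing, not zero)
  expect_false("ghost" %in% score_tracings(errors, cal)$session_id)
})

test_that("session scores correlate across shapes under shared skill", {
  set.seed(41)
  n_sess <- 120
  skill <- runif(n_sess)   # high skill -> low errors on both shapes
  rows <- list()
  for (s in seq_len(n_sess)) {
    for (shape in c("square", "star")) {
      noise <- (1 - skill[s]) * abs(rnorm(4, 0, c(0.3, 8, 0.15, 0.2)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        tracing_id = paste0("t", s, shape),
        session_id = paste0("s", s), shape_id = shape,
        shape_error = noise[1], translation_mag = noise[2],
        rotation_mag = noise[3], scaling_mag = noise[4])
    }
  }
  errors <- dplyr::bind_rows(rows)
  rt <- generate_ratings(errors, true_beta, true_th, rater_sd = 0.3,
                         n_raters = 15, ratings_per_tracing = 2, seed = 11)
  cal <- fit_tracing_calibration(errors, rt)
  per <- attr(score_tracings(errors, cal), "per_tracing")
  per$shape_id <- errors$shape_id[match(per$tracing_id, errors$tracing_id)]
  wide <- tidyr::pivot_wider(per[, c("session_id", "shape_id", "score")],
                             names_from = shape_id, values_from = score)
  expect_gt(cor(wide$square, wide$star), 0)
})
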