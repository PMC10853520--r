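# Synthetic-data generators: determinism, boundary behavior, and the
# statistical properties the downstream analyses rely on.

test_that("category library has the requested composition and is seeded", {
  lib <- generate_category_library(48, 22, seed = 1)
  meta <- library_meta(lib)
  expect_length(lib, 48)
  expect_equal(sum(meta$animate), 22)
  expect_equal(sum(!meta$animate), 26)
  expect_true(all(is.na(meta$big[meta$animate])))
  expect_true(all(!is.na(meta$big[!meta$animate])))

  expect_identical(generate_category_library(2, 1, seed = 7),
                   generate_category_library(2, 1, seed = 7))
  expect_true(all(!library_meta(generate_category_library(4, 0, seed = 3))$animate))
  expect_error(generate_category_library(1, 0), ">= 2")
})

test_that("drawing generator respects noise-free and empty limits", {
  lib <- tiny_library(4, 2)
  tmpl <- lib[[1]]
  am0 <- age_model(jitter_base = 0, jitter_slope = 0, jitter_min = 0)
  d <- generate_drawing(tmpl, 6, am0, seed = 3, inclusion_prob = 1)
  expect_length(d$strokes, length(tmpl$parts))
  # strokes equal the templates up to the fixed placement scaling
  canvas <- d$canvas_size[1]
  expected <- tmpl$parts[[1]]$poly * (canvas - 2 * 0.1 * canvas) + 0.1 * canvas
  expect_equal(unclass(d$strokes[[1]])[, 1:2], expected, ignore_attr = TRUE)
  expect_identical(attr(d, "true_parts"),
                   vapply(tmpl$parts, `[[`, character(1), "label"))

  d0 <- generate_drawing(tmpl, 6, am0, seed = 3, inclusion_prob = 0)
  expect_length(d0$strokes, 0)
})

test_that("part inclusion matches its binomial rate", {
  lib <- tiny_library(2, 1)
  tmpl <- lib[[1]]
  n_parts <- length(tmpl$parts)
  n <- 500
  incl <- vapply(seq_len(n), function(k) {
    length(generate_drawing(tmpl, 5, seed = k, inclusion_prob = 0.6)$strokes)
  }, numeric(1))
  p_hat <- mean(incl) / n_parts
  se <- sqrt(0.6 * 0.4 / (n * n_parts))
  expect_lt(abs(p_hat - 0.6), 3 * se)
})

test_that("tracing trials carry exact ground truth", {
  tg <- tracing_target("square", size = 96)
  id <- generate_tracing_trial(tg, affine_params(), 0, seed = 1)
  expect_equal(id$raster, tg$raster)   # identity, zero noise

  sh <- generate_tracing_trial(tg, affine_params(tx = 5, ty = 3), 0, seed = 1)
  com <- function(img) {
    w <- 1 - img; w <- w / sum(w)
    c(sum(w * (col(img) - 1)), sum(w * (row(img) - 1)))
  }
  expect_equal(com(sh$raster) - com(tg$raster), c(5, 3), tolerance = 0.05)

  expect_identical(generate_tracing_trial(tg, affine_params(theta = 0.1),
                                          1, seed = 9)$raster,
                   generate_tracing_trial(tg, affine_params(theta = 0.1),
                                          1, seed = 9)$raster)
  expect_error(generate_tracing_trial(tg, list(sx = 0)), "positive")
})

test_that("toy encoder limits: null gives chance, full signal separates", {
  lib <- tiny_library(6, 3)
  draws <- make_drawings(lib, per_category = 6, seed = 4)
  targets <- targets_of(draws)
  # signal 1: nearest prototype is perfect
  e1 <- toy_encode(draws, lib, signal = 1, seed = 5)
  lab <- toy_label_embeddings(lib)
  zs <- zero_shot_classify(e1, lab, targets)
  expect_true(all(zs$correct))
  # determinism per (drawing, seed); seed only enters through the noise
  expect_identical(e1, toy_encode(draws, lib, signal = 1, seed = 5))
  eh <- toy_encode(draws, lib, signal = 0.5, seed = 5)
  expect_identical(eh, toy_encode(draws, lib, signal = 0.5, seed = 5))
  expect_false(identical(eh, toy_encode(draws, lib, signal = 0.5, seed = 6)))
  # signal 0: no category information -> chance accuracy
  e0 <- prepare_features(toy_encode(draws, lib, signal = 0, seed = 5))
  cv <- balanced_crossval_classify(e0, targets, 2, seed = 6)
  se <- sqrt((1 / 6) * (5 / 6) / nrow(cv))
  expect_lt(abs(mean(cv$correct) - 1 / 6), 3 * se + 0.05)
})

test_that("annotation generator recovers truth at full agreement and is seeded", {
  lib <- tiny_library(2, 1)
  d <- generate_drawing(lib[[1]], 8, seed = 2, inclusion_prob = 1)
  ann <- generate_annotations(d, agreement_rate = 1, n_raters = 3, seed = 3)
  cons <- consensus_labels(ann)
  expect_identical(cons$strokes$consensus, attr(d, "true_parts"))
  expect_identical(generate_annotations(d, agreement_rate = 0.4, seed = 7),
                   generate_annotations(d, agreement_rate = 0.4, seed = 7))
})

test_that("zero-agreement consensus matches the analytic collision rate", {
  lib <- tiny_library(2, 1)
  vocab <- c(paste0("v", 1:9))
  cons_frac <- c()
  for (s in 1:40) {
    d <- generate_drawing(lib[[1 + s %% 2]], 8, seed = s,
                          inclusion_prob = 1)
    truth <- attr(d, "true_parts")
    ann <- generate_annotations(d, true_parts = truth, agreement_rate = 0,
                                n_raters = 3, seed = 100 + s,
                                vocabulary = c(vocab, truth))
    cons <- consensus_labels(ann)
    cons_frac <- c(cons_frac, cons$strokes$consensus != "no-consensus")
  }
  # each rater errs uniformly over the 9 + |truth|-1 wrong labels plus
  # "unintelligible"; alternatives per stroke m = 9 + n_parts - 1 + 1
  n_parts <- length(lib[[1]]$parts)
  m <- 9 + n_parts
  p_collide <- 1 - (m * (m - 1) * (m - 2)) / m^3
  se <- sqrt(p_collide * (1 - p_collide) / length(cons_frac))
  expect_lt(abs(mean(cons_frac) - p_collide), 4 * se)
})

test_that("rating generator obeys its proportional-odds truth", {
  errors <- tibble::tibble(
    tracing_id = sprintf("t%03d", 1:400), session_id = "s",
    shape_error = 0, translation_mag = 0, rotation_mag = 0,
    scaling_mag = 0, shape_id = "square")
  expect_error(generate_ratings(errors, rep(0, 4), c(1, 0.5, 2, 3)),
               "strictly increasing")
  # symmetric thresholds, zero predictors -> symmetric rating distribution
  rt <- generate_ratings(errors, rep(0, 4), c(-2, -0.7, 0.7, 2),
                         rater_sd = 0, ratings_per_tracing = 3, seed = 4)
  tab <- table(factor(rt$rating, levels = 1:5)) / nrow(rt)
  expect_lt(abs(tab[[1]] - tab[[5]]), 0.05)
  expect_lt(abs(tab[[2]] - tab[[4]]), 0.05)
  # extreme negative linear predictor concentrates at 1
  errors$shape_error <- 2
  rt1 <- generate_ratings(errors, c(-20, 0, 0, 0), c(-2, -0.7, 0.7, 2),
                          rater_sd = 0, seed = 5)
  expect_true(all(rt1$rating == 1))
})

test_that("recognition sessions hit chance when sensitivity is zero and saturate", {
  de <- tibble::tibble(drawing_id = sprintf("d%02d", 1:20),
                       category = rep(c("a", "b", "c", "d"), 5),
                       evidence = rnorm(20))
  tr <- generate_recognition_sessions(de, n_sessions = 60, beta0 = 0,
                                      beta_age = 0, catch_error_rate = 0,
                                      dont_know_rate = 0, seed = 3)
  dt <- tr[tr$trial_type == "drawing", ]
  se <- sqrt(0.25 * 0.75 / nrow(dt))
  expect_lt(abs(mean(dt$correct) - 0.25), 3 * se)

  de_hi <- de; de_hi$evidence <- 50
  tr_hi <- generate_recognition_sessions(de_hi, n_sessions = 20, beta0 = 1,
                                         beta_age = 0, dont_know_rate = 0,
                                         seed = 4)
  expect_gt(mean(tr_hi$correct[tr_hi$trial_type == "drawing"]), 0.99)
})

test_that("age monotonicity holds by construction", {
  lib <- tiny_library(4, 2)
  am <- age_model()
  mean_parts <- vapply(c(3, 6, 9), function(a) {
    mean(vapply(1:60, function(k) {
      length(generate_drawing(lib[[1 + k %% 4]], a, am, seed = k)$strokes)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_parts) > 0))
  expect_true(all(diff(vapply(c(3, 6, 9), am$jitter_px, numeric(1))) <= 0))
})
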