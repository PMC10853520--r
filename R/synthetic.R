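# Synthetic-data generators. Every input the pipeline consumes — drawings,
# tracings, ratings, part annotations, recognition sessions and embeddings —
# can be generated with controllable ground truth, so every downstream stage
# is testable end to end without any external data. Defaults mirror the
# study conditions: 48 categories (22 animate / 26 inanimate), children aged
# 2-10, a 30 s drawing cap, 4AFC games over sets of 4 categories, and three
# raters per annotated stroke. All generators are pure functions of their
# parameters and seed; independent streams are derived via child_seed().

#' Age model for synthetic drawings
#'
#' Captures the two age-graded properties the drawing generator emulates:
#' the probability that any given object part is included grows linearly
#' with age, and motor noise (Gaussian contour jitter, in canvas pixels)
#' shrinks with age.
#'
#' @param inclusion_base Per-part inclusion probability at the youngest age.
#' @param inclusion_slope Increase in inclusion probability per year.
#' @param jitter_base Contour jitter (px) at the youngest age.
#' @param jitter_slope Change in jitter per year (non-positive).
#' @param jitter_min Floor on the jitter scale.
#' @param min_age Youngest modeled age in years.
#' @return List of functions `inclusion_prob(age)`, `jitter_px(age)`.
#' @export
age_model <- function(inclusion_base = 0.35, inclusion_slope = 0.07,
                      jitter_base = 4, jitter_slope = -0.35,
                      jitter_min = 0.5, min_age = 2) {
  stopifnot(jitter_slope <= 0)
  list(
    inclusion_prob = function(age) {
      clip01(inclusion_base + inclusion_slope * (age - min_age))
    },
    jitter_px = function(age) {
      pmax(jitter_min, jitter_base + jitter_slope * (age - min_age))
    })
}

# Random open polyline inside a given box: a smoothed random walk.
random_polyline <- function(box, n_pts = 6) {
  x <- cumsum(stats::rnorm(n_pts)); y <- cumsum(stats::rnorm(n_pts))
  x <- (x - min(x)) / max(diff(range(x)), 1e-6)
  y <- (y - min(y)) / max(diff(range(y)), 1e-6)
  cbind(box[1] + x * (box[3] - box[1]), box[2] + y * (box[4] - box[2]))
}

#' Generate a library of category templates
#'
#' Each category is a set of named parts (polyline templates in the unit
#' square with positive salience weights). Categories within the same
#' animacy class share a subset of parts drawn from a class-level pool, so
#' that classifier confusions concentrate within animacy class — the
#' structure the semantic-attribute analyses probe. Half of the inanimate
#' categories are flagged "big" (larger than a chair); size is undefined for
#' animals.
#'
#' @param n_categories Number of categories (>= 2). Default 48.
#' @param n_animate Number of animate categories. Default 22.
#' @param seed Integer seed.
#' @param n_shared Parts shared from the class pool per category.
#' @param n_unique_range Range of category-specific part counts.
#' @param big_fraction Fraction of inanimate categories flagged big.
#' @return List of `category_template` objects with attributes
#'   `embedding_seed` and `meta` (a [category_meta()] tibble).
#' @export
generate_category_library <- function(n_categories = 48, n_animate = 22,
                                      seed = 1, n_shared = 3,
                                      n_unique_range = c(2, 3),
                                      big_fraction = 0.5) {
  if (n_categories < 2) stop("need >= 2 categories", call. = FALSE)
  stopifnot(n_animate >= 0, n_animate <= n_categories)
  set.seed(child_seed(seed, "library"))
  pool_size <- 4
  # class-level part pools: animate categories share one pool; inanimate
  # categories draw mostly from a size-specific sub-pool plus a common
  # inanimate pool, so confusions concentrate within animacy class and,
  # among inanimate categories, within real-world size class
  pools <- list(
    animate = paste0("apart_", letters[seq_len(pool_size)]),
    inanimate_big = paste0("bpart_", letters[1:3]),
    inanimate_small = paste0("spart_", letters[1:3]),
    inanimate_common = paste0("ipart_", letters[1:2]))
  animate <- c(rep(TRUE, n_animate), rep(FALSE, n_categories - n_animate))
  n_inan <- n_categories - n_animate
  big <- rep(NA, n_categories)
  if (n_inan > 0) {
    n_big <- round(big_fraction * n_inan)
    big[!animate] <- sample(c(rep(TRUE, n_big), rep(FALSE, n_inan - n_big)))
  }
  templates <- vector("list", n_categories)
  for (i in seq_len(n_categories)) {
    shared <- if (animate[i]) {
      sample(pools$animate, min(n_shared, pool_size))
    } else {
      size_pool <- if (isTRUE(big[i])) pools$inanimate_big else
        pools$inanimate_small
      c(sample(size_pool, min(n_shared - 1, length(size_pool))),
        sample(pools$inanimate_common, 1))
    }
    n_uni <- sample(seq(n_unique_range[1], n_unique_range[2]), 1)
    uniq <- sprintf("cat%02d_part%d", i, seq_len(n_uni))
    labels <- c(shared, uniq)
    # canonical layout: each part in its own cell of a jittered grid
    k <- length(labels)
    ncell <- ceiling(sqrt(k))
    parts <- vector("list", k)
    for (j in seq_len(k)) {
      row <- (j - 1) %/% ncell; col <- (j - 1) %% ncell
      pad <- 0.06
      box <- c(col / ncell + pad, row / ncell + pad,
               (col + 1) / ncell - pad, (row + 1) / ncell - pad)
      parts[[j]] <- list(label = labels[j],
                         poly = random_polyline(box),
                         salience = stats::runif(1, 0.5, 1.5))
    }
    templates[[i]] <- structure(
      list(category = sprintf("cat%02d", i), parts = parts,
           animate = animate[i], big = big[i]),
      class = "category_template")
  }
  names(templates) <- vapply(templates, `[[`, character(1), "category")
  attr(templates, "embedding_seed") <- child_seed(seed, "embeddings")
  attr(templates, "meta") <- category_meta(
    category = names(templates), animate = animate, big = big,
    draw_frequency = stats::runif(n_categories, 0, 5))
  templates
}

#' Metadata tibble of a category library
#' @param library Output of [generate_category_library()].
#' @return The [category_meta()] tibble stored with the library.
#' @export
library_meta <- function(library) attr(library, "meta")

#' Generate one synthetic drawing from a category template
#'
#' Each part of the template is independently included with its
#' age-dependent probability and rendered as one jittered polyline stroke;
#' the ground-truth part label of every stroke is retained in the
#' `true_parts` attribute for annotation and part-metric tests.
#'
#' @param template A `category_template`.
#' @param age_years Child age in years.
#' @param model An [age_model()].
#' @param seed Integer seed.
#' @param drawing_id,session_id Identifiers (defaults derived from seed).
#' @param canvas Canvas side in pixels.
#' @param inclusion_prob Optional constant inclusion probability overriding
#'   the age model (used for calibration checks).
#' @return A [drawing()] with attribute `true_parts`.
#' @export
generate_drawing <- function(template, age_years, model = age_model(),
                             seed = 1,
                             drawing_id = sprintf("%s_a%d_s%d",
                                                  template$category,
                                                  age_years, seed),
                             session_id = drawing_id, canvas = 224,
                             inclusion_prob = NULL) {
  set.seed(child_seed(seed, paste0("draw:", drawing_id)))
  p_inc <- inclusion_prob %||% model$inclusion_prob(age_years)
  jit <- model$jitter_px(age_years)
  margin <- 0.1 * canvas
  scale <- canvas - 2 * margin
  strokes <- list()
  labels <- character(0)
  t0 <- 0
  for (part in template$parts) {
    if (stats::runif(1) > p_inc) next
    pts <- part$poly * scale + margin
    if (jit > 0) pts <- pts + matrix(stats::rnorm(length(pts), 0, jit),
                                     ncol = 2)
    pts[, 1] <- pmin(pmax(pts[, 1], 0), canvas - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), canvas - 1)
    tt <- t0 + seq(0, 400, length.out = nrow(pts))
    t0 <- t0 + 600
    strokes <- c(strokes, list(cbind(pts, tt)))
    labels <- c(labels, part$label)
  }
  d <- drawing(drawing_id = drawing_id, strokes = strokes,
               category = template$category, age_years = age_years,
               session_id = session_id, canvas_size = c(canvas, canvas),
               draw_time_s = min(30, 0.6 * length(strokes) +
                                   stats::rexp(1, 2)))
  attr(d, "true_parts") <- labels
  d
}

#' Generate a synthetic tracing trial with known ground truth
#'
#' The tracing is the target contour transformed by a known affine map plus
#' Gaussian contour jitter; the true transform is retained so registration
#' recovery can be verified.
#'
#' @param target A [tracing_target()].
#' @param true_affine [affine_params()] applied to the contour.
#' @param contour_noise Gaussian jitter SD in pixels.
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @return A `tracing_trial` with attribute `true_affine`.
#' @export
generate_tracing_trial <- function(target, true_affine = affine_params(),
                                   contour_noise = 0, seed = 1,
                                   session_id = paste0("trace_s", seed)) {
  if (!inherits(true_affine, "affine_params")) {
    true_affine <- do.call(affine_params, true_affine)
  }
  set.seed(child_seed(seed, paste0("trace:", session_id)))
  c0 <- (target$size - 1) / 2
  pts <- apply_affine(target$contour, true_affine, center = c(c0, c0))
  if (contour_noise > 0) {
    pts <- pts + matrix(stats::rnorm(length(pts), 0, contour_noise), ncol = 2)
  }
  tr <- tracing_trial(session_id = session_id, shape_id = target$shape_id,
                      strokes = list(pts), target = target)
  attr(tr, "true_affine") <- true_affine
  tr
}

# Deterministic random vector for a string key under a base seed.
key_vector <- function(base_seed, key, dim) {
  set.seed(child_seed(base_seed, key))
  stats::rnorm(dim)
}

#' Toy encoder: embeddings with controllable category signal
#'
#' Stands in for a pretrained visual encoder so that classification stages
#' are testable offline. The embedding of a drawing is
#' `signal * (category prototype + mean of part vectors present) +
#' (1 - signal) * noise`; part vectors are shared across categories with the
#' same part label, so categories that share parts (within an animacy class)
#' are confusable at intermediate signal. Deterministic per (drawing, seed).
#'
#' @param drawings A [drawing()] or list of drawings (with `true_parts`).
#' @param library Library from [generate_category_library()].
#' @param signal Category signal in `[0, 1]`.
#' @param dim Embedding dimension (default `n_categories + 16`).
#' @param seed Integer seed for the noise stream.
#' @return Matrix with one row per drawing, rownames = drawing ids.
#' @export
toy_encode <- function(drawings, library, signal = 0.6, dim = NULL,
                       seed = 1) {
  stopifnot(signal >= 0, signal <= 1)
  if (inherits(drawings, "drawing")) drawings <- list(drawings)
  dim <- dim %||% (length(library) + 16L)
  if (dim < length(library)) stop("dim must be >= number of categories",
                                  call. = FALSE)
  es <- attr(library, "embedding_seed")
  proto_scale <- 3
  emb <- matrix(0, nrow = length(drawings), ncol = dim)
  rn <- character(length(drawings))
  for (i in seq_along(drawings)) {
    d <- drawings[[i]]
    proto <- proto_scale * key_vector(es, paste0("cat:", d$category), dim) /
      sqrt(dim)
    parts <- attr(d, "true_parts")
    pv <- rep(0, dim)
    if (length(parts)) {
      pm <- vapply(parts, function(p) key_vector(es, paste0("part:", p), dim),
                   numeric(dim))
      # scaled so the part contribution is commensurate with the prototype;
      # shared parts then pull confusions within the animacy class
      pv <- rowMeans(pm) * sqrt(length(parts)) * proto_scale / sqrt(dim)
    }
    set.seed(child_seed(seed, paste0("noise:", d$drawing_id)))
    noise <- stats::rnorm(dim) * proto_scale / sqrt(dim)
    emb[i, ] <- signal * (proto + pv) + (1 - signal) * noise
    rn[i] <- d$drawing_id
  }
  rownames(emb) <- rn
  emb
}

#' Zero-shot label embeddings for a library
#'
#' The toy analogue of text-label embeddings: each category label maps to
#' its prototype vector, so zero-shot cosine-similarity classification of
#' [toy_encode()] embeddings is well-posed.
#'
#' @inheritParams toy_encode
#' @return K x dim matrix with rownames = category labels.
#' @export
toy_label_embeddings <- function(library, dim = NULL) {
  dim <- dim %||% (length(library) + 16L)
  es <- attr(library, "embedding_seed")
  out <- t(vapply(names(library),
                  function(cat) key_vector(es, paste0("cat:", cat), dim),
                  numeric(dim)))
  out * 3 / sqrt(dim)
}

#' Generate multi-rater per-stroke part annotations
#'
#' Each rater reports a stroke's true label set with probability
#' `agreement_rate`, and otherwise a random other label from the vocabulary
#' or `"unintelligible"`.
#'
#' @param drawing A drawing with a `true_parts` attribute (or supply
#'   `true_parts` explicitly).
#' @param true_parts Character vector of per-stroke ground-truth labels.
#' @param agreement_rate Probability a rater reports the true label.
#' @param n_raters Number of raters (>= 1). Default 3.
#' @param seed Integer seed.
#' @param vocabulary Label vocabulary to draw errors from (default: the
#'   drawing's own labels plus generic alternatives).
#' @return Tibble (`drawing_id`, `stroke_index`, `rater_id`, `labels`), with
#'   `labels` a `;`-joined label set string.
#' @export
generate_annotations <- function(drawing, true_parts = attr(drawing, "true_parts"),
                                 agreement_rate = 0.7, n_raters = 3, seed = 1,
                                 vocabulary = NULL) {
  stopifnot(agreement_rate >= 0, agreement_rate <= 1, n_raters >= 1)
  set.seed(child_seed(seed, paste0("ann:", drawing$drawing_id)))
  vocabulary <- vocabulary %||% unique(c(true_parts,
                                         paste0("alt_", letters[1:6])))
  n_strokes <- length(drawing$strokes)
  stopifnot(length(true_parts) == n_strokes)
  out <- list()
  for (s in seq_len(n_strokes)) {
    for (r in seq_len(n_raters)) {
      if (stats::runif(1) < agreement_rate) {
        lab <- true_parts[s]
      } else {
        alt <- c(setdiff(vocabulary, true_parts[s]), "unintelligible")
        lab <- sample(alt, 1)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        drawing_id = drawing$drawing_id, stroke_index = s,
        rater_id = paste0("rater", r), labels = lab)
    }
  }
  dplyr::bind_rows(out)
}

#' Generate 4AFC recognition-game sessions with known choice model
#'
#' Simulates guessing-game sessions for one game (a fixed set of four
#' categories). Choice probabilities follow a softmax in which the utility
#' of the target is `sensitivity(age) * evidence` and the three foils have
#' utility 0, so accuracy is at chance (25%) when sensitivity is zero and
#' grows with both evidence and recognizer age. Sessions start with four
#' practice photograph trials, and a catch photograph trial recurs
#' periodically; reaction times are lognormal with a configurable fraction
#' of out-of-window outliers.
#'
#' @param drawing_evidence Tibble (`drawing_id`, `category`, `evidence`)
#'   over exactly 4 categories.
#' @param n_sessions Number of child sessions.
#' @param ages Optional vector of session ages (sampled 3-10 otherwise).
#' @param beta0 Evidence sensitivity at the youngest included age.
#' @param beta_age Increase in sensitivity per year of recognizer age.
#' @param min_age Youngest included recognizer age (3).
#' @param catch_error_rate Error probability on photograph trials.
#' @param dont_know_rate Probability of a "dont-know" response (incorrect).
#' @param rt_meanlog,rt_sdlog Lognormal RT parameters (ms scale).
#' @param rt_outlier_rate Fraction of trials with RTs outside `[100 ms, 10 s]`.
#' @param interference_rate Fraction of sessions with reported interference.
#' @param n_underage,n_adults Extra contaminant sessions (age 2 / adults).
#' @param trials_per_session Drawing trials per session.
#' @param catch_every Catch trial after this many drawing trials.
#' @param seed Integer seed.
#' @return Tibble of recognition trials; attribute `truth` stores the
#'   generator parameters.
#' @export
generate_recognition_sessions <- function(drawing_evidence, n_sessions = 100,
                                          ages = NULL, beta0 = 0.5,
                                          beta_age = 0.25, min_age = 3,
                                          catch_error_rate = 0.05,
                                          dont_know_rate = 0.02,
                                          rt_meanlog = log(1500),
                                          rt_sdlog = 0.5,
                                          rt_outlier_rate = 0,
                                          interference_rate = 0,
                                          n_underage = 0, n_adults = 0,
                                          trials_per_session = 24,
                                          catch_every = 10, seed = 1) {
  cats <- sort(unique(drawing_evidence$category))
  if (length(cats) != 4) {
    stop("a recognition game needs exactly 4 categories", call. = FALSE)
  }
  set.seed(child_seed(seed, "recog"))
  if (is.null(ages)) ages <- sample(min_age:10, n_sessions, replace = TRUE)
  ages <- c(ages, rep(2, n_underage), rep(25, n_adults))
  n_total <- length(ages)
  interfere <- stats::runif(n_total) < interference_rate
  rt_draw <- function(n) {
    rt <- stats::rlnorm(n, rt_meanlog, rt_sdlog)
    out <- stats::runif(n) < rt_outlier_rate
    n_out <- sum(out)
    if (n_out) {
      rt[out] <- ifelse(stats::runif(n_out) < 0.5,
                        stats::runif(n_out, 20, 99),
                        stats::runif(n_out, 10001, 14000))
    }
    pmin(rt, 25000)
  }
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    age <- ages[i]
    sens <- max(0, beta0 + beta_age * (age - min_age))
    if (age >= 18) sens <- beta0 + beta_age * 7   # adults at ceiling-ish
    sid <- sprintf("recog_s%04d", i)
    trials <- list()
    idx <- 0
    add_photo <- function(type) {
      idx <<- idx + 1
      cat <- sample(cats, 1)
      ok <- stats::runif(1) >= catch_error_rate
      resp <- if (ok) cat else sample(setdiff(cats, cat), 1)
      tibble::tibble(session_id = sid, recognizer_age_years = age,
                     interference = interfere[i], trial_index = idx,
                     trial_type = type, drawing_id = NA_character_,
                     category = cat,
                     choices = paste(cats, collapse = ";"),
                     response = resp, correct = ok, rt_ms = rt_draw(1))
    }
    for (k in 1:4) trials[[length(trials) + 1]] <- add_photo("practice")
    draws <- drawing_evidence[
      sample.int(nrow(drawing_evidence), trials_per_session,
                 replace = trials_per_session > nrow(drawing_evidence)), ]
    for (k in seq_len(nrow(draws))) {
      if (k > 1 && (k - 1) %% catch_every == 0) {
        trials[[length(trials) + 1]] <- add_photo("catch")
      }
      idx <- idx + 1
      u <- sens * draws$evidence[k]
      p_correct <- exp(u) / (exp(u) + 3)
      if (stats::runif(1) < dont_know_rate) {
        resp <- "dont-know"; ok <- FALSE
      } else if (stats::runif(1) < p_correct) {
        resp <- draws$category[k]; ok <- TRUE
      } else {
        resp <- sample(setdiff(cats, draws$category[k]), 1); ok <- FALSE
      }
      trials[[length(trials) + 1]] <- tibble::tibble(
        session_id = sid, recognizer_age_years = age,
        interference = interfere[i], trial_index = idx,
        trial_type = "drawing", drawing_id = draws$drawing_id[k],
        category = draws$category[k],
        choices = paste(cats, collapse = ";"),
        response = resp, correct = ok, rt_ms = rt_draw(1))
    }
    rows[[i]] <- dplyr::bind_rows(trials)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(beta0 = beta0, beta_age = beta_age,
                             min_age = min_age)
  out
}

#' Generate ordinal tracing-quality ratings from a known model
#'
#' Ratings are drawn from a proportional-odds model on the tracing error
#' components with rater random intercepts, providing ground truth for
#' calibration-recovery tests.
#'
#' @param errors Tibble with `tracing_id`, the four error components, and
#'   optionally `shape_id`.
#' @param true_coefficients Numeric vector: coefficients for (shape_error,
#'   translation_mag, rotation_mag, scaling_mag) and, if `shape_id` has two
#'   levels, a fifth shape-identity coefficient.
#' @param true_thresholds Strictly increasing thresholds (4 for 5 levels).
#' @param rater_sd SD of rater random intercepts.
#' @param n_raters Number of raters.
#' @param ratings_per_tracing Number of ratings per tracing (recycled).
#' @param seed Integer seed.
#' @return Tibble (`tracing_id`, `rater_id`, `rating`).
#' @export
generate_ratings <- function(errors, true_coefficients, true_thresholds,
                             rater_sd = 0.5, n_raters = 20,
                             ratings_per_tracing = 1, seed = 1) {
  if (is.unsorted(true_thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  set.seed(child_seed(seed, "ratings"))
  X <- cbind(errors$shape_error, errors$translation_mag,
             errors$rotation_mag, errors$scaling_mag)
  if (length(true_coefficients) == 5) {
    star <- as.numeric(errors$shape_id == sort(unique(errors$shape_id))[2])
    X <- cbind(X, star)
  }
  stopifnot(ncol(X) == length(true_coefficients))
  u <- stats::rnorm(n_raters, 0, rater_sd)
  eta0 <- as.vector(X %*% true_coefficients)
  n_lev <- length(true_thresholds) + 1
  reps <- rep_len(ratings_per_tracing, nrow(errors))
  out <- list()
  for (i in seq_len(nrow(errors))) {
    raters <- sample.int(n_raters, reps[i],
                         replace = reps[i] > n_raters)
    for (r in raters) {
      eta <- eta0[i] + u[r]
      pcum <- c(stats::plogis(true_thresholds - eta), 1)
      p <- diff(c(0, pcum))
      out[[length(out) + 1]] <- tibble::tibble(
        tracing_id = errors$tracing_id[i],
        rater_id = paste0("rater", r),
        rating = sample.int(n_lev, 1, prob = p))
    }
  }
  dplyr::bind_rows(out)
}
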