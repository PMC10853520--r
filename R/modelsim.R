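# Direct simulators for the mixed-model specifications: data generated on
# the models' own link scales with known coefficients, for parameter
# recovery and type-I calibration studies.

#' Simulate per-drawing production data from a known GLMM
#'
#' Generates the per-drawing table consumed by [fit_production_model()] /
#' [fit_conditional_evidence_model()] with effects planted on the
#' standardized (z-scored) predictor scale, so fitted standardized
#' coefficients are directly comparable to the truth.
#'
#' @param n_participants,n_categories,drawings_per_participant Design size.
#' @param beta Named coefficients on the z scale: `intercept`, `age`,
#'   `frequency`, `tracing`, `time`, `ink`, `strokes`, `age_frequency`.
#'   Missing names default to 0.
#' @param re_sd Random-intercept SDs, `c(participant = , category = )`.
#' @param response `"binary"` (logit link, for the production model) or
#'   `"evidence"` (identity link with residual SD `sigma`).
#' @param sigma Residual SD for the evidence response.
#' @param seed Integer seed.
#' @return Tibble with raw predictors, `correct` / `evidence`, ids, and the
#'   true linear predictor in attribute `truth`.
#' @export
simulate_production_data <- function(n_participants = 500,
                                     n_categories = 16,
                                     drawings_per_participant = 8,
                                     beta = c(intercept = -0.5, age = 0.25),
                                     re_sd = c(participant = 0.5,
                                               category = 0.5),
                                     response = c("binary", "evidence"),
                                     sigma = 1, seed = 1) {
  response <- match.arg(response)
  set.seed(child_seed(seed, "prodsim"))
  b <- c(intercept = 0, age = 0, frequency = 0, tracing = 0, time = 0,
         ink = 0, strokes = 0, age_frequency = 0)
  b[names(beta)] <- beta
  n <- n_participants * drawings_per_participant
  part <- rep(seq_len(n_participants), each = drawings_per_participant)
  cat_i <- sample.int(n_categories, n, replace = TRUE)
  age <- rep(sample(2:10, n_participants, replace = TRUE),
             each = drawings_per_participant)
  freq_cat <- stats::runif(n_categories, 0, 5)
  df <- tibble::tibble(
    session_id = sprintf("p%04d", part),
    category = sprintf("cat%02d", cat_i),
    age = age,
    draw_frequency = freq_cat[cat_i],
    tracing_score = stats::rnorm(n),
    draw_time_s = stats::runif(n, 2, 30),
    ink_proportion = stats::runif(n, 0.01, 0.3),
    n_strokes = stats::rpois(n, 5) + 1)
  u_p <- stats::rnorm(n_participants, 0, re_sd[["participant"]])
  u_c <- stats::rnorm(n_categories, 0, re_sd[["category"]])
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  eta <- b[["intercept"]] + b[["age"]] * zs(df$age) +
    b[["frequency"]] * zs(df$draw_frequency) +
    b[["tracing"]] * zs(df$tracing_score) +
    b[["time"]] * zs(df$draw_time_s) +
    b[["ink"]] * zs(df$ink_proportion) +
    b[["strokes"]] * zs(df$n_strokes) +
    b[["age_frequency"]] * zs(df$age) * zs(df$draw_frequency) +
    u_p[part] + u_c[cat_i]
  if (response == "binary") {
    df$correct <- stats::runif(n) < stats::plogis(eta)
  } else {
    df$correct <- TRUE
    df$evidence <- eta + stats::rnorm(n, 0, sigma)
  }
  attr(df, "truth") <- list(beta = b, eta = eta)
  df
}

#' Constructed recognition log with planted exclusion counts
#'
#' Builds a deterministic 4AFC guessing-game log engineered to lose an
#' exact, known number of sessions or trials at every stage of
#' [apply_exclusions()]: 2 interference sessions, 3 age-out sessions (two
#' 2-year-olds and one adult), 1 participant with a single post-practice
#' trial, 5 out-of-window reaction-time trials, and 2 participants below
#' the 75% photograph-accuracy gate, plus one boundary participant at
#' exactly 75% who must be retained. Used to verify that the staged
#' exclusion report reconciles exactly.
#'
#' @return List with `trials` (the log) and `truth` (the planted counts
#'   and the number of surviving participants).
#' @export
demo_exclusion_log <- function() {
  cats <- c("dog", "fish", "rabbit", "bird")
  mk_session <- function(sid, age, interference = FALSE, n_drawing = 10,
                         photo_correct = c(TRUE, TRUE, TRUE, TRUE),
                         rt_out_idx = integer(0), rt = 1500) {
    n_photo <- length(photo_correct)
    rows <- list()
    for (i in seq_len(n_photo)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        session_id = sid, recognizer_age_years = age,
        interference = interference, trial_index = i,
        trial_type = if (i <= 4) "practice" else "catch",
        drawing_id = NA_character_, category = cats[1 + (i - 1) %% 4],
        choices = paste(cats, collapse = ";"),
        response = if (photo_correct[i]) cats[1 + (i - 1) %% 4] else
          cats[1 + i %% 4],
        correct = photo_correct[i], rt_ms = rt)
    }
    for (j in seq_len(n_drawing)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        session_id = sid, recognizer_age_years = age,
        interference = interference, trial_index = n_photo + j,
        trial_type = "drawing", drawing_id = sprintf("%s_d%02d", sid, j),
        category = cats[1 + (j - 1) %% 4],
        choices = paste(cats, collapse = ";"),
        response = cats[1 + (j - 1) %% 4], correct = TRUE,
        rt_ms = if (j %in% rt_out_idx) 50 else rt)
    }
    dplyr::bind_rows(rows)
  }
  trials <- dplyr::bind_rows(
    mk_session("clean1", 5), mk_session("clean2", 6),
    mk_session("clean3", 7), mk_session("clean4", 8),
    mk_session("clean5", 4), mk_session("clean6", 9),
    mk_session("intf1", 5, interference = TRUE),
    mk_session("intf2", 6, interference = TRUE),
    mk_session("young1", 2), mk_session("young2", 2),
    mk_session("adult1", 30),
    mk_session("oneshot", 6, n_drawing = 1),
    mk_session("rtout", 7, rt_out_idx = 1:5),
    mk_session("fail1", 6, photo_correct = c(TRUE, TRUE, FALSE, FALSE)),
    mk_session("fail2", 7, photo_correct = c(TRUE, FALSE, TRUE, FALSE)),
    mk_session("edge75", 8, photo_correct = c(TRUE, TRUE, TRUE, FALSE)))
  # survivors: clean1-6, rtout, edge75
  truth <- list(interference = 2, age_out = 3, low_trial = 1,
                rt_out_trials = 5, catch_fail = 2, remaining = 8)
  list(trials = trials, truth = truth)
}

#' Simulate recognition-trial data from a known GLMM
#'
#' Generates 4AFC drawing-trial outcomes directly from the recognition
#' model's logit specification: planted fixed effects (on the z scale) for
#' classifier evidence, recognizer age and their interaction, random
#' intercepts for subject and category, and a random evidence slope by
#' category.
#'
#' @param n_subjects Number of recognizers.
#' @param trials_per_subject Drawing trials per recognizer.
#' @param n_categories Categories (default 4, one game).
#' @param drawings_per_category Distinct drawings per category.
#' @param beta Named coefficients on the z scale: `intercept`, `evidence`,
#'   `age`, `interaction`.
#' @param re_sd SDs `c(subject = , category = , slope = )`.
#' @param seed Integer seed.
#' @return Trial tibble for [fit_recognition_model()] with attribute
#'   `truth`.
#' @export
simulate_recognition_data <- function(n_subjects = 200,
                                      trials_per_subject = 10,
                                      n_categories = 4,
                                      drawings_per_category = 20,
                                      beta = c(intercept = 0,
                                               evidence = 0.5,
                                               age = 0.3,
                                               interaction = 0.1),
                                      re_sd = c(subject = 0.4,
                                                category = 0.3,
                                                slope = 0.1),
                                      seed = 1) {
  set.seed(child_seed(seed, "recsim"))
  b <- c(intercept = 0, evidence = 0, age = 0, interaction = 0)
  b[names(beta)] <- beta
  n_draw <- n_categories * drawings_per_category
  drawings <- tibble::tibble(
    drawing_id = sprintf("d%04d", seq_len(n_draw)),
    category = sprintf("cat%02d", rep(seq_len(n_categories),
                                      each = drawings_per_category)),
    evidence = stats::rnorm(n_draw, 0, 1.2))
  ages <- sample(3:10, n_subjects, replace = TRUE)
  u_s <- stats::rnorm(n_subjects, 0, re_sd[["subject"]])
  u_c <- stats::rnorm(n_categories, 0, re_sd[["category"]])
  u_b <- stats::rnorm(n_categories, 0, re_sd[["slope"]])
  n <- n_subjects * trials_per_subject
  subj <- rep(seq_len(n_subjects), each = trials_per_subject)
  dr <- sample.int(n_draw, n, replace = TRUE)
  ze <- (drawings$evidence[dr] - mean(drawings$evidence[dr])) /
    stats::sd(drawings$evidence[dr])
  za <- (ages[subj] - mean(ages[subj])) / stats::sd(ages[subj])
  cat_i <- as.integer(factor(drawings$category[dr]))
  eta <- b[["intercept"]] + (b[["evidence"]] + u_b[cat_i]) * ze +
    b[["age"]] * za + b[["interaction"]] * ze * za +
    u_s[subj] + u_c[cat_i]
  out <- tibble::tibble(
    session_id = sprintf("s%04d", subj),
    recognizer_age_years = ages[subj],
    trial_type = "drawing",
    drawing_id = drawings$drawing_id[dr],
    category = drawings$category[dr],
    evidence = drawings$evidence[dr],
    correct = stats::runif(n) < stats::plogis(eta))
  attr(out, "truth") <- list(beta = b, re_sd = re_sd)
  out
}
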