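# Recognition-game pipeline: staged exclusion rules for 4AFC guessing-game
# logs, per-game leave-one-out classifier evidence, and accuracy summaries.

#' Apply the staged exclusion rules to recognition-game logs
#'
#' Filters are applied in a fixed order, mirroring the study's inclusion
#' pipeline: (1) drop sessions with reported interference; (2) drop
#' recognizers younger than `min_age` and adult sessions; (3) drop
#' participants who completed at most one trial after the practice trials;
#' (4) drop trials with reaction times faster than 100 ms or slower than
#' 10 s; (5) drop participants with photograph-trial (practice + catch,
#' pooled) accuracy below 75% — exactly 75% is retained. "dont-know"
#' responses are retained as incorrect drawing responses.
#'
#' @param trials Trial tibble as produced by
#'   [generate_recognition_sessions()] (columns `session_id`,
#'   `recognizer_age_years`, `interference`, `trial_type`, `rt_ms`,
#'   `correct`, ...).
#' @param min_age Youngest included recognizer age (default 3).
#' @param adult_age Age at or above which a session counts as adult (18).
#' @param rt_min_ms,rt_max_ms Reaction-time window (100 ms, 10 s).
#' @param min_photo_acc Minimum photograph-trial accuracy (0.75).
#' @return List with `trials` (retained) and `report` (an
#'   `exclusion_report`: per-stage removal counts that reconcile exactly
#'   with the input totals, plus survivor summaries).
#' @export
apply_exclusions <- function(trials, min_age = 3, adult_age = 18,
                             rt_min_ms = 100, rt_max_ms = 10000,
                             min_photo_acc = 0.75) {
  n_sessions_in <- length(unique(trials$session_id))
  n_trials_in <- nrow(trials)

  sess_of <- function(tr) unique(tr$session_id)

  # stage 1: reported interference
  bad1 <- sess_of(trials[trials$interference, ])
  t1 <- trials[!trials$session_id %in% bad1, , drop = FALSE]

  # stage 2: underage and adult sessions
  bad2 <- sess_of(t1[t1$recognizer_age_years < min_age |
                       t1$recognizer_age_years >= adult_age, ])
  t2 <- t1[!t1$session_id %in% bad2, , drop = FALSE]

  # stage 3: participants with <= 1 post-practice trial
  post <- t2[t2$trial_type != "practice", , drop = FALSE]
  cnt <- table(factor(post$session_id, levels = sess_of(t2)))
  bad3 <- names(cnt)[cnt <= 1]
  t3 <- t2[!t2$session_id %in% bad3, , drop = FALSE]

  # stage 4: out-of-window reaction times (trial-level)
  if (anyNA(t3$rt_ms)) {
    bad_ids <- t3$session_id[is.na(t3$rt_ms)]
    stop("trials missing reaction times in sessions: ",
         paste(unique(bad_ids), collapse = ", "), call. = FALSE)
  }
  rt_out <- t3$rt_ms < rt_min_ms | t3$rt_ms > rt_max_ms
  n_rt_removed <- sum(rt_out)
  t4 <- t3[!rt_out, , drop = FALSE]

  # stage 5: photograph-trial accuracy (practice + catch pooled)
  photo <- t4[t4$trial_type %in% c("practice", "catch"), , drop = FALSE]
  acc <- tapply(photo$correct, photo$session_id, mean)
  bad5 <- names(acc)[acc < min_photo_acc]
  t5 <- t4[!t4$session_id %in% bad5, , drop = FALSE]

  drawing_trials <- t5[t5$trial_type == "drawing", , drop = FALSE]
  n_per <- table(drawing_trials$session_id)
  report <- structure(list(
    input = list(sessions = n_sessions_in, trials = n_trials_in),
    removed = list(
      interference_sessions = length(bad1),
      age_out_sessions = length(bad2),
      low_trial_participants = length(bad3),
      rt_out_trials = n_rt_removed,
      catch_fail_participants = length(bad5)),
    remaining_participants = length(unique(t5$session_id)),
    remaining_drawing_trials = nrow(drawing_trials),
    mean_trials_per_participant =
      if (length(n_per)) mean(n_per) else NA_real_),
    class = "exclusion_report")
  list(trials = t5, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat(sprintf("  input: %d sessions, %d trials\n",
              x$input$sessions, x$input$trials))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed %-26s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  cat(sprintf("  remaining participants: %d, drawing trials: %d (%.1f / participant)\n",
              x$remaining_participants, x$remaining_drawing_trials,
              x$mean_trials_per_participant))
  invisible(x)
}

#' Leave-one-out classifier evidence within a recognition game
#'
#' For each drawing presented in a game, trains a 4-way L2 logistic model
#' on all the game's other drawings and computes the held-out probability
#' vector over the game's four categories; evidence is the log-odds of the
#' drawing's target among the four. Categories with a single drawing are
#' skipped with a warning (their drawing cannot be held out and decoded).
#'
#' @param embeddings Matrix of the game's drawing embeddings (rownames =
#'   drawing ids).
#' @param targets Character vector of intended categories (4 unique).
#' @param hyper Classifier hyperparameters as in
#'   [balanced_crossval_classify()].
#' @return Tibble (`drawing_id`, `target`, `predicted`, `correct`,
#'   `p_target`, `evidence`, `prob` list-column) for the non-skipped
#'   drawings.
#' @export
loo_game_evidence <- function(embeddings, targets,
                              hyper = list(l2_strength = 0.1,
                                           tolerance = 0.1)) {
  targets <- as.character(targets)
  stopifnot(nrow(embeddings) == length(targets))
  counts <- table(targets)
  singles <- names(counts)[counts < 2]
  keep <- !(targets %in% singles)
  if (length(singles)) {
    warning("categories with a single drawing skipped: ",
            paste(singles, collapse = ", "))
  }
  x <- embeddings[keep, , drop = FALSE]
  y <- targets[keep]
  ids <- rownames(x) %||% as.character(which(keep))
  classes <- sort(unique(y))
  n <- nrow(x)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    prob[i, ] <- fit_l2_multinomial(
      x[-i, , drop = FALSE], y[-i], x[i, , drop = FALSE],
      l2_strength = hyper$l2_strength %||% 0.1,
      tolerance = hyper$tolerance %||% 0.1)[, classes]
  }
  predicted <- classes[max.col(prob, ties.method = "first")]
  p_target <- prob[cbind(seq_len(n), match(y, classes))]
  tibble::tibble(drawing_id = ids, target = y, predicted = predicted,
                 correct = predicted == y, p_target = p_target,
                 evidence = log_odds(p_target),
                 prob = lapply(seq_len(n), function(i) prob[i, ]))
}

#' Grouped recognition accuracy with bootstrap CIs
#'
#' Summarizes drawing-trial accuracy by recognizer age, optionally crossed
#' with deciles of per-drawing classifier evidence or with unique-part
#' counts. Decile bins are computed over the evidence distribution of the
#' distinct presented drawings, then mapped onto trials. CIs are percentile
#' bootstrap over trials within each group; empty groups yield no row.
#'
#' @param trials Retained drawing trials (must contain `recognizer_age_years`
#'   and `correct`; `evidence` / `n_unique_parts` joined on where needed).
#' @param grouping `"age"`, `"age_evidence"` or `"age_parts"`.
#' @param n_boot Bootstrap resamples per group.
#' @param seed Integer seed.
#' @return Tibble with group columns, `accuracy`, `ci_low`, `ci_high`, `n`.
#' @export
accuracy_summary <- function(trials,
                             grouping = c("age", "age_evidence", "age_parts"),
                             n_boot = 1000, seed = 1) {
  grouping <- match.arg(grouping)
  trials <- trials[trials$trial_type == "drawing", , drop = FALSE]
  trials$age_group <- trials$recognizer_age_years
  if (grouping == "age_evidence") {
    dr <- unique(trials[, c("drawing_id", "evidence")])
    breaks <- stats::quantile(dr$evidence, probs = seq(0, 1, 0.1), type = 7)
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
    dr$evidence_decile <- cut(dr$evidence, breaks = unique(breaks),
                              labels = FALSE, include.lowest = TRUE)
    trials <- dplyr::left_join(
      trials, dr[, c("drawing_id", "evidence_decile")], by = "drawing_id")
    grp <- c("age_group", "evidence_decile")
  } else if (grouping == "age_parts") {
    grp <- c("age_group", "n_unique_parts")
  } else {
    grp <- "age_group"
  }
  set.seed(child_seed(seed, "accsum"))
  boot_ci <- function(x) {
    if (length(x) == 1) return(c(mean(x), mean(x)))
    means <- vapply(seq_len(n_boot), function(b) {
      mean(sample(x, length(x), replace = TRUE))
    }, numeric(1))
    stats::quantile(means, c(0.025, 0.975), names = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(trials, dplyr::across(dplyr::all_of(grp))),
    accuracy = mean(correct),
    ci = list(boot_ci(correct)),
    n = dplyr::n(), .groups = "drop")
  out$ci_low <- vapply(out$ci, `[`, numeric(1), 1)
  out$ci_high <- vapply(out$ci, `[`, numeric(1), 2)
  out$ci <- NULL
  out[, c(grp, "accuracy", "ci_low", "ci_high", "n")]
}

#' Assign evidence deciles to drawings
#'
#' Helper exposing the decile rule used by [accuracy_summary()]: bins are
#' computed over the distinct drawings' evidence values.
#'
#' @param evidence Numeric vector of per-drawing evidence.
#' @return Integer decile (1-10) per value.
#' @export
evidence_deciles <- function(evidence) {
  breaks <- stats::quantile(evidence, probs = seq(0, 1, 0.1), type = 7)
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  cut(evidence, breaks = unique(breaks), labels = FALSE,
      include.lowest = TRUE)
}
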