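# Semantic structure in misclassified drawings: mean confusion-probability
# matrix, baseline-corrected animacy / real-world size decoding, and
# category-level bootstrap confidence intervals.

#' Mean confusion-probability matrix
#'
#' Row = intended category, column = category assigned probability; each row
#' is the mean probability vector over that target's drawings (optionally
#' restricted to misclassified drawings), so rows sum to 1.
#'
#' @param outputs Classifier output tibble with `target`, `correct` and the
#'   `prob` list-column (from [balanced_crossval_classify()] or
#'   [zero_shot_classify()]).
#' @param restrict If `TRUE` (default), use only misclassified drawings.
#' @return K x K matrix; targets with no drawings after restriction get a
#'   row of `NA` with a warning.
#' @export
confusion_matrix <- function(outputs, restrict = TRUE) {
  all_targets <- sort(unique(outputs$target))
  if (restrict) outputs <- outputs[!outputs$correct, , drop = FALSE]
  classes <- names(outputs$prob[[1]])
  m <- matrix(NA_real_, nrow = length(all_targets), ncol = length(classes),
              dimnames = list(all_targets, classes))
  for (tg in all_targets) {
    rows <- which(outputs$target == tg)
    if (!length(rows)) next
    m[tg, ] <- colMeans(do.call(rbind, outputs$prob[rows]))
  }
  if (anyNA(m)) warning("targets with no (misclassified) drawings: ",
                        paste(all_targets[is.na(m[, 1])], collapse = ", "))
  m
}

attr_value <- function(meta, cats, attribute) {
  i <- match(cats, meta$category)
  if (attribute == "animacy") meta$animate[i] else meta$big[i]
}

#' Baseline-corrected semantic attribute decoding from misclassifications
#'
#' For every misclassified drawing, checks whether the top (non-target)
#' predicted category shares the target's broad attribute — animacy, or
#' real-world size for inanimate targets — and averages these binary
#' matches per (age, category). The baseline is the prevalence of the
#' target's attribute class among the other K-1 candidate categories
#' (category-level, the default) or among the other drawings' categories
#' weighted by drawing counts (`baseline = "drawing"`); corrected scores
#' are match proportion minus baseline, so 0 means no attribute information.
#'
#' @param outputs Misclassification-capable classifier output tibble;
#'   must contain `target`, `predicted`, `correct`, and `age_years` if
#'   per-age scores are wanted.
#' @param meta [category_meta()] tibble for all candidate categories.
#' @param attribute `"animacy"` or `"size"`.
#' @param baseline `"category"` (default) or `"drawing"`.
#' @return Tibble of `AttributeScore` rows (`age_years` if present,
#'   `category`, `attribute`, `raw_match`, `baseline`, `corrected`,
#'   `n_drawings`); attribute `n_skipped` counts drawings skipped because
#'   the attribute is undefined for their target.
#' @export
attribute_match <- function(outputs, meta,
                            attribute = c("animacy", "size"),
                            baseline = c("category", "drawing")) {
  attribute <- match.arg(attribute)
  baseline <- match.arg(baseline)
  mis <- outputs[!outputs$correct, , drop = FALSE]
  tv <- attr_value(meta, mis$target, attribute)
  skipped <- is.na(tv)
  n_skipped <- sum(skipped)
  mis <- mis[!skipped, , drop = FALSE]
  tv <- tv[!skipped]
  pv <- attr_value(meta, mis$predicted, attribute)
  match_flag <- !is.na(pv) & pv == tv

  cat_attr <- attr_value(meta, meta$category, attribute)
  base_for <- function(target_cats) {
    vapply(target_cats, function(tg) {
      a <- cat_attr[match(tg, meta$category)]
      if (baseline == "category") {
        others <- meta$category != tg
        mean(!is.na(cat_attr[others]) & cat_attr[others] == a)
      } else {
        others <- outputs$target != tg
        oa <- attr_value(meta, outputs$target[others], attribute)
        mean(!is.na(oa) & oa == a)
      }
    }, numeric(1))
  }

  df <- tibble::tibble(category = mis$target, match = match_flag)
  if ("age_years" %in% names(mis)) df$age_years <- mis$age_years
  grp <- intersect(c("age_years", "category"), names(df))
  out <- dplyr::summarise(dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
                          raw_match = mean(match), n_drawings = dplyr::n(),
                          .groups = "drop")
  out$baseline <- unname(base_for(out$category))
  out$corrected <- out$raw_match - out$baseline
  out$attribute <- attribute
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Percentile bootstrap CI across categories
#'
#' Resamples category-level values with replacement and returns the
#' percentile interval of the mean; this is the interval drawn around the
#' corrected attribute scores and other category-level summaries.
#'
#' @param values Numeric vector of per-category values (>= 2).
#' @param B Number of resamples (>= 100).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(low, high)` with attribute `"mean"`.
#' @export
bootstrap_category_ci <- function(values, B = 1000, level = 0.95, seed = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 categories", call. = FALSE)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  set.seed(child_seed(seed, "boot"))
  means <- vapply(seq_len(B), function(b) {
    mean(sample(values, length(values), replace = TRUE))
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  structure(c(low = ci[1], high = ci[2]), mean = mean(values))
}
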