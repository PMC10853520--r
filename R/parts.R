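# Part annotations: multi-rater consensus, inter-rater agreement,
# unique-part counts, and per-part emphasis (arc-length proportions).

# Normalize a label field (";"-joined string or character vector) to a
# canonical sorted label-set string.
label_set <- function(labels) {
  if (length(labels) == 1 && grepl(";", labels)) {
    labels <- strsplit(labels, ";", fixed = TRUE)[[1]]
  }
  paste(sort(unique(trimws(labels))), collapse = ";")
}

#' Per-stroke consensus labels and agreement rate
#'
#' A stroke's consensus is the label set endorsed identically by at least
#' two raters (exact set match, the default) or, with `mode = "per-label"`,
#' the set of individual labels each endorsed by at least two raters.
#' Strokes with fewer than two raters are excluded from the agreement
#' denominator with a warning.
#'
#' @param annotations Tibble (`drawing_id`, `stroke_index`, `rater_id`,
#'   `labels`) with `labels` a `;`-joined label-set string.
#' @param mode `"set"` (default) or `"per-label"`.
#' @return List with `strokes` (tibble: `drawing_id`, `stroke_index`,
#'   `consensus` — label-set string or `"no-consensus"` — and `n_raters`)
#'   and `agreement` (tibble of per-drawing consensus rates).
#' @export
consensus_labels <- function(annotations, mode = c("set", "per-label")) {
  mode <- match.arg(mode)
  ann <- annotations
  ann$set <- vapply(ann$labels, label_set, character(1))
  per_stroke <- dplyr::group_by(ann, drawing_id, stroke_index)
  res <- dplyr::summarise(per_stroke, n_raters = dplyr::n(), consensus = {
    if (dplyr::n() < 2) {
      NA_character_
    } else if (mode == "set") {
      tab <- table(set)
      hit <- names(tab)[tab >= 2]
      if (length(hit)) hit[1] else "no-consensus"
    } else {
      labs <- unlist(strsplit(set, ";", fixed = TRUE))
      tab <- table(labs)
      hit <- sort(names(tab)[tab >= 2])
      if (length(hit)) paste(hit, collapse = ";") else "no-consensus"
    }
  }, .groups = "drop")
  if (anyNA(res$consensus)) {
    warning(sum(is.na(res$consensus)),
            " stroke(s) with a single rater excluded from agreement")
  }
  rated <- res[!is.na(res$consensus), , drop = FALSE]
  agreement <- dplyr::summarise(
    dplyr::group_by(rated, drawing_id),
    n_strokes = dplyr::n(),
    agreement = mean(consensus != "no-consensus"), .groups = "drop")
  list(strokes = res, agreement = agreement)
}

#' Unique-part count of a drawing
#'
#' Number of distinct consensus part labels across a drawing's strokes,
#' excluding `"unintelligible"`, no-consensus strokes, and (when a
#' vocabulary is supplied) custom labels outside it.
#'
#' @param consensus Per-stroke consensus tibble for one drawing (the
#'   `strokes` element of [consensus_labels()], already filtered).
#' @param vocabulary Optional character vector of valid part labels.
#' @return Integer count.
#' @export
unique_parts <- function(consensus, vocabulary = NULL) {
  lab <- consensus$consensus
  lab <- lab[!is.na(lab) & lab != "no-consensus"]
  parts <- unique(unlist(strsplit(lab, ";", fixed = TRUE)))
  parts <- setdiff(parts, "unintelligible")
  if (!is.null(vocabulary)) parts <- intersect(parts, vocabulary)
  length(parts)
}

#' Per-part emphasis: arc-length proportions
#'
#' Emphasis of a part is the fraction of the drawing's total stroke length
#' attributed to it: each consensus stroke contributes its Euclidean arc
#' length divided by the number of parts on that stroke, and the
#' denominator is the total length of all strokes (including no-consensus
#' and unintelligible strokes), so emphasis values plus the unattributed
#' fraction sum to exactly 1.
#'
#' @param drawing A [drawing()] (strokes in canvas units).
#' @param consensus Per-stroke consensus tibble for this drawing.
#' @param vocabulary Optional vocabulary; labels outside it (custom labels)
#'   are not credited.
#' @return Named numeric vector of per-part emphasis with attribute
#'   `"unattributed"` (fraction of length not credited to any part);
#'   all-`NA` when the drawing has zero total length.
#' @export
part_emphasis <- function(drawing, consensus, vocabulary = NULL) {
  lens <- vapply(drawing$strokes, polyline_length, numeric(1))
  total <- sum(lens)
  if (total == 0) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     unattributed = NA_real_))
  }
  emph <- list()
  credited <- 0
  for (i in seq_len(nrow(consensus))) {
    s <- consensus$stroke_index[i]
    lab <- consensus$consensus[i]
    if (is.na(lab) || lab == "no-consensus") next
    parts <- strsplit(lab, ";", fixed = TRUE)[[1]]
    share <- lens[s] / length(parts)
    for (p in parts) {
      if (p == "unintelligible") next
      if (!is.null(vocabulary) && !(p %in% vocabulary)) next
      emph[[p]] <- (emph[[p]] %||% 0) + share
      credited <- credited + share
    }
  }
  out <- unlist(emph) / total
  if (is.null(out)) out <- stats::setNames(numeric(0), character(0))
  structure(out, unattributed = 1 - credited / total)
}

#' Summarize part annotations for one drawing
#'
#' Convenience wrapper combining consensus, agreement, unique-part count and
#' emphasis into one `PartSummary` row.
#'
#' @inheritParams part_emphasis
#' @param annotations Annotation tibble for this drawing.
#' @param mode Consensus mode, see [consensus_labels()].
#' @return List with `drawing_id`, `consensus`, `agreement`,
#'   `n_unique_parts`, `emphasis`.
#' @export
part_summary <- function(drawing, annotations, vocabulary = NULL,
                         mode = "set") {
  cons <- consensus_labels(annotations, mode = mode)
  strokes <- cons$strokes[cons$strokes$drawing_id == drawing$drawing_id, ]
  list(drawing_id = drawing$drawing_id,
       consensus = strokes,
       agreement = cons$agreement$agreement[
         cons$agreement$drawing_id == drawing$drawing_id],
       n_unique_parts = unique_parts(strokes, vocabulary),
       emphasis = part_emphasis(drawing, strokes, vocabulary))
}
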