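# Part-annotation consensus, unique-part counts, and emphasis.

ann_row <- function(stroke, rater, labels, id = "d1") {
  tibble::tibble(drawing_id = id, stroke_index = stroke,
                 rater_id = rater, labels = labels)
}

test_that("consensus requires an exact label-set match by two raters", {
  ann <- dplyr::bind_rows(
    ann_row(1, "r1", "ear"), ann_row(1, "r2", "ear"), ann_row(1, "r3", "tail"),
    ann_row(2, "r1", "ear"), ann_row(2, "r2", "tail"), ann_row(2, "r3", "leg"),
    ann_row(3, "r1", "ear;head"), ann_row(3, "r2", "head;ear"),
    ann_row(3, "r3", "ear"))
  cons <- consensus_labels(ann)
  s <- cons$strokes
  expect_equal(s$consensus[s$stroke_index == 1], "ear")
  expect_equal(s$consensus[s$stroke_index == 2], "no-consensus")
  # order inside the set must not matter
  expect_equal(s$consensus[s$stroke_index == 3], "ear;head")
  expect_equal(cons$agreement$agreement, 2 / 3)

  # per-label mode: individually endorsed labels survive
  ann2 <- dplyr::bind_rows(
    ann_row(1, "r1", "ear;head"), ann_row(1, "r2", "ear"),
    ann_row(1, "r3", "head;tail"))
  c2 <- consensus_labels(ann2, mode = "per-label")
  expect_equal(c2$strokes$consensus, "ear;head")

  # single-rater strokes warn and leave the denominator
  ann3 <- dplyr::bind_rows(ann_row(1, "r1", "ear"),
                           ann_row(2, "r1", "ear"), ann_row(2, "r2", "ear"))
  expect_warning(c3 <- consensus_labels(ann3), "single rater")
  expect_equal(c3$agreement$agreement, 1)
})

test_that("agreement rate counts consensus strokes over all rated strokes", {
  ann <- dplyr::bind_rows(lapply(1:10, function(s) {
    if (s <= 7) {
      dplyr::bind_rows(ann_row(s, "r1", "a"), ann_row(s, "r2", "a"),
                       ann_row(s, "r3", "b"))
    } else {
      dplyr::bind_rows(ann_row(s, "r1", "a"), ann_row(s, "r2", "b"),
                       ann_row(s, "r3", "c"))
    }
  }))
  expect_equal(consensus_labels(ann)$agreement$agreement, 0.7)
})

test_that("unique parts exclude unintelligible, no-consensus, custom labels", {
  cons <- tibble::tibble(
    drawing_id = "d1", stroke_index = 1:4,
    consensus = c("ear", "ear", "unintelligible", "no-consensus"))
  expect_equal(unique_parts(cons), 1)
  cons2 <- tibble::tibble(drawing_id = "d1", stroke_index = 1:2,
                          consensus = c("ear", "ear;head"))
  expect_equal(unique_parts(cons2), 2)
  cons3 <- tibble::tibble(drawing_id = "d1", stroke_index = 1:2,
                          consensus = c("no-consensus", "no-consensus"))
  expect_equal(unique_parts(cons3), 0)
  # custom labels outside the vocabulary are not parts
  cons4 <- tibble::tibble(drawing_id = "d1", stroke_index = 1:2,
                          consensus = c("ear", "my-custom-thing"))
  expect_equal(unique_parts(cons4, vocabulary = c("ear", "head")), 1)
})

test_that("part emphasis splits multi-part strokes and conserves length", {
  # strokes of length 3 {ear} and length 1 {ear, head}
  d <- drawing("wk", list(cbind(c(0, 3), c(0, 0), c(0, 1)),
                          cbind(c(0, 1), c(5, 5), c(2, 3))),
               "cat", 5, canvas_size = c(32, 32))
  cons <- tibble::tibble(drawing_id = "wk", stroke_index = 1:2,
                         consensus = c("ear", "ear;head"))
  em <- part_emphasis(d, cons)
  expect_equal(em[["ear"]], 0.875)
  expect_equal(em[["head"]], 0.125)
  expect_equal(attr(em, "unattributed"), 0)

  # one stroke, single label -> emphasis 1
  d1 <- drawing("w1", list(cbind(c(0, 4), c(0, 0), c(0, 1))), "cat", 5)
  e1 <- part_emphasis(d1, tibble::tibble(drawing_id = "w1",
                                         stroke_index = 1,
                                         consensus = "ear"))
  expect_equal(unname(e1), 1, ignore_attr = TRUE)

  # half the length without consensus -> emphasis sums to 0.5
  d2 <- drawing("w2", list(cbind(c(0, 4), c(0, 0), c(0, 1)),
                           cbind(c(0, 4), c(5, 5), c(2, 3))),
                "cat", 5, canvas_size = c(32, 32))
  e2 <- part_emphasis(d2, tibble::tibble(drawing_id = "w2",
                                         stroke_index = 1:2,
                                         consensus = c("ear", "no-consensus")))
  expect_equal(sum(e2), 0.5)
  expect_equal(sum(e2) + attr(e2, "unattributed"), 1)

  # zero-length drawing -> undefined emphasis, not zero
  dz <- drawing("wz", list(cbind(c(2, 2), c(3, 3), c(0, 1))), "cat", 5)
  ez <- part_emphasis(dz, tibble::tibble(drawing_id = "wz",
                                         stroke_index = 1,
                                         consensus = "ear"))
  expect_true(is.na(attr(ez, "unattributed")))
})

test_that("metrics are invariant to stroke reordering", {
  d <- drawing("ro", list(cbind(c(0, 3), c(0, 0), c(0, 1)),
                          cbind(c(0, 1), c(5, 5), c(0, 1)),
                          cbind(c(0, 2), c(9, 9), c(0, 1))),
               "cat", 5, canvas_size = c(32, 32))
  cons <- tibble::tibble(drawing_id = "ro", stroke_index = 1:3,
                         consensus = c("ear", "head;ear", "tail"))
  perm <- c(3, 1, 2)
  d2 <- d; d2$strokes <- d$strokes[perm]
  cons2 <- cons; cons2$stroke_index <- match(1:3, perm)
  e1 <- part_emphasis(d, cons); e2 <- part_emphasis(d2, cons2)
  expect_equal(e1[sort(names(e1))], e2[sort(names(e2))])
  expect_equal(unique_parts(cons), unique_parts(cons2))
})

test_that("full-agreement generator annotations recover emphasis exactly", {
  lib <- tiny_library(2, 1)
  d <- generate_drawing(lib[[1]], 8, seed = 13, inclusion_prob = 1)
  ann <- generate_annotations(d, agreement_rate = 1, seed = 14)
  cons <- consensus_labels(ann)$strokes
  em <- part_emphasis(d, cons)
  lens <- vapply(d$strokes, sketchdev:::polyline_length, numeric(1))
  truth <- tapply(lens, attr(d, "true_parts"), sum) / sum(lens)
  expect_equal(em[names(truth)], as.numeric(truth), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unique_parts(cons), length(unique(attr(d, "true_parts"))))
})
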