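# Core data model: strokes, drawings, tracing trials, category metadata,
# corpus I/O, rasterization and effort covariates.
#
# Coordinate convention (used everywhere): origin at the top-left of the
# canvas, x rightward, y downward, 0-based pixel indices. Stroke coordinates
# are stored in source canvas units and scaled to the raster size at render
# time. Raster images are H x W numeric matrices in [0, 1] with 1 = white
# background and 0 = ink; `raster[y + 1, x + 1]` addresses pixel (x, y).

#' Construct a stroke
#'
#' A stroke is an ordered sequence of touch points `(x, y, t)` with `x`, `y`
#' in canvas pixel units and `t` in milliseconds since stroke onset.
#'
#' @param points Numeric matrix with >= 1 row and columns x, y, t.
#' @return A numeric matrix with columns `x`, `y`, `t` and class `"stroke"`.
#' @export
stroke <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) < 3) {
    stop("a stroke needs >= 1 point with columns x, y, t", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "t")
  if (any(diff(points[, "t"]) < 0)) {
    stop("stroke timestamps must be non-decreasing", call. = FALSE)
  }
  if (any(points[, "t"] < 0)) {
    stop("stroke timestamps must be non-negative", call. = FALSE)
  }
  structure(points, class = c("stroke", "matrix", "array"))
}

#' Construct and validate a drawing
#'
#' @param drawing_id Unique identifier.
#' @param strokes List of strokes (matrices with columns x, y, t).
#' @param category Category prompt label.
#' @param age_years Child age in whole years (2-10 by default).
#' @param session_id Kiosk session identifier (defaults to the drawing id).
#' @param canvas_size Canvas `(width, height)` in pixels.
#' @param draw_time_s Seconds spent drawing; clipped to `max_time_s` with a
#'   warning (the kiosk enforced a per-trial cap).
#' @param max_time_s Trial cap in seconds (default 30).
#' @param age_range Allowed integer age range.
#' @return An object of class `"drawing"`.
#' @export
drawing <- function(drawing_id, strokes, category, age_years,
                    session_id = drawing_id, canvas_size = c(224, 224),
                    draw_time_s = NULL, max_time_s = 30,
                    age_range = c(2, 10)) {
  strokes <- lapply(strokes, function(s) {
    s <- stroke(s)
    if (any(s[, "x"] < 0 | s[, "x"] > canvas_size[1] - 1 |
              s[, "y"] < 0 | s[, "y"] > canvas_size[2] - 1)) {
      stop(sprintf("drawing '%s': stroke coordinates outside canvas bounds",
                   drawing_id), call. = FALSE)
    }
    s
  })
  if (!is.null(age_years)) {
    if (age_years < age_range[1] || age_years > age_range[2]) {
      stop(sprintf("drawing '%s': age %s outside [%d, %d]",
                   drawing_id, age_years, age_range[1], age_range[2]),
           call. = FALSE)
    }
  }
  if (is.null(draw_time_s)) {
    tmax <- if (length(strokes)) {
      max(vapply(strokes, function(s) max(s[, "t"]), numeric(1)))
    } else 0
    draw_time_s <- tmax / 1000
  }
  if (draw_time_s < 0) {
    stop(sprintf("drawing '%s': negative draw time", drawing_id),
         call. = FALSE)
  }
  if (draw_time_s > max_time_s) {
    warning(sprintf("drawing '%s': draw time %.1f s clipped to the %g s cap",
                    drawing_id, draw_time_s, max_time_s), call. = FALSE)
    draw_time_s <- max_time_s
  }
  structure(
    list(drawing_id = as.character(drawing_id), strokes = strokes,
         category = as.character(category), age_years = age_years,
         session_id = as.character(session_id),
         canvas_size = as.numeric(canvas_size),
         draw_time_s = as.numeric(draw_time_s)),
    class = "drawing")
}

#' @export
print.drawing <- function(x, ...) {
  cat(sprintf("<drawing %s> category '%s', age %s, %d stroke(s), %.1f s\n",
              x$drawing_id, x$category,
              x$age_years %||% NA, length(x$strokes), x$draw_time_s))
  invisible(x)
}

#' Category metadata table
#'
#' Builds the per-category metadata used by the semantic-attribute analyses.
#' Real-world size (`big`: approximately larger than a chair) is defined only
#' for inanimate categories and must be `NA` for animate ones.
#'
#' @param category Character vector of category labels.
#' @param animate Logical vector.
#' @param big Logical vector; `NA` exactly where `animate` is `TRUE`.
#' @param draw_frequency Optional numeric parent-report drawing frequency.
#' @return A tibble with one row per category.
#' @export
category_meta <- function(category, animate, big,
                          draw_frequency = rep(NA_real_, length(category))) {
  if (any(animate & !is.na(big)) || any(!animate & is.na(big))) {
    stop("`big` must be defined iff the category is inanimate", call. = FALSE)
  }
  if (anyDuplicated(category)) stop("duplicate category labels", call. = FALSE)
  tibble::tibble(category = as.character(category), animate = animate,
                 big = big, draw_frequency = draw_frequency)
}

# ---------------------------------------------------------------------------
# Corpus I/O: JSON-lines for stroke data, CSV for metadata.

drawing_to_json <- function(d) {
  jsonlite::toJSON(
    list(drawing_id = d$drawing_id, session_id = d$session_id,
         category = d$category, age = d$age_years,
         canvas = d$canvas_size, draw_time_s = d$draw_time_s,
         strokes = lapply(d$strokes, function(s) unclass(s[, 1:3, drop = FALSE]))),
    auto_unbox = TRUE, digits = NA)
}

json_to_drawing <- function(line, max_time_s = 30, age_range = c(2, 10)) {
  # no simplification: jsonlite would collapse equal-length strokes into a
  # single 3-d array
  rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  id <- rec$drawing_id %||% "<missing id>"
  strokes <- lapply(rec$strokes, function(s) {
    do.call(rbind, lapply(s, function(p) unlist(p)))
  })
  tryCatch(
    drawing(drawing_id = id, strokes = strokes, category = rec$category,
            age_years = rec$age, session_id = rec$session_id %||% id,
            canvas_size = unlist(rec$canvas), draw_time_s = rec$draw_time_s,
            max_time_s = max_time_s, age_range = age_range),
    error = function(e) {
      stop(sprintf("record '%s': %s", id, conditionMessage(e)), call. = FALSE)
    })
}

#' Save a corpus to a directory
#'
#' Writes `drawings.jsonl` (one drawing per line), `tracings.jsonl` if any
#' tracing trials are present, and `categories.csv`.
#'
#' @param corpus A `sketch_corpus` object (see [load_corpus()]).
#' @param path Directory (created if missing).
#' @return `path`, invisibly.
#' @export
save_corpus <- function(corpus, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(vapply(corpus$drawings, drawing_to_json, character(1)),
             file.path(path, "drawings.jsonl"))
  if (length(corpus$tracings)) {
    writeLines(vapply(corpus$tracings, tracing_to_json, character(1)),
               file.path(path, "tracings.jsonl"))
  }
  if (!is.null(corpus$categories)) {
    utils::write.csv(corpus$categories, file.path(path, "categories.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Load a corpus of drawings, tracing trials and category metadata
#'
#' Reads the JSON-lines / CSV layout written by [save_corpus()]. Records that
#' violate type invariants (negative timestamps, out-of-bounds coordinates,
#' unknown categories) are rejected with an error naming the offending
#' record. An empty directory yields an empty corpus.
#'
#' @param path Directory holding `drawings.jsonl` and optional
#'   `tracings.jsonl` / `categories.csv`.
#' @inheritParams drawing
#' @return A `sketch_corpus`: list with `drawings` (list of [drawing()]),
#'   `tracings` (list of tracing trials) and `categories` (tibble or `NULL`).
#' @export
load_corpus <- function(path, max_time_s = 30, age_range = c(2, 10)) {
  drawings <- list()
  f <- file.path(path, "drawings.jsonl")
  if (file.exists(f)) {
    lines <- readLines(f, warn = FALSE)
    drawings <- lapply(lines[nzchar(lines)], json_to_drawing,
                       max_time_s = max_time_s, age_range = age_range)
    names(drawings) <- vapply(drawings, `[[`, character(1), "drawing_id")
  }
  categories <- NULL
  fc <- file.path(path, "categories.csv")
  if (file.exists(fc)) {
    categories <- tibble::as_tibble(utils::read.csv(fc))
    bad <- setdiff(vapply(drawings, `[[`, character(1), "category"),
                   categories$category)
    if (length(bad)) {
      stop("unknown categories in corpus: ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
  }
  tracings <- list()
  ft <- file.path(path, "tracings.jsonl")
  if (file.exists(ft)) {
    lines <- readLines(ft, warn = FALSE)
    tracings <- lapply(lines[nzchar(lines)], json_to_tracing)
  }
  structure(list(drawings = drawings, tracings = tracings,
                 categories = categories),
            class = "sketch_corpus")
}

#' Build a corpus object from components
#' @param drawings List of [drawing()] objects.
#' @param tracings List of tracing trials (may be empty).
#' @param categories Optional [category_meta()] tibble.
#' @return A `sketch_corpus` object.
#' @export
sketch_corpus <- function(drawings = list(), tracings = list(),
                          categories = NULL) {
  names(drawings) <- vapply(drawings, `[[`, character(1), "drawing_id")
  structure(list(drawings = drawings, tracings = tracings,
                 categories = categories),
            class = "sketch_corpus")
}

#' @export
print.sketch_corpus <- function(x, ...) {
  cat(sprintf("<sketch_corpus> %d drawings, %d tracings, %s categories\n",
              length(x$drawings), length(x$tracings),
              if (is.null(x$categories)) "no" else nrow(x$categories)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rasterization.

# Disc of integer pixel offsets covered by a stroke of the given width.
stamp_offsets <- function(stroke_width) {
  r <- stroke_width / 2
  ri <- floor(r)
  g <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Rasterize a drawing to a grayscale image
#'
#' Renders strokes as connected polylines, black on white, in recorded
#' order. Ink is binary (no anti-aliasing) so that ink-proportion counts are
#' exactly reproducible; overlapping strokes are idempotent.
#'
#' @param drawing A [drawing()] (or a bare list of stroke matrices together
#'   with `canvas_size`).
#' @param size Output raster side in pixels (square), >= 16. Default 224.
#' @param stroke_width Stroke width in output pixels, >= 1. Default 3.
#' @return `size` x `size` numeric matrix in `[0, 1]`; 1 = background.
#' @export
rasterize <- function(drawing, size = 224, stroke_width = 3) {
  stopifnot(size >= 16, stroke_width >= 1)
  canvas <- drawing$canvas_size
  strokes <- drawing$strokes
  img <- matrix(1, nrow = size, ncol = size)
  if (!length(strokes)) return(img)
  sx <- if (canvas[1] > 1) (size - 1) / (canvas[1] - 1) else 1
  sy <- if (canvas[2] > 1) (size - 1) / (canvas[2] - 1) else 1
  offs <- stamp_offsets(stroke_width)
  for (s in strokes) {
    px <- s[, 1] * sx
    py <- s[, 2] * sy
    # densely sample each segment (step 0.25 px) and stamp the disc
    xs <- px[1]; ys <- py[1]
    if (length(px) > 1) {
      for (i in seq_len(length(px) - 1)) {
        len <- sqrt((px[i + 1] - px[i])^2 + (py[i + 1] - py[i])^2)
        n <- max(2L, ceiling(len * 4) + 1L)
        tt <- seq(0, 1, length.out = n)
        xs <- c(xs, px[i] + tt * (px[i + 1] - px[i]))
        ys <- c(ys, py[i] + tt * (py[i + 1] - py[i]))
      }
    }
    cx <- round(xs); cy <- round(ys)
    for (k in seq_len(nrow(offs))) {
      xk <- cx + offs$dx[k]; yk <- cy + offs$dy[k]
      ok <- xk >= 0 & xk < size & yk >= 0 & yk < size
      img[cbind(yk[ok] + 1L, xk[ok] + 1L)] <- 0
    }
  }
  img
}

# Rasterize bare stroke point matrices given in raster coordinates already.
rasterize_points <- function(strokes, size, stroke_width = 3) {
  d <- list(strokes = lapply(strokes, function(s) {
    s <- as.matrix(s)
    if (ncol(s) == 2) s <- cbind(s, seq_len(nrow(s)))
    s
  }), canvas_size = c(size, size))
  # clip to canvas: points outside are dropped by the stamping bounds check
  rasterize(d, size = size, stroke_width = stroke_width)
}

#' Effort covariates of a drawing
#'
#' Time spent drawing, number of strokes, and "ink used": the proportion of
#' raster pixels that are non-white (intensity < 1).
#'
#' @param drawing A [drawing()].
#' @param raster Raster produced from `drawing` by [rasterize()]; rendered on
#'   the fly with defaults when omitted.
#' @return One-row tibble with `draw_time_s`, `n_strokes`, `ink_proportion`.
#' @export
effort_covariates <- function(drawing, raster = NULL) {
  if (is.null(raster)) raster <- rasterize(drawing)
  tibble::tibble(
    drawing_id = drawing$drawing_id,
    draw_time_s = drawing$draw_time_s,
    n_strokes = length(drawing$strokes),
    ink_proportion = mean(raster < 1))
}
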