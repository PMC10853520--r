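# Tracing accuracy: affine registration of a tracing to its target shape
# under a normalized cross-correlation loss, and decomposition of the fitted
# transform into translation / rotation / scaling error magnitudes.

#' Affine parameters (translation, rotation, anisotropic scale)
#'
#' The transform acts about the raster center `c`:
#' `A(p) = R(theta) %*% diag(sx, sy) %*% (p - c) + c + (tx, ty)`.
#' No shear term is included, which makes the decomposition into
#' translation, rotation and scaling components unique.
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation in radians.
#' @param sx,sy Scale factors (> 0).
#' @return An object of class `"affine_params"`.
#' @export
affine_params <- function(tx = 0, ty = 0, theta = 0, sx = 1, sy = 1) {
  if (sx <= 0 || sy <= 0) stop("scale factors must be positive", call. = FALSE)
  structure(list(tx = tx, ty = ty, theta = theta, sx = sx, sy = sy),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("<affine> t = (%.2f, %.2f) px, theta = %.2f deg, s = (%.3f, %.3f)\n",
              x$tx, x$ty, x$theta * 180 / pi, x$sx, x$sy))
  invisible(x)
}

#' Apply an affine transform to points
#' @param pts n x 2 matrix of (x, y) points.
#' @param par [affine_params()].
#' @param center Length-2 center of rotation/scaling (raster center).
#' @return Transformed n x 2 matrix.
#' @export
apply_affine <- function(pts, par, center) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  p <- sweep(pts, 2, center)
  p <- cbind(p[, 1] * par$sx, p[, 2] * par$sy)
  ct <- cos(par$theta); st <- sin(par$theta)
  q <- cbind(ct * p[, 1] - st * p[, 2], st * p[, 1] + ct * p[, 2])
  sweep(q, 2, center + c(par$tx, par$ty), `+`)
}

# Inverse-map output pixel coordinates and sample `img` bilinearly;
# samples outside the image take the background value. The warp family is
# A(p) = diag(sx, sy) %*% R(theta) %*% (p - c) + c + t — the opposite
# composition order to apply_affine(), so that the alignment inverse of a
# generated tracing transform is exactly representable.
warp_affine_raster <- function(img, par, background = 1) {
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xo <- rep(0:(w - 1), each = h); yo <- rep(0:(h - 1), times = w)
  vx <- (xo - cx - par$tx) / par$sx
  vy <- (yo - cy - par$ty) / par$sy
  ct <- cos(par$theta); st <- sin(par$theta)
  sxp <- ct * vx + st * vy + cx
  syp <- -st * vx + ct * vy + cy
  x0 <- floor(sxp); y0 <- floor(syp)
  fx <- sxp - x0; fy <- syp - y0
  get <- function(xi, yi) {
    v <- rep(background, length(xi))
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * get(x0, y0) + fx * (1 - fy) * get(x0 + 1, y0) +
    (1 - fx) * fy * get(x0, y0 + 1) + fx * fy * get(x0 + 1, y0 + 1)
  matrix(v, nrow = h, ncol = w)
}

# Forward transform of the registration warp family:
# A(p) = diag(sx, sy) %*% R(theta) %*% (p - c) + c + t.
warp_points_forward <- function(pts, par, center) {
  p <- sweep(as.matrix(pts)[, 1:2, drop = FALSE], 2, center)
  ct <- cos(par$theta); st <- sin(par$theta)
  q <- cbind(ct * p[, 1] - st * p[, 2], st * p[, 1] + ct * p[, 2])
  q <- cbind(q[, 1] * par$sx, q[, 2] * par$sy)
  sweep(q, 2, center + c(par$tx, par$ty), `+`)
}

#' Alignment inverse of a generation transform
#'
#' Given the affine `G` applied to a target contour when generating a
#' tracing (scale, then rotation, then translation, as in
#' [apply_affine()]), returns the parameters of the registration transform
#' `A = G^{-1}` in the warp family used by [register_affine()], i.e. the
#' ground truth the registration should recover.
#'
#' @param true_affine [affine_params()] used to generate the tracing.
#' @return [affine_params()] of the expected registration result.
#' @export
alignment_inverse <- function(true_affine) {
  ct <- cos(true_affine$theta); st <- sin(true_affine$theta)
  # A(p) = S^-1 R^-1 (p - c) + c - S^-1 R^-1 t
  tx <- -( ct * true_affine$tx + st * true_affine$ty) / true_affine$sx
  ty <- -(-st * true_affine$tx + ct * true_affine$ty) / true_affine$sy
  affine_params(tx = tx, ty = ty, theta = -true_affine$theta,
                sx = 1 / true_affine$sx, sy = 1 / true_affine$sy)
}

# Pixel-wise normalized cross-correlation (Pearson over pixels).
ncc <- function(a, b) {
  va <- as.vector(a); vb <- as.vector(b)
  sa <- stats::sd(va); sb <- stats::sd(vb)
  if (sa == 0 || sb == 0) return(NA_real_)
  mean((va - mean(va)) * (vb - mean(vb))) * length(va) /
    ((length(va) - 1) * sa * sb)
}

#' Standard tracing target shapes
#'
#' Builds the contour polyline and raster for the tracing task's target
#' shapes: an easy shape (a square) and a complex shape with curved and
#' sharp segments (a five-point star).
#'
#' @param shape_id `"square"` or `"star"`.
#' @param size Raster side in pixels.
#' @param stroke_width Contour width in pixels.
#' @param radius Target radius as a fraction of `size`; the default leaves
#'   room for affine perturbations (translations to 20 px, rotations to 30
#'   degrees, scales to 1.4 at the default size) without canvas clipping.
#' @return List with `shape_id`, `contour` (closed polyline, raster pixel
#'   coordinates) and `raster`.
#' @export
tracing_target <- function(shape_id = c("square", "star"), size = 128,
                           stroke_width = 3, radius = 0.16) {
  shape_id <- match.arg(shape_id)
  c0 <- (size - 1) / 2
  r <- radius * size
  if (shape_id == "square") {
    u <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(-1, -1))
    pts <- sweep(u * r, 2, c(c0, c0), `+`)
  } else {
    k <- 0:10
    ang <- -pi / 2 + k * pi / 5
    rad <- ifelse(k %% 2 == 0, r, 0.45 * r)
    pts <- cbind(c0 + rad * cos(ang), c0 + rad * sin(ang))
  }
  # densify so jittered tracings look like pen paths
  dense <- densify_polyline(pts, step = 2)
  raster <- rasterize_points(list(dense), size = size,
                             stroke_width = stroke_width)
  list(shape_id = shape_id, contour = dense, raster = raster, size = size,
       stroke_width = stroke_width)
}

densify_polyline <- function(pts, step = 2) {
  out <- pts[1, , drop = FALSE]
  for (i in seq_len(nrow(pts) - 1)) {
    len <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
    n <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n)[-1]
    out <- rbind(out, cbind(pts[i, 1] + tt * (pts[i + 1, 1] - pts[i, 1]),
                            pts[i, 2] + tt * (pts[i + 1, 2] - pts[i, 2])))
  }
  out
}

# JSON-lines (de)serialization for tracing trials.
tracing_to_json <- function(tr) {
  jsonlite::toJSON(
    list(session_id = tr$session_id, shape_id = tr$shape_id, size = tr$size,
         strokes = lapply(tr$strokes, function(s) unclass(as.matrix(s)))),
    auto_unbox = TRUE, digits = NA)
}

json_to_tracing <- function(line) {
  rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  target <- tracing_target(rec$shape_id, size = rec$size)
  strokes <- lapply(rec$strokes, function(s) {
    do.call(rbind, lapply(s, function(p) unlist(p)))
  })
  tracing_trial(session_id = rec$session_id, shape_id = rec$shape_id,
                strokes = strokes, target = target)
}

#' Assemble a tracing trial
#' @param session_id Session identifier.
#' @param shape_id Target shape label.
#' @param strokes List of stroke point matrices in raster coordinates.
#' @param target A [tracing_target()].
#' @return An object of class `"tracing_trial"` with the tracing rendered at
#'   the target's resolution.
#' @export
tracing_trial <- function(session_id, shape_id, strokes, target) {
  stopifnot(shape_id == target$shape_id)
  raster <- rasterize_points(strokes, size = target$size,
                             stroke_width = target$stroke_width)
  structure(list(session_id = as.character(session_id), shape_id = shape_id,
                 strokes = strokes, raster = raster, target = target$raster,
                 size = target$size),
            class = "tracing_trial")
}

#' Register a tracing to its target shape by an affine transform
#'
#' Finds the translation/rotation/scale transform of the tracing that
#' maximizes the pixel-wise normalized cross-correlation (NCC) with the
#' target; the loss minimized is `-NCC`, i.e. the correlation distance up to
#' a constant. Optimization is two-level multi-resolution Nelder-Mead on
#' Gaussian-smoothed rasters with several rotation starts, which makes the
#' result deterministic for fixed options.
#'
#' @param tracing Tracing raster (H x W matrix) or a `tracing_trial`.
#' @param target Target raster; taken from the trial if omitted.
#' @param options List of optimizer options: `smooth_sigma` (pixels, default
#'   2), `rotation_starts` (radians, default `c(0, -15, 15, -30, 30) * pi/180`),
#'   `maxit_coarse`, `maxit_fine`, `reltol`.
#' @return List with `params` ([affine_params()]), `final_ncc` in `[-1, 1]`
#'   (`NA` with `flag = "blank"` for a constant tracing), `loss_trace`
#'   (best loss per optimization stage) and `flag`.
#' @export
register_affine <- function(tracing, target = NULL, options = list()) {
  strokes <- NULL
  stroke_width <- 3
  if (inherits(tracing, "tracing_trial")) {
    if (is.null(target)) target <- tracing$target
    strokes <- tracing$strokes
    tracing <- tracing$raster
  }
  stopifnot(all(dim(tracing) == dim(target)))
  if (stats::sd(as.vector(target)) == 0) {
    stop("target raster is constant; registration undefined", call. = FALSE)
  }
  if (stats::sd(as.vector(tracing)) == 0) {
    return(list(params = affine_params(), final_ncc = NA_real_,
                loss_trace = numeric(0), flag = "blank"))
  }
  o <- utils::modifyList(
    list(smooth_sigma = 3,
         rotation_starts = c(0, -15, 15, -30, 30) * pi / 180,
         max_rotation = pi / 4,
         maxit_coarse = 300, maxit_refine = 250, reltol = 1e-9),
    options)

  tr_s <- blur_gaussian(tracing, o$smooth_sigma)
  tg_s <- blur_gaussian(target, o$smooth_sigma)
  # pyramid: full, half, quarter resolution
  pyr <- list(list(tr = tr_s, tg = tg_s))
  for (l in 2:3) {
    pyr[[l]] <- list(tr = downsample2(pyr[[l - 1]]$tr),
                     tg = downsample2(pyr[[l - 1]]$tg))
  }

  # Rotations beyond the target's symmetry order are unidentifiable (a
  # square maps to itself at 90 deg with swapped axis scales); a soft
  # barrier keeps the decomposition on the smallest-magnitude branch.
  loss_fun <- function(img, ref) {
    function(p) {
      par <- list(tx = p[1], ty = p[2], theta = p[3],
                  sx = exp(p[4]), sy = exp(p[5]))
      v <- ncc(warp_affine_raster(img, par), ref)
      pen <- 10 * pmax(0, abs(p[3]) - o$max_rotation)^2
      (if (is.na(v)) 1 else -v) + pen
    }
  }
  pscale <- c(4, 4, 0.15, 0.1, 0.1)
  trace <- numeric(0)

  # moment-based initialization at the coarse level: centroid shift and
  # per-axis ink spread seed translation and scale
  ink_moments <- function(img) {
    wgt <- pmax(1 - img, 0)
    wgt <- wgt / sum(wgt)
    xs <- col(img) - 1; ys <- row(img) - 1
    mx <- sum(wgt * xs); my <- sum(wgt * ys)
    c(mx = mx, my = my,
      sx = sqrt(sum(wgt * (xs - mx)^2)), sy = sqrt(sum(wgt * (ys - my)^2)))
  }
  mT <- ink_moments(pyr[[3]]$tr); mS <- ink_moments(pyr[[3]]$tg)
  t0 <- c(mS["mx"] - mT["mx"], mS["my"] - mT["my"])
  ls0 <- c(log(mS["sx"] / mT["sx"]), log(mS["sy"] / mT["sy"]))

  # coarse level (quarter resolution): multi-start over rotations
  f_c <- loss_fun(pyr[[3]]$tr, pyr[[3]]$tg)
  best <- NULL
  for (th0 in o$rotation_starts) {
    fit <- stats::optim(c(t0, th0, ls0), f_c, method = "Nelder-Mead",
                        control = list(maxit = o$maxit_coarse,
                                       reltol = o$reltol, parscale = pscale))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  trace <- c(trace, best$value)

  # refine up the pyramid from the best coarse optimum
  fit <- best
  for (l in c(2, 1)) {
    p0 <- fit$par
    p0[1:2] <- p0[1:2] * 2
    f_l <- loss_fun(pyr[[l]]$tr, pyr[[l]]$tg)
    fit <- stats::optim(p0, f_l, method = "Nelder-Mead",
                        control = list(maxit = o$maxit_refine,
                                       reltol = o$reltol,
                                       parscale = pscale * if (l == 1) 0.25 else 1))
    trace <- c(trace, fit$value)
  }

  # When the tracing's strokes are available, finish by optimizing the
  # stroke-based NCC: warp the stroke points with the candidate transform
  # and re-rasterize at the standard pen width before correlating. The pen
  # does not scale with the tracing, so the image-based NCC optimum is
  # slightly biased by pen-width distortion under scaling; the stroke-based
  # objective isolates shape mismatch and is exact for noise-free tracings.
  # Raster-only input keeps the smoothed-image NCC.
  if (!is.null(strokes)) {
    size <- nrow(target)
    c0 <- (size - 1) / 2
    tg_b <- blur_gaussian(target, 2)
    stroke_loss <- function(p) {
      par <- list(tx = p[1], ty = p[2], theta = p[3],
                  sx = exp(p[4]), sy = exp(p[5]))
      warped <- lapply(strokes, function(s) {
        warp_points_forward(as.matrix(s)[, 1:2, drop = FALSE], par,
                            center = c(c0, c0))
      })
      re <- rasterize_points(warped, size = size,
                             stroke_width = stroke_width)
      v <- ncc(blur_gaussian(re, 2), tg_b)
      pen <- 10 * pmax(0, abs(p[3]) - o$max_rotation)^2
      (if (is.na(v)) 1 else -v) + pen
    }
    # restart once: a fresh simplex escapes the plateaus that pixel
    # rounding of the re-rasterized strokes creates
    for (rep in 1:2) {
      fit <- stats::optim(fit$par, stroke_loss, method = "Nelder-Mead",
                          control = list(maxit = o$maxit_refine,
                                         reltol = o$reltol,
                                         parscale = pscale * 0.25))
    }
    trace <- c(trace, fit$value)
  }
  p <- fit$par
  params <- affine_params(tx = p[1], ty = p[2], theta = p[3],
                          sx = exp(p[4]), sy = exp(p[5]))
  if (!is.null(strokes)) {
    warped <- lapply(strokes, function(s) {
      warp_points_forward(as.matrix(s)[, 1:2, drop = FALSE], params,
                          center = c(c0, c0))
    })
    re <- rasterize_points(warped, size = size, stroke_width = stroke_width)
    final_ncc <- ncc(blur_gaussian(re, 1), blur_gaussian(target, 1))
  } else {
    final_ncc <- ncc(warp_affine_raster(tr_s, params), tg_s)
  }
  list(params = params, final_ncc = final_ncc, loss_trace = trace,
       flag = "ok")
}

#' Decompose a registration result into error magnitudes
#'
#' Shape error is the residual correlation distance after alignment,
#' `1 - NCC`, in `[0, 2]`. Spatial error magnitudes are the norm of the
#' translation (pixels at the working resolution), `|theta|` (radians) and
#' `|log sx| + |log sy|` (symmetric in expansion and shrinkage).
#'
#' @param affine [affine_params()] from [register_affine()].
#' @param final_ncc Final NCC from the registration.
#' @return One-row tibble with `shape_error`, `translation_mag`,
#'   `rotation_mag`, `scaling_mag`.
#' @export
tracing_errors <- function(affine, final_ncc) {
  tibble::tibble(
    shape_error = 1 - final_ncc,
    translation_mag = sqrt(affine$tx^2 + affine$ty^2),
    rotation_mag = abs(affine$theta),
    scaling_mag = abs(log(affine$sx)) + abs(log(affine$sy)))
}
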