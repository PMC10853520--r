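# Internal numerical helpers shared across modules.

#' Derive a child seed from a global seed and a component tag
#'
#' All generators in the package take a single integer seed; independent
#' random streams for sub-components are derived with this arithmetic hash so
#' that a whole simulated study is reproducible from one number.
#'
#' @param seed Integer global seed.
#' @param tag Character tag naming the component (and, optionally, the item).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 1009 + h) %% 2147483645 + 1)
}

clip01 <- function(x) pmin(1, pmax(0, x))

logit <- function(p) log(p / (1 - p))

#' Log-odds of a clipped probability
#' @noRd
log_odds <- function(p, eps = 1e-12) {
  p <- pmin(1 - eps, pmax(eps, p))
  log(p / (1 - p))
}

# Row-wise softmax of a matrix of scores.
softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# 1-D Gaussian kernel, radius 3*sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge replication; exact normalization at edges.
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# 2x downsampling by block averaging (pads by edge replication if odd).
downsample2 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h %% 2 == 1) img <- rbind(img, img[h, , drop = FALSE])
  if (w %% 2 == 1) img <- cbind(img, img[, w, drop = FALSE])
  h <- nrow(img); w <- ncol(img)
  (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
    img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)]) / 4
}

# Polyline arc length (Euclidean) of an n x >=2 matrix of points.
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts[, 1:2, drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
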