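# Recognizability: embedding preparation, balanced cross-validated
# multiclass classification with L2-regularized logistic regression, per-
# drawing log-odds evidence, and zero-shot embedding-similarity
# classification.

#' Prepare embedding features
#'
#' Fully-connected features are z-scored per column over the corpus;
#' convolutional feature maps (n x C x H x W arrays) are first spatially
#' averaged per channel. Zero-variance columns are dropped with a warning.
#'
#' @param raw Matrix (n x D) or 4-d array (n x C x H x W).
#' @param layer_kind `"fc"` or `"conv"`.
#' @return Normalized matrix (columns mean 0, sd 1), rownames preserved.
#' @export
prepare_features <- function(raw, layer_kind = c("fc", "conv")) {
  layer_kind <- match.arg(layer_kind)
  if (layer_kind == "conv") {
    stopifnot(length(dim(raw)) == 4)
    raw <- apply(raw, c(1, 2), mean)
  }
  x <- as.matrix(raw)
  if (nrow(x) < 2) stop("need >= 2 rows to normalize", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance column(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

# Ridge multinomial logistic regression by direct penalized-likelihood
# optimization (no intercepts). Matches the glmnet objective
# (1/n) * NLL + lambda/2 * ||B||_F^2; used where glmnet refuses the design
# (classes with a single training observation, as in leave-one-out games).
ridge_multinomial <- function(x_train, y_train, x_test, lambda) {
  classes <- sort(unique(as.character(y_train)))
  K <- length(classes); p <- ncol(x_train); n <- nrow(x_train)
  yi <- match(y_train, classes)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1
  obj <- function(b) {
    B <- matrix(b, p, K)
    s <- x_train %*% B
    m <- apply(s, 1, max)
    lse <- m + log(rowSums(exp(s - m)))
    -sum(s[cbind(seq_len(n), yi)] - lse) / n + lambda / 2 * sum(B^2)
  }
  grad <- function(b) {
    B <- matrix(b, p, K)
    P <- softmax_rows(x_train %*% B)
    as.vector(crossprod(x_train, P - Y) / n + lambda * B)
  }
  fit <- stats::optim(rep(0, p * K), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  P <- softmax_rows(x_test %*% matrix(fit$par, p, K))
  colnames(P) <- classes
  P
}

# Shared glmnet multinomial fit + probability prediction.
fit_l2_multinomial <- function(x_train, y_train, x_test, l2_strength = 0.1,
                               tolerance = 0.1) {
  classes <- sort(unique(as.character(y_train)))
  lambda <- 1 / (nrow(x_train) * l2_strength)
  if (min(table(y_train)) < 2) {
    return(ridge_multinomial(x_train, y_train, x_test, lambda))
  }
  # no class intercepts: training sets are category-balanced, so
  # intercepts are redundant, and unpenalized intercepts are unstable
  # under perfect separation. A short decreasing lambda path warm-starts
  # the coordinate descent (single-lambda multinomial fits can stall at
  # the degenerate equal-coefficients solution).
  fit <- withCallingHandlers(
    glmnet::glmnet(x_train, factor(y_train, levels = classes),
                   family = "multinomial", alpha = 0,
                   lambda = lambda * c(100, 10, 1),
                   standardize = FALSE, intercept = FALSE,
                   thresh = tolerance * 1e-6, maxit = 1e5),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  # probabilities via a stable softmax on the link scale (glmnet's own
  # response transform can overflow for near-separable data)
  lk <- drop(stats::predict(fit, newx = x_test, type = "link", s = lambda))
  if (is.null(dim(lk))) lk <- matrix(lk, nrow = 1)
  pr <- softmax_rows(lk)
  colnames(pr) <- classes
  pr
}

#' Classifier evidence: log-odds of the target probability
#'
#' `ln(p / (1 - p))` for the probability assigned to the target category,
#' with `p` clipped to `[1e-12, 1 - 1e-12]`. This is the graded
#' recognizability measure used throughout the analyses.
#'
#' @param prob Probability vector over categories (named), or matrix with
#'   one row per item.
#' @param target Target label (vector for the matrix case).
#' @return Numeric evidence value(s).
#' @export
classifier_evidence <- function(prob, target) {
  if (is.matrix(prob)) {
    p <- prob[cbind(seq_len(nrow(prob)), match(target, colnames(prob)))]
  } else {
    p <- prob[[target]]
  }
  log_odds(p)
}

#' Balanced cross-validated multiclass classification
#'
#' Subsamples an equal number of drawings per category (seed-controlled,
#' without replacement), partitions each category into disjoint folds of
#' `holdout_per_category` items, and classifies every held-out item with an
#' L2-regularized multinomial logistic model trained on all remaining items.
#' Each item is classified exactly once by a model never trained on it.
#'
#' @param embeddings Normalized matrix from [prepare_features()] with
#'   rownames = drawing ids.
#' @param targets Character vector of intended categories, aligned to rows.
#' @param holdout_per_category Held-out items per category per fold
#'   (default 2, so a category with 2n items yields n folds).
#' @param hyper List with `l2_strength` (inverse regularization strength C;
#'   default 0.1) and `tolerance` (optimizer convergence tolerance, mapped
#'   to the coordinate-descent threshold; default 0.1).
#' @param seed Integer seed controlling the balanced subsample and folds.
#' @return Tibble (`drawing_id`, `target`, `predicted`, `correct`,
#'   `p_target`, `evidence`, `fold`) with list-column `prob` holding each
#'   item's named probability vector.
#' @export
balanced_crossval_classify <- function(embeddings, targets,
                                       holdout_per_category = 2,
                                       hyper = list(l2_strength = 0.1,
                                                    tolerance = 0.1),
                                       seed = 1) {
  stopifnot(nrow(embeddings) == length(targets))
  targets <- as.character(targets)
  ids <- rownames(embeddings) %||% as.character(seq_len(nrow(embeddings)))
  counts <- table(targets)
  too_small <- names(counts)[counts < 2 * holdout_per_category]
  if (length(too_small)) {
    stop("categories below the 2x holdout minimum: ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  set.seed(child_seed(seed, "cv"))
  n_bal <- min(counts)
  n_bal <- n_bal - n_bal %% holdout_per_category
  n_folds <- n_bal %/% holdout_per_category
  # balanced subsample + fold assignment per category
  keep <- integer(0); fold <- integer(0)
  for (cat in names(counts)) {
    rows <- sample(which(targets == cat), n_bal)
    keep <- c(keep, rows)
    fold <- c(fold, rep(seq_len(n_folds), each = holdout_per_category))
  }
  x <- embeddings[keep, , drop = FALSE]
  y <- targets[keep]
  id <- ids[keep]
  classes <- sort(unique(y))
  out_prob <- matrix(NA_real_, nrow = length(keep), ncol = length(classes),
                     dimnames = list(NULL, classes))
  for (f in seq_len(n_folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    out_prob[te, ] <- fit_l2_multinomial(
      x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
      l2_strength = hyper$l2_strength %||% 0.1,
      tolerance = hyper$tolerance %||% 0.1)
  }
  predicted <- classes[max.col(out_prob, ties.method = "first")]
  p_target <- out_prob[cbind(seq_along(y), match(y, classes))]
  tibble::tibble(
    drawing_id = id, target = y, predicted = predicted,
    correct = predicted == y, p_target = p_target,
    evidence = log_odds(p_target), fold = fold,
    prob = lapply(seq_along(y), function(i) out_prob[i, ]))
}

#' Zero-shot classification by embedding similarity
#'
#' Assigns each image the label whose embedding has the highest cosine
#' similarity; an item is correct when that label is its target.
#' Probabilities are a softmax over similarities at a fixed documented
#' temperature so that log-odds evidence is defined for this classifier too.
#'
#' @param image_embeddings n x D matrix (rownames = ids).
#' @param label_embeddings K x D matrix (rownames = labels).
#' @param targets Character vector of intended categories.
#' @param temperature Softmax inverse temperature on cosines (default 100).
#' @return Tibble as in [balanced_crossval_classify()] plus a `tie` flag
#'   (ties broken toward the lowest label index).
#' @export
zero_shot_classify <- function(image_embeddings, label_embeddings, targets,
                               temperature = 100) {
  ni <- sqrt(rowSums(image_embeddings^2))
  nl <- sqrt(rowSums(label_embeddings^2))
  if (any(ni == 0) || any(nl == 0)) {
    stop("zero-norm embedding encountered", call. = FALSE)
  }
  sim <- (image_embeddings / ni) %*% t(label_embeddings / nl)
  labels <- rownames(label_embeddings)
  colnames(sim) <- labels
  best <- max.col(sim, ties.method = "first")
  tie <- apply(sim, 1, function(r) sum(r == max(r)) > 1)
  prob <- softmax_rows(temperature * sim)
  p_target <- prob[cbind(seq_along(targets), match(targets, labels))]
  tibble::tibble(
    drawing_id = rownames(image_embeddings) %||%
      as.character(seq_along(targets)),
    target = as.character(targets), predicted = labels[best],
    correct = labels[best] == targets, p_target = p_target,
    evidence = log_odds(p_target), tie = tie,
    prob = lapply(seq_along(targets), function(i) prob[i, ]),
    similarity = lapply(seq_along(targets), function(i) sim[i, ]))
}
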