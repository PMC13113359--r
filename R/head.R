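#' Initialize screening-head parameters
#'
#' The head is bias-free: a linear projection `W_s h` of the fused
#' representation into a compact `screen_dim`-dimensional screening space,
#' followed by one independent sigmoid classifier weight vector per disease
#' class. Single-disease screening is the `n_classes = 1` special case.
#'
#' @param embed_dim Encoder embedding width E.
#' @param n_classes Number of disease classes C.
#' @param screen_dim Screening-space dimension D (default 256, or E if
#'   smaller).
#' @param seed Integer seed.
#' @return List with `screening_projection` (`D x E`) and `class_weights`
#'   (`C x D`).
#' @export
init_head_params <- function(embed_dim, n_classes, screen_dim = NULL,
                             seed = 1L) {
  if (is.null(screen_dim)) screen_dim <- min(256L, embed_dim)
  stopifnot(screen_dim >= 1, n_classes >= 1)
  with_seed(seed, list(
    screening_projection = init_matrix(screen_dim, embed_dim),
    class_weights = init_matrix(n_classes, screen_dim)
  ))
}

#' Project the fused representation into screening space
#'
#' Bias-free linear map `W_s h`.
#'
#' @param h Fused representation (length E).
#' @param head_params A [init_head_params()] list.
#' @return Length-D screening feature vector.
#' @export
project_screening <- function(h, head_params) {
  W <- head_params$screening_projection
  if (length(h) != ncol(W)) stop("dimension mismatch: h vs screening projection")
  as.numeric(W %*% h)
}

#' Per-class sigmoid screening probabilities
#'
#' `y_hat_c = sigmoid(w_c . r)` independently per class — no mutual
#' exclusivity is assumed, so co-occurring diseases are representable.
#' Optionally thresholds the probabilities into binary decisions.
#'
#' @param r Screening feature vector (length D).
#' @param head_params A [init_head_params()] list.
#' @param thresholds Optional per-class decision thresholds in (0, 1);
#'   default 0.5.
#' @return Object of class `screening_prediction`: list with `probabilities`,
#'   `decisions`, `thresholds`, `logits`.
#' @export
predict_screening <- function(r, head_params, thresholds = NULL) {
  logits <- as.numeric(head_params$class_weights %*% r)
  probs <- sigmoid(logits)
  C <- length(probs)
  if (is.null(thresholds)) thresholds <- rep(0.5, C)
  stopifnot(length(thresholds) == C)
  structure(list(
    probabilities = probs,
    decisions = as.integer(probs >= thresholds),
    thresholds = thresholds,
    logits = logits
  ), class = "screening_prediction")
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy loss (single disease)
#'
#' `-(y log y_hat + (1 - y) log(1 - y_hat))`, with the predicted probability
#' clipped to `[1e-7, 1 - 1e-7]` for numerical stability.
#'
#' @param y Binary label (0 or 1).
#' @param y_hat Predicted probability in (0, 1).
#' @return Non-negative scalar.
#' @export
loss_single <- function(y, y_hat) {
  if (!all(y %in% c(0, 1))) stop("y must be 0 or 1")
  p <- clip_prob(y_hat)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Summed binary cross-entropy loss (multi-disease)
#'
#' Unweighted sum over classes of the per-class binary cross-entropy;
#' decomposes exactly as `sum_c loss_single(y_c, y_hat_c)`.
#'
#' @param y Binary label vector of length C.
#' @param y_hat Probability vector of length C.
#' @return Non-negative scalar.
#' @export
loss_multi <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("label/probability length mismatch")
  sum(loss_single(y, y_hat))
}

#' Ordinal severity grading via one-vs-rest indicators
#'
#' Severity grading (five ordinal grades, 0 = healthy through 4) is handled
#' with the same sigmoid machinery as multi-label screening: each grade gets
#' a one-vs-rest indicator column, and the reported grade is the
#' argmax-by-probability. No softmax is introduced anywhere in the head.
#'
#' @param severity Integer vector of ordinal grades in `0 .. n_grades - 1`.
#' @param n_grades Number of grades (default 5).
#' @return `severity_indicators` returns an `n x n_grades` 0/1 matrix;
#'   `grade_from_probabilities` returns integer grades.
#' @export
severity_indicators <- function(severity, n_grades = 5L) {
  stopifnot(all(severity >= 0), all(severity < n_grades))
  m <- matrix(0L, length(severity), n_grades)
  m[cbind(seq_along(severity), severity + 1L)] <- 1L
  colnames(m) <- paste0("grade", seq_len(n_grades) - 1L)
  m
}

#' @rdname severity_indicators
#' @param probabilities `n x n_grades` matrix of per-grade probabilities.
#' @export
grade_from_probabilities <- function(probabilities) {
  max.col(as.matrix(probabilities), ties.method = "first") - 1L
}

#' Select per-class decision thresholds on validation data
#'
#' For each class, scans every observed predicted probability as a candidate
#' threshold and picks the one maximizing Youden's J statistic
#' (sensitivity + specificity - 1), breaking ties toward the higher
#' threshold. Decisions use `probability >= threshold`.
#'
#' @param validation_probs `n x C` matrix (or length-n vector for C = 1) of
#'   validation-set probabilities.
#' @param validation_labels Matching binary labels.
#' @return Numeric vector of length C of thresholds.
#' @export
select_thresholds <- function(validation_probs, validation_labels) {
  p <- as.matrix(validation_probs)
  y <- as.matrix(validation_labels)
  stopifnot(identical(dim(p), dim(y)))
  vapply(seq_len(ncol(p)), function(c) {
    pc <- p[, c]; yc <- y[, c]
    if (length(unique(yc)) < 2) {
      stop("validation column for class ", c, " contains a single label value")
    }
    cands <- sort(unique(pc), decreasing = TRUE)
    best_j <- -Inf; best_t <- cands[1]
    npos <- sum(yc == 1); nneg <- sum(yc == 0)
    for (t in cands) {
      dec <- pc >= t
      j <- sum(dec & yc == 1) / npos + sum(!dec & yc == 0) / nneg - 1
      if (j > best_j) { best_j <- j; best_t <- t }  # ties keep higher t
    }
    best_t
  }, numeric(1))
}
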