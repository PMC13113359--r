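#' @useDynLib fundusformer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom qnorm plogis
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes its seed through here so
# that (config, seed) pairs are bit-reproducible and never touch global state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483587L) + 1L
}

#' Gaussian error linear unit
#'
#' Element-wise GELU activation in its tanh form,
#' `0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))`, the convention used
#' throughout the encoder's feed-forward blocks.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @export
gelu <- function(x) {
  0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}

# Derivative of the tanh-form GELU, needed by backpropagation.
gelu_grad <- function(x) {
  inner <- 0.7978845608028654 * (x + 0.044715 * x^3)
  th <- tanh(inner)
  0.5 * (1 + th) + 0.5 * x * (1 - th^2) * 0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
}

# Numerically safe row-wise softmax over an optional logical support mask.
# Off-support entries are exact zeros; each row must have non-empty support.
softmax_rows <- function(logits, support = NULL) {
  logits <- as.matrix(logits)
  if (!is.null(support)) {
    support <- as.matrix(support)
    stopifnot(identical(dim(support), dim(logits)))
    if (any(rowSums(support) == 0)) {
      stop("softmax_rows(): a row has empty support")
    }
    masked <- logits
    masked[!support] <- -Inf
  } else {
    masked <- logits
  }
  m <- apply(masked, 1L, max)
  w <- exp(masked - m)
  w[w < 1e-150] <- 0  # flush numerically irrelevant weights (denormal guard)
  if (!is.null(support)) w[!support] <- 0
  w / rowSums(w)
}

sigmoid <- function(x) plogis(x)

is_binary <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
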