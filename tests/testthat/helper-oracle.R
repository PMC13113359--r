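# Naive nested-loop reference implementations, kept deliberately independent
# of the package's vectorized/compiled code paths. Only used on tiny inputs.

oracle_gelu <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

# Row softmax by explicit two-loop accumulation over an index support set.
oracle_softmax_row <- function(logits, support) {
  out <- numeric(length(logits))
  denom <- 0
  for (j in support) denom <- denom + exp(logits[j])
  for (j in support) out[j] <- exp(logits[j]) / denom
  out
}

oracle_neighborhood <- function(i, rows, cols, radius) {
  r0 <- (i - 1) %/% cols + 1
  c0 <- (i - 1) %% cols + 1
  res <- integer(0)
  for (j in seq_len(rows * cols)) {
    r <- (j - 1) %/% cols + 1
    c <- (j - 1) %% cols + 1
    if (max(abs(r - r0), abs(c - c0)) <= radius) res <- c(res, j)
  }
  res
}

# Full encoder forward by explicit per-element loops (no layer norm: the
# literal single-residual formulation).
oracle_encoder <- function(Z, params, alphas, grid, radius, n_heads,
                           fusion_depths) {
  N <- nrow(Z)
  E <- nrow(params$patch_projection)
  d <- E / n_heads
  tokens <- matrix(0, N, E)
  for (i in seq_len(N)) {
    e_i <- numeric(E)
    for (a in seq_len(E)) e_i[a] <- sum(params$patch_projection[a, ] * Z[i, ])
    tokens[i, ] <- e_i + params$positional_table[i, ]
  }
  pools <- matrix(0, length(fusion_depths), E)
  for (l in seq_along(params$layers)) {
    lp <- params$layers[[l]]
    q <- tokens %*% t(lp$Wq); k <- tokens %*% t(lp$Wk); v <- tokens %*% t(lp$Wv)
    s_cat <- matrix(0, N, E)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1) * d + 1):(h * d)
      for (i in seq_len(N)) {
        logits <- numeric(N)
        for (j in seq_len(N)) {
          logits[j] <- sum(q[i, idx] * k[j, idx]) / sqrt(d)
        }
        nbr <- oracle_neighborhood(i, grid$grid_rows, grid$grid_cols, radius)
        a_loc <- oracle_softmax_row(logits, nbr)
        a_glo <- oracle_softmax_row(logits, seq_len(N))
        a_mix <- alphas[l] * a_glo + (1 - alphas[l]) * a_loc
        for (a in idx) s_cat[i, a] <- sum(a_mix * v[, a])
      }
    }
    s <- s_cat %*% t(lp$Wo)
    f <- matrix(0, N, E)
    for (i in seq_len(N)) {
      hidden <- oracle_gelu(as.numeric(lp$W1 %*% s[i, ]))
      f[i, ] <- as.numeric(lp$W2 %*% hidden)
    }
    tokens <- tokens + f
    kk <- match(l, fusion_depths)
    if (!is.na(kk)) {
      for (a in seq_len(E)) pools[kk, a] <- mean(tokens[, a])
    }
  }
  w <- exp(params$fusion_logits - max(params$fusion_logits))
  beta <- w / sum(w)
  fused <- numeric(E)
  for (a in seq_len(E)) fused[a] <- sum(beta * pools[, a])
  list(fused = fused, pools = pools, tokens = tokens, beta = beta)
}

# Pooled per-channel moments by naive double loop.
oracle_channel_moments <- function(images) {
  nc <- dim(images[[1]])[3]
  means <- sds <- numeric(nc)
  for (c in seq_len(nc)) {
    vals <- c()
    for (im in images) vals <- c(vals, as.vector(im[, , c]))
    means[c] <- mean(vals)
    sds[c] <- sqrt(mean((vals - means[c])^2))
  }
  list(means = means, sds = sds)
}

# AUROC by exhaustive pair counting with half credit for ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Youden-J threshold by exhaustive enumeration of observed cut points.
oracle_youden <- function(probs, labels) {
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(probs))) {
    dec <- probs >= t
    j <- sum(dec & labels == 1) / sum(labels == 1) +
      sum(!dec & labels == 0) / sum(labels == 0) - 1
    if (j > best_j || (j == best_j && t > best_t)) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, j = best_j)
}
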