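# Independent brute-force oracles used to check the implementation.
# Everything here is written as plain loops over definitions, deliberately
# avoiding the package's vectorised code paths.

# Cross-diffusion fusion transcribed directly from its published definition:
# full kernel with half the mass on the diagonal, sparse row-normalised
# local kernel over K neighbours, t rounds of P_v <- S_v P_avg S_v', final
# average + renormalise + symmetrise.
oracle_snf <- function(mats, K, t) {
  n <- nrow(mats[[1]])
  m <- length(mats)
  ids <- rownames(mats[[1]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  normalize <- function(W) {
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) if (j != i) s <- s + W[i, j]
      if (s == 0) s <- 1
      for (j in seq_len(n)) if (j != i) P[i, j] <- W[i, j] / (2 * s)
      P[i, i] <- 0.5
    }
    P
  }
  local_kernel <- function(W) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      w <- W[i, ]
      w[i] <- -Inf
      nb <- order(-w, ids)[seq_len(min(K, n - 1))]
      tot <- 0
      for (j in nb) tot <- tot + W[i, j]
      if (tot <= 0) tot <- 1
      for (j in nb) S[i, j] <- W[i, j] / tot
    }
    S
  }
  P <- lapply(mats, normalize)
  S <- lapply(mats, local_kernel)
  for (it in seq_len(t)) {
    P_next <- vector("list", m)
    for (v in seq_len(m)) {
      avg <- matrix(0, n, n)
      if (m == 1) {
        avg <- P[[1]]
      } else {
        for (u in seq_len(m)) if (u != v) avg <- avg + P[[u]]
        avg <- avg / (m - 1)
      }
      P0 <- S[[v]] %*% avg %*% t(S[[v]])
      P0 <- normalize(P0)
      P_next[[v]] <- (P0 + t(P0)) / 2
    }
    P <- P_next
  }
  W <- matrix(0, n, n)
  for (v in seq_len(m)) W <- W + P[[v]]
  W <- normalize(W / m)
  W <- (W + t(W)) / 2
  dimnames(W) <- list(ids, ids)
  W
}

# Confusion-matrix metrics by explicit counting.
oracle_metrics <- function(y_true, y_pred, classes) {
  K <- length(classes)
  conf <- matrix(0, K, K)
  for (i in seq_along(y_true)) {
    a <- which(classes == y_true[i])
    b <- which(classes == y_pred[i])
    conf[a, b] <- conf[a, b] + 1
  }
  acc <- sum(diag(conf)) / length(y_true)
  wf1 <- 0
  for (cc in seq_len(K)) {
    tp <- conf[cc, cc]
    fp <- sum(conf[, cc]) - tp
    fn <- sum(conf[cc, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    wf1 <- wf1 + (sum(conf[cc, ]) / length(y_true)) * f1
  }
  list(accuracy = acc, weighted_f1 = wf1, confusion = conf)
}

# Benjamini-Hochberg by its step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Per-dimension median by explicit sorting.
oracle_median_rows <- function(X) {
  out <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- sort(X[, j])
    n <- length(v)
    out[j] <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  out
}

# Sign partition of the Fiedler vector of the normalised graph Laplacian.
fiedler_partition <- function(W) {
  d <- rowSums(W)
  Dinv <- diag(1 / sqrt(pmax(d, 1e-12)))
  L <- diag(nrow(W)) - Dinv %*% W %*% Dinv
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  f <- ev$vectors[, ncol(W) - 1]
  f >= 0
}
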