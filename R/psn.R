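#' @title Patient similarity networks and similarity network fusion
#' @description One similarity matrix per modality (Pearson correlation for
#'   high-dimensional continuous modalities, a scaled Euclidean kernel
#'   otherwise), sparsified to a k-nearest-neighbour graph, then fused
#'   across modalities by iterative cross-diffusion into a single network
#'   spanning the union of participants.
#' @name psn_fusion
NULL

#' Graph / fusion parameters
#'
#' @param k Neighbours kept per node when sparsifying a similarity matrix.
#' @param snf_K Neighbours of the local kernel used inside fusion.
#' @param snf_t Cross-diffusion iterations.
#' @param snf_mu Kernel bandwidth scale of the Euclidean affinity.
#' @return A `graph_params` list.
#' @export
graph_params <- function(k = 15L, snf_K = 20L, snf_t = 20L, snf_mu = 0.5) {
  stopifnot(k >= 1, snf_K >= 1, snf_t >= 1, snf_mu > 0)
  structure(list(k = as.integer(k), snf_K = as.integer(snf_K),
                 snf_t = as.integer(snf_t), snf_mu = snf_mu),
            class = "graph_params")
}

#' Participant-participant similarity matrix
#'
#' `pearson` correlates participant feature vectors (rows); a participant
#' with zero variance gets similarity 0 to everyone (correlation undefined)
#' and 1 to itself. `euclidean_kernel` is the standard fusion affinity
#' `exp(-d^2 / (mu * sigma^2))` where `sigma` averages each pair's mean
#' k-nearest-neighbour distance and their own distance.
#'
#' @param X Participants-by-features matrix (rownames = participant IDs).
#' @param metric `"pearson"` or `"euclidean_kernel"`.
#' @param k Neighbourhood size for the kernel bandwidth.
#' @param mu Kernel bandwidth scale.
#' @return A `similarity_matrix`: list with `ids`, square matrix `S`,
#'   and `metric`.
#' @export
compute_similarity <- function(X, metric = c("pearson", "euclidean_kernel"),
                               k = 20L, mu = 0.5) {
  metric <- match.arg(metric)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 participants")
  ids <- rownames(X)
  if (is.null(ids)) stop("X must have participant IDs as rownames")
  if (metric == "pearson") {
    if (ncol(X) < 2) stop("pearson similarity requires >= 2 features")
    sds <- apply(X, 1, stats::sd)
    S <- suppressWarnings(stats::cor(t(X)))
    S[is.na(S)] <- 0  # constant participant vectors: correlation undefined
    diag(S) <- 1
  } else {
    d <- as.matrix(stats::dist(X))
    kk <- min(k, n - 1)
    # mean distance to the kk nearest neighbours (self excluded)
    mean_knn <- vapply(seq_len(n),
                       function(i) mean(sort(d[i, -i])[seq_len(kk)]),
                       numeric(1))
    sigma <- (outer(mean_knn, mean_knn, "+") + d) / 3
    sigma2 <- pmax(sigma^2, 1e-12)
    S <- exp(-d^2 / (mu * sigma2))
    diag(S) <- 1
  }
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, S = S, metric = metric),
            class = "similarity_matrix")
}

#' Sparsify a similarity matrix to a weighted KNN graph
#'
#' Each node keeps edges to its `k` most-similar neighbours (self excluded;
#' ties broken by participant-ID order); the edge set is union-symmetrised
#' and edge weights are the similarity values.
#'
#' @param S A `similarity_matrix` or a square matrix with ID dimnames.
#' @param k Neighbours per node; must satisfy `1 <= k < n`.
#' @return Square weighted adjacency matrix (zero diagonal).
#' @export
knn_sparsify <- function(S, k) {
  if (inherits(S, "similarity_matrix")) S <- S$S
  n <- nrow(S)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of participants")
  ids <- rownames(S)
  A <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(-s, ids)[seq_len(k)]
    A[i, nb] <- S[i, nb]
  }
  pmax(A, t(A))
}

# Row-normalisation used by the fusion: off-diagonal mass 1/2, diagonal 1/2.
snf_normalize <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1
  P <- off / (2 * rs)
  diag(P) <- 0.5
  P
}

# Sparse local kernel: row-normalised over each node's snf_K nearest
# neighbours (by affinity, ties by ID order), zero elsewhere.
snf_local <- function(W, K) {
  n <- nrow(W)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  K <- min(K, n - 1)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(-w, ids)[seq_len(K)]
    tot <- sum(W[i, nb])
    if (tot <= 0) tot <- 1
    S[i, nb] <- W[i, nb] / tot
  }
  S
}

#' Fuse per-modality affinity matrices by cross-diffusion
#'
#' Implements similarity network fusion: each modality's affinity matrix is
#' row-normalised into a full transition kernel and a sparse local kernel
#' over `snf_K` neighbours; for `snf_t` rounds each full kernel is updated
#' by diffusing the average of the other modalities' kernels through its own
#' local kernel (`P_v <- S_v %*% mean(P_-v) %*% t(S_v)`), re-normalised and
#' symmetrised. The fused network is the symmetrised, re-normalised average
#' of the final kernels. With a single modality there is no cross partner
#' and the update diffuses the modality's own kernel. The diagonal is fixed
#' at 1/2 by the normalisation convention; downstream consumers ignore it
#' and add self-loops explicitly.
#'
#' @param affinities List of square nonnegative matrices (or
#'   `similarity_matrix` objects), all with identical ID dimnames.
#' @param params A [graph_params()].
#' @return A `fused_network`: list with `ids`, fused matrix `W`, `params`.
#' @export
snf_fuse <- function(affinities, params = graph_params()) {
  if (length(affinities) == 0) stop("need at least one affinity matrix")
  mats <- lapply(affinities, function(a) {
    if (inherits(a, "similarity_matrix")) a$S else a
  })
  ids <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), dim(mats[[1]])) || !identical(rownames(m), ids)) {
      stop("affinity matrices are not aligned")
    }
  }
  m <- length(mats)
  P <- lapply(mats, snf_normalize)
  S <- lapply(mats, snf_local, K = params$snf_K)
  for (it in seq_len(params$snf_t)) {
    P_next <- vector("list", m)
    for (v in seq_len(m)) {
      others <- if (m == 1) P[[1]] else Reduce(`+`, P[-v]) / (m - 1)
      P0 <- S[[v]] %*% others %*% t(S[[v]])
      P0 <- snf_normalize(P0)
      P_next[[v]] <- (P0 + t(P0)) / 2
    }
    P <- P_next
  }
  W <- Reduce(`+`, P) / m
  W <- snf_normalize(W)
  W <- (W + t(W)) / 2
  dimnames(W) <- list(ids, ids)
  structure(list(ids = ids, W = W, params = params), class = "fused_network")
}

# Expand an affinity matrix to a larger ID set, inserting uniform small
# affinity 1/n for participants absent from the modality.
expand_affinity <- function(A, ids) {
  n <- length(ids)
  out <- matrix(1 / n, n, n, dimnames = list(ids, ids))
  present <- rownames(A)
  out[present, present] <- A
  out
}

#' Build the fused patient similarity network for a set of modalities
#'
#' Per modality: similarity between participant feature vectors (Pearson for
#' modalities with at least `pearson_min_features` features, the Euclidean
#' kernel otherwise; Pearson values are mapped to `(1+r)/2` so affinities
#' are nonnegative), KNN sparsification, then alignment to the union of
#' participants (absent participants receive uniform affinity `1/n`) and
#' fusion. Class labels are never used.
#'
#' @param selected Named list of participants-by-features matrices, one per
#'   modality, already reduced to selected features.
#' @param params A [graph_params()].
#' @param metric_policy Optional named character vector forcing
#'   `"pearson"`/`"euclidean_kernel"` per modality.
#' @param pearson_min_features Feature-count threshold above which Pearson
#'   is considered suitable (default 10).
#' @return A `fused_network` over the union of participants.
#' @export
build_psn <- function(selected, params = graph_params(), metric_policy = NULL,
                      pearson_min_features = 10L) {
  if (length(selected) == 0) stop("need at least one modality")
  ids <- sort(unique(unlist(lapply(selected, rownames))))
  if (length(ids) == 0) stop("no participants in any modality")
  affinities <- list()
  for (m in names(selected)) {
    X <- selected[[m]]
    metric <- if (!is.null(metric_policy) && m %in% names(metric_policy)) {
      metric_policy[[m]]
    } else if (ncol(X) >= pearson_min_features) "pearson" else "euclidean_kernel"
    sim <- compute_similarity(X, metric, k = params$snf_K, mu = params$snf_mu)
    S <- sim$S
    if (metric == "pearson") S <- (1 + S) / 2
    k <- min(params$k, nrow(S) - 1)
    A <- knn_sparsify(S, k)
    affinities[[m]] <- expand_affinity(A, ids)
  }
  snf_fuse(affinities, params)
}

#' Weighted adjacency of a fused network for the classifier
#'
#' KNN-sparsifies the fused matrix (diagonal ignored) so the graph
#' convolution operates on a sparse neighbourhood graph.
#'
#' @param fused A `fused_network`.
#' @param k Neighbours per node (defaults to the fusion parameters' `k`).
#' @return Square weighted adjacency matrix with zero diagonal.
#' @export
fused_adjacency <- function(fused, k = fused$params$k) {
  W <- fused$W
  diag(W) <- 0
  knn_sparsify(W, min(k, nrow(W) - 1))
}

#' Write a fused network as an edge-list TSV
#' @param fused A `fused_network`.
#' @param path Output TSV path (`id_a`, `id_b`, `weight`; upper triangle).
#' @export
write_edge_list <- function(fused, path) {
  W <- fused$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(id_a = fused$ids[idx[, 1]], id_b = fused$ids[idx[, 2]],
                   weight = W[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
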