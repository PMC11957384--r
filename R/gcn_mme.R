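#' @title Graph convolutional network with multi-modal encoders
#' @description The classifier at the heart of the pipeline: each modality
#'   is compressed by a two-layer encoder (fixed-length first layer,
#'   per-modality second layer), participants missing from a modality are
#'   median-imputed at the second layer, all modalities are decompressed to
#'   a shared latent space and mean-pooled into node features, and a graph
#'   convolutional network over the fused patient similarity network emits
#'   class logits. Training is semi-supervised and transductive: every node
#'   is in the graph, and cross-entropy is evaluated on the training mask
#'   only, with gradients flowing back through the GCN into every encoder.
#'   All forward/backward passes are explicit matrix algebra, so training is
#'   deterministic given a seed.
#' @name gcn_mme
NULL

#' GCN architecture specification
#' @param n_layers Number of graph convolution layers (default 2).
#' @param hidden_dim Hidden width (default 64).
#' @param dropout Dropout rate applied between convolutions during training.
#' @param n_classes Number of output classes.
#' @return A `gcn_spec` list.
#' @export
gcn_spec <- function(n_layers = 2L, hidden_dim = 64L, dropout = 0.5,
                     n_classes = 3L) {
  stopifnot(n_layers >= 1, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, n_classes = as.integer(n_classes)),
            class = "gcn_spec")
}

#' Training configuration
#' @param epochs Maximum epochs (default 300).
#' @param learning_rate Adam step size (default 0.01).
#' @param weight_decay L2 penalty on weight matrices (default 5e-4).
#' @param patience Early-stopping patience on validation loss (default 30).
#' @param seed RNG seed for initialisation and dropout.
#' @param class_weighting Weight the loss inversely to class size
#'   (default TRUE, appropriate for imbalanced cohorts).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, learning_rate = 0.01,
                         weight_decay = 5e-4, patience = 30L, seed = 1L,
                         class_weighting = TRUE) {
  stopifnot(epochs >= 1, patience >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, patience = as.integer(patience),
                 seed = as.integer(seed), class_weighting = class_weighting),
            class = "train_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(input_dims, layer1_dim, layer2_dims, shared_dim,
                        spec) {
  enc <- list()
  for (m in names(input_dims)) {
    p <- input_dims[[m]]; d2 <- layer2_dims[[m]]
    enc[[m]] <- list(W1 = glorot(p, layer1_dim), b1 = numeric(layer1_dim),
                     W2 = glorot(layer1_dim, d2), b2 = numeric(d2),
                     W3 = glorot(d2, shared_dim), b3 = numeric(shared_dim))
  }
  gcn <- list()
  din <- shared_dim
  for (l in seq_len(spec$n_layers)) {
    dout <- if (l == spec$n_layers) spec$n_classes else spec$hidden_dim
    gcn[[l]] <- list(Theta = glorot(din, dout), bias = numeric(dout))
    din <- dout
  }
  list(enc = enc, gcn = gcn)
}

# Recursively combine two parameter-shaped nested lists.
pmap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- pmap2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}
pmap1 <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- pmap1(a[[nm]], f)
    out
  } else f(a)
}

#' Symmetric normalisation of an adjacency matrix with self-loops
#'
#' Computes `D^(-1/2) (W + I) D^(-1/2)` with `D` the degree matrix of
#' `W + I`, the propagation operator of the graph convolution.
#'
#' @param W Square nonnegative adjacency matrix.
#' @return Normalised matrix of the same shape.
#' @export
normalize_adjacency <- function(W) {
  if (any(!is.finite(W))) stop("adjacency contains non-finite values")
  A <- W + diag(nrow(W))
  d <- rowSums(A)
  inv <- 1 / sqrt(d)
  An <- A * outer(inv, inv)
  dimnames(An) <- dimnames(W)
  An
}

#' Encode one modality with a two-layer encoder
#'
#' Two affine layers with a ReLU after the first; rows are emitted only for
#' participants present in the modality.
#'
#' @param X Present-participants-by-features matrix.
#' @param enc Encoder parameter list (`W1`, `b1`, `W2`, `b2`).
#' @return Present-participants-by-layer2 matrix.
#' @export
encode_modality <- function(X, enc) {
  if (ncol(X) != nrow(enc$W1)) stop("feature dimension mismatch with encoder")
  H1 <- pmax(sweep(X %*% enc$W1, 2, enc$b1, "+"), 0)
  sweep(H1 %*% enc$W2, 2, enc$b2, "+")
}

#' Median imputation of missing-modality participants
#'
#' Every network node absent from the modality receives the per-dimension
#' median of the present nodes' second-layer values; present rows are
#' unchanged.
#'
#' @param layer2 Present-participants-by-dims matrix (rownames = IDs).
#' @param network_ids All node IDs of the network, in node order.
#' @return Full nodes-by-dims matrix aligned to `network_ids`.
#' @export
median_impute <- function(layer2, network_ids) {
  present <- rownames(layer2)
  if (is.null(present) || length(present) == 0) {
    stop("no present participants to impute from")
  }
  med <- apply(layer2, 2, stats::median)
  out <- matrix(med, length(network_ids), ncol(layer2), byrow = TRUE,
                dimnames = list(network_ids, colnames(layer2)))
  keep <- intersect(network_ids, present)
  out[keep, ] <- layer2[keep, , drop = FALSE]
  out
}

#' Mean-pool per-modality latents into shared node features
#'
#' Each modality's (imputed) second-layer matrix is linearly decompressed to
#' the shared dimension (when projection parameters are given) and the
#' element-wise mean over modalities is returned.
#'
#' @param latents Named list of nodes-by-dims matrices, row-aligned.
#' @param proj Optional named list of projections (`W3`, `b3`) per modality;
#'   if `NULL` the matrices are averaged as-is (dims must agree).
#' @return Nodes-by-shared-dim matrix.
#' @export
pool_shared <- function(latents, proj = NULL) {
  if (length(latents) == 0) stop("no modalities to pool")
  dec <- lapply(names(latents), function(m) {
    H <- latents[[m]]
    if (!is.null(proj)) H <- sweep(H %*% proj[[m]]$W3, 2, proj[[m]]$b3, "+")
    H
  })
  Reduce(`+`, dec) / length(dec)
}

#' Graph convolution forward pass
#'
#' Stacks `length(layers)` graph convolutions
#' `H <- act(A_norm %*% H %*% Theta + bias)` with ReLU between layers and no
#' activation after the last; `A_norm` is the symmetric-normalised adjacency
#' with self-loops.
#'
#' @param W Adjacency matrix (normalised internally unless
#'   `normalized = TRUE`).
#' @param H Node feature matrix.
#' @param layers List of `list(Theta, bias)` per layer.
#' @param normalized Set TRUE if `W` is already the propagation operator.
#' @return Nodes-by-output-dim logits.
#' @export
gcn_forward <- function(W, H, layers, normalized = FALSE) {
  if (nrow(W) != nrow(H)) stop("adjacency and features are misaligned")
  A <- if (normalized) W else normalize_adjacency(W)
  out <- H
  for (l in seq_along(layers)) {
    out <- sweep(A %*% out %*% layers[[l]]$Theta, 2, layers[[l]]$bias, "+")
    if (l < length(layers)) out <- pmax(out, 0)
  }
  out
}

# Full forward pass with caches for backprop.
mme_forward <- function(params, A_norm, X_list, node_ids, dropout = 0,
                        training = FALSE) {
  M <- length(X_list)
  cache <- list(mod = list())
  U_sum <- NULL
  for (m in names(X_list)) {
    enc <- params$enc[[m]]
    Xp <- X_list[[m]]
    Z1 <- sweep(Xp %*% enc$W1, 2, enc$b1, "+")
    H1 <- pmax(Z1, 0)
    H2p <- sweep(H1 %*% enc$W2, 2, enc$b2, "+")
    H2 <- median_impute(H2p, node_ids)
    U <- sweep(H2 %*% enc$W3, 2, enc$b3, "+")
    cache$mod[[m]] <- list(Xp = Xp, Z1 = Z1, H1 = H1, H2p = H2p, H2 = H2)
    U_sum <- if (is.null(U_sum)) U else U_sum + U
  }
  H <- U_sum / M
  cache$H <- H
  acts <- list(); pre <- list(); masks <- list()
  out <- H
  L <- length(params$gcn)
  for (l in seq_len(L)) {
    AX <- A_norm %*% out
    acts[[l]] <- list(input = out, AX = AX)
    Z <- sweep(AX %*% params$gcn[[l]]$Theta, 2, params$gcn[[l]]$bias, "+")
    pre[[l]] <- Z
    if (l < L) {
      out <- pmax(Z, 0)
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(out)) >= dropout, nrow(out))
        out <- out * mask / (1 - dropout)
        masks[[l]] <- mask
      }
    } else {
      out <- Z
    }
  }
  cache$acts <- acts; cache$pre <- pre; cache$masks <- masks
  cache$dropout <- dropout; cache$training <- training
  list(logits = out, cache = cache)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Weighted cross-entropy on a node index subset; returns loss and dlogits.
masked_ce <- function(logits, y_idx, mask_idx, class_weights) {
  P <- softmax_rows(logits[mask_idx, , drop = FALSE])
  w <- class_weights[y_idx[mask_idx]]
  picked <- P[cbind(seq_along(mask_idx), y_idx[mask_idx])]
  loss <- sum(w * -log(pmax(picked, 1e-12))) / sum(w)
  dZ <- P
  dZ[cbind(seq_along(mask_idx), y_idx[mask_idx])] <-
    dZ[cbind(seq_along(mask_idx), y_idx[mask_idx])] - 1
  dZ <- dZ * (w / sum(w))
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[mask_idx, ] <- dZ
  list(loss = loss, dlogits = dlogits)
}

# Backward pass mirroring mme_forward. Gradient through median imputation is
# routed to the row(s) attaining each per-dimension median (split evenly for
# an even count).
mme_backward <- function(params, cache, A_norm, node_ids, dlogits) {
  L <- length(params$gcn)
  grads <- list(enc = list(), gcn = vector("list", L))
  dout <- dlogits
  for (l in rev(seq_len(L))) {
    if (l < L) {
      if (cache$training && cache$dropout > 0 &&
          length(cache$masks) >= l && !is.null(cache$masks[[l]])) {
        dout <- dout * cache$masks[[l]] / (1 - cache$dropout)
      }
      dout <- dout * (cache$pre[[l]] > 0)
    }
    AX <- cache$acts[[l]]$AX
    grads$gcn[[l]] <- list(Theta = crossprod(AX, dout),
                           bias = colSums(dout))
    dAX <- dout %*% t(params$gcn[[l]]$Theta)
    dout <- A_norm %*% dAX  # A_norm symmetric
  }
  dH <- dout
  M <- length(cache$mod)
  for (m in names(cache$mod)) {
    cc <- cache$mod[[m]]
    enc <- params$enc[[m]]
    dU <- dH / M
    gW3 <- crossprod(cc$H2, dU)
    gb3 <- colSums(dU)
    dH2 <- dU %*% t(enc$W3)
    present <- rownames(cc$H2p)
    pres_idx <- match(present, node_ids)
    abs_idx <- setdiff(seq_along(node_ids), pres_idx)
    dH2p <- dH2[pres_idx, , drop = FALSE]
    if (length(abs_idx) > 0) {
      gmed <- colSums(dH2[abs_idx, , drop = FALSE])
      np <- nrow(cc$H2p)
      for (j in seq_len(ncol(cc$H2p))) {
        if (gmed[j] == 0) next
        ord <- order(cc$H2p[, j])
        if (np %% 2 == 1) {
          dH2p[ord[(np + 1) / 2], j] <- dH2p[ord[(np + 1) / 2], j] + gmed[j]
        } else {
          mid <- c(ord[np / 2], ord[np / 2 + 1])
          dH2p[mid, j] <- dH2p[mid, j] + gmed[j] / 2
        }
      }
    }
    gW2 <- crossprod(cc$H1, dH2p)
    gb2 <- colSums(dH2p)
    dH1 <- dH2p %*% t(enc$W2)
    dZ1 <- dH1 * (cc$Z1 > 0)
    gW1 <- crossprod(cc$Xp, dZ1)
    gb1 <- colSums(dZ1)
    grads$enc[[m]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                           W3 = gW3, b3 = gb3)
  }
  grads
}

adam_update <- function(params, grads, state, lr, t, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, m, v) {
    if (is.matrix(p) && wd > 0) g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      pm <- p; sm <- m; sv <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        pm[[i]] <- r$p; sm[[i]] <- r$m; sv[[i]] <- r$v
      }
      list(p = pm, m = sm, v = sv)
    } else step(p, g, m, v)
  }
  walk(params, grads, state$m, state$v)
}

#' Train the GCN-MME on a fused patient similarity network
#'
#' Semi-supervised transductive training: all nodes are in the graph,
#' cross-entropy is computed on the training mask, early stopping monitors
#' validation loss, and the loss is back-propagated through the GCN into
#' every modality encoder.
#'
#' @param A Weighted adjacency of the fused network (rownames = node IDs).
#' @param X_list Named list of present-participants-by-selected-features
#'   matrices, one per modality (rownames identify present participants).
#' @param labels Named class vector covering the labelled nodes.
#' @param masks List with `train`, `val`, `test` ID vectors (disjoint).
#' @param layer1_dim Fixed first-layer width shared by all encoders.
#' @param layer2_dims Named per-modality second-layer widths (scalar is
#'   recycled).
#' @param shared_dim Shared latent dimension = GCN input width.
#' @param spec A [gcn_spec()].
#' @param cfg A [train_config()].
#' @return A `gcn_mme_model` with parameters, history and metadata.
#' @export
fit_gcn_mme <- function(A, X_list, labels, masks,
                        layer1_dim = 128L, layer2_dims = 32L,
                        shared_dim = 64L, spec = gcn_spec(),
                        cfg = train_config()) {
  node_ids <- rownames(A)
  if (is.null(node_ids)) stop("adjacency must carry node IDs as rownames")
  if (length(masks$train) == 0) stop("empty training mask")
  class_order <- sort(unique(as.character(labels)))
  spec$n_classes <- length(class_order)
  y_idx <- match(as.character(labels[node_ids]), class_order)
  train_idx <- match(masks$train, node_ids)
  val_idx <- match(masks$val, node_ids)
  if (any(is.na(train_idx))) stop("training mask contains unknown IDs")
  if (!all(class_order %in% labels[masks$train])) {
    stop("a class is absent from the training mask")
  }

  input_dims <- lapply(X_list, ncol)
  if (length(layer2_dims) == 1 && is.null(names(layer2_dims))) {
    layer2_dims <- stats::setNames(rep(as.integer(layer2_dims),
                                       length(X_list)), names(X_list))
  }
  layer2_dims <- as.list(layer2_dims)

  set.seed(cfg$seed)
  params <- init_params(input_dims, layer1_dim, layer2_dims, shared_dim, spec)
  state <- list(m = pmap1(params, function(x) x * 0),
                v = pmap1(params, function(x) x * 0))

  cw <- rep(1, length(class_order))
  if (cfg$class_weighting) {
    tab <- table(factor(labels[masks$train], levels = class_order))
    cw <- as.numeric(sum(tab) / (length(class_order) * pmax(tab, 1)))
  }

  A_norm <- normalize_adjacency(A)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  best_val <- Inf; best_params <- params; wait <- 0
  for (epoch in seq_len(cfg$epochs)) {
    fw <- mme_forward(params, A_norm, X_list, node_ids,
                      dropout = spec$dropout, training = TRUE)
    ce <- masked_ce(fw$logits, y_idx, train_idx, cw)
    grads <- mme_backward(params, fw$cache, A_norm, node_ids, ce$dlogits)
    upd <- adam_update(params, grads, state, cfg$learning_rate, epoch,
                       cfg$weight_decay)
    params <- upd$p; state$m <- upd$m; state$v <- upd$v

    val_loss <- NA_real_; val_acc <- NA_real_
    if (length(val_idx) > 0) {
      ev <- mme_forward(params, A_norm, X_list, node_ids, training = FALSE)
      vce <- masked_ce(ev$logits, y_idx, val_idx, cw)
      val_loss <- vce$loss
      val_acc <- mean(apply(ev$logits[val_idx, , drop = FALSE], 1,
                            which.max) == y_idx[val_idx])
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_params <- params; wait <- 0
      } else {
        wait <- wait + 1
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ce$loss,
                                         val_loss = val_loss,
                                         val_acc = val_acc))
    if (length(val_idx) > 0 && wait >= cfg$patience) break
  }
  if (length(val_idx) > 0) params <- best_params
  structure(list(params = params, node_ids = node_ids,
                 class_order = class_order, spec = spec, cfg = cfg,
                 layer1_dim = layer1_dim, layer2_dims = layer2_dims,
                 shared_dim = shared_dim, input_dims = input_dims,
                 feature_names = lapply(X_list, colnames),
                 history = history),
            class = "gcn_mme_model")
}

#' Predict classes for all nodes of a (possibly rebuilt) network
#'
#' @param object A `gcn_mme_model`.
#' @param A Weighted adjacency (rownames = node IDs). May differ from the
#'   training network, e.g. a network rebuilt at another time point.
#' @param X_list Named list of per-modality feature matrices whose columns
#'   match the encoders' input features.
#' @param ... Unused.
#' @return List with `logits` (nodes x classes) and `classes` (named
#'   character vector of predicted labels).
#' @export
predict.gcn_mme_model <- function(object, A, X_list, ...) {
  node_ids <- rownames(A)
  A_norm <- normalize_adjacency(A)
  fw <- mme_forward(object$params, A_norm, X_list, node_ids,
                    training = FALSE)
  cls <- object$class_order[apply(fw$logits, 1, which.max)]
  list(logits = fw$logits,
       classes = stats::setNames(cls, node_ids))
}

#' Tune per-modality second-layer dimensions
#'
#' Coordinate hyperparameter search: for each modality in turn, every
#' candidate width is evaluated (others held at the current best) by mean
#' validation weighted F1 over the supplied splits, and the best is kept.
#'
#' @param A Weighted adjacency of the fused network.
#' @param X_list Named list of per-modality feature matrices.
#' @param labels Named class vector.
#' @param splits List of split assignments (each with `train`, `val`,
#'   `test`).
#' @param grid Named list of candidate widths per modality (a single
#'   unnamed vector is used for all).
#' @param cfg A [train_config()].
#' @param ... Passed to [fit_gcn_mme()].
#' @return List with `dims` (named chosen widths) and `trace` (search log).
#' @export
tune_layer2 <- function(A, X_list, labels, splits, grid, cfg = train_config(),
                        ...) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) stop("empty grid")
  if (is.null(names(grid))) {
    grid <- stats::setNames(rep(list(unlist(grid)), length(X_list)),
                            names(X_list))
  }
  current <- vapply(grid, function(g) g[1], numeric(1))
  trace <- data.frame()
  for (m in names(X_list)) {
    scores <- numeric(length(grid[[m]]))
    for (gi in seq_along(grid[[m]])) {
      dims <- current; dims[m] <- grid[[m]][gi]
      f1s <- vapply(splits, function(sp) {
        model <- fit_gcn_mme(A, X_list, labels, sp,
                             layer2_dims = as.list(dims), cfg = cfg, ...)
        pred <- predict(model, A, X_list)
        rep <- compute_metrics(labels[sp$val], pred$classes[sp$val],
                               model$class_order)
        rep$weighted_f1
      }, numeric(1))
      scores[gi] <- mean(f1s)
      trace <- rbind(trace, data.frame(modality = m, dim = grid[[m]][gi],
                                       mean_val_f1 = scores[gi]))
    }
    current[m] <- grid[[m]][which.max(scores)]
  }
  list(dims = current, trace = trace)
}
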