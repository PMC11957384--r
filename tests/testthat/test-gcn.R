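# Shared fixture: a small fused network + two modalities, one with
# missing participants.
gcn_fixture <- function(seed = 1, n = 24, effect = 2) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  labels <- setNames(rep_len(c("PD", "PL", "HC"), n), ids)
  cls <- match(labels, c("HC", "PL", "PD")) - 1
  X1 <- matrix(rnorm(n * 10), n, 10, dimnames = list(ids, paste0("a", 1:10)))
  X1[, 1:4] <- X1[, 1:4] + effect * cls
  present <- ids[seq_len(n - 4)]
  X2 <- matrix(rnorm(length(present) * 6), length(present), 6,
               dimnames = list(present, paste0("b", 1:6)))
  fused <- build_psn(list(m1 = X1, m2 = X2), graph_params(k = 5, snf_t = 5))
  A <- fused_adjacency(fused, 5)
  list(ids = ids, labels = labels, X_list = list(m1 = X1, m2 = X2), A = A)
}

test_that("encoder emits rows only for present participants with the right shape", {
  set.seed(2)
  for (dims in list(c(8, 6, 3), c(5, 10, 2), c(3, 4, 4))) {
    p <- dims[1]; d1 <- dims[2]; d2 <- dims[3]
    enc <- list(W1 = matrix(rnorm(p * d1), p, d1), b1 = rnorm(d1),
                W2 = matrix(rnorm(d1 * d2), d1, d2), b2 = rnorm(d2))
    X <- matrix(rnorm(7 * p), 7, p, dimnames = list(sprintf("P%d", 1:7), NULL))
    H2 <- encode_modality(X, enc)
    expect_equal(dim(H2), c(7, d2))
    expect_equal(rownames(H2), rownames(X))
  }
  # identity-parameterised degenerate path: output reproduces the input
  enc_id <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  X <- matrix(abs(rnorm(10)), 5, 2, dimnames = list(sprintf("P%d", 1:5), NULL))
  expect_equal(unname(encode_modality(X, enc_id)), unname(X))
  expect_error(encode_modality(X, list(W1 = diag(3), b1 = rep(0, 3),
                                       W2 = diag(3), b2 = rep(0, 3))),
               "dimension mismatch")
})

test_that("median imputation fills absent nodes with per-dimension medians", {
  L <- matrix(c(0, 2, 2, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("d1", "d2")))
  out <- median_impute(L, c("P1", "P2", "P3"))
  expect_equal(unname(out["P3", ]), c(1, 3))
  expect_equal(out[c("P1", "P2"), ], L)

  # all present: identity
  expect_equal(median_impute(L, c("P1", "P2")), L)

  # 5 present rows vs the sort-based oracle
  set.seed(3)
  L5 <- matrix(rnorm(5 * 7), 5, 7, dimnames = list(paste0("P", 1:5), NULL))
  out5 <- median_impute(L5, c(paste0("P", 1:5), "Q1", "Q2"))
  expect_equal(unname(out5["Q1", ]), oracle_median_rows(L5))
  expect_error(median_impute(L5[0, , drop = FALSE], "P1"), "no present")
})

test_that("mean pooling averages decompressed modalities", {
  set.seed(4)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  C <- matrix(rnorm(12), 4, 3)
  expect_equal(pool_shared(list(m = A)), A)
  expect_equal(pool_shared(list(a = A, b = A)), A)
  expect_equal(pool_shared(list(a = A, b = B, c = C)), (A + B + C) / 3)
  proj <- list(a = list(W3 = diag(3), b3 = c(1, 1, 1)))
  expect_equal(pool_shared(list(a = A), proj), A + 1)
  expect_error(pool_shared(list()), "no modalities")
})

test_that("graph convolution matches hand propagation and its degenerate limits", {
  # 4-node path graph, hand-set weights, one layer: manual computation
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- W[3, 4] <- W[4, 3] <- 1
  H <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 4, 2)
  Theta <- matrix(c(1, -1, 0.5, 2), 2, 2)
  bias <- c(0.1, -0.2)
  A_hat <- W + diag(4)
  d <- rowSums(A_hat)
  An <- diag(1 / sqrt(d)) %*% A_hat %*% diag(1 / sqrt(d))
  manual <- An %*% H %*% Theta + matrix(bias, 4, 2, byrow = TRUE)
  got <- gcn_forward(W, H, list(list(Theta = Theta, bias = bias)))
  expect_equal(unname(got), unname(manual), tolerance = 1e-12)

  # identity adjacency (self-loops only): reduces to a per-node MLP —
  # changing one node's features changes only that node's logits
  layers <- list(list(Theta = matrix(rnorm(4), 2, 2), bias = rnorm(2)),
                 list(Theta = matrix(rnorm(6), 2, 3), bias = rnorm(3)))
  W0 <- matrix(0, 4, 4)
  base <- gcn_forward(W0, H, layers)
  H2 <- H; H2[2, ] <- H2[2, ] + 5
  pert <- gcn_forward(W0, H2, layers)
  expect_equal(base[-2, ], pert[-2, ])
  expect_false(isTRUE(all.equal(base[2, ], pert[2, ])))

  # two connected nodes with identical features get identical logits
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  Hs <- rbind(c(1, 2), c(1, 2))
  out2 <- gcn_forward(W2, Hs, layers)
  expect_equal(out2[1, ], out2[2, ])

  expect_error(gcn_forward(W2, H, layers), "misaligned")
  expect_error(normalize_adjacency(matrix(c(0, NA, NA, 0), 2, 2)),
               "non-finite")
})

test_that("analytic gradients match finite differences through the whole model", {
  set.seed(5)
  n <- 7
  ids <- sprintf("P%d", 1:n)
  X1 <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("a", 1:4)))
  X2 <- matrix(rnorm((n - 2) * 3), n - 2, 3,
               dimnames = list(ids[1:(n - 2)], paste0("b", 1:3)))
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
  dimnames(W) <- list(ids, ids)
  labels <- setNames(rep_len(c("A", "B", "C"), n), ids)
  ns <- asNamespace("psnstrat")
  spec <- gcn_spec(n_layers = 2, hidden_dim = 5, dropout = 0, n_classes = 3)
  params <- ns$init_params(list(m1 = 4L, m2 = 3L), 6L,
                           list(m1 = 3L, m2 = 2L), 4L, spec)
  An <- normalize_adjacency(W)
  y <- match(labels, c("A", "B", "C"))
  tr <- 1:5
  cw <- c(1.2, 0.9, 1.1)
  X_list <- list(m1 = X1, m2 = X2)
  loss_of <- function(p) {
    fw <- ns$mme_forward(p, An, X_list, ids, training = FALSE)
    ns$masked_ce(fw$logits, y, tr, cw)$loss
  }
  fw <- ns$mme_forward(params, An, X_list, ids, training = TRUE, dropout = 0)
  ce <- ns$masked_ce(fw$logits, y, tr, cw)
  gr <- ns$mme_backward(params, fw$cache, An, ids, ce$dlogits)
  eps <- 1e-6
  assign_in <- function(lst, path, v) {
    if (length(path) == 0) return(v)
    lst[[path[1]]] <- assign_in(lst[[path[1]]], path[-1], v)
    lst
  }
  check <- function(path) {
    p <- params; g <- gr
    for (k in path) { p <- p[[k]]; g <- g[[k]] }
    for (i in sample(length(p), min(3, length(p)))) {
      val <- p; val[i] <- val[i] + eps
      num <- (loss_of(assign_in(params, path, val)) - ce$loss) / eps
      expect_equal(num, g[i], tolerance = 1e-3)
    }
  }
  for (m in c("m1", "m2")) {
    for (w in c("W1", "b1", "W2", "b2", "W3", "b3")) check(c("enc", m, w))
  }
  for (l in 1:2) for (w in c("Theta", "bias")) check(c("gcn", l, w))
})

test_that("training is deterministic, reaches separable signal and updates every encoder", {
  fx <- gcn_fixture(seed = 6, effect = 2.5)
  masks <- list(train = fx$ids[1:16], val = fx$ids[17:20],
                test = fx$ids[21:24])
  cfg <- train_config(epochs = 150, patience = 40, seed = 11)
  m1 <- fit_gcn_mme(fx$A, fx$X_list, fx$labels, masks, layer1_dim = 16,
                    layer2_dims = 8, shared_dim = 8, cfg = cfg)
  m2 <- fit_gcn_mme(fx$A, fx$X_list, fx$labels, masks, layer1_dim = 16,
                    layer2_dims = 8, shared_dim = 8, cfg = cfg)
  expect_identical(m1$history, m2$history)   # same seed, same trajectory
  expect_identical(m1$params, m2$params)

  # gradient flow: every encoder's parameters moved away from init
  ns <- asNamespace("psnstrat")
  set.seed(cfg$seed)
  init <- ns$init_params(lapply(fx$X_list, ncol), 16,
                         list(m1 = 8, m2 = 8), 8, m1$spec)
  for (m in c("m1", "m2")) {
    expect_gt(max(abs(m1$params$enc[[m]]$W1 - init$enc[[m]]$W1)), 1e-6)
  }

  # strongly separable planted signal: high train accuracy
  pred <- predict(m1, fx$A, fx$X_list)
  expect_gte(mean(pred$classes[masks$train] == fx$labels[masks$train]), 0.95)
  # every network node gets a prediction (retention through imputation)
  expect_equal(sort(names(pred$classes)), sort(rownames(fx$A)))

  expect_error(fit_gcn_mme(fx$A, fx$X_list, fx$labels,
                           list(train = character(0)), cfg = cfg),
               "empty training mask")
  bad <- masks; bad$train <- fx$ids[fx$labels[fx$ids] != "PD"][1:8]
  expect_error(fit_gcn_mme(fx$A, fx$X_list, fx$labels, bad, cfg = cfg),
               "absent from the training mask")
})

test_that("shuffled labels yield chance-level validation accuracy", {
  fx <- gcn_fixture(seed = 7, n = 30, effect = 2.5)
  set.seed(99)
  shuffled <- setNames(sample(fx$labels), names(fx$labels))
  masks <- list(train = fx$ids[1:20], val = fx$ids[21:30], test = character(0))
  m <- fit_gcn_mme(fx$A, fx$X_list, shuffled, masks, layer1_dim = 16,
                   layer2_dims = 8, shared_dim = 8,
                   cfg = train_config(epochs = 120, patience = 30, seed = 12))
  pred <- predict(m, fx$A, fx$X_list)
  val_acc <- mean(pred$classes[masks$val] == shuffled[masks$val])
  expect_lte(val_acc, 0.75)  # near the majority rate, far below the signal run
})

test_that("removing a participant from one modality leaves other rows bitwise unchanged", {
  fx <- gcn_fixture(seed = 8)
  enc <- list(W1 = matrix(rnorm(60), 10, 6), b1 = rnorm(6),
              W2 = matrix(rnorm(24), 6, 4), b2 = rnorm(4))
  full <- encode_modality(fx$X_list$m1, enc)
  dropped <- encode_modality(fx$X_list$m1[-3, ], enc)
  expect_identical(full[rownames(dropped), ], dropped)
})

test_that("layer-2 tuning selects from the grid reproducibly", {
  fx <- gcn_fixture(seed = 9)
  splits <- list(list(train = fx$ids[1:14], val = fx$ids[15:20],
                      test = fx$ids[21:24]))
  cfg <- train_config(epochs = 40, patience = 15, seed = 3)
  one <- tune_layer2(fx$A, fx$X_list, fx$labels, splits,
                     grid = list(m1 = 6, m2 = 6), cfg = cfg,
                     layer1_dim = 12, shared_dim = 8)
  expect_equal(unname(one$dims), c(6, 6))  # single candidate: selected

  g <- list(m1 = c(4, 8), m2 = c(4, 8))
  t1 <- tune_layer2(fx$A, fx$X_list, fx$labels, splits, grid = g, cfg = cfg,
                    layer1_dim = 12, shared_dim = 8)
  t2 <- tune_layer2(fx$A, fx$X_list, fx$labels, splits, grid = g, cfg = cfg,
                    layer1_dim = 12, shared_dim = 8)
  expect_identical(t1$dims, t2$dims)
  expect_identical(t1$trace, t2$trace)
  expect_error(tune_layer2(fx$A, fx$X_list, fx$labels, splits,
                           grid = list(), cfg = cfg), "empty grid")
})
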