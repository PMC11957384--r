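#' @title Longitudinal cross-time-point transfer experiments
#' @description Train the full pipeline at one time point on a fixed
#'   participant subset and test it at every other time point, rebuilding
#'   the network and node features from test-time data with test-time
#'   feature selection. Produces the train-time x test-time transfer
#'   matrix, within-class accuracy with misclassification flows, and
#'   per-participant prediction-consistency profiles.
#' @name longitudinal
NULL

#' Fix the longitudinal cohort and its train/test partition
#'
#' Restricts to participants present at every time point in at least one of
#' the included modalities and draws a single stratified train/test split
#' that is reused at every time point, so all transfer-matrix cells are
#' evaluated on the same test set.
#'
#' @param bundle A `cohort_bundle`.
#' @param modalities Modalities defining presence.
#' @param test_frac Test fraction (default 0.2).
#' @param seed RNG seed for the split.
#' @return A `longitudinal_cohort`: list with `ids`, `labels`,
#'   `train_ids`, `test_ids`, `modalities`.
#' @export
subset_longitudinal <- function(bundle, modalities, test_frac = 0.2,
                                seed = 1L) {
  tp <- length(bundle$matrices[[modalities[1]]])
  qualifying <- NULL
  for (t in seq_len(tp) - 1L) {
    mats <- timepoint_matrices(bundle, t, modalities)
    present_t <- sort(unique(unlist(lapply(mats, rownames))))
    qualifying <- if (is.null(qualifying)) present_t else {
      intersect(qualifying, present_t)
    }
  }
  labels <- cohort_labels(bundle)[qualifying]
  if (any(table(labels) < 2)) stop("a class is empty (or singleton) after subsetting")
  set.seed(seed)
  test_ids <- character(0)
  for (cl in sort(unique(labels))) {
    members <- sample(qualifying[labels == cl])
    n_test <- max(1L, round(test_frac * length(members)))
    test_ids <- c(test_ids, members[seq_len(n_test)])
  }
  structure(list(ids = qualifying, labels = labels,
                 train_ids = setdiff(qualifying, test_ids),
                 test_ids = test_ids, modalities = modalities,
                 n_timepoints = tp),
            class = "longitudinal_cohort")
}

# Selection + selected matrices + network for the cohort at one time point.
longitudinal_stage <- function(bundle, cohort, t, gparams, policy, families,
                               selection_cache = NULL, seed = 1L) {
  mats <- timepoint_matrices(bundle, t, cohort$modalities)
  mats <- lapply(mats, function(X) {
    X[intersect(rownames(X), cohort$ids), , drop = FALSE]
  })
  mats <- mats[vapply(mats, nrow, integer(1)) >= 2]
  labels <- cohort$labels
  prepped <- prepare_modalities(mats, labels, gparams, policy,
                                families = families, seed = seed,
                                selection_cache = selection_cache)
  net <- combo_network(prepped, names(prepped), gparams)
  list(prepped = prepped, net = net, labels = labels[net$ids])
}

#' Train the full pipeline at one time point of the longitudinal cohort
#'
#' Feature selection, network construction and GCN-MME training at time
#' `t`, using the cohort's fixed training IDs (further split 85/15 into
#' train/validation, stratified) and its fixed test IDs.
#'
#' @param bundle A `cohort_bundle`.
#' @param cohort A `longitudinal_cohort`.
#' @param t Training time point (0-based).
#' @param gparams,spec,cfg,layer1_dim,layer2_dims,shared_dim Model settings.
#' @param policy Feature-selection policy.
#' @param families Optional modality-family map.
#' @param selection_cache Optional precomputed selections (e.g. genotype
#'   loadings fit once at baseline).
#' @param seed Seed for selection and the inner train/val split.
#' @param stage Optional precomputed stage (selection + network) for `t`.
#' @return A `longitudinal_model` wrapping the fitted model, its stage data
#'   and its own-time-point metrics.
#' @export
train_at <- function(bundle, cohort, t, gparams = graph_params(),
                     spec = gcn_spec(), cfg = train_config(),
                     layer1_dim = 64L, layer2_dims = 16L, shared_dim = 32L,
                     policy = default_selection_policy(), families = NULL,
                     selection_cache = NULL, seed = 1L, stage = NULL) {
  if (t < 0 || t >= cohort$n_timepoints) stop("invalid time point: ", t)
  if (is.null(families)) families <- bundle_families(bundle)
  if (is.null(stage)) {
    stage <- longitudinal_stage(bundle, cohort, t, gparams, policy, families,
                                selection_cache, seed)
  }
  set.seed(seed + 7L)
  train_pool <- intersect(cohort$train_ids, stage$net$ids)
  val <- character(0)
  pool_labels <- cohort$labels[train_pool]
  for (cl in sort(unique(pool_labels))) {
    members <- sample(train_pool[pool_labels == cl])
    n_val <- max(1L, round(0.15 * length(members)))
    val <- c(val, members[seq_len(n_val)])
  }
  masks <- list(train = setdiff(train_pool, val), val = val,
                test = intersect(cohort$test_ids, stage$net$ids))
  X_list <- lapply(stage$prepped, `[[`, "X")
  model <- fit_gcn_mme(stage$net$A, X_list, stage$labels, masks,
                       layer1_dim = layer1_dim, layer2_dims = layer2_dims,
                       shared_dim = shared_dim, spec = spec, cfg = cfg)
  pred <- predict(model, stage$net$A, X_list)
  own <- compute_metrics(stage$labels[masks$test], pred$classes[masks$test],
                         model$class_order)
  structure(list(model = model, stage = stage, masks = masks, t = t,
                 own_metrics = own, own_pred = pred$classes[masks$test],
                 cohort = cohort, gparams = gparams, policy = policy,
                 families = families, selection_cache = selection_cache,
                 seed = seed),
            class = "longitudinal_model")
}

# Reconcile a trained encoder with a different test-time feature set.
# "intersect": restrict first-layer weights to the shared features.
# "lsq": refit the first affine layer by least squares so the full
# test-time feature set reproduces the shared-feature pre-activations.
reconcile_encoder <- function(enc, train_features, X_test,
                              strategy = c("intersect", "lsq")) {
  strategy <- match.arg(strategy)
  test_features <- colnames(X_test)
  shared <- intersect(train_features, test_features)
  if (length(shared) == 0) stop("no shared features between time points")
  W1s <- enc$W1[match(shared, train_features), , drop = FALSE]
  if (strategy == "intersect") {
    enc$W1 <- W1s
    return(list(enc = enc, X = X_test[, shared, drop = FALSE]))
  }
  Z_target <- X_test[, shared, drop = FALSE] %*% W1s
  fit <- stats::lm.fit(cbind(1, X_test), Z_target)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  enc$b1 <- enc$b1 + cf[1, ]
  enc$W1 <- cf[-1, , drop = FALSE]
  list(enc = enc, X = X_test)
}

#' Test a time-t model at another time point
#'
#' Rebuilds the network and node features from time-`t_prime` data using
#' the features selected at `t_prime`, reconciles each encoder's input
#' layer with the test-time feature set, applies the frozen model, and
#' reports metrics on the cohort's fixed test IDs.
#'
#' @param lmodel A `longitudinal_model` from [train_at()].
#' @param bundle The `cohort_bundle`.
#' @param t_prime Test time point (0-based).
#' @param strategy Feature reconciliation: `"intersect"` (default) or
#'   `"lsq"`.
#' @param stage Optional precomputed stage for `t_prime`.
#' @return List with `metrics` (a `metrics_report` on the fixed test set),
#'   `pred` (named predictions for the test IDs) and `t_prime`.
#' @export
test_at <- function(lmodel, bundle, t_prime,
                    strategy = c("intersect", "lsq"), stage = NULL) {
  strategy <- match.arg(strategy)
  cohort <- lmodel$cohort
  if (t_prime < 0 || t_prime >= cohort$n_timepoints) {
    stop("invalid time point: ", t_prime)
  }
  if (is.null(stage)) {
    if (t_prime == lmodel$t) {
      stage <- lmodel$stage
    } else {
      stage <- longitudinal_stage(bundle, cohort, t_prime, lmodel$gparams,
                                  lmodel$policy, lmodel$families,
                                  lmodel$selection_cache, lmodel$seed)
    }
  }
  model <- lmodel$model
  params <- model$params
  X_list <- list()
  for (m in names(stage$prepped)) {
    rec <- reconcile_encoder(params$enc[[m]], model$feature_names[[m]],
                             stage$prepped[[m]]$X, strategy)
    params$enc[[m]] <- rec$enc
    X_list[[m]] <- rec$X
  }
  model$params <- params
  pred <- predict(model, stage$net$A, X_list)
  test_ids <- intersect(cohort$test_ids, stage$net$ids)
  metrics <- compute_metrics(cohort$labels[test_ids], pred$classes[test_ids],
                             model$class_order)
  list(metrics = metrics, pred = pred$classes[test_ids], t_prime = t_prime)
}

#' Train-time x test-time transfer matrix
#'
#' Trains one model per time point and evaluates every model at every time
#' point on the fixed test set, collecting accuracy and weighted F1 grids
#' plus the per-cell predictions.
#'
#' @param bundle A `cohort_bundle`.
#' @param cohort A `longitudinal_cohort`.
#' @param strategy Feature reconciliation passed to [test_at()].
#' @param gparams,policy,families,seed Shared stage settings (selection and
#'   network construction are computed once per time point and reused by
#'   every model).
#' @param ... Passed to [train_at()] (model dimensions, spec, cfg).
#' @return A `transfer_matrix`: list with `accuracy` and `f1` (T x T
#'   matrices, rows = training time), `preds` (nested list of predictions),
#'   `models`, `truth`.
#' @export
transfer_matrix <- function(bundle, cohort, strategy = "intersect",
                            gparams = graph_params(),
                            policy = default_selection_policy(),
                            families = NULL, seed = 1L, ...) {
  tp <- cohort$n_timepoints
  if (tp < 2) stop("transfer analysis needs at least 2 time points")
  if (is.null(families)) families <- bundle_families(bundle)
  # One stage (selection + network) per time point, shared by every model.
  # Genotype-family selections are fit once at baseline and reused, since
  # genotypes are time-invariant.
  stages <- vector("list", tp)
  sel_cache <- NULL
  for (t in seq_len(tp) - 1L) {
    stages[[t + 1]] <- longitudinal_stage(bundle, cohort, t, gparams, policy,
                                          families, sel_cache, seed)
    if (t == 0L && !is.null(families)) {
      geno <- names(families)[families == "genotype_pc"]
      geno <- intersect(geno, names(stages[[1]]$prepped))
      if (length(geno) > 0) {
        sel_cache <- lapply(stages[[1]]$prepped[geno], `[[`, "selection")
      }
    }
  }
  acc <- matrix(NA_real_, tp, tp,
                dimnames = list(train = paste0("t", seq_len(tp) - 1),
                                test = paste0("t", seq_len(tp) - 1)))
  f1 <- acc
  preds <- vector("list", tp)
  models <- vector("list", tp)
  for (t in seq_len(tp) - 1L) {
    lm_t <- train_at(bundle, cohort, t, gparams = gparams, policy = policy,
                     families = families, seed = seed,
                     stage = stages[[t + 1]], ...)
    models[[t + 1]] <- lm_t
    preds[[t + 1]] <- vector("list", tp)
    for (tq in seq_len(tp) - 1L) {
      res <- test_at(lm_t, bundle, tq, strategy = strategy,
                     stage = stages[[tq + 1]])
      acc[t + 1, tq + 1] <- res$metrics$accuracy
      f1[t + 1, tq + 1] <- res$metrics$weighted_f1
      preds[[t + 1]][[tq + 1]] <- res$pred
    }
  }
  structure(list(accuracy = acc, f1 = f1, preds = preds, models = models,
                 truth = cohort$labels[cohort$test_ids]),
            class = "transfer_matrix")
}

#' Within-class accuracy and misclassification flows over time
#'
#' For one trained model's predictions at every time point: per-class
#' recall, and counts of each misclassification direction (e.g. PD
#' predicted as PL), per time point.
#'
#' @param preds_by_time List over time points of named prediction vectors.
#' @param truth Named true-label vector covering the predicted IDs.
#' @param class_order Class levels.
#' @return List with `recall` (classes x T matrix) and `flows`
#'   (from x to x T array of counts; diagonal = correct).
#' @export
within_class_accuracy <- function(preds_by_time, truth,
                                  class_order = sort(unique(as.character(truth)))) {
  tp <- length(preds_by_time)
  K <- length(class_order)
  recall <- matrix(NA_real_, K, tp,
                   dimnames = list(class_order, paste0("t", seq_len(tp) - 1)))
  flows <- array(0L, dim = c(K, K, tp),
                 dimnames = list(from = class_order, to = class_order,
                                 time = paste0("t", seq_len(tp) - 1)))
  for (t in seq_len(tp)) {
    pred <- preds_by_time[[t]]
    ids <- names(pred)
    conf <- table(factor(as.character(truth[ids]), levels = class_order),
                  factor(as.character(pred), levels = class_order))
    flows[, , t] <- unclass(conf)
    recall[, t] <- ifelse(rowSums(conf) > 0, diag(conf) / rowSums(conf), NA)
  }
  list(recall = recall, flows = flows)
}

#' Per-participant prediction consistency across time points
#'
#' @param preds_by_time List over time points of named prediction vectors
#'   for the same fixed test IDs.
#' @param truth Named true-label vector.
#' @return Data frame (`participant_id`, `class`, `fraction_correct`)
#'   sorted by class then descending fraction.
#' @export
consistency_profile <- function(preds_by_time, truth) {
  ids <- names(preds_by_time[[1]])
  for (p in preds_by_time) {
    if (!setequal(names(p), ids)) stop("predictions cover different IDs")
  }
  correct <- sapply(preds_by_time, function(p) {
    as.character(p[ids]) == as.character(truth[ids])
  })
  frac <- rowMeans(correct)
  out <- data.frame(participant_id = ids,
                    class = as.character(truth[ids]),
                    fraction_correct = frac, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$class, -out$fraction_correct), ]
}
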