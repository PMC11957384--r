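#' @title Cross-validated evaluation and modality ablation
#' @description Stratified train/validation/test splits, accuracy and
#'   class-size-weighted F1, improvement over the majority-class baseline,
#'   a severity-score comparator model, and the brute-force modality
#'   ablation with the participant-retention tie rule.
#' @name evaluation
NULL

#' Stratified cross-validation splits (68/12/20)
#'
#' Builds `n_splits` stratified folds: each fold in turn is the 20% test
#' set, and the remaining 80% is further stratified-split into training and
#' validation so the overall proportions are 68%/12%/20%. Class proportions
#' per fold deviate from the global ones by at most one participant.
#'
#' @param labels Named class vector (names = participant IDs).
#' @param n_splits Number of folds (default 5).
#' @param val_frac Validation fraction of the non-test portion
#'   (default 0.15, i.e. 12% overall).
#' @param seed RNG seed; assignments are deterministic given it.
#' @return List of splits, each `list(split_id, train, val, test)`.
#' @export
stratified_splits <- function(labels, n_splits = 5L, val_frac = 0.15,
                              seed = 1L) {
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by participant ID")
  classes <- sort(unique(as.character(labels)))
  if (any(table(labels) < n_splits)) stop("a class has fewer members than folds")
  set.seed(seed)
  folds <- vector("list", n_splits)
  for (cl in classes) {
    members <- sample(ids[labels == cl])
    f <- rep_len(seq_len(n_splits), length(members))
    for (s in seq_len(n_splits)) {
      folds[[s]] <- c(folds[[s]], members[f == s])
    }
  }
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    test <- folds[[s]]
    rest <- setdiff(ids, test)
    target <- round(val_frac * length(rest))
    # largest-remainder allocation of validation counts across classes
    rest_by_class <- lapply(classes, function(cl) rest[labels[rest] == cl])
    raw <- vapply(rest_by_class, length, numeric(1)) * val_frac
    alloc <- floor(raw)
    remainder <- target - sum(alloc)
    if (remainder > 0) {
      extra <- order(raw - alloc, decreasing = TRUE)[seq_len(remainder)]
      alloc[extra] <- alloc[extra] + 1
    }
    val <- character(0)
    for (ci in seq_along(classes)) {
      pool <- sample(rest_by_class[[ci]])
      val <- c(val, pool[seq_len(alloc[ci])])
    }
    splits[[s]] <- list(split_id = s, train = setdiff(rest, val),
                        val = val, test = test)
  }
  splits
}

#' Classification metrics report
#'
#' Confusion matrix, accuracy, per-class precision/recall/F1 (zero
#' convention for empty denominators) and class-size-weighted F1
#' (`sum_c (n_c/N) * F1_c`, with `n_c` the true size of class c).
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same length).
#' @param class_order Class levels ordering the confusion matrix.
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(y_true, y_pred,
                            class_order = sort(unique(as.character(y_true)))) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  conf <- table(true = factor(as.character(y_true), levels = class_order),
                pred = factor(as.character(y_pred), levels = class_order))
  conf <- unclass(conf)
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wf1 <- sum(rowSums(conf) / n * f1)
  structure(list(accuracy = acc, weighted_f1 = wf1,
                 per_class_precision = prec, per_class_recall = rec,
                 per_class_f1 = f1, confusion = conf),
            class = "metrics_report")
}

#' Improvement in accuracy over the majority-class baseline
#'
#' @param accuracy Model accuracy.
#' @param labels Label vector defining the majority rate
#'   (max class count / N).
#' @return `accuracy - majority_rate`; may be negative.
#' @export
improvement_over_majority <- function(accuracy, labels) {
  if (length(labels) == 0) stop("labels must be nonempty")
  accuracy - max(table(labels)) / length(labels)
}

#' Aggregate per-split metrics into mean and SD
#' @param reports List of `metrics_report`s (one per split).
#' @param labels Optional labels to also report mean improvement.
#' @return List with `accuracy_mean/sd`, `f1_mean/sd`, `improvement_mean`.
#' @export
summarize_metrics <- function(reports, labels = NULL) {
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  f1 <- vapply(reports, `[[`, numeric(1), "weighted_f1")
  out <- list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
              f1_mean = mean(f1), f1_sd = stats::sd(f1),
              n_splits = length(reports))
  if (!is.null(labels)) {
    out$improvement_mean <- improvement_over_majority(mean(acc), labels)
  }
  out
}

# Per-modality preparation shared across ablation combinations: feature
# selection (once, on all participants present in the modality, matching the
# transductive design) and the modality's KNN affinity on its own
# participants.
prepare_modalities <- function(mats, labels, gparams = graph_params(),
                               policy = default_selection_policy(),
                               families = NULL, seed = 1L,
                               selection_cache = NULL,
                               pearson_min_features = 10L) {
  prepped <- list()
  for (m in names(mats)) {
    X <- mats[[m]]
    fam <- if (!is.null(families)) families[[m]] else NULL
    sel <- if (!is.null(selection_cache) && m %in% names(selection_cache)) {
      selection_cache[[m]]
    } else {
      select_for(m, X, labels[rownames(X)], policy = policy, family = fam,
                 seed = seed)
    }
    Xs <- apply_selection(sel, X)
    metric <- if (ncol(Xs) >= pearson_min_features) "pearson" else "euclidean_kernel"
    sim <- compute_similarity(Xs, metric, k = gparams$snf_K, mu = gparams$snf_mu)
    S <- sim$S
    if (metric == "pearson") S <- (1 + S) / 2
    A <- knn_sparsify(S, min(gparams$k, nrow(S) - 1))
    prepped[[m]] <- list(selection = sel, X = Xs, affinity = A)
  }
  prepped
}

# Fuse the prepared affinities of one modality combination.
combo_network <- function(prepped, combo, gparams = graph_params()) {
  ids <- sort(unique(unlist(lapply(prepped[combo],
                                   function(p) rownames(p$X)))))
  aff <- lapply(prepped[combo], function(p) expand_affinity(p$affinity, ids))
  fused <- snf_fuse(aff, gparams)
  list(ids = ids, fused = fused,
       A = fused_adjacency(fused, min(gparams$k, length(ids) - 1)))
}

# Train/evaluate one combination across splits; metrics on test masks only.
evaluate_combo <- function(prepped, combo, labels, splits,
                           gparams = graph_params(), spec = gcn_spec(),
                           cfg = train_config(), layer1_dim = 64L,
                           layer2_dims = 16L, shared_dim = 32L) {
  net <- combo_network(prepped, combo, gparams)
  X_list <- lapply(prepped[combo], `[[`, "X")
  node_labels <- labels[net$ids]
  reports <- list()
  for (sp in splits) {
    masks <- list(train = intersect(sp$train, net$ids),
                  val = intersect(sp$val, net$ids),
                  test = intersect(sp$test, net$ids))
    model <- fit_gcn_mme(net$A, X_list, node_labels, masks,
                         layer1_dim = layer1_dim, layer2_dims = layer2_dims,
                         shared_dim = shared_dim, spec = spec, cfg = cfg)
    pred <- predict(model, net$A, X_list)
    reports[[length(reports) + 1]] <-
      compute_metrics(node_labels[masks$test], pred$classes[masks$test],
                      model$class_order)
  }
  summ <- summarize_metrics(reports, node_labels)
  list(combo = combo, n_participants = length(net$ids), reports = reports,
       summary = summ)
}

# Tie rule: among combinations whose mean accuracy is within one pooled
# standard error of the best, report the one with most participants.
choose_best_row <- function(tab) {
  tab <- tab[order(-tab$accuracy_mean, -tab$f1_mean), ]
  best <- tab[1, ]
  se <- tab$accuracy_sd / sqrt(tab$n_splits)
  pooled <- sqrt(se^2 + se[1]^2)
  tied <- union(1L, which(best$accuracy_mean - tab$accuracy_mean < pooled))
  cand <- tab[tied, ]
  cand <- cand[order(-cand$n_participants, -cand$accuracy_mean), ]
  cand[1, ]
}

#' Brute-force modality ablation at one time point
#'
#' Trains and evaluates every nonempty modality combination with identical
#' splits (restricted to each combination's participant union). Feature
#' selection and each modality's affinity are computed once and shared
#' across combinations. Rows are ranked by mean accuracy then weighted F1;
#' among combinations within one pooled standard error of the best, the one
#' retaining the most participants is reported best.
#'
#' @param bundle A `cohort_bundle`.
#' @param timepoint Time point (0-based).
#' @param modalities Modalities to ablate (default: all in the bundle).
#' @param splits Optional precomputed splits over the full label set.
#' @param gparams,spec,cfg,layer1_dim,layer2_dims,shared_dim Model settings.
#' @param policy Feature-selection policy.
#' @param families Optional named modality-family map.
#' @param selection_cache Optional named list of precomputed
#'   `selection_result`s (e.g. time-invariant genotype loadings).
#' @param seed Seed for splits and selection.
#' @return List with `table` (one row per combination), `rows` (full
#'   results) and `best` (the selected row).
#' @export
run_ablation <- function(bundle, timepoint, modalities = NULL, splits = NULL,
                         gparams = graph_params(), spec = gcn_spec(),
                         cfg = train_config(), layer1_dim = 64L,
                         layer2_dims = 16L, shared_dim = 32L,
                         policy = default_selection_policy(),
                         families = NULL, selection_cache = NULL,
                         seed = 1L) {
  if (is.null(modalities)) modalities <- names(bundle$matrices)
  if (is.null(families)) families <- bundle_families(bundle)
  mats <- timepoint_matrices(bundle, timepoint, modalities)
  labels <- cohort_labels(bundle)
  present <- sort(unique(unlist(lapply(mats, rownames))))
  labels_t <- labels[present]
  if (is.null(splits)) {
    splits <- stratified_splits(labels_t, seed = seed)
  }
  prepped <- prepare_modalities(mats, labels, gparams, policy,
                                families = families, seed = seed,
                                selection_cache = selection_cache)
  combos <- unlist(lapply(seq_along(modalities), function(k) {
    utils::combn(modalities, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(combos, function(cmb) {
    evaluate_combo(prepped, cmb, labels, splits, gparams, spec, cfg,
                   layer1_dim, layer2_dims, shared_dim)
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(combination = paste(sort(r$combo), collapse = "+"),
               n_participants = r$n_participants,
               accuracy_mean = r$summary$accuracy_mean,
               accuracy_sd = r$summary$accuracy_sd,
               f1_mean = r$summary$f1_mean,
               f1_sd = r$summary$f1_sd,
               improvement_mean = r$summary$improvement_mean,
               n_splits = r$summary$n_splits,
               stringsAsFactors = FALSE)
  }))
  best <- choose_best_row(tab)
  list(table = tab, rows = rows, best = best, splits = splits,
       prepped = prepped)
}

#' Cross-validated evaluation of one modality combination
#'
#' Runs the full pipeline (selection, network, GCN-MME) for a single set of
#' modalities at one time point, across stratified splits.
#'
#' @inheritParams run_ablation
#' @return List with `combo`, `n_participants`, per-split `reports` and
#'   `summary` (mean/SD accuracy and weighted F1, mean improvement).
#' @export
evaluate_modalities <- function(bundle, timepoint, modalities, splits = NULL,
                                gparams = graph_params(), spec = gcn_spec(),
                                cfg = train_config(), layer1_dim = 64L,
                                layer2_dims = 16L, shared_dim = 32L,
                                policy = default_selection_policy(),
                                families = NULL, selection_cache = NULL,
                                seed = 1L) {
  if (is.null(families)) families <- bundle_families(bundle)
  mats <- timepoint_matrices(bundle, timepoint, modalities)
  labels <- cohort_labels(bundle)
  present <- sort(unique(unlist(lapply(mats, rownames))))
  if (is.null(splits)) {
    splits <- stratified_splits(labels[present], seed = seed)
  }
  prepped <- prepare_modalities(mats, labels, gparams, policy,
                                families = families, seed = seed,
                                selection_cache = selection_cache)
  evaluate_combo(prepped, modalities, labels, splits, gparams, spec, cfg,
                 layer1_dim, layer2_dims, shared_dim)
}

bundle_families <- function(bundle) {
  if (is.null(bundle$config)) return(NULL)
  specs <- bundle$config$modalities
  stats::setNames(vapply(specs, `[[`, character(1), "family"),
                  vapply(specs, `[[`, character(1), "name"))
}

#' Severity-scale comparator model
#'
#' Runs the identical pipeline (selection, single-modality network, GCN-MME)
#' on the severity-score modality alone, producing the clinician-scale
#' baseline against which the omic models are compared.
#'
#' @param bundle A `cohort_bundle`.
#' @param timepoint Time point (0-based).
#' @param severity Name of the severity modality (default "severity").
#' @param ... Passed to [run_ablation()] machinery.
#' @inheritParams run_ablation
#' @return As [evaluate_combo()]: summary metrics across splits.
#' @export
baseline_severity_model <- function(bundle, timepoint, severity = "severity",
                                    splits = NULL, gparams = graph_params(),
                                    spec = gcn_spec(), cfg = train_config(),
                                    seed = 1L, ...) {
  if (!severity %in% names(bundle$matrices)) {
    stop("severity modality '", severity, "' not present")
  }
  res <- run_ablation(bundle, timepoint, modalities = severity,
                      splits = splits, gparams = gparams, spec = spec,
                      cfg = cfg, seed = seed, ...)
  res$rows[[1]]
}

#' Select the modality combination for the longitudinal experiment
#'
#' Averages each combination's weighted F1 across all time points'
#' cross-sectional ablation tables and picks the maximiser, applying the
#' participant-retention tie rule within one pooled standard error.
#'
#' @param ablation_by_timepoint List (one per time point) of [run_ablation()]
#'   results or their `table`s.
#' @return Character vector of modality names.
#' @export
select_longitudinal_combo <- function(ablation_by_timepoint) {
  if (length(ablation_by_timepoint) == 0) stop("no time points supplied")
  tabs <- lapply(ablation_by_timepoint, function(a) {
    if (is.data.frame(a)) a else a$table
  })
  combos <- Reduce(intersect, lapply(tabs, `[[`, "combination"))
  if (length(combos) == 0) stop("no combination present at every time point")
  agg <- do.call(rbind, lapply(combos, function(cmb) {
    rows <- lapply(tabs, function(t) t[t$combination == cmb, ])
    f1 <- vapply(rows, `[[`, numeric(1), "f1_mean")
    sds <- vapply(rows, `[[`, numeric(1), "f1_sd")
    ns <- vapply(rows, `[[`, numeric(1), "n_participants")
    k <- rows[[1]]$n_splits
    data.frame(combination = cmb, f1_mean = mean(f1),
               se = sqrt(mean(sds^2 / k)) / sqrt(length(rows)),
               n_participants = mean(ns), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$f1_mean), ]
  pooled <- sqrt(agg$se^2 + agg$se[1]^2)
  tied <- union(1L, which(agg$f1_mean[1] - agg$f1_mean < pooled))
  cand <- agg[tied, ]
  cand <- cand[order(-cand$n_participants, -cand$f1_mean), ]
  strsplit(cand$combination[1], "\\+")[[1]]
}
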