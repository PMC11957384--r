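#' @title Per-modality feature selection
#' @description Selection rules applied before similarity computation:
#'   pairwise differential tests on count modalities, elastic-net regression
#'   on continuous modalities, a variance cap for methylation, principal
#'   components for genotypes, and no selection for small clinical blocks.
#'   If a rule finds no informative features, all features are retained.
#' @name feature_selection
NULL

selection_result <- function(modality, method, selected_features, stats = NULL,
                             loadings = NULL, center = NULL,
                             fallback_used = FALSE) {
  structure(list(modality = modality, method = method,
                 selected_features = selected_features, stats = stats,
                 loadings = loadings, center = center,
                 fallback_used = fallback_used),
            class = "selection_result")
}

# Median-of-ratios size factors. Features whose geometric mean is zero are
# excluded from the reference; falls back to library-size ratios if none
# remain.
size_factors <- function(counts) {
  logc <- log(counts)
  logc[!is.finite(logc)] <- NA
  ref <- colMeans(logc)  # log geometric mean per feature
  usable <- which(is.finite(ref) & colSums(is.na(logc)) == 0)
  if (length(usable) == 0) {
    ls <- rowSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  sf <- apply(logc[, usable, drop = FALSE], 1,
              function(r) stats::median(r - ref[usable]))
  exp(sf)
}

#' Differential-expression style selection for count modalities
#'
#' For every pairwise contrast between the classes present, tests each
#' feature for a class difference on normalised counts: median-of-ratios
#' size factors, a method-of-moments negative-binomial dispersion estimate,
#' and a Wald test on the log mean difference. P-values are
#' Benjamini-Hochberg adjusted per contrast; a feature is selected when its
#' adjusted p-value falls below `alpha` in any contrast. This is an
#' approximate per-feature test, not a reimplementation of shrinkage-based
#' differential-expression tools.
#'
#' @param counts Participants-by-features matrix of nonnegative integers.
#' @param labels Class labels aligned to the rows of `counts`.
#' @param alpha FDR threshold (default 0.05).
#' @param modality Modality name recorded in the result.
#' @return A `selection_result` with per-feature statistics (`feature_id`,
#'   `effect` = largest absolute log2 fold change over contrasts, `p_value`,
#'   `padj` = minima over contrasts).
#' @export
de_select <- function(counts, labels, alpha = 0.05, modality = "counts") {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("de_select requires nonnegative integer counts")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  tab <- table(labels)
  if (any(tab < 2)) stop("each class needs at least 2 samples")

  sf <- size_factors(counts)
  norm <- counts / sf
  p <- ncol(counts)
  feat <- colnames(counts)
  if (is.null(feat)) feat <- sprintf("f%04d", seq_len(p))

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pmat <- matrix(NA_real_, p, length(pairs))
  amat <- matrix(NA_real_, p, length(pairs))
  emat <- matrix(NA_real_, p, length(pairs))
  for (j in seq_along(pairs)) {
    g1 <- norm[labels == pairs[[j]][1], , drop = FALSE]
    g2 <- norm[labels == pairs[[j]][2], , drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    mu1 <- colMeans(g1); mu2 <- colMeans(g2)
    v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
    # pooled method-of-moments dispersion: Var = mu + a mu^2
    mu_p <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
    v_p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    disp <- pmax(0, (v_p - mu_p) / pmax(mu_p, 1e-8)^2)
    # Wald on log means; delta-method variance of a log NB mean
    se2 <- (1 / pmax(mu1, 1e-8) + disp) / n1 + (1 / pmax(mu2, 1e-8) + disp) / n2
    lfc <- log2(pmax(mu2, 0.5) / pmax(mu1, 0.5))
    z <- (log(pmax(mu2, 1e-8)) - log(pmax(mu1, 1e-8))) / sqrt(pmax(se2, 1e-12))
    # t reference (not normal): the moment-based dispersion estimate is
    # noisy, and a normal reference is anti-conservative in the far tail
    pv <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)
    pv[mu1 + mu2 == 0] <- NA
    pmat[, j] <- pv
    amat[, j] <- stats::p.adjust(pv, method = "BH")
    emat[, j] <- lfc
  }
  padj_min <- apply(amat, 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  p_min <- apply(pmat, 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  eff <- emat[cbind(seq_len(p),
                    apply(abs(emat), 1, function(x) which.max(replace(x, is.na(x), -Inf))))]
  sel <- feat[!is.na(padj_min) & padj_min < alpha]
  fallback <- length(sel) == 0
  if (fallback) sel <- feat
  selection_result(modality, "de_pairwise", sel,
                   stats = data.frame(feature_id = feat, effect = eff,
                                      p_value = p_min, padj = padj_min,
                                      stringsAsFactors = FALSE),
                   fallback_used = fallback)
}

#' Elastic-net selection for continuous modalities
#'
#' Fits a multinomial elastic-net regression of class on standardised
#' features, with the penalty chosen by internal cross-validation; features
#' with any nonzero class coefficient at the selected penalty are retained.
#'
#' @param X Participants-by-features numeric matrix.
#' @param labels Class labels aligned to rows.
#' @param l1_ratio Mixing parameter between ridge (0) and lasso (1);
#'   default 0.5.
#' @param lambda_path Optional penalty sequence passed to the fitter.
#' @param nfolds Internal cross-validation folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @param modality Modality name recorded in the result.
#' @return A `selection_result`; `stats$effect` holds the largest absolute
#'   class coefficient per feature.
#' @export
enet_select <- function(X, labels, l1_ratio = 0.5, lambda_path = NULL,
                        nfolds = 5, seed = 1L, modality = "continuous") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("all columns are constant")
  feat <- colnames(X)
  if (is.null(feat)) feat <- sprintf("f%04d", seq_len(ncol(X)))
  colnames(X) <- feat

  # deterministic stratified fold assignment
  set.seed(seed)
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fit <- glmnet::cv.glmnet(X, factor(labels), family = "multinomial",
                           alpha = l1_ratio, standardize = TRUE,
                           foldid = foldid, lambda = lambda_path)
  # one-standard-error rule: the sparsest model within one SE of the CV
  # optimum, guarding against chance selections on uninformative data
  cf <- glmnet::coef.glmnet(fit, s = "lambda.1se")
  w <- do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1, 1]))
  eff <- apply(abs(w), 1, max)
  sel <- feat[eff > 0]
  # "no informative features found": the cross-validated model must beat the
  # intercept-only model (largest lambda) by more than one SE, otherwise the
  # active set is indistinguishable from chance and everything is retained
  i_1se <- which(fit$lambda == fit$lambda.1se)[1]
  informative <- fit$cvm[i_1se] < fit$cvm[1] - fit$cvsd[1]
  fallback <- length(sel) == 0 || !informative
  if (fallback) sel <- feat
  selection_result(modality, "elastic_net", sel,
                   stats = data.frame(feature_id = feat, effect = eff,
                                      p_value = NA_real_, padj = NA_real_,
                                      stringsAsFactors = FALSE),
                   fallback_used = fallback)
}

#' Retain the top-k most variable features
#'
#' Columns are ranked by variance (descending, ties broken by feature ID so
#' the result is deterministic) and the top `min(k, n_features)` retained.
#' The default cap of 300,000 is sized for genome-wide methylation arrays.
#'
#' @param X Participants-by-features numeric matrix.
#' @param k Number of features to keep (default 300000).
#' @param modality Modality name recorded in the result.
#' @return A `selection_result`.
#' @export
variance_topk <- function(X, k = 300000L, modality = "methylation") {
  if (k <= 0) stop("k must be positive")
  feat <- colnames(X)
  if (is.null(feat)) feat <- sprintf("f%04d", seq_len(ncol(X)))
  n <- nrow(X)
  v <- colMeans(X * X) - colMeans(X)^2
  v <- v * n / (n - 1)
  ord <- order(-v, feat)
  sel <- feat[ord[seq_len(min(k, length(feat)))]]
  selection_result(modality, "variance_topk", sel,
                   stats = data.frame(feature_id = feat, effect = v,
                                      p_value = NA_real_, padj = NA_real_,
                                      stringsAsFactors = FALSE))
}

#' Principal-component reduction for genotype-like modalities
#'
#' Mean-centres the matrix and emits the first `n_components` principal
#' component scores as derived features, storing the loadings and centre so
#' held-out or later-time-point data can be projected into the same space.
#'
#' @param X Participants-by-features numeric matrix (`nrow >= 2`).
#' @param n_components Number of components (default 20). If it exceeds the
#'   matrix rank, the available rank is returned with a message.
#' @param modality Modality name recorded in the result.
#' @return A `selection_result` with `loadings` (features x components) and
#'   `center`; derived features are named `PC1`, `PC2`, ...
#' @export
pca_reduce <- function(X, n_components = 20L, modality = "genotype") {
  if (n_components <= 0) stop("n_components must be positive")
  if (nrow(X) < 2) stop("need at least 2 samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  m <- min(n_components, rank)
  if (m < n_components) {
    message("pca_reduce: rank ", rank, " < requested ", n_components,
            " components; returning ", m)
  }
  load <- pc$rotation[, seq_len(m), drop = FALSE]
  colnames(load) <- sprintf("PC%d", seq_len(m))
  selection_result(modality, "pca", colnames(load),
                   loadings = load, center = pc$center)
}

#' Apply a selection result to a feature matrix
#'
#' Subsets columns for feature-list methods; projects through the stored
#' centre and loadings for PCA results. Used both at train time and when
#' reconstructing networks from later-time-point data.
#'
#' @param result A `selection_result`.
#' @param X Matrix whose columns cover the result's input features.
#' @return Matrix restricted/projected to the selected feature space.
#' @export
apply_selection <- function(result, X) {
  if (identical(result$method, "pca")) {
    feats <- rownames(result$loadings)
    missing <- setdiff(feats, colnames(X))
    if (length(missing) > 0) stop("matrix lacks features required by the projection")
    Xc <- sweep(X[, feats, drop = FALSE], 2, result$center[feats])
    return(Xc %*% result$loadings)
  }
  missing <- setdiff(result$selected_features, colnames(X))
  if (length(missing) > 0) {
    stop("matrix lacks ", length(missing), " selected features")
  }
  X[, result$selected_features, drop = FALSE]
}

#' Default modality-family to selection-method policy
#'
#' Count modalities get pairwise differential testing; methylation gets the
#' variance cap followed by elastic net; protein and severity panels get
#' elastic net; genotypes get principal components (fit once, reused across
#' time points since genotypes are fixed); small clinical blocks are kept
#' whole.
#'
#' @return Named list mapping family to a character vector of methods
#'   applied in order.
#' @export
default_selection_policy <- function() {
  list(nb_counts = "de_pairwise",
       logit_normal_beta = c("variance_topk", "elastic_net"),
       gaussian = "elastic_net",
       severity_score = "elastic_net",
       genotype_pc = "pca",
       clinical = "none")
}

default_family_map <- function() {
  c(mrna = "nb_counts", mirna = "nb_counts", dnam = "logit_normal_beta",
    snp = "genotype_pc", csf_protein = "gaussian", clinical = "clinical",
    severity = "severity_score")
}

#' Dispatch feature selection for one modality
#'
#' Looks up the modality's family in `policy`, applies the configured
#' method(s) in order (chains subset the matrix between steps), and applies
#' the retain-all fallback when a rule selects nothing.
#'
#' @param modality_name Modality name.
#' @param X Participants-by-features matrix.
#' @param labels Class labels aligned to rows (ignored by unsupervised
#'   methods).
#' @param policy Family-to-method map, see [default_selection_policy()].
#' @param family Modality family; defaults to a lookup of standard modality
#'   names (mrna, mirna, dnam, snp, csf_protein, clinical, severity).
#' @param variance_k Cap for the variance filter step.
#' @param pca_components Component count for the PCA step.
#' @param seed Seed for cross-validated steps.
#' @return A `selection_result` (for chained methods, the final step's
#'   result; `fallback_used` is true if any step fell back).
#' @export
select_for <- function(modality_name, X, labels,
                       policy = default_selection_policy(),
                       family = NULL, variance_k = 300000L,
                       pca_components = 20L, seed = 1L) {
  if (is.null(family)) {
    fam_map <- default_family_map()
    if (!modality_name %in% names(fam_map)) {
      stop("unknown modality: ", modality_name,
           " (supply family= explicitly)")
    }
    family <- fam_map[[modality_name]]
  }
  if (!family %in% names(policy)) stop("no selection policy for family ", family)
  methods <- policy[[family]]
  res <- selection_result(modality_name, "none", colnames(X))
  fallback_any <- FALSE
  for (m in methods) {
    res <- switch(m,
      none = selection_result(modality_name, "none", colnames(X)),
      de_pairwise = de_select(X, labels, modality = modality_name),
      elastic_net = enet_select(X, labels, seed = seed, modality = modality_name),
      variance_topk = variance_topk(X, k = variance_k, modality = modality_name),
      pca = pca_reduce(X, n_components = pca_components, modality = modality_name),
      stop("unknown selection method: ", m))
    fallback_any <- fallback_any || isTRUE(res$fallback_used)
    if (m != "pca") X <- X[, res$selected_features, drop = FALSE]
  }
  res$fallback_used <- fallback_any
  res
}

#' Write a selection result as TSV
#' @param result A `selection_result`.
#' @param path Output path for the statistics table; PCA loadings (if any)
#'   go to `paste0(path, ".loadings.tsv")`.
#' @export
write_selection <- function(result, path) {
  stats <- result$stats
  if (is.null(stats)) {
    stats <- data.frame(feature_id = result$selected_features,
                        effect = NA_real_, p_value = NA_real_,
                        padj = NA_real_, stringsAsFactors = FALSE)
  }
  stats$method <- result$method
  stats$selected <- stats$feature_id %in% result$selected_features
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$loadings)) {
    df <- data.frame(feature_id = rownames(result$loadings), result$loadings,
                     check.names = FALSE)
    utils::write.table(df, paste0(path, ".loadings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
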