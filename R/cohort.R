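#' Modality specification for the synthetic cohort generator
#'
#' Describes one data modality to simulate: its distributional family, how
#' many features it has, how many carry class signal, and how strong that
#' signal is at each time point.
#'
#' @param name Modality name (e.g. "mrna", "dnam").
#' @param family Distributional family. One of `"nb_counts"` (negative
#'   binomial sequencing-like counts with per-participant library-size
#'   factors), `"logit_normal_beta"` (methylation-like beta values generated
#'   as Gaussians on the logit scale), `"gaussian"` (continuous assay, e.g. a
#'   CSF protein panel), `"genotype_pc"` (time-invariant continuous
#'   genotype-PC-like features; signal separates risk-variant carriers from
#'   everyone else), `"clinical"` (small demographic covariate block) or
#'   `"severity_score"` (clinician-scale style scores: class baseline plus a
#'   class-specific time slope plus noise).
#' @param n_features Number of features.
#' @param n_informative Number of features carrying class signal
#'   (`<= n_features`).
#' @param effect_schedule Numeric vector, one entry per time point: the
#'   class-mean separation between adjacent classes (HC < PL < PD) in units
#'   of the feature noise SD on the family's natural (or latent) scale.
#'   For `genotype_pc` only the first entry is used at every time point,
#'   since genotypes do not change.
#' @param missing_rate Fraction of enrolled participants whose row is absent
#'   from this modality at each time point, in `[0, 1)`.
#' @param subgroup_restriction Optional character vector of subgroups; when
#'   set, participants outside these subgroups are removed from the modality
#'   (except a single retained participant, mirroring near-total
#'   subgroup-specific missingness seen in real multi-omic cohorts).
#' @param class_offsets Optional `n_timepoints x 3` matrix (columns named
#'   `HC`, `PL`, `PD`) of per-class mean offsets on the informative
#'   features, in noise-SD units, overriding the equally-spaced
#'   `HC = 0, PL = e_t, PD = 2 e_t` default. Lets a modality emulate
#'   disease drift, e.g. PD moving away from PL over time while PL-HC
#'   separation stays constant.
#' @param progression_sd Lognormal SD of a per-participant progression-rate
#'   multiplier applied to the PD class's drift beyond the PL offset
#'   (default 0 = homogeneous progression). Only meaningful together with
#'   `class_offsets`; emulates slow/fast progressors, so a fraction of PD
#'   participants still overlaps the prodromal class at mid time points.
#' @return A `modality_spec` list.
#' @export
modality_spec <- function(name, family, n_features, n_informative,
                          effect_schedule, missing_rate = 0,
                          subgroup_restriction = NULL,
                          class_offsets = NULL, progression_sd = 0) {
  families <- c("nb_counts", "logit_normal_beta", "gaussian",
                "genotype_pc", "clinical", "severity_score")
  if (!family %in% families) {
    stop("unknown modality family: ", family)
  }
  if (n_informative > n_features) stop("n_informative must be <= n_features")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(class_offsets)) {
    class_offsets <- as.matrix(class_offsets)
    if (ncol(class_offsets) != 3 ||
        !all(c("HC", "PL", "PD") %in% colnames(class_offsets))) {
      stop("class_offsets must have columns HC, PL, PD")
    }
    if (nrow(class_offsets) != length(effect_schedule)) {
      stop("class_offsets must have one row per time point")
    }
  }
  if (progression_sd < 0) stop("progression_sd must be nonnegative")
  structure(list(name = name, family = family,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_schedule = as.numeric(effect_schedule),
                 missing_rate = missing_rate,
                 subgroup_restriction = subgroup_restriction,
                 class_offsets = class_offsets,
                 progression_sd = progression_sd),
            class = "modality_spec")
}

#' Default six-modality panel
#'
#' A desk-scale panel mirroring the structure of a longitudinal Parkinson's
#' cohort: two count modalities (mRNA- and miRNA-like), methylation beta
#' values whose class signal strengthens over time, time-invariant
#' genotype-PC features separating risk-variant carriers from controls, a CSF
#' protein panel nearly absent from the genetic subgroup, a small clinical
#' covariate block, and a severity score used only by the baseline
#' comparator.
#'
#' @param n_timepoints Number of time points the schedules must cover.
#' @param effect Overall effect scale multiplier (0 gives a null cohort).
#' @return List of [modality_spec()] objects.
#' @export
default_modalities <- function(n_timepoints = 4, effect = 1) {
  tp <- n_timepoints
  list(
    modality_spec("mrna", "nb_counts", 400, 40,
                  rep(0.8 * effect, tp), missing_rate = 0.15),
    modality_spec("mirna", "nb_counts", 150, 15,
                  rep(0.6 * effect, tp), missing_rate = 0.15),
    modality_spec("dnam", "logit_normal_beta", 600, 50,
                  seq(0.4, 1.4, length.out = tp) * effect,
                  missing_rate = 0.2),
    modality_spec("snp", "genotype_pc", 60, 25,
                  rep(1.5 * effect, tp), missing_rate = 0.1),
    modality_spec("csf_protein", "gaussian", 200, 25,
                  rep(0.8 * effect, tp), missing_rate = 0.2,
                  subgroup_restriction = c("idiopathic", "rbd", "hyposmia", "control")),
    modality_spec("clinical", "clinical", 6, 2,
                  rep(0.3 * effect, tp), missing_rate = 0.05),
    modality_spec("severity", "severity_score", 6, 6,
                  rep(1 * effect, tp), missing_rate = 0.05)
  )
}

#' Cohort configuration
#'
#' @param n_per_class Named integer vector of participants per class. The
#'   default mirrors the imbalance of Parkinson's progression cohorts, where
#'   healthy controls are the smallest class.
#' @param subgroup_fractions Named list: per class, a named numeric vector of
#'   subgroup fractions summing to 1. Defaults follow the genetic /
#'   idiopathic / RBD / hyposmia taxonomy.
#' @param n_timepoints Number of annual time points (default 4: years 0-3).
#' @param modalities List of [modality_spec()] objects.
#' @param dropout_rate Fraction of (non-core) participants lost per year.
#' @param core_fraction Fraction of each class designated as a longitudinal
#'   core that never drops out, guaranteeing a usable all-time-point subset.
#' @param seed Integer seed; generation is bitwise deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_class = c(PD = 60, PL = 50, HC = 40),
                          subgroup_fractions = list(
                            PD = c(genetic = 0.42, idiopathic = 0.58),
                            PL = c(genetic = 0.77, rbd = 0.12, hyposmia = 0.11),
                            HC = c(control = 1)),
                          n_timepoints = 4,
                          modalities = default_modalities(n_timepoints),
                          dropout_rate = 0.1,
                          core_fraction = 0.4,
                          seed = 1L) {
  stopifnot(n_timepoints >= 1)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  for (cl in names(subgroup_fractions)) {
    if (abs(sum(subgroup_fractions[[cl]]) - 1) > 1e-8) {
      stop("subgroup fractions for class ", cl, " do not sum to 1")
    }
  }
  for (m in modalities) {
    if (!inherits(m, "modality_spec")) stop("modalities must be modality_spec objects")
    if (length(m$effect_schedule) != n_timepoints) {
      stop("effect_schedule of modality ", m$name,
           " must have length n_timepoints (", n_timepoints, ")")
    }
  }
  structure(list(n_per_class = n_per_class,
                 subgroup_fractions = subgroup_fractions,
                 n_timepoints = as.integer(n_timepoints),
                 modalities = modalities,
                 dropout_rate = dropout_rate,
                 core_fraction = core_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

class_index <- function(class_label) {
  # HC = 0, PL = 1, PD = 2: adjacent classes separated by one effect unit
  unname(c(HC = 0, PL = 1, PD = 2)[class_label])
}

# Allocate integer counts to categories by largest remainder, preserving total.
largest_remainder <- function(fracs, total) {
  raw <- fracs * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

generate_metadata <- function(config) {
  classes <- names(config$n_per_class)
  rows <- list()
  idx <- 0
  for (cl in classes) {
    n <- config$n_per_class[[cl]]
    fr <- config$subgroup_fractions[[cl]]
    counts <- largest_remainder(fr, n)
    subs <- rep(names(fr), counts)
    for (s in subs) {
      idx <- idx + 1
      rows[[idx]] <- data.frame(participant_id = sprintf("P%04d", idx),
                                class_label = cl, subgroup = s,
                                stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)

  # Year-over-year dropout outside a per-class longitudinal core.
  tp <- config$n_timepoints
  last_tp <- integer(nrow(meta))
  core <- logical(nrow(meta))
  for (cl in classes) {
    members <- which(meta$class_label == cl)
    n_core <- max(1L, floor(config$core_fraction * length(members)))
    core[sample(members, n_core)] <- TRUE
  }
  last_tp[] <- tp - 1L
  if (tp > 1 && config$dropout_rate > 0) {
    active <- which(!core)
    for (t in seq_len(tp - 1L)) {
      drop <- active[stats::runif(length(active)) < config$dropout_rate]
      last_tp[drop] <- t - 1L
      active <- setdiff(active, drop)
    }
  }
  meta$core <- core
  meta$last_timepoint <- last_tp
  meta$enrolled_timepoints <- vapply(
    last_tp, function(l) paste(0:l, collapse = ","), character(1))
  meta
}

sim_modality_values <- function(spec, meta, config) {
  # Returns list over time points of full (all enrolled participants) value
  # matrices; missingness is applied separately.
  tp <- config$n_timepoints
  n <- nrow(meta)
  p <- spec$n_features
  ninf <- spec$n_informative
  cls_idx <- class_index(meta$class_label)
  feat_ids <- sprintf("%s_f%04d", spec$name, seq_len(p))
  out <- vector("list", tp)
  # per-participant mean offset (noise-SD units) at time t: either the
  # equally-spaced HC=0, PL=e, PD=2e default or an explicit per-class grid;
  # PD drift beyond the PL offset is scaled by a per-participant
  # progression rate when heterogeneity is configured
  prog_rate <- rep(1, n)
  if (!is.null(spec$class_offsets) && spec$progression_sd > 0) {
    prog_rate <- exp(stats::rnorm(n, 0, spec$progression_sd))
  }
  offset_at <- function(t) {
    if (!is.null(spec$class_offsets)) {
      off <- unname(spec$class_offsets[t, meta$class_label])
      is_pd <- meta$class_label == "PD"
      pl_off <- spec$class_offsets[t, "PL"]
      off[is_pd] <- pl_off + prog_rate[is_pd] * (off[is_pd] - pl_off)
      off
    } else {
      spec$effect_schedule[t] * cls_idx
    }
  }

  if (spec$family == "nb_counts") {
    base_mu <- exp(stats::rnorm(p, log(100), 1))
    disp <- 0.2
    libf <- exp(stats::rnorm(n, 0, 0.3))
    sd_log <- sqrt(disp)  # approximate log-scale SD for large means
    for (t in seq_len(tp)) {
      shift <- matrix(0, n, p)
      if (ninf > 0) {
        shift[, seq_len(ninf)] <- outer(offset_at(t) * sd_log, rep(1, ninf))
      }
      mu <- libf * sweep(exp(shift), 2, base_mu, "*")
      vals <- matrix(stats::rnbinom(n * p, mu = mu, size = 1 / disp), n, p)
      dimnames(vals) <- list(meta$participant_id, feat_ids)
      out[[t]] <- vals
    }
  } else if (spec$family == "logit_normal_beta") {
    base_mu <- stats::rnorm(p, 0, 1.5)  # logit-scale baseline per CpG
    for (t in seq_len(tp)) {
      z <- matrix(stats::rnorm(n * p), n, p) +
        matrix(base_mu, n, p, byrow = TRUE)
      if (ninf > 0) {
        z[, seq_len(ninf)] <- z[, seq_len(ninf)] + outer(offset_at(t), rep(1, ninf))
      }
      vals <- stats::plogis(z)
      dimnames(vals) <- list(meta$participant_id, feat_ids)
      out[[t]] <- vals
    }
  } else if (spec$family == "gaussian") {
    base_mu <- stats::rnorm(p, 0, 1)
    for (t in seq_len(tp)) {
      vals <- matrix(stats::rnorm(n * p), n, p) +
        matrix(base_mu, n, p, byrow = TRUE)
      if (ninf > 0) {
        vals[, seq_len(ninf)] <- vals[, seq_len(ninf)] +
          outer(offset_at(t), rep(1, ninf))
      }
      dimnames(vals) <- list(meta$participant_id, feat_ids)
      out[[t]] <- vals
    }
  } else if (spec$family == "genotype_pc") {
    # Drawn once; identical at every time point (genotypes are fixed).
    # Signal separates risk-variant carriers (genetic-subgroup PD + PL)
    # from everyone else; it does not separate PD from PL.
    carrier <- meta$subgroup == "genetic" & meta$class_label %in% c("PD", "PL")
    eff <- spec$effect_schedule[1]
    vals <- matrix(stats::rnorm(n * p), n, p)
    if (ninf > 0 && eff != 0) {
      vals[, seq_len(ninf)] <- vals[, seq_len(ninf)] +
        outer(as.numeric(carrier), rep(eff, ninf))
    }
    dimnames(vals) <- list(meta$participant_id, feat_ids)
    for (t in seq_len(tp)) out[[t]] <- vals
  } else if (spec$family == "clinical") {
    # age, sex, education are stable covariates; methylation-derived
    # lifestyle scores (smoking, alcohol, bmi) carry any class signal.
    p <- 6L
    feat_ids <- c("age", "sex", "education", "smoking", "alcohol", "bmi")
    age0 <- stats::rnorm(n, 62, 8)
    sex <- stats::rbinom(n, 1, 0.5)
    educ <- stats::rnorm(n, 14, 3)
    for (t in seq_len(tp)) {
      eff <- spec$effect_schedule[t]
      lifestyle <- matrix(stats::rnorm(n * 3), n, 3)
      k <- min(spec$n_informative, 3L)
      if (k > 0 && eff != 0) {
        lifestyle[, seq_len(k)] <- lifestyle[, seq_len(k)] +
          outer(cls_idx, rep(eff, k))
      }
      vals <- cbind(age0 + (t - 1), sex, educ, lifestyle)
      dimnames(vals) <- list(meta$participant_id, feat_ids)
      out[[t]] <- vals
    }
  } else if (spec$family == "severity_score") {
    # Clinician-scale analog: class-dependent baseline + class-dependent
    # time slope + noise, on a handful of sub-scores.
    slope_by_class <- c(HC = 0, PL = 0.15, PD = 0.4)
    slopes <- unname(slope_by_class[meta$class_label])
    for (t in seq_len(tp)) {
      eff <- spec$effect_schedule[t]
      vals <- matrix(stats::rnorm(n * p), n, p)
      base <- eff * cls_idx + slopes * (t - 1)
      vals <- vals + matrix(base, n, p)
      dimnames(vals) <- list(meta$participant_id, feat_ids)
      out[[t]] <- vals
    }
  } else {
    stop("unknown modality family: ", spec$family)
  }
  out
}

#' Generate a synthetic longitudinal multi-omic cohort
#'
#' Draws participant metadata (class, subgroup, enrolment with year-over-year
#' dropout outside a longitudinal core) and one participants-by-features
#' matrix per modality per time point, with class-discriminative effects as
#' configured. Per-modality missingness is applied afterwards by
#' [apply_missingness()].
#'
#' @param config A [cohort_config()].
#' @return A `cohort_bundle`: list with `metadata` (data frame), `matrices`
#'   (named list: per modality, a list over time points of matrices whose
#'   rows are the participants enrolled at that time point) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  meta <- generate_metadata(config)
  matrices <- list()
  for (spec in config$modalities) {
    full <- sim_modality_values(spec, meta, config)
    per_t <- vector("list", config$n_timepoints)
    for (t in seq_len(config$n_timepoints)) {
      enrolled <- meta$participant_id[meta$last_timepoint >= (t - 1)]
      per_t[[t]] <- structure(
        list(modality = spec$name, timepoint = t - 1L,
             values = full[[t]][enrolled, , drop = FALSE]),
        class = "modality_matrix")
    }
    matrices[[spec$name]] <- per_t
  }
  structure(list(metadata = meta, matrices = matrices, config = config),
            class = "cohort_bundle")
}

#' Apply per-modality row missingness to a generated cohort
#'
#' Drops whole participant rows from each modality at the configured
#' `missing_rate`, subject to two rules: a `subgroup_restriction` removes
#' (almost) all participants outside the allowed subgroups, keeping exactly
#' one; and every enrolled participant is guaranteed to remain present in at
#' least one modality at every enrolled time point.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param config The cohort configuration (defaults to `bundle$config`).
#' @return The bundle with rows removed per modality.
#' @export
apply_missingness <- function(bundle, config = bundle$config) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  set.seed(config$seed + 104729L)  # distinct stream from generation
  meta <- bundle$metadata
  specs <- config$modalities
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  mod_names <- names(bundle$matrices)

  for (t in seq_len(config$n_timepoints)) {
    enrolled <- meta$participant_id[meta$last_timepoint >= (t - 1)]
    # allowed[i, m]: participant may appear in modality m (restriction)
    allowed <- matrix(TRUE, length(enrolled), length(mod_names),
                      dimnames = list(enrolled, mod_names))
    for (m in mod_names) {
      restr <- specs[[m]]$subgroup_restriction
      if (!is.null(restr)) {
        sub <- meta$subgroup[match(enrolled, meta$participant_id)]
        outside <- !(sub %in% restr)
        if (any(outside) && !all(outside)) {
          keep_one <- enrolled[outside][1]  # single retained participant
          allowed[outside, m] <- FALSE
          allowed[keep_one, m] <- TRUE
        }
      }
    }
    if (any(rowSums(allowed) == 0)) {
      stop("subgroup restrictions leave a participant with no modality")
    }
    keep <- allowed
    for (m in mod_names) {
      r <- specs[[m]]$missing_rate
      if (r > 0) {
        drop <- stats::runif(length(enrolled)) < r
        keep[drop, m] <- FALSE
      }
    }
    # presence guarantee: re-admit one allowed modality for orphaned rows
    orphan <- which(rowSums(keep) == 0)
    for (i in orphan) {
      ok <- which(allowed[i, ])
      if (length(ok) == 0) stop("presence guarantee unsatisfiable")
      pick <- if (length(ok) == 1) ok else sample(ok, 1)
      keep[i, pick] <- TRUE
    }
    for (m in mod_names) {
      mm <- bundle$matrices[[m]][[t]]
      rows <- enrolled[keep[, m]]
      mm$values <- mm$values[intersect(rownames(mm$values), rows), , drop = FALSE]
      bundle$matrices[[m]][[t]] <- mm
    }
  }
  bundle
}

#' Write / read a cohort bundle as TSV files
#'
#' `write_cohort()` writes `metadata.tsv` plus one
#' `<modality>_t<time>.tsv` per modality and time point (participant ID in
#' the first column). `read_cohort()` reads them back; the round trip is
#' lossless up to numeric text precision.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Directory to write to / read from.
#' @return `read_cohort()` returns a `cohort_bundle` (without the generating
#'   config).
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- bundle$metadata[, c("participant_id", "class_label", "subgroup",
                              "enrolled_timepoints")]
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (m in names(bundle$matrices)) {
    for (mm in bundle$matrices[[m]]) {
      # %.17g so the double -> text -> double round trip is lossless
      txt <- apply(mm$values, 2, function(col) sprintf("%.17g", col))
      df <- data.frame(participant_id = rownames(mm$values),
                       txt, check.names = FALSE, stringsAsFactors = FALSE)
      colnames(df) <- c("participant_id", colnames(mm$values))
      utils::write.table(df,
                         file.path(dir, sprintf("%s_t%d.tsv", m, mm$timepoint)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("no metadata.tsv in ", dir)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = c(enrolled_timepoints = "character"))
  if (anyDuplicated(meta$participant_id)) {
    stop("duplicated participant ID in metadata")
  }
  meta$last_timepoint <- vapply(strsplit(meta$enrolled_timepoints, ","),
                                function(x) max(as.integer(x)), integer(1))
  files <- list.files(dir, pattern = "_t[0-9]+\\.tsv$")
  matrices <- list()
  for (f in files) {
    base <- sub("\\.tsv$", "", f)
    t <- as.integer(sub(".*_t([0-9]+)$", "\\1", base))
    m <- sub("_t[0-9]+$", "", base)
    df <- utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                            check.names = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicated participant ID in ", f)
    if (!all(ids %in% meta$participant_id)) {
      stop("participant IDs in ", f, " not present in metadata")
    }
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    mm <- structure(list(modality = m, timepoint = t, values = vals),
                    class = "modality_matrix")
    if (is.null(matrices[[m]])) matrices[[m]] <- list()
    matrices[[m]][[t + 1]] <- mm
  }
  structure(list(metadata = meta, matrices = matrices, config = NULL),
            class = "cohort_bundle")
}

#' Class labels of a cohort as a named factor-like character vector
#' @param bundle A `cohort_bundle`.
#' @return Named character vector (names = participant IDs).
#' @export
cohort_labels <- function(bundle) {
  stats::setNames(bundle$metadata$class_label, bundle$metadata$participant_id)
}

#' Modality matrices of one time point as a named list of matrices
#' @param bundle A `cohort_bundle`.
#' @param timepoint Time point (0-based).
#' @param modalities Optional subset of modality names.
#' @return Named list of participants-by-features matrices.
#' @export
timepoint_matrices <- function(bundle, timepoint, modalities = NULL) {
  mods <- if (is.null(modalities)) names(bundle$matrices) else modalities
  out <- list()
  for (m in mods) {
    per_t <- bundle$matrices[[m]]
    if (is.null(per_t) || length(per_t) < timepoint + 1) {
      stop("modality ", m, " has no data at time point ", timepoint)
    }
    out[[m]] <- per_t[[timepoint + 1]]$values
  }
  out
}
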