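test_that("generation is deterministic and enrolment is contiguous", {
  cfg <- three_modality_config(seed = 7)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)

  meta <- b1$metadata
  expect_equal(nrow(meta), 75)
  expect_false(anyDuplicated(meta$participant_id) > 0)
  # enrolment runs 0..last with no gaps
  for (e in meta$enrolled_timepoints) {
    tps <- as.integer(strsplit(e, ",")[[1]])
    expect_equal(tps, seq(0, max(tps)))
  }
  # matrix rows are enrolled participants
  for (m in names(b1$matrices)) {
    for (mm in b1$matrices[[m]]) {
      enrolled <- meta$participant_id[meta$last_timepoint >= mm$timepoint]
      expect_true(all(rownames(mm$values) %in% enrolled))
    }
  }
})

test_that("dropout removes participants over time but never the core", {
  cfg <- three_modality_config(seed = 3, tp = 4, dropout = 0.25)
  b <- generate_cohort(cfg)
  meta <- b$metadata
  n_at <- vapply(0:3, function(t) sum(meta$last_timepoint >= t), integer(1))
  expect_true(all(diff(n_at) <= 0))
  expect_lt(n_at[4], n_at[1])
  expect_true(all(meta$last_timepoint[meta$core] == 3))
})

test_that("count modality is negative-binomial-like with library-size factors", {
  cfg <- cohort_config(
    n_per_class = c(PD = 120, PL = 120, HC = 120),
    n_timepoints = 1,
    modalities = list(modality_spec("mrna", "nb_counts", 60, 0, 0)),
    dropout_rate = 0, seed = 5)
  X <- generate_cohort(cfg)$matrices$mrna[[1]]$values
  expect_true(all(X >= 0) && all(X == round(X)))
  mu <- colMeans(X)
  v <- apply(X, 2, var)
  # overdispersion: Var ~ mu + (disp + lib-size var) mu^2, far above Poisson
  expect_gt(median(v / mu), 5)
  # the quadratic coefficient should be near disp 0.2 + library-size
  # lognormal variance (exp(0.09)-1 ~ 0.094); wide band for sampling noise
  ratio <- (v - mu) / mu^2
  expect_gt(median(ratio), 0.1)
  expect_lt(median(ratio), 0.6)
})

test_that("null cohorts are label-exchangeable", {
  cfg <- cohort_config(
    n_per_class = c(PD = 40, PL = 40, HC = 40),
    n_timepoints = 1,
    modalities = list(modality_spec("csf_protein", "gaussian", 400, 50, 0)),
    dropout_rate = 0, seed = 11)
  b <- generate_cohort(cfg)
  X <- b$matrices$csf_protein[[1]]$values
  labels <- cohort_labels(b)[rownames(X)]
  pd <- X[labels == "PD", ]
  hc <- X[labels == "HC", ]
  pv <- vapply(seq_len(ncol(X)),
               function(j) stats::t.test(pd[, j], hc[, j])$p.value,
               numeric(1))
  rej <- mean(pv < 0.05)
  expect_gt(rej, 0.005)  # two-sample test rejects at about the nominal rate
  expect_lt(rej, 0.11)
})

test_that("class effects are planted only on informative features and are monotone", {
  sep <- function(effect, seed = 21) {
    cfg <- cohort_config(
      n_per_class = c(PD = 60, PL = 60, HC = 60), n_timepoints = 1,
      modalities = list(modality_spec("dnam", "logit_normal_beta", 40, 10,
                                      effect)),
      dropout_rate = 0, seed = seed)
    b <- generate_cohort(cfg)
    X <- qlogis(b$matrices$dnam[[1]]$values)  # back to the latent scale
    labels <- cohort_labels(b)[rownames(X)]
    colMeans(X[labels == "PD", ]) - colMeans(X[labels == "HC", ])
  }
  d1 <- sep(1)
  d2 <- sep(2)
  expect_gt(mean(d1[1:10]), 1.5)          # informative: ~2 x effect
  expect_lt(max(abs(d1[11:40])), 0.75)    # noise features: no separation
  expect_gt(mean(d2[1:10]), mean(d1[1:10]))  # monotone in effect size
  b <- generate_cohort(cohort_config(
    n_per_class = c(PD = 20, PL = 20, HC = 20), n_timepoints = 1,
    modalities = list(modality_spec("dnam", "logit_normal_beta", 10, 10, 1)),
    dropout_rate = 0, seed = 2))
  vals <- b$matrices$dnam[[1]]$values
  expect_true(all(vals > 0 & vals < 1))  # beta support preserved
})

test_that("genotype features are time-invariant and separate carriers only", {
  cfg <- cohort_config(
    n_per_class = c(PD = 40, PL = 40, HC = 40), n_timepoints = 3,
    subgroup_fractions = list(PD = c(genetic = 0.5, idiopathic = 0.5),
                              PL = c(genetic = 0.5, rbd = 0.5),
                              HC = c(control = 1)),
    modalities = list(modality_spec("snp", "genotype_pc", 30, 10,
                                    c(2, 0.1, 5))),
    dropout_rate = 0, seed = 9)
  b <- generate_cohort(cfg)
  m0 <- b$matrices$snp[[1]]$values
  m2 <- b$matrices$snp[[3]]$values
  expect_identical(m0, m2)  # schedule ignored after the first entry
  meta <- b$metadata
  carrier <- meta$subgroup == "genetic" & meta$class_label %in% c("PD", "PL")
  names(carrier) <- meta$participant_id
  inf <- m0[, 1:10]
  expect_gt(mean(inf[carrier[rownames(m0)], ]) -
            mean(inf[!carrier[rownames(m0)], ]), 1.5)
  # idiopathic PD participants look like controls in this modality
  idio <- meta$participant_id[meta$subgroup == "idiopathic"]
  hc <- meta$participant_id[meta$class_label == "HC"]
  expect_lt(abs(mean(inf[idio, ]) - mean(inf[hc, ])), 0.5)
})

test_that("missingness honours rates, the presence guarantee and restrictions", {
  # rate 0: nothing dropped
  cfg0 <- three_modality_config(seed = 13, miss = 0)
  g <- generate_cohort(cfg0)
  expect_identical(apply_missingness(g)$matrices, g$matrices)

  # one modality at rate 0.5: the guarantee overrides the rate entirely
  cfg1 <- cohort_config(
    n_per_class = c(PD = 20, PL = 20, HC = 20), n_timepoints = 1,
    modalities = list(modality_spec("mrna", "nb_counts", 20, 0, 0,
                                    missing_rate = 0.5)),
    dropout_rate = 0, seed = 17)
  b1 <- apply_missingness(generate_cohort(cfg1))
  expect_equal(sort(rownames(b1$matrices$mrna[[1]]$values)),
               sort(b1$metadata$participant_id))

  # two modalities at rate 0.3: the union covers every enrolled participant
  cfg2 <- cohort_config(
    n_per_class = c(PD = 25, PL = 25, HC = 25), n_timepoints = 2,
    modalities = list(
      modality_spec("mrna", "nb_counts", 20, 0, c(0, 0), missing_rate = 0.3),
      modality_spec("csf_protein", "gaussian", 20, 0, c(0, 0),
                    missing_rate = 0.3)),
    dropout_rate = 0.1, seed = 19)
  b2 <- apply_missingness(generate_cohort(cfg2))
  for (t in 0:1) {
    enrolled <- b2$metadata$participant_id[b2$metadata$last_timepoint >= t]
    union_ids <- sort(unique(unlist(lapply(timepoint_matrices(b2, t),
                                           rownames))))
    expect_equal(union_ids, sort(enrolled))
    # some rows must actually be missing from single modalities
    expect_lt(nrow(timepoint_matrices(b2, t)$mrna), length(enrolled))
  }

  # subgroup restriction keeps exactly one participant from outside it
  cfg3 <- cohort_config(
    n_per_class = c(PD = 30, PL = 30, HC = 30), n_timepoints = 1,
    subgroup_fractions = list(PD = c(genetic = 0.5, idiopathic = 0.5),
                              PL = c(genetic = 0.5, rbd = 0.5),
                              HC = c(control = 1)),
    modalities = list(
      modality_spec("mrna", "nb_counts", 20, 0, 0),
      modality_spec("csf_protein", "gaussian", 20, 0, 0,
                    subgroup_restriction = c("idiopathic", "rbd", "hyposmia",
                                             "control"))),
    dropout_rate = 0, seed = 23)
  b3 <- apply_missingness(generate_cohort(cfg3))
  prot_ids <- rownames(b3$matrices$csf_protein[[1]]$values)
  sub <- b3$metadata$subgroup[match(prot_ids, b3$metadata$participant_id)]
  expect_equal(sum(sub == "genetic"), 1)
})

test_that("cohort TSV round trip is lossless and readers validate input", {
  b <- small_cohort(seed = 29)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  b2 <- read_cohort(dir)
  expect_equal(sort(b2$metadata$participant_id),
               sort(b$metadata$participant_id))
  for (m in names(b$matrices)) {
    for (t in seq_along(b$matrices[[m]])) {
      a <- b$matrices[[m]][[t]]$values
      z <- b2$matrices[[m]][[t]]$values
      expect_identical(z[rownames(a), colnames(a)], a)
    }
  }

  # duplicated participant ID
  lines <- readLines(file.path(dir, "clinical_t0.tsv"))
  writeLines(c(lines, lines[2]), file.path(dir, "clinical_t0.tsv"))
  expect_error(read_cohort(dir), "duplicated")

  # IDs disjoint from metadata
  writeLines(c(lines[1], sub("^P[0-9]+", "ZZZ", lines[2])),
             file.path(dir, "clinical_t0.tsv"))
  expect_error(read_cohort(dir), "not present in metadata")
})

test_that("per-class offset schedules plant disease drift", {
  # PL fixed at 1.5 SD from HC; PD drifts away from PL over two visits
  drift <- cbind(HC = c(0, 0), PL = c(1.5, 1.5), PD = c(1.6, 3.5))
  cfg <- cohort_config(
    n_per_class = c(PD = 60, PL = 60, HC = 60), n_timepoints = 2,
    modalities = list(modality_spec("csf_protein", "gaussian", 30, 10,
                                    c(1, 1), class_offsets = drift)),
    dropout_rate = 0, seed = 31)
  b <- generate_cohort(cfg)
  labels <- cohort_labels(b)
  gap <- function(t) {
    X <- b$matrices$csf_protein[[t + 1]]$values[, 1:10]
    l <- labels[rownames(X)]
    c(pd_pl = mean(X[l == "PD", ]) - mean(X[l == "PL", ]),
      pl_hc = mean(X[l == "PL", ]) - mean(X[l == "HC", ]))
  }
  g0 <- gap(0); g1 <- gap(1)
  expect_equal(unname(g0["pl_hc"]), 1.5, tolerance = 0.35)
  expect_equal(unname(g1["pl_hc"]), 1.5, tolerance = 0.35)  # PL-HC constant
  expect_gt(g1["pd_pl"], g0["pd_pl"] + 1)                   # PD drifts away
  expect_equal(unname(g0["pd_pl"]), 0.1, tolerance = 0.35)

  # progression-rate heterogeneity widens the PD class without moving PL/HC
  het <- cohort_config(
    n_per_class = c(PD = 80, PL = 80, HC = 80), n_timepoints = 2,
    modalities = list(modality_spec("csf_protein", "gaussian", 30, 10,
                                    c(1, 1), class_offsets = drift,
                                    progression_sd = 0.8)),
    dropout_rate = 0, seed = 37)
  bh <- generate_cohort(het)
  lh <- cohort_labels(bh)
  Xh <- bh$matrices$csf_protein[[2]]$values
  hom <- generate_cohort(cohort_config(
    n_per_class = c(PD = 80, PL = 80, HC = 80), n_timepoints = 2,
    modalities = list(modality_spec("csf_protein", "gaussian", 30, 10,
                                    c(1, 1), class_offsets = drift)),
    dropout_rate = 0, seed = 37))
  Xo <- hom$matrices$csf_protein[[2]]$values
  pd_rowmean <- function(X, l) rowMeans(X[l == "PD", 1:10])
  expect_gt(sd(pd_rowmean(Xh, lh[rownames(Xh)])),
            sd(pd_rowmean(Xo, lh[rownames(Xo)])) * 1.5)
  expect_error(modality_spec("x", "gaussian", 10, 2, 0, progression_sd = -1),
               "nonnegative")

  expect_error(modality_spec("x", "gaussian", 10, 2, c(0, 0),
                             class_offsets = cbind(HC = 0, PL = 1)),
               "columns HC, PL, PD")
  expect_error(modality_spec("x", "gaussian", 10, 2, c(0, 0),
                             class_offsets = drift[1, , drop = FALSE]),
               "one row per time point")
})

test_that("configuration invariants are enforced", {
  expect_error(modality_spec("x", "weibull", 10, 2, 0), "unknown modality family")
  expect_error(modality_spec("x", "gaussian", 10, 20, 0), "n_informative")
  expect_error(modality_spec("x", "gaussian", 10, 2, 0, missing_rate = 1),
               "missing_rate")
  expect_error(cohort_config(subgroup_fractions = list(
    PD = c(genetic = 0.5, idiopathic = 0.3),
    PL = c(genetic = 1), HC = c(control = 1))), "sum to 1")
  expect_error(cohort_config(modalities = list(
    modality_spec("x", "gaussian", 10, 2, c(0, 0)))), "effect_schedule")
})
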