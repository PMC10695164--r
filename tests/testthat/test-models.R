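test_that("folds partition patients into near-equal patient-level groups", {
  ids <- sprintf("P%03d", 1:100)
  f <- make_folds(ids, k = 5, seed = 3)
  expect_setequal(names(f), ids)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  expect_identical(f, make_folds(ids, k = 5, seed = 3))
  expect_false(identical(f, make_folds(ids, k = 5, seed = 4)))
  expect_error(make_folds(ids[1:3], k = 5), "exceeds")

  f2 <- make_folds(sprintf("P%03d", 1:103), k = 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)

  # stratified assignment balances the classes across folds
  ids <- sprintf("P%03d", 1:100)
  y <- setNames(rep(c(TRUE, FALSE), c(60, 40)), ids)
  fs <- make_folds(ids, k = 5, seed = 2, labels = y)
  expect_equal(unname(table(fs)), rep(20L, 5), ignore_attr = TRUE)
  pos_per_fold <- table(fs[names(y)[y]])
  expect_lte(diff(range(pos_per_fold)), 1)
})

test_that("F1 and AUROC follow their definitions", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  m <- compute_metrics(y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$f1, 1)
  expect_equal(m$auroc, 1)

  # all scores equal: AUROC 0.5 by tie credit
  expect_equal(compute_metrics(y, rep(0.3, 4))$auroc, 0.5)

  # hand-enumerated: 3 of 4 pairs concordant
  expect_equal(compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))$auroc,
               0.75)

  expect_error(compute_metrics(c(TRUE, TRUE), c(0.1, 0.2)), "single-class")
})

test_that("AUROC equals pairwise enumeration and F1 equals precision/recall arithmetic", {
  withr::with_seed(41, {
    for (rep in 1:40) {
      n <- sample(5:30, 1)
      y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
      m <- compute_metrics(y, s)
      expect_equal(m$auroc, orc_auroc(y, s))
      expect_equal(m$f1, orc_f1(y, s))
    }
  })
})

test_that("AUROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(44, {
    for (rep in 1:5) {
      y <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(0.55, 0.45))
      if (!any(y) || all(y)) next
      s <- round(runif(50), 2)
      ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
        y, s, quiet = TRUE, direction = "<", levels = c(FALSE, TRUE)))))
      expect_equal(compute_metrics(y, s)$auroc, ref, tolerance = 1e-12)
    }
  })
})

test_that("metrics are invariant under monotone transforms and co-permutation", {
  withr::with_seed(42, {
    y <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.6, 0.4))
    s <- runif(60)
    a0 <- compute_metrics(y, s)$auroc
    expect_equal(compute_metrics(y, plogis(5 * qlogis(pmin(pmax(s, 1e-6),
                                                           1 - 1e-6))))$auroc,
                 a0)
    perm <- sample(60)
    m0 <- compute_metrics(y, s)
    m1 <- compute_metrics(y[perm], s[perm])
    expect_equal(m0$f1, m1$f1)
    expect_equal(m0$auroc, m1$auroc)
  })
})

test_that("bootstrap intervals are deterministic, cover the point, degenerate to zero width", {
  withr::with_seed(7, {
    y <- sample(c(TRUE, FALSE), 200, replace = TRUE)
    s <- ifelse(y, runif(200, 0.3, 1), runif(200, 0, 0.7))
  })
  ci1 <- bootstrap_ci(y, s, "auroc", n_boot = 500, seed = 11)
  ci2 <- bootstrap_ci(y, s, "auroc", n_boot = 500, seed = 11)
  expect_identical(ci1, ci2)
  pt <- compute_metrics(y, s)$auroc
  expect_lte(ci1$lower, pt)
  expect_gte(ci1$upper, pt)

  # perfectly separated scores: every resample has AUROC 1
  yp <- rep(c(TRUE, FALSE), 20)
  sp <- ifelse(yp, 1, 0)
  ci <- bootstrap_ci(yp, sp, "auroc", n_boot = 100, seed = 2)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
})

test_that("elastic-net fit separates separable data and rejects single-class labels", {
  withr::with_seed(8, {
    n <- 120
    # strictly separated classes on feature "a"
    x <- cbind(a = c(runif(n / 2, 1, 2), runif(n / 2, -2, -1)), b = rnorm(n))
    y <- rep(c(TRUE, FALSE), each = n / 2)
    perm <- sample(n)
    x <- x[perm, ]; y <- y[perm]
  })
  s <- fit_predict(model_spec("elasticnet_logistic"), x[1:80, ], y[1:80],
                   x[81:120, ])
  expect_equal(compute_metrics(y[81:120], s)$auroc, 1)
  expect_error(fit_predict(model_spec("elasticnet_logistic"),
                           x[1:10, ], rep(TRUE, 10), x[1:2, ]),
               "single-class")
  expect_error(model_spec("elasticnet_logistic", list(bogus = 1)), "unknown")
})

test_that("class balancing makes the decision direction robust to duplicated negatives", {
  withr::with_seed(9, {
    n <- 60
    x <- cbind(sig = c(rnorm(n / 2, 1), rnorm(n / 2, -1)),
               noise = rnorm(n))
    y <- rep(c(TRUE, FALSE), each = n / 2)
  })
  fit_dir <- function(xx, yy) {
    w <- ifelse(yy, length(yy) / (2 * sum(yy)), length(yy) / (2 * sum(!yy)))
    f <- glmnet::glmnet(xx, as.numeric(yy), family = "binomial", alpha = 0.5,
                        weights = w, lambda = 0.01)
    as.numeric(coef(f))[2]
  }
  d1 <- fit_dir(x, y)
  dup <- c(seq_len(n), which(!y), which(!y))  # triple every negative
  d2 <- fit_dir(x[dup, ], y[dup])
  expect_equal(sign(d1), sign(d2))
  expect_gt(d1, 0)
})

test_that("gradient-boosted trees learn a deterministic separable rule", {
  withr::with_seed(10, {
    n <- 200
    x <- matrix(runif(n * 3), n, 3)
    y <- x[, 1] > 0.5
  })
  spec <- model_spec("gradient_boosted_trees", list(nrounds = 50))
  s1 <- fit_predict(spec, x[1:150, ], y[1:150], x[151:200, ])
  s2 <- fit_predict(spec, x[1:150, ], y[1:150], x[151:200, ])
  expect_identical(s1, s2)
  expect_gt(compute_metrics(y[151:200], s1)$auroc, 0.95)
})

test_that("no patient leaks between fit and score sets in any fold", {
  reg <- code_registry()
  co <- simulate_cohort(sim_config(n_patients = 120, seed = 14))
  ct <- build_cohort(co, reg)
  lab <- label_cohort(co, ct, reg)
  y <- setNames(lab$composite, lab$patient_id)
  folds <- make_folds(lab$patient_id, k = 5, seed = 2)
  notes <- filter_notes_for_prediction(
    co$notes[co$notes$patient_id %in% lab$patient_id, ], ct)

  seen <- new.env()
  seen$fit_ids <- list()
  recording_factory <- function() {
    inner <- scorer_tf()
    structure(list(
      fit = function(notes, labels) {
        seen$fit_ids[[length(seen$fit_ids) + 1]] <- unique(notes$patient_id)
        inner$fit(notes, labels)
      },
      score = inner$score), class = "note_scorer")
  }
  res <- evaluate_notes_pipeline(notes, y, folds,
                                 scorer_factory = recording_factory,
                                 n_boot = 50, seed = 1)
  for (f in seq_along(seen$fit_ids)) {
    test_ids <- res$pooled$patient_id[res$pooled$fold == f]
    expect_length(intersect(seen$fit_ids[[f]], test_ids), 0)
  }

  # structured path: flipping one patient's label never changes that
  # patient's own held-out score
  feats <- build_feature_matrix(co, ct)
  spec <- model_spec("gradient_boosted_trees", list(nrounds = 20))
  base <- evaluate_structured(feats, y, folds, spec, "prevalence", 0.01,
                              n_boot = 50, seed = 1)
  pid <- lab$patient_id[[1]]
  y2 <- y
  y2[pid] <- !y2[pid]
  flip <- evaluate_structured(feats, y2, folds, spec, "prevalence", 0.01,
                              n_boot = 50, seed = 1)
  expect_equal(base$pooled$score[base$pooled$patient_id == pid],
               flip$pooled$score[flip$pooled$patient_id == pid])
})

test_that("note-type ablation reports per-type rows and excludes noteless patients", {
  reg <- code_registry()
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 15,
                                   text_signal_strength = 2))
  ct <- build_cohort(co, reg)
  lab <- label_cohort(co, ct, reg)
  y <- setNames(lab$composite, lab$patient_id)
  folds <- make_folds(lab$patient_id, k = 5, seed = 3)
  notes <- filter_notes_for_prediction(
    co$notes[co$notes$patient_id %in% lab$patient_id, ], ct)
  tab <- ablate_by_note_type(notes, y, folds, n_boot = 50, seed = 1)
  expect_true(all(c("neurology", "all") %in% tab$group))
  neuro <- tab[tab$group == "neurology", ]
  expect_equal(neuro$n_patients + neuro$n_excluded, length(y))

  # a single present note type gives that row plus an identical "all" row
  solo <- notes[notes$note_type == "neurology", ]
  tab2 <- ablate_by_note_type(solo, y, folds, n_boot = 50, seed = 1)
  expect_setequal(tab2$group, c("neurology", "all"))
  expect_equal(tab2$auroc[tab2$group == "all"],
               tab2$auroc[tab2$group == "neurology"])
})
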