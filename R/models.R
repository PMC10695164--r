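#' Patient-level cross-validation folds
#'
#' Standard k-fold assignment: patients are shuffled under the seed and dealt
#' into k test folds of near-equal size (sizes differ by at most one), so
#' each fold serves once as the held-out 20% when k = 5. Folds are
#' patient-level: all of a patient's notes and features travel together.
#'
#' When `labels` are supplied the assignment is stratified: each class is
#' shuffled and dealt round-robin, so every fold carries (within one patient)
#' the same class balance. Stratification keeps training prevalence constant
#' across folds, which prevents fold-level score-scale shifts from biasing
#' pooled cross-validation metrics.
#'
#' @param patient_ids Character vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param labels Optional named logical vector (by patient id) to stratify
#'   on.
#' @return Named integer vector mapping patient id to fold (1..k).
#' @export
make_folds <- function(patient_ids, k = 5L, seed = 1L, labels = NULL) {
  n <- length(patient_ids)
  if (k > n) stop("make_folds: k exceeds the number of patients")
  withr::with_seed(seed, {
    if (is.null(labels)) {
      shuffled <- sample(patient_ids)
    } else {
      stopifnot(all(patient_ids %in% names(labels)))
      y <- as.logical(labels[patient_ids])
      shuffled <- c(sample(patient_ids[y]), sample(patient_ids[!y]))
    }
    stats::setNames(rep_len(seq_len(k), n), shuffled)[patient_ids]
  })
}

#' Specify a baseline classifier
#'
#' Two families with the settings that won the original pipeline sweeps as
#' defaults: `elasticnet_logistic` (elastic-net penalised logistic regression
#' with class-balanced weights) and `gradient_boosted_trees` (500 estimators,
#' L1 and L2 regularisation terms 0.1, other parameters at their defaults).
#'
#' @param family `"elasticnet_logistic"` or `"gradient_boosted_trees"`.
#' @param params Named list overriding family defaults. For
#'   `elasticnet_logistic`: `alpha` (elastic-net mixing, default 0.5),
#'   `lambda` (penalty; default `1/n_train`), `class_balance` (default
#'   `TRUE`). For `gradient_boosted_trees`: `nrounds` (default 500),
#'   `reg_lambda`/`reg_alpha` (default 0.1), `max_depth`, `eta`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("elasticnet_logistic",
                                  "gradient_boosted_trees"),
                       params = list()) {
  family <- match.arg(family)
  defaults <- if (family == "elasticnet_logistic") {
    list(alpha = 0.5, lambda = NULL, class_balance = TRUE)
  } else {
    list(nrounds = 500L, reg_lambda = 0.1, reg_alpha = 0.1,
         max_depth = 6L, eta = 0.3)
  }
  for (nm in names(params)) {
    if (!nm %in% names(defaults)) {
      stop("model_spec: unknown parameter '", nm, "' for family ", family)
    }
    defaults[[nm]] <- params[[nm]]
  }
  structure(list(family = family, params = defaults), class = "model_spec")
}

#' Fit a classifier on training rows and score held-out rows
#'
#' Deterministic given the inputs (single-threaded boosting; fixed penalty
#' path for the elastic net). Training labels must contain both classes.
#'
#' @param spec A [model_spec()].
#' @param x_train,y_train Training matrix and logical/0-1 labels.
#' @param x_test Held-out matrix sharing the training columns.
#' @return Numeric scores in `[0, 1]`, one per test row.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as.numeric(as.logical(y_train))
  if (length(unique(y)) < 2) {
    stop("fit_predict: training labels are single-class; cannot fit")
  }
  if (spec$family == "elasticnet_logistic") {
    p <- spec$params
    n <- nrow(x_train)
    w <- if (isTRUE(p$class_balance)) {
      # inverse-prevalence weights, normalised to sum to n
      wt <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
      wt
    } else rep(1, n)
    if (is.null(p$lambda)) {
      # default penalty chosen by internal cross-validation (deterministic
      # fold ids) under the one-standard-error parsimony rule, the standard
      # glmnet practice; the extra shrinkage keeps null data at a null score
      foldid <- rep_len(1:5, n)
      cv <- glmnet::cv.glmnet(x_train, y, family = "binomial",
                              alpha = p$alpha, weights = w, foldid = foldid,
                              standardize = TRUE)
      lam <- cv$lambda.1se
      fit <- cv$glmnet.fit
    } else {
      lam <- p$lambda
      fit <- glmnet::glmnet(x_train, y, family = "binomial", alpha = p$alpha,
                            weights = w, lambda = lam, standardize = TRUE)
    }
    as.numeric(stats::predict(fit, x_test, type = "response", s = lam))
  } else {
    p <- spec$params
    dtrain <- xgboost::xgb.DMatrix(x_train, label = y)
    params <- xgboost::xgb.params(objective = "binary:logistic",
                                  nthread = 1L,
                                  reg_lambda = p$reg_lambda,
                                  reg_alpha = p$reg_alpha,
                                  max_depth = p$max_depth, eta = p$eta,
                                  seed = 0L)
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = p$nrounds, verbose = 0)
    as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(x_test)))
  }
}

#' F1 and AUROC from first principles
#'
#' F1 is the harmonic mean of precision and recall at the threshold (scores
#' at or above the threshold predict positive); AUROC is the Mann-Whitney
#' statistic over all positive/negative pairs with half credit for ties.
#' AUROC requires at least one positive and one negative label.
#'
#' @param labels Logical or 0/1 vector.
#' @param scores Numeric scores.
#' @param threshold Classification threshold for F1 (default 0.5).
#' @return List with `f1` and `auroc`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.logical(labels)
  stopifnot(length(y) == length(scores))
  if (!any(y) || all(y)) {
    stop("compute_metrics: AUROC undefined for single-class labels")
  }
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(y); n_neg <- sum(!y)
  auroc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(f1 = f1, auroc = auroc)
}

#' Percentile bootstrap confidence interval for an evaluation metric
#'
#' Resamples patients (label/score pairs) with replacement; resamples
#' containing a single class are redrawn and the redraw count reported.
#'
#' @param labels,scores Pooled patient-level labels and scores.
#' @param metric `"auroc"`, `"f1"`, or a function `(labels, scores) ->
#'   number`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `n_redrawn`.
#' @export
bootstrap_ci <- function(labels, scores, metric = "auroc", n_boot = 1000L,
                         seed = 1L, conf = 0.95) {
  y <- as.logical(labels)
  fn <- if (is.function(metric)) metric else {
    metric <- match.arg(metric, c("auroc", "f1"))
    function(l, s) compute_metrics(l, s)[[metric]]
  }
  n <- length(y)
  withr::with_seed(seed, {
    vals <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
        redrawn <- redrawn + 1L
      }
      vals[b] <- fn(y[idx], scores[idx])
    }
    q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         names = FALSE)
    list(lower = q[[1]], upper = q[[2]], n_redrawn = redrawn)
  })
}

#' Cross-validated evaluation of a structured-data model
#'
#' Runs patient-level k-fold cross-validation: within each fold the feature
#' selection mask is fitted on training rows only, the classifier is fit on
#' the masked training matrix, and held-out rows are scored. Pooled held-out
#' predictions yield F1/AUROC with bootstrap confidence intervals; per-fold
#' metrics are also returned.
#'
#' @param features Output of [build_feature_matrix()].
#' @param labels Named logical vector over the feature-matrix patients.
#' @param folds Fold assignment from [make_folds()].
#' @param spec A [model_spec()].
#' @param selection Feature-selection scheme `"prevalence"` or `"chi2"`
#'   (or `"none"`).
#' @param selection_param Scheme parameter (see [select_features()]).
#' @param n_boot,seed Bootstrap settings.
#' @return List with `pooled` (tibble patient_id, fold, label, score),
#'   `metrics` (f1, auroc, CIs), `per_fold` tibble.
#' @export
evaluate_structured <- function(features, labels, folds, spec,
                                selection = "prevalence",
                                selection_param = NULL,
                                n_boot = 1000L, seed = 1L) {
  ids <- features$patient_ids
  y <- as.logical(labels[ids])
  stopifnot(!anyNA(y), all(ids %in% names(folds)))
  fold_of <- folds[ids]
  k <- max(fold_of)
  pooled <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    x_tr <- features$matrix[tr, , drop = FALSE]
    mask <- if (identical(selection, "none")) rep(TRUE, ncol(x_tr)) else
      select_features(x_tr, y[tr], scheme = selection, param = selection_param)
    if (!any(mask)) stop("evaluate_structured: selection removed all features")
    s <- fit_predict(spec, x_tr[, mask, drop = FALSE], y[tr],
                     features$matrix[!tr, mask, drop = FALSE])
    pooled[[f]] <- tibble::tibble(patient_id = ids[!tr], fold = f,
                                  label = y[!tr], score = s)
    m <- fold_metrics(y[!tr], s)
    per_fold[[f]] <- tibble::tibble(fold = f, f1 = m$f1, auroc = m$auroc)
  }
  pooled <- dplyr::bind_rows(pooled)
  m <- compute_metrics(pooled$label, pooled$score)
  ci_a <- bootstrap_ci(pooled$label, pooled$score, "auroc", n_boot, seed)
  ci_f <- bootstrap_ci(pooled$label, pooled$score, "f1", n_boot, seed)
  list(pooled = pooled,
       metrics = tibble::tibble(f1 = m$f1, f1_lower = ci_f$lower,
                                f1_upper = ci_f$upper, auroc = m$auroc,
                                auroc_lower = ci_a$lower,
                                auroc_upper = ci_a$upper),
       per_fold = dplyr::bind_rows(per_fold))
}

#' Cross-validated evaluation of the note pipeline
#'
#' Within each fold the scorer is fit on training patients' notes, held-out
#' patients' notes are scored (with chunking), and note scores are aggregated
#' to the patient level by the largest-margin rule. Patients without any
#' eligible note are excluded and counted.
#'
#' @param notes Notes table (already restricted via
#'   [filter_notes_for_prediction()] if desired).
#' @param labels Named logical vector of patient labels.
#' @param folds Fold assignment from [make_folds()].
#' @param scorer_factory Zero-argument function returning a fresh scorer.
#' @param chunking A [chunking_config()].
#' @param threshold Decision threshold.
#' @param n_boot,seed Bootstrap settings.
#' @return Same shape as [evaluate_structured()], plus `n_excluded`.
#' @export
evaluate_notes_pipeline <- function(notes, labels, folds,
                                    scorer_factory = scorer_tf,
                                    chunking = chunking_config(),
                                    threshold = 0.5, n_boot = 1000L,
                                    seed = 1L) {
  ids <- names(folds)
  has_notes <- ids[ids %in% unique(notes$patient_id)]
  n_excluded <- length(ids) - length(has_notes)
  if (length(has_notes) == 0) {
    stop("evaluate_notes_pipeline: no patient has an eligible note")
  }
  k <- max(folds)
  pooled <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- has_notes[folds[has_notes] != f]
    test_ids <- has_notes[folds[has_notes] == f]
    if (length(test_ids) == 0) next
    scorer <- scorer_factory()
    test_notes <- notes[notes$patient_id %in% test_ids, , drop = FALSE]
    scorer$fit(notes[notes$patient_id %in% train_ids, , drop = FALSE],
               labels)
    preds <- score_fitted_notes(test_notes, scorer, chunking, threshold)
    agg <- aggregate_patients(preds, threshold)
    y <- as.logical(labels[agg$patient_id])
    pooled[[f]] <- tibble::tibble(patient_id = agg$patient_id, fold = f,
                                  label = y, score = agg$score)
    m <- fold_metrics(y, agg$score, threshold)
    per_fold[[f]] <- tibble::tibble(fold = f, f1 = m$f1, auroc = m$auroc)
  }
  pooled <- dplyr::bind_rows(pooled)
  m <- compute_metrics(pooled$label, pooled$score, threshold)
  ci_a <- bootstrap_ci(pooled$label, pooled$score, "auroc", n_boot, seed)
  ci_f <- bootstrap_ci(pooled$label, pooled$score, "f1", n_boot, seed)
  list(pooled = pooled,
       metrics = tibble::tibble(f1 = m$f1, f1_lower = ci_f$lower,
                                f1_upper = ci_f$upper, auroc = m$auroc,
                                auroc_lower = ci_a$lower,
                                auroc_upper = ci_a$upper),
       per_fold = dplyr::bind_rows(per_fold),
       n_excluded = n_excluded)
}

# per-fold metrics tolerate degenerate single-class test folds (NA AUROC)
fold_metrics <- function(labels, scores, threshold = 0.5) {
  tryCatch(compute_metrics(labels, scores, threshold),
           error = function(e) list(f1 = NA_real_, auroc = NA_real_))
}

# score already-fitted scorer over notes (no refit)
score_fitted_notes <- function(notes, scorer, chunking, threshold) {
  scores <- vapply(seq_len(nrow(notes)), function(i) {
    tokens <- strsplit(trimws(notes$text[[i]]), "\\s+")[[1]]
    cs <- vapply(chunk_note(tokens, chunking), scorer$score, numeric(1))
    if (any(cs < 0 | cs > 1)) {
      stop("score_notes: scorer returned a score outside [0, 1]")
    }
    margin_reduce(cs, threshold)$score
  }, numeric(1))
  tibble::tibble(note_id = notes$note_id, patient_id = notes$patient_id,
                 note_type = notes$note_type, score = scores)
}

#' Note-type ablation
#'
#' Retrains and evaluates the note pipeline restricted to each note-type
#' group (neurology, communication, EEG report, brain MRI report, head CT
#' report, discharge summary) plus `"all"`, localising where the predictive
#' signal is encoded. Patients without notes of a group are excluded from
#' that group's evaluation and the exclusion count is reported; groups with
#' zero notes are reported as absent (no row).
#'
#' @inheritParams evaluate_notes_pipeline
#' @return Tibble: `group`, `n_patients`, `n_excluded`, `f1`, `f1_lower`,
#'   `f1_upper`, `auroc`, `auroc_lower`, `auroc_upper`.
#' @export
ablate_by_note_type <- function(notes, labels, folds,
                                scorer_factory = scorer_tf,
                                chunking = chunking_config(),
                                threshold = 0.5, n_boot = 1000L, seed = 1L) {
  types <- c("neurology", "communication", "eeg_report", "mri_report",
             "ct_report", "discharge_summary")
  groups <- c(stats::setNames(as.list(types), types), list(all = types))
  rows <- list()
  for (g in names(groups)) {
    sub <- notes[notes$note_type %in% groups[[g]], , drop = FALSE]
    if (nrow(sub) == 0) next
    res <- evaluate_notes_pipeline(sub, labels, folds, scorer_factory,
                                   chunking, threshold, n_boot, seed)
    rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(group = g,
                     n_patients = length(unique(res$pooled$patient_id)),
                     n_excluded = res$n_excluded),
      res$metrics)
  }
  dplyr::bind_rows(rows)
}

#' Run the full comparison experiment
#'
#' Orchestrates the pipeline over a simulated or loaded cohort: inclusion
#' filtering, composite labelling, structured features with both classifier
#' families, and (EMR modality) the note pipeline, each evaluated with
#' patient-level five-fold cross-validation and bootstrap confidence
#' intervals. Sub-label evaluations can be requested in addition to the
#' composite.
#'
#' @param cohort An `ehr_cohort`.
#' @param registry A [code_registry()].
#' @param config An [outcome_config()].
#' @param outcomes Character vector of label columns to evaluate (default
#'   `"composite"`).
#' @param k Folds (default 5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed controlling folds and bootstrap.
#' @param selection_logistic,selection_logistic_param Feature selection for
#'   the elastic-net model (default chi-square top 500).
#' @param selection_xgb,selection_xgb_param Feature selection for the
#'   boosted-trees model (default 1% prevalence).
#' @param note_window_days Latest note date relative to index fed to the
#'   note pipeline (default 7).
#' @return List with `cohort_table`, `labels`, `folds`, and `results` (one
#'   row per pipeline x outcome with F1/AUROC and CIs).
#' @export
run_experiment <- function(cohort, registry = code_registry(),
                           config = outcome_config(),
                           outcomes = "composite", k = 5L, n_boot = 1000L,
                           seed = 1L,
                           selection_logistic = "chi2",
                           selection_logistic_param = 500L,
                           selection_xgb = "prevalence",
                           selection_xgb_param = 0.01,
                           note_window_days = 7L) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  records <- as_patient_records(cohort)
  ct <- build_cohort(records, registry, cohort$modality)
  lab <- label_cohort(records, ct, registry, config)
  if (nrow(lab) < k) stop("run_experiment: fewer included patients than folds")
  feats <- build_feature_matrix(records, ct)
  folds <- make_folds(lab$patient_id, k = k, seed = seed,
                      labels = stats::setNames(lab$composite, lab$patient_id))
  eligible_notes <- filter_notes_for_prediction(
    cohort$notes[cohort$notes$patient_id %in% lab$patient_id, , drop = FALSE],
    ct, note_window_days)

  results <- list()
  for (oc in outcomes) {
    y <- stats::setNames(as.logical(lab[[oc]]), lab$patient_id)
    res_lr <- evaluate_structured(feats, y, folds,
                                  model_spec("elasticnet_logistic"),
                                  selection = selection_logistic,
                                  selection_param = selection_logistic_param,
                                  n_boot = n_boot, seed = seed)
    res_xgb <- evaluate_structured(feats, y, folds,
                                   model_spec("gradient_boosted_trees"),
                                   selection = selection_xgb,
                                   selection_param = selection_xgb_param,
                                   n_boot = n_boot, seed = seed)
    results[[length(results) + 1]] <- dplyr::bind_cols(
      tibble::tibble(pipeline = "elasticnet_logistic",
                     modality = cohort$modality, outcome = oc),
      res_lr$metrics)
    results[[length(results) + 1]] <- dplyr::bind_cols(
      tibble::tibble(pipeline = "gradient_boosted_trees",
                     modality = cohort$modality, outcome = oc),
      res_xgb$metrics)
    if (cohort$modality == "emr" && nrow(eligible_notes) > 0) {
      res_nt <- evaluate_notes_pipeline(eligible_notes, y, folds,
                                        scorer_factory = scorer_tf,
                                        n_boot = n_boot, seed = seed)
      results[[length(results) + 1]] <- dplyr::bind_cols(
        tibble::tibble(pipeline = "notes_tf", modality = cohort$modality,
                       outcome = oc),
        res_nt$metrics)
    }
  }
  list(cohort_table = ct, labels = lab, folds = folds,
       results = dplyr::bind_rows(results))
}
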