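reg <- code_registry()

test_that("chunk starts follow the stride with exact overlaps and full coverage", {
  cfg <- chunking_config()  # 4096 / 512
  toks <- function(n) sprintf("t%d", seq_len(n))

  w <- chunk_note(toks(4000), cfg)
  expect_length(w, 1)
  expect_equal(attr(w, "starts"), 0L)

  w <- chunk_note(toks(5000), cfg)
  expect_equal(attr(w, "starts"), c(0L, 3584L))

  w <- chunk_note(toks(8192), cfg)
  expect_equal(attr(w, "starts"), c(0L, 3584L, 7168L))

  for (n in c(4096, 4097, 5000, 8192, 12288)) {
    tk <- toks(n)
    w <- chunk_note(tk, cfg)
    starts <- attr(w, "starts")
    expect_true(all(diff(starts) == 4096 - 512))
    expect_true(all(lengths(w) <= 4096))
    # exact 512-token overlap between consecutive windows
    if (length(w) > 1) {
      for (i in seq_len(length(w) - 1)) {
        expect_identical(utils::tail(w[[i]], 512), utils::head(w[[i + 1]], 512))
      }
    }
    # removing the overlaps reconstructs the note exactly
    rebuilt <- c(w[[1]], unlist(lapply(w[-1], function(x) x[-(1:512)])))
    expect_identical(rebuilt, tk)
  }

  expect_error(chunk_note(character(0), cfg), "empty")
  expect_error(chunking_config(max_tokens = 100, overlap_tokens = 100),
               "overlap")
})

test_that("medication extraction finds sectioned mentions, aliases, negation", {
  note <- list(note_id = "n1", text =
    "Discharge Medications : 1. levetiracetam 250 mg BID")
  m <- extract_medications(note, reg)
  expect_equal(nrow(m), 1)
  expect_equal(m$name, "levetiracetam")
  expect_equal(m$class, "ASM")
  expect_false(m$negated)
  expect_equal(m$section, "discharge_meds")

  neg <- list(note_id = "n2", text =
    "Medications : patient denies taking levetiracetam currently")
  m <- extract_medications(neg, reg)
  expect_true(m$negated)

  abbr <- list(note_id = "n3", text = "medications : LEV 500 mg daily")
  m <- extract_medications(abbr, reg)
  expect_equal(m$name, "levetiracetam")
  expect_equal(m$surface, "LEV")

  # mention outside any medication section is not emitted
  loose <- list(note_id = "n4", text = "patient tolerated levetiracetam well")
  expect_equal(nrow(extract_medications(loose, reg)), 0)
})

test_that("largest-margin aggregation follows the declared tie rules", {
  a <- aggregate_patient(c(0.9, 0.4))
  expect_true(a$class)
  expect_equal(a$margin, 0.4)

  a <- aggregate_patient(c(0.6, 0.05))
  expect_false(a$class)
  expect_equal(a$margin, 0.45)

  # single score exactly at threshold: positive with margin 0
  a <- aggregate_patient(0.5)
  expect_true(a$class)
  expect_equal(a$margin, 0)

  # tied margins on opposite sides resolve positive
  a <- aggregate_patient(c(0.3, 0.7))
  expect_true(a$class)

  expect_error(aggregate_patient(tibble::tibble(score = numeric())), "empty")
})

test_that("aggregation is invariant to order and duplicated winners", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      s <- round(runif(sample(1:8, 1)), 3)
      base <- aggregate_patient(s)
      perm <- aggregate_patient(sample(s))
      expect_equal(base$class, perm$class)
      expect_equal(base$margin, perm$margin)
      dup <- aggregate_patient(c(s, s[which.max(abs(s - 0.5))]))
      expect_equal(base$class, dup$class)
      expect_equal(base$margin, dup$margin)
    }
  })
})

test_that("note scores reduce chunk scores by the same margin rule", {
  # scorer reads its score off the first token of the chunk
  first_token_scorer <- function() {
    structure(list(fit = function(notes, labels) invisible(NULL),
                   score = function(tokens) as.numeric(tokens[1])),
              class = "note_scorer")
  }
  cfg <- chunking_config(max_tokens = 4, overlap_tokens = 1)
  # chunks start at 0 and 3: first tokens are "0.9" and "0.45"
  txt <- paste(c("0.9", "0", "0", "0.45", "0", "0", "0"), collapse = " ")
  notes <- tibble::tibble(note_id = "n1", patient_id = "P1",
                          note_type = "neurology", date = fx_base, text = txt)
  preds <- score_notes(notes, first_token_scorer(), train_ids = character(0),
                       labels = c(P1 = TRUE), chunking = cfg)
  expect_equal(preds$score, 0.9)

  # constant scorer: every note scores 0.5
  preds <- score_notes(notes, scorer_constant(0.5), train_ids = character(0),
                       labels = c(P1 = TRUE), chunking = cfg)
  expect_equal(preds$score, 0.5)

  # out-of-range scorer violates the contract
  expect_error(
    score_notes(notes, scorer_constant(1.5), train_ids = character(0),
                labels = c(P1 = TRUE), chunking = cfg),
    "outside")
})

test_that("the term-frequency scorer recovers planted text signal", {
  co <- simulate_cohort(sim_config(n_patients = 300, seed = 19,
                                   text_signal_strength = 2,
                                   structured_signal_strength = 0))
  ct <- build_cohort(co, reg)
  lab <- label_cohort(co, ct, reg)
  y <- setNames(lab$composite, lab$patient_id)
  notes <- filter_notes_for_prediction(
    co$notes[co$notes$patient_id %in% lab$patient_id, ], ct)
  ids <- lab$patient_id
  withr::with_seed(3, train <- sample(ids, length(ids) %/% 2))
  test_ids <- setdiff(ids, train)
  sc <- scorer_tf()
  preds <- score_notes(notes[notes$patient_id %in% c(train, test_ids), ],
                       sc, train_ids = train, labels = y)
  eval_preds <- preds[preds$patient_id %in% test_ids, ]
  m <- compute_metrics(y[eval_preds$patient_id], eval_preds$score)
  expect_gt(m$auroc, 0.65)

  # permutation null: with shuffled training labels the signal disappears
  withr::with_seed(4, yperm <- setNames(sample(y), names(y)))
  null_aucs <- vapply(1:5, function(i) {
    withr::with_seed(i, yp <- setNames(sample(y), names(y)))
    sc2 <- scorer_tf()
    p2 <- score_notes(notes, sc2, train_ids = train, labels = yp)
    e2 <- p2[p2$patient_id %in% test_ids, ]
    compute_metrics(y[e2$patient_id], e2$score)$auroc
  }, numeric(1))
  expect_gt(m$auroc, max(null_aucs))
})

test_that("note filtering keeps only notes up to the blanking boundary", {
  notes <- tibble::tibble(note_id = c("n1", "n2", "n3"),
                          patient_id = "P1",
                          date = fx_base + c(0, 7, 30),
                          note_type = "neurology", text = "x")
  ct <- tibble::tibble(patient_id = "P1", index_date = fx_base)
  kept <- filter_notes_for_prediction(notes, ct)
  expect_equal(kept$note_id, c("n1", "n2"))
})
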