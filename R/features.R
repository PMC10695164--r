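#' Pre-index code counts for one patient
#'
#' Counts every observed code in the year before the index event, up to and
#' including the index day itself: window `[index - 365, index]`. Diagnoses,
#' medications and procedures are namespaced in the feature id (`dx:`, `rx:`,
#' `px:`); diagnosis and procedure codes are stored in normalized
#' `DIALECT:VALUE` form. An optional code-to-group mapping (e.g. an
#' ICD-to-PheCode table) collapses raw codes into phenotype groups; the
#' default identity mapping keeps raw codes.
#'
#' @param patient A `patient_record`.
#' @param index Index event from [find_index_event()].
#' @param mapping Optional named character vector mapping feature ids to
#'   group ids.
#' @return Named integer vector of counts (possibly empty).
#' @export
extract_code_counts <- function(patient, index, mapping = NULL) {
  lo <- index$index_date - DAYS_YEAR
  hi <- index$index_date
  ids <- character(0)
  enc <- patient$encounters
  enc <- enc[enc$date >= lo & enc$date <= hi, , drop = FALSE]
  if (nrow(enc) > 0) {
    codes <- unlist(enc$codes, use.names = FALSE)
    pc <- parse_codes(codes)
    ids <- c(ids, paste0("dx:", pc$dialect, ":", pc$value))
  }
  med <- patient$medications
  med <- med[med$date >= lo & med$date <= hi, , drop = FALSE]
  if (nrow(med) > 0) ids <- c(ids, paste0("rx:", tolower(med$drug)))
  prc <- patient$procedures
  prc <- prc[prc$date >= lo & prc$date <= hi, , drop = FALSE]
  if (nrow(prc) > 0) {
    pc <- parse_codes(prc$code)
    ids <- c(ids, paste0("px:", pc$dialect, ":", pc$value))
  }
  if (!is.null(mapping)) {
    mapped <- mapping[ids]
    ids <- ifelse(is.na(mapped), ids, mapped)
  }
  if (length(ids) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Log-normalize code counts
#'
#' `value = min(log(count + 1), 1)` with the natural logarithm: a count of 0
#' maps to 0, a count of 1 to `log 2 ~ 0.693`, and counts of 2 or more clip
#' at 1. Later occurrences of a code therefore contribute decreasingly — the
#' first observation of a code is most informative — and values are bounded
#' in `[0, 1]`.
#'
#' @param counts Nonnegative numeric vector (names preserved).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_counts <- function(counts) {
  if (any(counts < 0)) stop("normalize_counts: counts must be nonnegative")
  pmin(log(counts + 1), 1)
}

#' Build the patient-by-feature design matrix
#'
#' Extracts pre-index counts for every listed patient, fixes the feature
#' vocabulary (sorted union of observed feature ids, unless supplied), and
#' fills a dense matrix of log-normalized values.
#'
#' @param records Named list of `patient_record`s or an `ehr_cohort`.
#' @param cohort_table Output of [build_cohort()]; only included patients are
#'   used.
#' @param vocabulary Optional fixed feature vocabulary (character); features
#'   outside it are dropped, features absent from a patient are 0. When
#'   `NULL` the vocabulary is built from these patients (fit time) and must
#'   be reused at transform time.
#' @param mapping Optional code-to-group mapping passed to
#'   [extract_code_counts()].
#' @return List with `matrix` (patients x features, dimnames set),
#'   `vocabulary`, `patient_ids`.
#' @export
build_feature_matrix <- function(records, cohort_table, vocabulary = NULL,
                                 mapping = NULL) {
  if (inherits(records, "ehr_cohort")) records <- as_patient_records(records)
  inc <- cohort_table[cohort_table$included, , drop = FALSE]
  counts <- lapply(seq_len(nrow(inc)), function(i) {
    idx <- list(index_date = inc$index_date[[i]])
    extract_code_counts(records[[inc$patient_id[[i]]]], idx, mapping)
  })
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  }
  m <- matrix(0, nrow = nrow(inc), ncol = length(vocabulary),
              dimnames = list(inc$patient_id, vocabulary))
  for (i in seq_along(counts)) {
    ct <- counts[[i]]
    ct <- ct[names(ct) %in% vocabulary]
    if (length(ct) > 0) m[i, names(ct)] <- normalize_counts(ct)
  }
  list(matrix = m, vocabulary = vocabulary, patient_ids = inc$patient_id)
}

#' One-degree-of-freedom chi-square scores on presence/absence
#'
#' For each feature, binarizes to presence (value > 0) and computes the
#' chi-square statistic of the 2x2 presence-by-label table without continuity
#' correction. Degenerate features (all present or all absent) score 0.
#'
#' @param matrix Numeric patients-by-features matrix.
#' @param labels Logical or 0/1 vector, one per row.
#' @return Numeric vector of scores, one per column.
#' @export
chi2_scores <- function(matrix, labels) {
  y <- as.logical(labels)
  n <- nrow(matrix)
  stopifnot(length(y) == n)
  pres <- matrix > 0
  n1 <- sum(y)
  a <- colSums(pres & y)        # present & positive
  c1 <- colSums(pres) - a       # present & negative
  b <- n1 - a                   # absent & positive
  d <- (n - n1) - c1            # absent & negative
  num <- n * (a * d - b * c1)^2
  den <- (a + b) * (c1 + d) * (a + c1) * (b + d)
  out <- ifelse(den == 0, 0, num / den)
  as.numeric(out)
}

#' Select features by prevalence or chi-square ranking
#'
#' Two schemes from the structured-data pipeline: `prevalence` keeps features
#' nonzero in at least `param` fraction of the training rows (default 0.01,
#' i.e. present in at least 1% of the data); `chi2` keeps the `param`
#' highest-scoring features (default 500, capped at the number available) by
#' the one-degree-of-freedom chi-square statistic on presence/absence versus
#' the label, ties broken by vocabulary order. Masks must be computed on
#' training rows only and then applied unchanged to held-out rows.
#'
#' @param matrix Training patients-by-features matrix.
#' @param labels Training labels (required for `chi2`).
#' @param scheme `"prevalence"` or `"chi2"`.
#' @param param Fraction in (0, 1] for `prevalence`; positive integer count
#'   for `chi2`.
#' @return Logical mask over columns.
#' @export
select_features <- function(matrix, labels = NULL,
                            scheme = c("prevalence", "chi2"), param = NULL) {
  scheme <- match.arg(scheme)
  p <- ncol(matrix)
  if (scheme == "prevalence") {
    if (is.null(param)) param <- 0.01
    if (param <= 0 || param > 1) {
      stop("select_features: prevalence param must be in (0, 1]")
    }
    colMeans(matrix > 0) >= param
  } else {
    if (is.null(param)) param <- 500L
    if (param < 1) stop("select_features: chi2 param must be >= 1")
    if (is.null(labels)) stop("select_features: chi2 scheme requires labels")
    k <- min(as.integer(param), p)
    sc <- chi2_scores(matrix, labels)
    keep_idx <- order(-sc, seq_len(p))[seq_len(k)]
    mask <- rep(FALSE, p)
    mask[keep_idx] <- TRUE
    mask
  }
}
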