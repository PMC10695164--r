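#' Code-set registry for seizure phenotyping
#'
#' A registry bundles the named sets of diagnosis/procedure code prefixes and
#' the antiseizure-medication (ASM) lexicon that the cohort, outcome and
#' feature stages consult. Codes carry an explicit dialect tag
#' (`"ICD9"`, `"ICD10"`, `"CPT"`) and are matched by normalized prefix:
#' dots stripped, uppercased, so `"345.**"` is the prefix `"345"` and matches
#' any ICD-9 code starting `345`, and `"G40.*"` is `"G40"`.
#'
#' The default registry encodes the epilepsy-specific rule (ICD-9 `345.*` or
#' ICD-10 `G40.*`, explicitly excluding convulsions `780.*` / `R56.*`), a
#' broad seizure-like set used only for index-event detection, a status
#' epilepticus set, diagnostic-testing and epilepsy-procedure sets, and an ASM
#' lexicon with adjunctive-use flags and common abbreviations (e.g. `LEV` for
#' levetiracetam). Every set is user-replaceable: supply your own prefix
#' tables to work with site-specific code lists.
#'
#' @param sets Named list of data frames with columns `dialect` and `prefix`.
#'   Missing names fall back to the package defaults.
#' @param asm_lexicon Data frame with columns `name`, `class`, `adjunctive`.
#' @param asm_aliases Data frame with columns `alias`, `name` mapping
#'   abbreviations and misspellings to lexicon names.
#' @return An object of class `code_registry`.
#' @export
code_registry <- function(sets = list(), asm_lexicon = NULL, asm_aliases = NULL) {
  defaults <- default_code_sets()
  for (nm in names(sets)) {
    s <- sets[[nm]]
    stopifnot(is.data.frame(s), all(c("dialect", "prefix") %in% names(s)))
    s$prefix <- normalize_code_value(s$prefix)
    defaults[[nm]] <- s[c("dialect", "prefix")]
  }
  if (is.null(asm_lexicon)) asm_lexicon <- default_asm_lexicon()
  if (is.null(asm_aliases)) asm_aliases <- default_asm_aliases()
  # epilepsy-specific and convulsion sets must never overlap: the outcome
  # definition relies on convulsion codes being excluded
  ep <- defaults$epilepsy_specific
  cv <- defaults$convulsion_excluded
  clash <- merge(ep, cv, by = c("dialect", "prefix"))
  if (nrow(clash) > 0) {
    stop("registry invalid: epilepsy_specific and convulsion_excluded share prefixes: ",
         paste(clash$prefix, collapse = ", "))
  }
  structure(
    list(sets = defaults, asm_lexicon = asm_lexicon, asm_aliases = asm_aliases),
    class = "code_registry"
  )
}

#' @export
print.code_registry <- function(x, ...) {
  cat("<code_registry>\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-24s %3d prefixes\n", nm, nrow(x$sets[[nm]])))
  }
  cat(sprintf("  asm_lexicon              %3d drugs (%d adjunctive), %d aliases\n",
              nrow(x$asm_lexicon), sum(x$asm_lexicon$adjunctive),
              nrow(x$asm_aliases)))
  invisible(x)
}

default_code_sets <- function() {
  set <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(dialect = m[, 1], prefix = normalize_code_value(m[, 2]),
               stringsAsFactors = FALSE)
  }
  list(
    # broad index-event definition: epilepsy, convulsions, febrile seizures
    seizure_like_broad = set(
      "ICD9", "345", "ICD9", "780.3",
      "ICD10", "G40", "ICD10", "R56"
    ),
    # strict outcome codes: 345.** / G40.* only
    epilepsy_specific = set(
      "ICD9", "345",
      "ICD10", "G40"
    ),
    convulsion_excluded = set(
      "ICD9", "780",
      "ICD10", "R56"
    ),
    # status epilepticus: ICD-9 petit/grand mal status; ICD-10-CM "with
    # status epilepticus" codes (…01/…11 patterns given as full-code prefixes)
    status_epilepticus = set(
      "ICD9", "345.2", "ICD9", "345.3",
      "ICD10", "G40.901", "ICD10", "G40.911",
      "ICD10", "G40.401", "ICD10", "G40.411",
      "ICD10", "G40.A11", "ICD10", "G40.B11"
    ),
    # seizure-related (broader than epilepsy-specific): used for the
    # utilisation / inpatient / diagnostics criteria
    seizure_related = set(
      "ICD9", "345", "ICD9", "780.3",
      "ICD10", "G40", "ICD10", "R56"
    ),
    # diagnostic testing orders: routine/extended EEG, brain MRI, head CT
    diagnostic_testing = set(
      "CPT", "95819", "CPT", "95816", "CPT", "95950", "CPT", "95951",
      "CPT", "70551", "CPT", "70552", "CPT", "70450"
    ),
    # epilepsy-directed procedures: long-term EEG monitoring, VNS implant,
    # invasive monitoring / resection
    epilepsy_procedures = set(
      "CPT", "95951", "CPT", "95954", "CPT", "64568", "CPT", "61534",
      "CPT", "61537"
    )
  )
}

default_asm_lexicon <- function() {
  # first-line treatments plus ASMs indicated for adjunctive use
  tibble::tribble(
    ~name,            ~class, ~adjunctive,
    "levetiracetam",  "ASM",  FALSE,
    "valproate",      "ASM",  FALSE,
    "lamotrigine",    "ASM",  FALSE,
    "oxcarbazepine",  "ASM",  FALSE,
    "carbamazepine",  "ASM",  FALSE,
    "topiramate",     "ASM",  FALSE,
    "ethosuximide",   "ASM",  FALSE,
    "phenobarbital",  "ASM",  FALSE,
    "phenytoin",      "ASM",  FALSE,
    "zonisamide",     "ASM",  FALSE,
    "gabapentin",     "ASM",  FALSE,
    "clobazam",       "ASM",  TRUE,
    "lacosamide",     "ASM",  TRUE,
    "perampanel",     "ASM",  TRUE,
    "rufinamide",     "ASM",  TRUE,
    "cannabidiol",    "ASM",  TRUE
  )
}

default_asm_aliases <- function() {
  tibble::tribble(
    ~alias,           ~name,
    "lev",            "levetiracetam",
    "keppra",         "levetiracetam",
    "levatiracetam",  "levetiracetam",  # common misspelling
    "vpa",            "valproate",
    "depakote",       "valproate",
    "ltg",            "lamotrigine",
    "oxc",            "oxcarbazepine",
    "cbz",            "carbamazepine",
    "tpm",            "topiramate",
    "phb",            "phenobarbital",
    "pht",            "phenytoin",
    "zns",            "zonisamide"
  )
}

# ---- code normalization and matching ------------------------------------

normalize_code_value <- function(code) {
  toupper(gsub(".", "", code, fixed = TRUE))
}

#' Split tagged codes into dialect and normalized value
#'
#' Codes throughout the package are strings of the form `"DIALECT:code"`,
#' e.g. `"ICD10:G40.311"`. Normalization strips dots and uppercases the value
#' so prefix matching is dialect-aware and punctuation-insensitive.
#'
#' @param codes Character vector of tagged codes.
#' @return Data frame with columns `dialect` and `value` (normalized).
#' @export
parse_codes <- function(codes) {
  if (length(codes) == 0) {
    return(data.frame(dialect = character(), value = character()))
  }
  bad <- !grepl(":", codes, fixed = TRUE)
  if (any(bad)) {
    stop("code without a dialect tag: ", codes[which(bad)[1]])
  }
  pos <- regexpr(":", codes, fixed = TRUE)
  data.frame(
    dialect = toupper(substr(codes, 1, pos - 1)),
    value = normalize_code_value(substr(codes, pos + 1, nchar(codes))),
    stringsAsFactors = FALSE
  )
}

#' Test tagged codes against a named registry set
#'
#' @param codes Character vector of tagged codes (`"ICD10:G40.9"`).
#' @param registry A [code_registry()].
#' @param set_name Name of the prefix set to match against.
#' @return Logical vector, `TRUE` where the code's dialect matches and its
#'   normalized value starts with one of the set's prefixes.
#' @export
code_in_set <- function(codes, registry, set_name) {
  stopifnot(inherits(registry, "code_registry"))
  set <- registry$sets[[set_name]]
  if (is.null(set)) stop("unknown registry set: ", set_name)
  if (length(codes) == 0) return(logical(0))
  parsed <- parse_codes(codes)
  known <- c("ICD9", "ICD10", "CPT")
  if (any(!parsed$dialect %in% known)) {
    stop("unknown code dialect tag: ",
         parsed$dialect[which(!parsed$dialect %in% known)[1]])
  }
  out <- logical(length(codes))
  for (i in seq_len(nrow(set))) {
    out <- out | (parsed$dialect == set$dialect[i] &
                    startsWith(parsed$value, set$prefix[i]))
  }
  out
}

#' Resolve a medication name through the ASM lexicon
#'
#' Lowercases the surface form and resolves aliases/abbreviations (e.g.
#' `"LEV"` to levetiracetam). Names absent from the lexicon resolve to `NA`.
#'
#' @param names Character vector of drug surface forms.
#' @param registry A [code_registry()].
#' @return Data frame with columns `name` (normalized, `NA` if unknown),
#'   `class`, `adjunctive`.
#' @export
resolve_drug <- function(names, registry) {
  stopifnot(inherits(registry, "code_registry"))
  lex <- registry$asm_lexicon
  ali <- registry$asm_aliases
  low <- tolower(trimws(names))
  via_alias <- ali$name[match(low, ali$alias)]
  resolved <- ifelse(low %in% lex$name, low, via_alias)
  idx <- match(resolved, lex$name)
  data.frame(
    name = resolved,
    class = lex$class[idx],
    adjunctive = lex$adjunctive[idx],
    stringsAsFactors = FALSE
  )
}
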