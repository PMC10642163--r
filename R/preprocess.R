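#' Clean, tokenise and stem free text
#'
#' Applies the text-cleansing pipeline used for both referral text and CPC
#' criteria text: lowercase, drop everything that is not a letter
#' (special characters, digits, punctuation become token breaks), split on
#' whitespace, remove stopwords, then Porter-stem the remaining tokens.
#' Token order is preserved.
#'
#' @param text A single character string (empty allowed).
#' @param stopwords Character vector of stopwords to drop (compared before
#'   stemming). Defaults to [default_stopwords()].
#' @param stem Stem tokens with [porter_stem()]? Default `TRUE`.
#' @return Character vector of cleaned tokens (possibly empty).
#' @examples
#' clean_tokens("Hearing loss, 3 months!!")
#' @export
clean_tokens <- function(text, stopwords = default_stopwords(), stem = TRUE) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% stopwords]
  if (stem && length(toks)) toks <- porter_stem(toks)
  toks
}

#' Entity categories and types retained from medical NER output
#'
#' The whitelist of (category, type) pairs kept when harvesting medical
#' terms from entity files: diagnosis names, generic and brand medication
#' names, treatment and procedure names, and anatomical direction terms.
#'
#' @return A data.frame with columns `category` and `type`.
#' @export
entity_whitelist <- function() {
  data.frame(
    category = c("Medical_Condition", "Medication", "Medication",
                 "Test_Treatment_Procedure", "Test_Treatment_Procedure",
                 "Anatomy"),
    type = c("DX_Name", "Generic_Name", "Brand_Name",
             "Treatment_Name", "Procedure_Name", "Direction"),
    stringsAsFactors = FALSE
  )
}

.as_entity_df <- function(entities) {
  if (is.null(entities) || NROW(entities) == 0L) {
    return(data.frame(text = character(0), category = character(0),
                      type = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(entities),
            all(c("text", "category", "type", "score") %in% names(entities)))
  if (any(entities$score < 0 | entities$score > 1, na.rm = TRUE)) {
    stop("entity scores must lie in [0, 1]")
  }
  entities
}

#' Filter medical entities and return their cleaned tokens
#'
#' Keeps entities whose confidence score is greater than or equal to
#' `threshold` (boundary inclusive) and whose (category, type) pair is in
#' the allowed set, then cleans and stems their text, concatenated in
#' input order.
#'
#' @param entities data.frame with columns `text`, `category`, `type`,
#'   `score` (scores in `[0, 1]`).
#' @param threshold Minimum confidence score, in `[0, 1]`. Default 0.5.
#' @param allowed data.frame of allowed (category, type) pairs; defaults
#'   to [entity_whitelist()].
#' @param stopwords Stopword set forwarded to [clean_tokens()].
#' @return Character vector of cleaned, stemmed tokens.
#' @export
filter_entities <- function(entities, threshold = 0.5,
                            allowed = entity_whitelist(),
                            stopwords = default_stopwords()) {
  stopifnot(threshold >= 0, threshold <= 1)
  entities <- .as_entity_df(entities)
  if (nrow(entities) == 0L) return(character(0))
  pair <- paste(entities$category, entities$type, sep = "\r")
  ok_pair <- pair %in% paste(allowed$category, allowed$type, sep = "\r")
  keep <- entities$score >= threshold & ok_pair
  kept <- entities$text[keep]
  if (!length(kept)) return(character(0))
  unlist(lapply(kept, clean_tokens, stopwords = stopwords), use.names = FALSE)
}

#' Deterministic dictionary-based entity extraction
#'
#' A pluggable, fully deterministic stand-in for an external medical NER
#' service: scans `text` for case-insensitive occurrences of lexicon
#' terms, longest match first, keeping only non-overlapping spans. Every
#' match is reported with confidence score 1.0. Any extractor producing
#' the same record shape can be substituted.
#'
#' @param text A single character string.
#' @param lexicon data.frame with columns `term`, `category`, `type`.
#' @return data.frame of entity records (`text`, `category`, `type`,
#'   `score`), ordered by match position.
#' @export
extract_entities_lexicon <- function(text, lexicon) {
  stopifnot(length(text) == 1L, is.data.frame(lexicon), nrow(lexicon) > 0L,
            all(c("term", "category", "type") %in% names(lexicon)))
  low <- tolower(text)
  n <- nchar(low)
  occupied <- logical(n)
  hits <- list()
  ord <- order(-nchar(lexicon$term))
  for (k in ord) {
    term <- tolower(lexicon$term[k])
    if (!nzchar(term)) next
    m <- gregexpr(term, low, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (start in as.integer(m)) {
      span <- start:(start + nchar(term) - 1L)
      if (any(occupied[span])) next
      occupied[span] <- TRUE
      hits[[length(hits) + 1L]] <- data.frame(
        text = substr(text, start, start + nchar(term) - 1L),
        category = lexicon$category[k], type = lexicon$type[k],
        score = 1.0, start = start, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(text = character(0), category = character(0),
                      type = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start), c("text", "category", "type", "score")]
  rownames(out) <- NULL
  out
}

#' Age in completed years
#'
#' @param dob,at Dates (coerced with [as.Date()]).
#' @return Integer vector of completed years between `dob` and `at`.
#' @export
age_completed_years <- function(dob, at) {
  dob <- as.Date(dob)
  at <- as.Date(at)
  if (any(at < dob)) stop("submission date precedes date of birth")
  d <- as.POSIXlt(dob)
  a <- as.POSIXlt(at)
  age <- a$year - d$year
  before_birthday <- (a$mon < d$mon) | (a$mon == d$mon & a$mday < d$mday)
  as.integer(age - before_birthday)
}

#' Resolve a referral's age group
#'
#' Computes the patient's age in completed years at the referral's
#' submission date; ages strictly below the cutoff are paediatric, the
#' cutoff itself and above are adult. The clinical default cutoff is 16
#' years (a patient on their 16th birthday is adult).
#'
#' @param date_of_birth,submission_date Dates.
#' @param cutoff_years Integer cutoff in years, default 16.
#' @return Character vector, `"adult"` or `"paediatric"`.
#' @export
age_group <- function(date_of_birth, submission_date, cutoff_years = 16L) {
  age <- age_completed_years(date_of_birth, submission_date)
  ifelse(age < cutoff_years, "paediatric", "adult")
}

#' Read a referral table from CSV or JSON-lines
#'
#' Expected columns: `referral_id`, `text`, `dob` (ISO-8601), `submitted`
#' (ISO-8601), `cpc_label`, `category`, `lodgment`. Missing optional
#' columns are filled with `NA`.
#'
#' @param path File path (`.csv`, `.jsonl`/`.ndjson`).
#' @return data.frame of referrals with `Date` columns `dob`, `submitted`.
#' @export
read_referrals <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      obj <- jsonlite::fromJSON(l)
      obj <- lapply(obj, function(v) if (is.null(v)) NA else v)
      as.data.frame(obj, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("referral_id", "text", "dob", "submitted")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("referral table is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (opt in c("cpc_label", "category", "lodgment")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  df$referral_id <- as.character(df$referral_id)
  df$dob <- as.Date(df$dob)
  df$submitted <- as.Date(df$submitted)
  df$category <- suppressWarnings(as.integer(df$category))
  if (any(!is.na(df$category) & !df$category %in% .categories)) {
    stop("historical categories must be 1, 2 or 3")
  }
  df
}

#' Read medical-entity JSON files
#'
#' Accepts either a single-referral file of the shape
#' `{"Entities": [{"Text", "Category", "Type", "Score"}, ...]}` or a
#' multi-referral file keyed by referral id,
#' `{"<id>": {"Entities": [...]}, ...}`.
#'
#' @param path Path to a JSON entity file.
#' @return A named list of entity data.frames (one per referral id), or a
#'   list of length one named `""` for single-referral files.
#' @export
read_entities <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_one <- function(obj) {
    ents <- obj$Entities
    if (is.null(ents) || !length(ents)) {
      return(.as_entity_df(NULL))
    }
    do.call(rbind, lapply(ents, function(e) {
      data.frame(text = as.character(e$Text),
                 category = as.character(e$Category),
                 type = as.character(e$Type),
                 score = as.numeric(e$Score), stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(raw$Entities)) {
    return(setNames(list(parse_one(raw)), ""))
  }
  lapply(raw, parse_one)
}

#' Attach medical terms and age groups to a referral table
#'
#' Derives each referral's medical-term token sequence: from its entity
#' records when available (via [filter_entities()]), else from a lexicon
#' scan of the raw text when a lexicon is supplied, else directly from the
#' cleaned raw text. Referrals whose entity path yields no tokens fall
#' back to the cleaned raw text and are flagged `degraded` so similarity
#' is never computed on an empty document when any text exists.
#'
#' @param referrals data.frame as returned by [read_referrals()].
#' @param entities Optional named list of entity data.frames keyed by
#'   `referral_id`.
#' @param lexicon Optional lexicon data.frame for
#'   [extract_entities_lexicon()].
#' @param score_threshold Entity confidence cutoff, default 0.5.
#' @param allowed Allowed entity (category, type) pairs.
#' @param stopwords Stopword set.
#' @param cutoff_years Age-group cutoff, default 16.
#' @return The input data.frame with list-column `medical_terms`, logical
#'   column `degraded` and character column `age_group` added.
#' @export
prepare_referrals <- function(referrals, entities = NULL, lexicon = NULL,
                              score_threshold = 0.5,
                              allowed = entity_whitelist(),
                              stopwords = default_stopwords(),
                              cutoff_years = 16L) {
  stopifnot(is.data.frame(referrals), nrow(referrals) > 0L)
  n <- nrow(referrals)
  terms <- vector("list", n)
  degraded <- logical(n)
  for (i in seq_len(n)) {
    id <- referrals$referral_id[i]
    ents <- if (!is.null(entities)) entities[[id]] else NULL
    if (is.null(ents) && !is.null(lexicon)) {
      ents <- extract_entities_lexicon(referrals$text[i], lexicon)
    }
    tk <- if (!is.null(ents)) {
      filter_entities(ents, threshold = score_threshold, allowed = allowed,
                      stopwords = stopwords)
    } else {
      character(0)
    }
    if (!length(tk)) {
      tk <- clean_tokens(referrals$text[i], stopwords = stopwords)
      degraded[i] <- !is.null(ents)
    }
    terms[[i]] <- tk
  }
  referrals$medical_terms <- terms
  referrals$degraded <- degraded
  referrals$age_group <- age_group(referrals$dob, referrals$submitted,
                                   cutoff_years = cutoff_years)
  referrals
}
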