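#' Construct a single CPC definition
#'
#' A CPC (Clinical Prioritisation Criteria) definition describes one
#' clinical condition for one age group, carrying up to three text
#' representations (`criteria_words`: the cleaned criteria document text;
#' `medical_terms`: NER-extracted terms; `keywords`: clinician-curated
#' keywords), each split into token sequences for urgency categories 1, 2
#' and 3. Some CPCs mandate a single category for every referral (for
#' example head and neck mass is always category 1); those carry
#' `fixed_category`.
#'
#' @param cpc_id Unique identifier within an age group.
#' @param age_group `"adult"` or `"paediatric"`.
#' @param condition_name Free-text condition name (matched against raw
#'   referral CPC labels after normalisation).
#' @param representations Named list; names among `criteria_words`,
#'   `medical_terms`, `keywords`; each element a list with elements
#'   `"1"`, `"2"`, `"3"` holding character token vectors (missing or
#'   empty categories allowed, but each representation must have at least
#'   one non-empty category).
#' @param fixed_category Optional category in `1:3` forced for all
#'   referrals under this CPC.
#' @return An object of class `cpc_definition`.
#' @export
cpc_definition <- function(cpc_id, age_group, condition_name,
                           representations, fixed_category = NULL) {
  stopifnot(is.character(cpc_id), length(cpc_id) == 1L, nzchar(cpc_id))
  if (!age_group %in% .age_groups) {
    stop("age_group must be one of: ", paste(.age_groups, collapse = ", "),
         " (entry '", cpc_id, "')")
  }
  stopifnot(is.character(condition_name), length(condition_name) == 1L)
  if (!is.list(representations) || is.null(names(representations)) ||
      !length(representations)) {
    stop("representations must be a non-empty named list (entry '",
         cpc_id, "')")
  }
  bad <- setdiff(names(representations), .rep_names)
  if (length(bad)) {
    stop("unknown representation(s) ", paste(bad, collapse = ", "),
         " in entry '", cpc_id, "'")
  }
  reps <- lapply(representations, function(rep) {
    units <- lapply(as.character(.categories), function(cat) {
      u <- rep[[cat]]
      if (is.null(u)) character(0) else as.character(u)
    })
    names(units) <- as.character(.categories)
    units
  })
  nonempty <- vapply(reps, function(rep) any(lengths(rep) > 0L), logical(1))
  if (any(!nonempty)) {
    stop("representation(s) ",
         paste(names(reps)[!nonempty], collapse = ", "),
         " of entry '", cpc_id, "' have no non-empty category unit")
  }
  if (!is.null(fixed_category)) {
    fixed_category <- as.integer(fixed_category)
    if (!fixed_category %in% .categories) {
      stop("fixed_category of entry '", cpc_id, "' must be 1, 2 or 3")
    }
  }
  structure(
    list(cpc_id = cpc_id, age_group = age_group,
         condition_name = condition_name, representations = reps,
         fixed_category = fixed_category),
    class = "cpc_definition"
  )
}

#' Assemble CPC definitions into a catalog
#'
#' @param entries List of [cpc_definition()] objects. `cpc_id`s must be
#'   unique within each age group.
#' @return An object of class `cpc_catalog` with components `entries`,
#'   `adult_count` and `paediatric_count`.
#' @export
cpc_catalog <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0L)
  ok <- vapply(entries, inherits, logical(1), "cpc_definition")
  if (any(!ok)) stop("all catalog entries must be cpc_definition objects")
  ids <- vapply(entries, `[[`, character(1), "cpc_id")
  ags <- vapply(entries, `[[`, character(1), "age_group")
  key <- paste(ags, ids)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate cpc_id within an age group: ",
         paste(dup, collapse = "; "))
  }
  structure(
    list(entries = entries,
         adult_count = sum(ags == "adult"),
         paediatric_count = sum(ags == "paediatric")),
    class = "cpc_catalog"
  )
}

#' @export
print.cpc_catalog <- function(x, ...) {
  cat("<cpc_catalog>", x$adult_count, "adult,", x$paediatric_count,
      "paediatric CPC definitions\n")
  invisible(x)
}

#' List catalog entries for an age group
#'
#' @param catalog A [cpc_catalog()].
#' @param age_group `"adult"` or `"paediatric"`.
#' @return List of `cpc_definition` objects, ordered by ascending
#'   `cpc_id`.
#' @export
catalog_entries <- function(catalog, age_group) {
  stopifnot(inherits(catalog, "cpc_catalog"), age_group %in% .age_groups)
  ents <- Filter(function(e) e$age_group == age_group, catalog$entries)
  ids <- vapply(ents, `[[`, character(1), "cpc_id")
  ents[order(ids)]
}

.get_cpc <- function(catalog, cpc_id, age_group) {
  for (e in catalog$entries) {
    if (e$age_group == age_group && e$cpc_id == cpc_id) return(e)
  }
  stop("unknown cpc_id '", cpc_id, "' for age group '", age_group, "'")
}

#' Retrieve CPC text in a representation
#'
#' Returns a CPC's text either as one combined token sequence (the three
#' category units concatenated in category order 1, 2, 3 — the unit used
#' for CPC prediction) or as the per-category map (used for category
#' prediction). The concatenation order is pinned because the Levenshtein
#' metric operates on joined text and is order-sensitive.
#'
#' @param catalog A [cpc_catalog()].
#' @param cpc_id,age_group Identify the entry.
#' @param representation One of `criteria_words`, `medical_terms`,
#'   `keywords`.
#' @param unit `"combined"` (default) or `"per_category"`.
#' @return A character token vector, or a named list of three token
#'   vectors for `unit = "per_category"`.
#' @export
cpc_text <- function(catalog, cpc_id, age_group, representation,
                     unit = c("combined", "per_category")) {
  unit <- match.arg(unit)
  stopifnot(representation %in% .rep_names)
  e <- .get_cpc(catalog, cpc_id, age_group)
  rep <- e$representations[[representation]]
  if (is.null(rep)) {
    stop("entry '", cpc_id, "' has no '", representation,
         "' representation")
  }
  if (unit == "per_category") return(rep)
  unlist(rep[as.character(.categories)], use.names = FALSE)
}

.normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Validate a raw CPC label against the catalog
#'
#' Checks whether a referral's raw CPC label names a catalogued condition
#' for its age group. Matching is exact after normalisation (lowercase,
#' punctuation stripped, whitespace collapsed); no fuzzy matching is
#' attempted, so an unrecognised label simply routes the referral to CPC
#' prediction rather than silently re-labelling it.
#'
#' @param raw_label Character label (may be empty or `NA`).
#' @param catalog A [cpc_catalog()].
#' @param age_group `"adult"` or `"paediatric"`.
#' @return The matching `cpc_id`, or `NA_character_` if none.
#' @export
validate_cpc_label <- function(raw_label, catalog, age_group) {
  stopifnot(inherits(catalog, "cpc_catalog"), age_group %in% .age_groups)
  if (is.null(raw_label) || length(raw_label) != 1L || is.na(raw_label) ||
      !nzchar(trimws(raw_label))) {
    return(NA_character_)
  }
  target <- .normalize_label(raw_label)
  if (!nzchar(target)) return(NA_character_)
  for (e in catalog_entries(catalog, age_group)) {
    if (.normalize_label(e$condition_name) == target) return(e$cpc_id)
  }
  NA_character_
}

.def_to_json_list <- function(e) {
  reps <- lapply(e$representations, function(rep) {
    lapply(rep, function(u) as.list(u))
  })
  list(
    cpc_id = jsonlite::unbox(e$cpc_id),
    condition_name = jsonlite::unbox(e$condition_name),
    fixed_category = if (is.null(e$fixed_category)) NULL else
      jsonlite::unbox(e$fixed_category),
    representations = reps
  )
}

#' Write a CPC catalog to JSON
#'
#' @param catalog A [cpc_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "cpc_catalog"))
  out <- list(adult = list(), paediatric = list())
  for (ag in .age_groups) {
    out[[ag]] <- lapply(catalog_entries(catalog, ag), .def_to_json_list)
  }
  jsonlite::write_json(out, path, null = "null", digits = NA)
  invisible(path)
}

#' Load a CPC catalog from JSON
#'
#' The file must have top level `{"adult": [...], "paediatric": [...]}`,
#' each entry carrying `cpc_id`, `condition_name`, optional
#' `fixed_category` and a `representations` map of per-category token
#' arrays.
#'
#' @param path Path to a catalog JSON file.
#' @return A validated [cpc_catalog()].
#' @export
load_catalog <- function(path) {
  stopifnot(file.exists(path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse catalog file '", path, "': ",
                         conditionMessage(e))
                  })
  entries <- list()
  for (ag in intersect(names(raw), .age_groups)) {
    for (k in seq_along(raw[[ag]])) {
      obj <- raw[[ag]][[k]]
      if (is.null(obj$cpc_id) || is.null(obj$condition_name) ||
          is.null(obj$representations)) {
        stop("malformed catalog entry #", k, " in '", ag,
             "': cpc_id, condition_name and representations are required")
      }
      reps <- lapply(obj$representations, function(rep) {
        lapply(rep, function(u) unlist(u, use.names = FALSE))
      })
      entries[[length(entries) + 1L]] <- cpc_definition(
        cpc_id = as.character(obj$cpc_id), age_group = ag,
        condition_name = as.character(obj$condition_name),
        representations = reps,
        fixed_category = obj$fixed_category
      )
    }
  }
  cpc_catalog(entries)
}
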