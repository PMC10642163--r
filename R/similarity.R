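.term_counts <- function(tokens) {
  if (!length(tokens)) return(numeric(0))
  tab <- table(tokens)
  setNames(as.numeric(tab), names(tab))
}

.aligned_counts <- function(a, b) {
  ta <- .term_counts(a)
  tb <- .term_counts(b)
  terms <- union(names(ta), names(tb))
  va <- setNames(numeric(length(terms)), terms)
  vb <- va
  va[names(ta)] <- ta
  vb[names(tb)] <- tb
  list(a = va, b = vb)
}

#' Cosine similarity of two token sequences
#'
#' Both sequences are turned into term-frequency vectors over the union
#' vocabulary; the result is the dot product over the product of norms,
#' in `[0, 1]`. Defined as 0 when either sequence is empty.
#'
#' @param a,b Character token vectors.
#' @return Numeric scalar in `[0, 1]`.
#' @export
cosine_sim <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  v <- .aligned_counts(a, b)
  num <- sum(v$a * v$b)
  den <- sqrt(sum(v$a^2)) * sqrt(sum(v$b^2))
  if (den == 0) return(0)
  num / den
}

#' Euclidean distance of two token sequences
#'
#' Root sum of squared term-count differences over the union vocabulary
#' of the two raw frequency vectors (no weighting, no length
#' normalisation).
#'
#' @param a,b Character token vectors.
#' @return Non-negative numeric scalar.
#' @export
euclidean_dist <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  v <- .aligned_counts(a, b)
  sqrt(sum((v$a - v$b)^2))
}

#' Jaccard similarity of two token sets
#'
#' The ratio of shared distinct tokens to the total distinct tokens in
#' both sequences. Defined as 0 when both are empty.
#'
#' @param a,b Character token vectors (duplicates ignored).
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_sim <- function(a, b) {
  sa <- unique(a)
  sb <- unique(b)
  u <- union(sa, sb)
  if (!length(u)) return(0)
  length(intersect(sa, sb)) / length(u)
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions turning `a` into `b`, computed with the standard
#' dynamic-programming matrix (compiled kernel). Vectorised with
#' recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of edit distances.
#' @export
levenshtein_dist <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) > 0, length(b) > 0)
  .lev_dist_cpp(a, b)
}

#' Normalised Levenshtein distance
#'
#' Divides the edit distance by a length-based maximum so values are
#' comparable across string lengths. `max_len` (the default) divides by
#' `max(nchar(a), nchar(b))`, the true maximum possible edit distance,
#' giving values in `[0, 1]`; `sum_len` divides by
#' `nchar(a) + nchar(b)`, giving values in `[0, 1)`. Defined as 0 when
#' both strings are empty.
#'
#' @param a,b Single character strings.
#' @param denominator `"max_len"` (default) or `"sum_len"`.
#' @return Numeric scalar.
#' @export
normalized_levenshtein <- function(a, b,
                                   denominator = c("max_len", "sum_len")) {
  denominator <- match.arg(denominator)
  la <- nchar(a)
  lb <- nchar(b)
  den <- if (denominator == "max_len") max(la, lb) else la + lb
  if (den == 0) return(0)
  as.numeric(levenshtein_dist(a, b)) / den
}

#' Token-level (1-gram) normalised Levenshtein distance
#'
#' Compares two token sequences at single-token granularity: every token
#' of one sequence is matched to its nearest token of the other under
#' [normalized_levenshtein()], and the two directed mean best-match
#' distances are averaged (a symmetric Monge-Elkan-style aggregate).
#' This is the edit-distance variant that is robust to typos and
#' morphological variants ("blockednose" still nearly matches
#' "blocked"), which a single edit distance over whole joined documents
#' dilutes. Defined as 0 when both sequences are empty and 1 when
#' exactly one is.
#'
#' @param a,b Character token vectors.
#' @param denominator Per-pair normalisation, see
#'   [normalized_levenshtein()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
token_levenshtein_dist <- function(a, b,
                                   denominator = c("max_len", "sum_len")) {
  denominator <- match.arg(denominator)
  if (!length(a) && !length(b)) return(0)
  if (!length(a) || !length(b)) return(1)
  d <- matrix(as.numeric(levenshtein_dist(rep(a, each = length(b)),
                                          rep(b, times = length(a)))),
              nrow = length(b))
  den <- if (denominator == "max_len") {
    outer(nchar(b), nchar(a), pmax)
  } else {
    outer(nchar(b), nchar(a), "+")
  }
  den[den == 0] <- 1
  nd <- d / den
  (mean(apply(nd, 2L, min)) + mean(apply(nd, 1L, min))) / 2
}

#' Ensemble similarity weights
#'
#' One non-negative weight per metric of the similarity ensemble. When
#' used for classification at least one weight must be positive.
#'
#' @param w_cos,w_euc,w_jac,w_lev Non-negative reals.
#' @return Object of class `similarity_weights`.
#' @export
similarity_weights <- function(w_cos = 1, w_euc = 1, w_jac = 1, w_lev = 1) {
  w <- c(w_cos = w_cos, w_euc = w_euc, w_jac = w_jac, w_lev = w_lev)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("similarity weights must be finite and non-negative")
  }
  structure(as.list(w), class = "similarity_weights")
}

#' Weights placing unit mass on a single metric
#'
#' @param metric One of `"cosine"`, `"euclidean"`, `"jaccard"`,
#'   `"levenshtein"`.
#' @return A [similarity_weights()] object.
#' @export
metric_weights <- function(metric = c("cosine", "euclidean", "jaccard",
                                      "levenshtein")) {
  metric <- match.arg(metric)
  w <- list(cosine = c(1, 0, 0, 0), euclidean = c(0, 1, 0, 0),
            jaccard = c(0, 0, 1, 0), levenshtein = c(0, 0, 0, 1))[[metric]]
  similarity_weights(w[1], w[2], w[3], w[4])
}

#' Write / read ensemble weights as JSON
#'
#' @param weights A [similarity_weights()] object.
#' @param path File path.
#' @return `path` (write) or a `similarity_weights` object (read).
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "similarity_weights"))
  jsonlite::write_json(unclass(weights), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- jsonlite::fromJSON(path)
  similarity_weights(w$w_cos, w$w_euc, w$w_jac, w$w_lev)
}

#' Weighted ensemble score between a referral and a CPC text
#'
#' Combines the four metrics as
#' `w_cos * Cos + w_jac * Jac - w_euc * Euc - w_lev * NLev`: similarities
#' are added, distances subtracted. Cosine, Euclidean and Jaccard operate
#' on the token sequences; the Levenshtein term operates on the
#' space-joined strings (tokens joined in stored order) and is normalised
#' by `lev_denominator`. Note that cosine, Jaccard and normalised
#' Levenshtein are bounded while the raw Euclidean term is not, so with
#' comparable weights the Euclidean term can dominate on long documents.
#'
#' @param referral_tokens,cpc_tokens Character token vectors.
#' @param weights A [similarity_weights()] object.
#' @param lev_denominator Passed to [normalized_levenshtein()].
#' @return Numeric scalar (may be negative).
#' @export
ensemble_score <- function(referral_tokens, cpc_tokens,
                           weights = similarity_weights(),
                           lev_denominator = c("max_len", "sum_len")) {
  stopifnot(inherits(weights, "similarity_weights"))
  lev_denominator <- match.arg(lev_denominator)
  sc <- 0
  if (weights$w_cos > 0) {
    sc <- sc + weights$w_cos * cosine_sim(referral_tokens, cpc_tokens)
  }
  if (weights$w_jac > 0) {
    sc <- sc + weights$w_jac * jaccard_sim(referral_tokens, cpc_tokens)
  }
  if (weights$w_euc > 0) {
    sc <- sc - weights$w_euc * euclidean_dist(referral_tokens, cpc_tokens)
  }
  if (weights$w_lev > 0) {
    sc <- sc - weights$w_lev *
      normalized_levenshtein(paste(referral_tokens, collapse = " "),
                             paste(cpc_tokens, collapse = " "),
                             denominator = lev_denominator)
  }
  sc
}

#' Predict a referral's CPC by text similarity
#'
#' Scores the referral's medical terms against every catalogued CPC of
#' its age group (combined-unit text in the chosen representation) with
#' [ensemble_score()] and returns the argmax. Ties break toward the
#' lexicographically smallest `cpc_id`.
#'
#' @param referral_tokens Character token vector.
#' @param catalog A [cpc_catalog()].
#' @param age_group `"adult"` or `"paediatric"`.
#' @param representation CPC text representation, default `"keywords"`.
#' @param weights A [similarity_weights()] object; at least one positive
#'   weight.
#' @param lev_denominator Passed to [ensemble_score()].
#' @return List with elements `cpc_id` and `scores` (named numeric vector
#'   over all candidate CPCs, ascending `cpc_id` order).
#' @export
predict_cpc_by_similarity <- function(referral_tokens, catalog, age_group,
                                      representation = "keywords",
                                      weights = similarity_weights(),
                                      lev_denominator = c("max_len",
                                                          "sum_len")) {
  stopifnot(inherits(weights, "similarity_weights"))
  lev_denominator <- match.arg(lev_denominator)
  if (all(unlist(weights) == 0)) {
    stop("at least one similarity weight must be positive for classification")
  }
  ents <- catalog_entries(catalog, age_group)
  ents <- Filter(function(e) representation %in% names(e$representations),
                 ents)
  if (!length(ents)) {
    stop("no CPC with representation '", representation,
         "' available for age group '", age_group, "'")
  }
  scores <- vapply(ents, function(e) {
    ensemble_score(referral_tokens,
                   cpc_text(catalog, e$cpc_id, age_group, representation),
                   weights = weights, lev_denominator = lev_denominator)
  }, numeric(1))
  names(scores) <- vapply(ents, `[[`, character(1), "cpc_id")
  best <- names(scores)[which.max(scores)]  # first max = smallest cpc_id
  list(cpc_id = best, scores = scores)
}

#' Predict a referral's CPC with a single metric
#'
#' Ranks the age group's CPCs (combined-unit text) by one metric:
#' similarities are maximised, distances minimised. `"levenshtein"`
#' operates on the space-joined document strings (the printed ensemble's
#' form); `"levenshtein_token"` uses the 1-gram best-match aggregate of
#' [token_levenshtein_dist()], the typo-robust variant. Ties break
#' toward the lexicographically smallest `cpc_id`.
#'
#' @param referral_tokens Character token vector.
#' @param catalog A [cpc_catalog()].
#' @param age_group `"adult"` or `"paediatric"`.
#' @param representation CPC text representation, default `"keywords"`.
#' @param metric One of `"cosine"`, `"euclidean"`, `"jaccard"`,
#'   `"levenshtein"`, `"levenshtein_token"`.
#' @param lev_denominator Normalisation for the Levenshtein variants.
#' @return List with `cpc_id` and `scores` (named, oriented so higher is
#'   better: distances are negated).
#' @export
predict_cpc_by_metric <- function(referral_tokens, catalog, age_group,
                                  representation = "keywords",
                                  metric = c("levenshtein_token",
                                             "levenshtein", "cosine",
                                             "euclidean", "jaccard"),
                                  lev_denominator = c("max_len",
                                                      "sum_len")) {
  metric <- match.arg(metric)
  lev_denominator <- match.arg(lev_denominator)
  ents <- catalog_entries(catalog, age_group)
  ents <- Filter(function(e) representation %in% names(e$representations),
                 ents)
  if (!length(ents)) {
    stop("no CPC with representation '", representation,
         "' available for age group '", age_group, "'")
  }
  scores <- vapply(ents, function(e) {
    u <- cpc_text(catalog, e$cpc_id, age_group, representation)
    switch(metric,
           cosine = cosine_sim(referral_tokens, u),
           jaccard = jaccard_sim(referral_tokens, u),
           euclidean = -euclidean_dist(referral_tokens, u),
           levenshtein = -normalized_levenshtein(
             paste(referral_tokens, collapse = " "),
             paste(u, collapse = " "), denominator = lev_denominator),
           levenshtein_token = -token_levenshtein_dist(
             referral_tokens, u, denominator = lev_denominator))
  }, numeric(1))
  names(scores) <- vapply(ents, `[[`, character(1), "cpc_id")
  list(cpc_id = names(scores)[which.max(scores)], scores = scores)
}

#' Estimate ensemble weights from labelled referrals
#'
#' Each metric's weight is its accuracy at the category-assignment task
#' on referrals that carry a valid CPC label and a historical category:
#' for each metric alone, every labelled referral's category is assigned
#' from its given CPC's per-category text with that metric, and the
#' weight is the fraction of referrals whose assigned category equals the
#' historical category.
#'
#' @param referrals A prepared referral data.frame (see
#'   [prepare_referrals()]) with columns `medical_terms`, `age_group`,
#'   `cpc_label` and `category`; every row must carry a valid CPC label
#'   and a historical category.
#' @param catalog A [cpc_catalog()].
#' @param representation CPC text representation, default `"keywords"`
#'   (the clinician-curated keyword texts).
#' @param lev_denominator Passed to the Levenshtein metric.
#' @return A [similarity_weights()] object. Warns when all four
#'   accuracies are zero (unusable for classification).
#' @export
estimate_weights <- function(referrals, catalog, representation = "keywords",
                             lev_denominator = c("max_len", "sum_len")) {
  lev_denominator <- match.arg(lev_denominator)
  stopifnot(is.data.frame(referrals))
  if (nrow(referrals) == 0L) stop("labelled referral set is empty")
  cpc_ids <- vapply(seq_len(nrow(referrals)), function(i) {
    validate_cpc_label(referrals$cpc_label[i], catalog,
                       referrals$age_group[i])
  }, character(1))
  if (any(is.na(cpc_ids))) {
    stop("every referral must carry a CPC label valid for its age group")
  }
  if (any(is.na(referrals$category))) {
    stop("every referral must carry a historical category")
  }
  metrics <- c("cosine", "euclidean", "jaccard", "levenshtein")
  acc <- vapply(metrics, function(m) {
    hit <- vapply(seq_len(nrow(referrals)), function(i) {
      def <- .get_cpc(catalog, cpc_ids[i], referrals$age_group[i])
      res <- assign_category(referrals$medical_terms[[i]], def,
                             representation = representation, metric = m,
                             lev_denominator = lev_denominator)
      res$category == referrals$category[i]
    }, logical(1))
    mean(hit)
  }, numeric(1))
  if (all(acc == 0)) {
    warning("all four metrics scored zero accuracy; ",
            "resulting weights are unusable for classification")
  }
  similarity_weights(acc[["cosine"]], acc[["euclidean"]],
                     acc[["jaccard"]], acc[["levenshtein"]])
}
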