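#' Triage pipeline configuration
#'
#' Collects every tunable of the end-to-end triage flow: which CPC
#' predictor family to use for referrals without a valid CPC label,
#' which CPC text representation drives both CPC and category
#' prediction, and which single metric scores the per-category units.
#' The default configuration (keyword representation, Levenshtein
#' category metric) is the best-performing combination on real referral
#' data; every representation-by-metric combination remains selectable.
#'
#' @param predictor CPC predictor family: `"similarity"`, `"knn"`,
#'   `"supervised"`, `"semi_supervised"` or `"kmeans"`.
#' @param representation CPC text representation, default `"keywords"`.
#' @param metric Category-assignment metric: `"cosine"`, `"euclidean"`,
#'   `"jaccard"` or `"levenshtein"` (default).
#' @param weights [similarity_weights()] for the similarity predictor
#'   (default: equal weights).
#' @param cpc_by_metric When `TRUE` the similarity predictor ranks CPCs
#'   with the single configured `metric` ([predict_cpc_by_metric()])
#'   instead of the weighted ensemble — the one-metric-per-column
#'   protocol of the benchmark grid. Default `FALSE`.
#' @param lev_denominator Normalisation for the Levenshtein metric.
#' @param classifier [classifier_spec()] for the (semi-)supervised
#'   predictors.
#' @param min_doc_count,max_doc_fraction,ngram_range Feature-matrix
#'   parameters for the feature-space predictors (defaults 30 / 0.8 /
#'   unigrams+bigrams; lower `min_doc_count` for small corpora).
#' @param knn_k Neighbour count for the KNN predictor, default 10.
#' @param pseudo_label_threshold Self-training cut-off, default 0.75.
#' @param self_train_max_iter Self-training iteration cap, default 10.
#' @param kmeans_max_iter,kmeans_tol Seeded k-means controls.
#' @param normalize_rows L2-normalise document count vectors for the
#'   KNN and (semi-)supervised predictors (default `TRUE`), removing
#'   document-length effects; the k-means predictor always operates on
#'   raw counts per its within-cluster sum-of-squares objective.
#' @param seed Integer seed for all stochastic steps.
#' @return Object of class `triage_config`.
#' @export
triage_config <- function(predictor = c("similarity", "knn", "supervised",
                                        "semi_supervised", "kmeans"),
                          representation = "keywords",
                          metric = c("levenshtein", "cosine", "euclidean",
                                     "jaccard", "levenshtein_token"),
                          weights = similarity_weights(),
                          cpc_by_metric = FALSE,
                          lev_denominator = c("max_len", "sum_len"),
                          classifier = classifier_spec(),
                          min_doc_count = 30L, max_doc_fraction = 0.8,
                          ngram_range = c(1L, 2L), knn_k = 10L,
                          pseudo_label_threshold = 0.75,
                          self_train_max_iter = 10L,
                          kmeans_max_iter = 300L, kmeans_tol = 1e-4,
                          normalize_rows = TRUE, seed = 1L) {
  predictor <- match.arg(predictor)
  metric <- match.arg(metric)
  lev_denominator <- match.arg(lev_denominator)
  stopifnot(representation %in% .rep_names,
            inherits(weights, "similarity_weights"),
            inherits(classifier, "classifier_spec"),
            knn_k >= 1L, pseudo_label_threshold > 0.5,
            pseudo_label_threshold <= 1)
  structure(
    list(predictor = predictor, representation = representation,
         metric = metric, weights = weights,
         cpc_by_metric = isTRUE(cpc_by_metric),
         lev_denominator = lev_denominator, classifier = classifier,
         min_doc_count = min_doc_count,
         max_doc_fraction = max_doc_fraction, ngram_range = ngram_range,
         knn_k = knn_k, pseudo_label_threshold = pseudo_label_threshold,
         self_train_max_iter = self_train_max_iter,
         kmeans_max_iter = kmeans_max_iter, kmeans_tol = kmeans_tol,
         normalize_rows = normalize_rows, seed = seed),
    class = "triage_config"
  )
}

#' Resolve a referral's CPC: given label or prediction
#'
#' Implements the first branch of the triage flowchart: when the
#' referral carries a CPC label that validates against its age group's
#' catalog the label is used as given; otherwise the supplied predictor
#' is invoked.
#'
#' @param referral One-row slice of a prepared referral data.frame (or a
#'   list with `cpc_label`, `age_group`, `medical_terms`).
#' @param catalog A [cpc_catalog()].
#' @param predict_fn Function `(medical_terms, age_group) -> cpc_id`
#'   (may return `NA_character_` for no prediction).
#' @param method Method tag recorded when the predictor path is taken.
#' @return List with `cpc_id` (may be `NA`), `source` (`"given"` or
#'   `"predicted"`) and `method` (`NA` for given CPCs).
#' @export
resolve_cpc <- function(referral, catalog, predict_fn,
                        method = "similarity") {
  lbl <- referral$cpc_label
  if (is.list(lbl)) lbl <- lbl[[1]]
  ag <- referral$age_group
  if (is.list(ag)) ag <- ag[[1]]
  given <- validate_cpc_label(lbl, catalog, ag)
  if (!is.na(given)) {
    return(list(cpc_id = given, source = "given", method = NA_character_))
  }
  terms <- referral$medical_terms
  if (is.list(terms) && !is.character(terms)) terms <- terms[[1]]
  list(cpc_id = predict_fn(terms, ag), source = "predicted",
       method = method)
}

#' Assign an urgency category from a CPC's per-category text
#'
#' When the CPC mandates a category (`fixed_category`), that category is
#' returned regardless of the referral text. Otherwise the referral's
#' medical terms are scored against each non-empty category unit of the
#' chosen representation with one metric; similarities are maximised and
#' distances minimised (the Levenshtein distance is normalised and
#' computed on space-joined token strings). Reported scores are oriented
#' so that higher is better (distances are negated), and ties break
#' toward the more urgent (lower) category.
#'
#' @param referral_terms Character token vector.
#' @param cpc A [cpc_definition()].
#' @param representation CPC text representation, default `"keywords"`.
#' @param metric One of `"cosine"`, `"euclidean"`, `"jaccard"`,
#'   `"levenshtein"`.
#' @param lev_denominator Normalisation for the Levenshtein metric.
#' @return List with `category` (integer) and `scores` (named numeric
#'   vector over the scored categories, higher = better).
#' @export
assign_category <- function(referral_terms, cpc,
                            representation = "keywords",
                            metric = c("levenshtein", "cosine",
                                       "euclidean", "jaccard",
                                       "levenshtein_token"),
                            lev_denominator = c("max_len", "sum_len")) {
  metric <- match.arg(metric)
  lev_denominator <- match.arg(lev_denominator)
  stopifnot(inherits(cpc, "cpc_definition"))
  if (!is.null(cpc$fixed_category)) {
    return(list(category = cpc$fixed_category,
                scores = setNames(1, as.character(cpc$fixed_category))))
  }
  units <- cpc$representations[[representation]]
  if (is.null(units)) {
    stop("CPC '", cpc$cpc_id, "' has no '", representation,
         "' representation")
  }
  cand <- names(units)[lengths(units) > 0L]
  if (!length(cand)) {
    stop("all category units of CPC '", cpc$cpc_id, "' are empty")
  }
  scores <- vapply(cand, function(cat) {
    u <- units[[cat]]
    switch(metric,
           cosine = cosine_sim(referral_terms, u),
           jaccard = jaccard_sim(referral_terms, u),
           euclidean = -euclidean_dist(referral_terms, u),
           levenshtein = -normalized_levenshtein(
             paste(referral_terms, collapse = " "),
             paste(u, collapse = " "),
             denominator = lev_denominator),
           levenshtein_token = -token_levenshtein_dist(
             referral_terms, u, denominator = lev_denominator))
  }, numeric(1))
  # ties break toward urgency: candidates are in ascending category
  # order and which.max returns the first maximum
  best <- cand[which.max(scores)]
  list(category = as.integer(best), scores = scores)
}

# build the per-age-group CPC prediction vector for rows lacking a valid
# label; returns character vector (NA = unresolvable) plus method tag
.predict_group_cpcs <- function(terms, ids, valid_id, catalog, ag, config) {
  n <- length(terms)
  need <- is.na(valid_id)
  preds <- rep(NA_character_, n)
  if (!any(need)) return(preds)
  if (config$predictor == "similarity") {
    preds[need] <- vapply(which(need), function(i) {
      if (config$cpc_by_metric) {
        predict_cpc_by_metric(terms[[i]], catalog, ag,
                              representation = config$representation,
                              metric = config$metric,
                              lev_denominator =
                                config$lev_denominator)$cpc_id
      } else {
        predict_cpc_by_similarity(terms[[i]], catalog, ag,
                                  representation = config$representation,
                                  weights = config$weights,
                                  lev_denominator =
                                    config$lev_denominator)$cpc_id
      }
    }, character(1))
    return(preds)
  }
  fm <- build_features(terms, ids = ids,
                       min_doc_count = config$min_doc_count,
                       max_doc_fraction = config$max_doc_fraction,
                       ngram_range = config$ngram_range)
  x <- fm$matrix
  if (config$normalize_rows && config$predictor != "kmeans") {
    # unit-length document vectors for neighbour search and linear
    # classification: raw-count Euclidean geometry otherwise makes the
    # shortest document everyone's nearest neighbour
    rn <- sqrt(Matrix::rowSums(x^2))
    rn[rn == 0] <- 1
    x <- x / rn
  }
  labeled <- which(!need)
  if (config$predictor == "kmeans") {
    ents <- catalog_entries(catalog, ag)
    seeds <- lapply(ents, function(e) {
      tk <- character(0)
      for (rp in intersect(c("medical_terms", "keywords"),
                           names(e$representations))) {
        tk <- c(tk, cpc_text(catalog, e$cpc_id, ag, rp))
      }
      unique(tk)
    })
    names(seeds) <- vapply(ents, `[[`, character(1), "cpc_id")
    seedmat <- as.matrix(vectorize_tokens(seeds, fm, ids = names(seeds)))
    # seeds whose vocabulary is absent from the corpus cannot anchor a
    # cluster; and surviving seeds are rescaled to the typical document
    # norm so that document-frequency filtering does not leave low-norm
    # seeds that hijack every row (the seed list fixes the direction,
    # the corpus sets the scale)
    nonzero <- rowSums(abs(seedmat)) > 0
    if (any(!nonzero)) {
      warning("dropping CPC seed(s) absent from the corpus vocabulary: ",
              paste(rownames(seedmat)[!nonzero], collapse = ", "))
    }
    if (sum(nonzero) < 2L) return(preds)
    seedmat <- seedmat[nonzero, , drop = FALSE]
    rown <- sqrt(Matrix::rowSums(x^2))
    target <- mean(rown[rown > 0])
    if (is.finite(target) && target > 0) {
      seedmat <- seedmat * (target / sqrt(rowSums(seedmat^2)))
    }
    km <- seeded_kmeans(fm, seedmat,
                        max_iter = config$kmeans_max_iter,
                        tol = config$kmeans_tol)
    preds[need] <- km$assignments[need]
    return(preds)
  }
  if (!length(labeled)) return(preds) # nothing to learn from
  if (config$predictor == "knn") {
    lab_x <- as.matrix(x[labeled, , drop = FALSE])
    lab_y <- valid_id[labeled]
    # "similarity larger than 0": a labelled referral sharing no
    # vocabulary with the query has zero similarity and cannot vote
    # (exp(-distance) alone never reaches zero and would let many
    # distant same-class rows dilute the vote)
    overlap <- x[which(need), , drop = FALSE] %*% t(lab_x) > 0
    for (j in seq_along(which(need))) {
      i <- which(need)[j]
      cand <- which(overlap[j, ])
      if (!length(cand)) next # sentinel: flagged unresolvable
      preds[i] <- knn_predict(x[i, ], lab_x[cand, , drop = FALSE],
                              lab_y[cand], k = config$knn_k)$cpc_id
    }
    return(preds)
  }
  if (length(unique(valid_id[labeled])) < 2L) return(preds)
  if (config$predictor == "supervised") {
    model <- train_supervised(x[labeled, , drop = FALSE],
                              valid_id[labeled],
                              spec = config$classifier,
                              seed = config$seed)
  } else { # semi_supervised
    model <- self_train(x[labeled, , drop = FALSE], valid_id[labeled],
                        x[need, , drop = FALSE],
                        spec = config$classifier,
                        threshold = config$pseudo_label_threshold,
                        max_iter = config$self_train_max_iter,
                        seed = config$seed)$model
  }
  preds[need] <- predict(model, x[need, , drop = FALSE])
  preds
}

#' Triage a batch of referrals end to end
#'
#' Runs the full flowchart per referral: validate any attached CPC label
#' against the age-group catalog, predict the CPC for the rest with the
#' configured predictor family, then assign the urgency category from
#' the resolved CPC's per-category text. Per-referral failures (for
#' example no prediction possible) are collected and the batch
#' continues; the run is deterministic given the configuration seed.
#'
#' @param referrals A prepared referral data.frame
#'   ([prepare_referrals()]) with `medical_terms` and `age_group`.
#' @param catalog A [cpc_catalog()].
#' @param config A [triage_config()].
#' @return data.frame with columns `referral_id`, `age_group`, `cpc_id`,
#'   `cpc_source`, `cpc_method`, `category` and `score_cat1..3`
#'   (higher = better; `NA` for unscored categories). Failed referrals
#'   are attached as attribute `"failures"` (data.frame `referral_id`,
#'   `reason`).
#' @export
triage_batch <- function(referrals, catalog, config = triage_config()) {
  stopifnot(is.data.frame(referrals), inherits(catalog, "cpc_catalog"),
            inherits(config, "triage_config"))
  if (!all(c("medical_terms", "age_group") %in% names(referrals))) {
    stop("referrals must be prepared first (see prepare_referrals)")
  }
  if (!"cpc_label" %in% names(referrals)) referrals$cpc_label <- NA
  rows <- list()
  failures <- list()
  for (ag in intersect(.age_groups, unique(referrals$age_group))) {
    g <- referrals[referrals$age_group == ag, , drop = FALSE]
    terms <- g$medical_terms
    ids <- g$referral_id
    valid_id <- vapply(seq_len(nrow(g)), function(i) {
      validate_cpc_label(g$cpc_label[i], catalog, ag)
    }, character(1))
    preds <- tryCatch(
      .predict_group_cpcs(terms, ids, valid_id, catalog, ag, config),
      error = function(e) {
        structure(rep(NA_character_, nrow(g)),
                  reason = conditionMessage(e))
      })
    reason <- attr(preds, "reason")
    for (i in seq_len(nrow(g))) {
      cpc_id <- if (!is.na(valid_id[i])) valid_id[i] else preds[i]
      if (is.na(cpc_id)) {
        failures[[length(failures) + 1L]] <- data.frame(
          referral_id = ids[i],
          reason = if (!is.null(reason)) reason else
            "no CPC prediction available",
          stringsAsFactors = FALSE)
        next
      }
      src <- if (!is.na(valid_id[i])) "given" else "predicted"
      def <- .get_cpc(catalog, cpc_id, ag)
      cat_res <- tryCatch(
        assign_category(terms[[i]], def,
                        representation = config$representation,
                        metric = config$metric,
                        lev_denominator = config$lev_denominator),
        error = function(e) NULL)
      if (is.null(cat_res)) {
        failures[[length(failures) + 1L]] <- data.frame(
          referral_id = ids[i], reason = "category assignment failed",
          stringsAsFactors = FALSE)
        next
      }
      sc <- setNames(rep(NA_real_, 3L), as.character(.categories))
      sc[names(cat_res$scores)] <- cat_res$scores
      rows[[length(rows) + 1L]] <- data.frame(
        referral_id = ids[i], age_group = ag, cpc_id = cpc_id,
        cpc_source = src,
        cpc_method = if (src == "given") NA_character_ else
          config$predictor,
        category = cat_res$category,
        score_cat1 = sc[["1"]], score_cat2 = sc[["2"]],
        score_cat3 = sc[["3"]], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(referral_id = character(0), age_group = character(0),
               cpc_id = character(0), cpc_source = character(0),
               cpc_method = character(0), category = integer(0),
               score_cat1 = numeric(0), score_cat2 = numeric(0),
               score_cat3 = numeric(0), stringsAsFactors = FALSE)
  # preserve input order
  out <- out[order(match(out$referral_id, referrals$referral_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures)) {
    do.call(rbind, failures)
  } else {
    data.frame(referral_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  out
}

#' Level of agreement between predicted and reference categories
#'
#' Historical categories are a noisy reference, not ground truth, so the
#' headline statistic is called *agreement*: the fraction of referrals
#' whose predicted category equals the historically assigned one
#' (equal to the trace of the confusion matrix over n). Per-category
#' precision (`TP / column sum`, 0 when the category is never
#' predicted) and sensitivity (`TP / row sum`) are reported with their
#' unweighted means.
#'
#' @param predicted,actual Integer vectors of categories in `1:3`.
#' @return Object of class `agreement_report`: list with `n`,
#'   `agreement`, `confusion` (3x3, rows = actual, columns = predicted),
#'   `per_category`, `overall_precision`, `overall_sensitivity`,
#'   `accuracy`.
#' @export
evaluate_agreement <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  if (!length(predicted)) stop("no results to evaluate")
  if (any(!predicted %in% .categories) || any(!actual %in% .categories)) {
    stop("categories must be 1, 2 or 3")
  }
  f <- factor(actual, levels = .categories)
  p <- factor(predicted, levels = .categories)
  confusion <- table(actual = f, predicted = p)
  n <- length(predicted)
  tp <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  sensitivity <- ifelse(rowsum > 0, tp / rowsum, 0)
  agreement <- sum(tp) / n
  structure(
    list(n = n, agreement = agreement,
         confusion = unclass(confusion),
         per_category = data.frame(category = .categories,
                                   precision = as.numeric(precision),
                                   sensitivity = as.numeric(sensitivity)),
         overall_precision = mean(precision),
         overall_sensitivity = mean(sensitivity),
         accuracy = agreement),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> n =", x$n,
      sprintf("| agreement = %.3f\n", x$agreement))
  print(x$confusion)
  cat(sprintf("overall precision %.3f | overall sensitivity %.3f\n",
              x$overall_precision, x$overall_sensitivity))
  invisible(x)
}

#' Evaluate triage results against historical categories
#'
#' @param results A [triage_batch()] result.
#' @param historical Either a named integer vector keyed by
#'   `referral_id` or a data.frame with columns `referral_id` and
#'   `category`. Every result row must have a historical category.
#' @return An [evaluate_agreement()] report.
#' @export
evaluate <- function(results, historical) {
  stopifnot(is.data.frame(results))
  if (!nrow(results)) stop("no results to evaluate")
  if (is.data.frame(historical)) {
    historical <- setNames(historical$category, historical$referral_id)
  }
  actual <- historical[results$referral_id]
  if (any(is.na(actual))) {
    stop("missing historical category for referral(s): ",
         paste(head(results$referral_id[is.na(actual)], 5L),
               collapse = ", "))
  }
  evaluate_agreement(results$category, as.integer(actual))
}

#' Write an agreement report to JSON
#'
#' @param report An `agreement_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  out <- list(
    n = jsonlite::unbox(report$n),
    agreement = jsonlite::unbox(report$agreement),
    accuracy = jsonlite::unbox(report$accuracy),
    confusion = matrix(as.integer(report$confusion), 3L, 3L),
    per_category = report$per_category,
    overall_precision = jsonlite::unbox(report$overall_precision),
    overall_sensitivity = jsonlite::unbox(report$overall_sensitivity)
  )
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
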