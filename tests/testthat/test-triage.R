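test_that("CPC resolution prefers a valid given label and falls back to prediction", {
  cat0 <- make_test_catalog()
  seen <- new.env()
  predict_fn <- function(terms, ag) {
    seen$ag <- ag
    "ad-tinnitus"
  }
  given <- resolve_cpc(list(cpc_label = "hearing loss", age_group = "adult",
                            medical_terms = list(c("hear"))),
                       cat0, predict_fn)
  expect_identical(given$cpc_id, "ad-hearing-loss")
  expect_identical(given$source, "given")
  expect_identical(given$method, NA_character_)
  pred <- resolve_cpc(list(cpc_label = "hearing issues",
                           age_group = "adult",
                           medical_terms = list(c("ring"))),
                      cat0, predict_fn, method = "similarity")
  expect_identical(pred$source, "predicted")
  expect_identical(pred$method, "similarity")
  # unlabelled paediatric referral invokes the predictor with the
  # paediatric catalog scope
  resolve_cpc(list(cpc_label = NA, age_group = "paediatric",
                   medical_terms = list(c("ear"))), cat0, predict_fn)
  expect_identical(seen$ag, "paediatric")
})

test_that("category assignment scores per-category units with one metric", {
  cat0 <- make_test_catalog()
  hl <- Filter(function(e) e$cpc_id == "ad-hearing-loss",
               cat0$entries)[[1]]
  # exact match with the category-1 unit under levenshtein: distance 0
  got <- assign_category(c("hear", "loss", "sudden"), hl,
                         metric = "levenshtein")
  expect_identical(got$category, 1L)
  expect_equal(unname(got$scores["1"]), 0)
  # fixed-category CPC ignores the referral text
  nm <- Filter(function(e) e$cpc_id == "ad-neck-mass", cat0$entries)[[1]]
  forced <- assign_category(c("hear", "loss"), nm, metric = "cosine")
  expect_identical(forced$category, 1L)
  expect_identical(names(forced$scores), "1")
  # hand-computed normalised levenshtein per unit picks the argmin
  terms <- c("hear", "aid")
  dists <- vapply(cpc_text(cat0, "ad-hearing-loss", "adult", "keywords",
                           "per_category"), function(u) {
    normalized_levenshtein("hear aid", paste(u, collapse = " "))
  }, numeric(1))
  got2 <- assign_category(terms, hl, metric = "levenshtein")
  expect_identical(got2$category, as.integer(names(which.min(dists))))
  expect_equal(unname(got2$scores), unname(-dists))
  # ties break toward the more urgent category
  tin <- Filter(function(e) e$cpc_id == "ad-tinnitus", cat0$entries)[[1]]
  tie <- assign_category(c("zzz"), tin, metric = "cosine")
  expect_identical(tie$category, 1L)
})

test_that("triage_batch composes resolution and categorisation deterministically", {
  cat0 <- make_test_catalog()
  prep <- make_prepared(list(c("hear", "loss", "sudden")),
                        cpc_label = "hearing loss")
  res <- triage_batch(prep, cat0,
                      triage_config(predictor = "similarity",
                                    metric = "levenshtein"))
  expect_identical(nrow(res), 1L)
  expect_identical(res$cpc_source, "given")
  expect_true(is.na(res$cpc_method))
  expect_identical(res$category, 1L)
  expect_identical(nrow(attr(res, "failures")), 0L)
  # predicted path records the method tag
  prep2 <- make_prepared(list(c("ring", "noise")))
  res2 <- triage_batch(prep2, cat0, triage_config(metric = "cosine"))
  expect_identical(res2$cpc_source, "predicted")
  expect_identical(res2$cpc_method, "similarity")
  expect_identical(res2$cpc_id, "ad-tinnitus")
  # determinism: identical config and inputs give identical results
  res3 <- triage_batch(prep2, cat0, triage_config(metric = "cosine"))
  expect_identical(res2, res3)
})

test_that("per-referral failures are collected while the batch continues", {
  cat0 <- make_test_catalog()
  terms <- list(c("hear", "loss", "sudden"), c("ring", "noise"),
                c("hear", "aid"), c("neck", "mass"), c("ring", "puls"))
  prep <- make_prepared(terms,
                        cpc_label = c("hearing loss", "tinnitus",
                                      "hearing loss",
                                      "head and neck mass", NA))
  # knn with feature thresholds that empty the vocabulary: the four
  # given-CPC referrals still triage, the unlabelled one is flagged
  res <- triage_batch(prep, cat0,
                      triage_config(predictor = "knn",
                                    min_doc_count = 50L))
  expect_identical(nrow(res), 4L)
  fails <- attr(res, "failures")
  expect_identical(fails$referral_id, "T005")
  expect_match(fails$reason, "filtered")
})

test_that("noise-free synthetic batches reproduce the generator's categories", {
  cfg <- generator_config(seed = 11, n_referrals = 150,
                          signal_fraction = 1, typo_rate = 0,
                          historical_noise = 0)
  corp <- generate_corpus(cfg)
  prep <- prepare_referrals(corp$referrals, entities = corp$entities)
  res <- triage_batch(prep, corp$catalog,
                      triage_config(metric = "cosine"))
  expect_equal(cpc_agreement(res, corp$truth), 1)
  expect_equal(category_agreement(res, corp$truth), 1)
})

test_that("agreement evaluation produces exact confusion accounting", {
  perfect <- evaluate_agreement(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(perfect$agreement, 1)
  expect_equal(perfect$per_category$precision, rep(1, 3))
  expect_equal(perfect$per_category$sensitivity, rep(1, 3))
  half <- evaluate_agreement(c(1, 2, 3, 1), c(1, 3, 3, 2))
  expect_equal(half$agreement, 0.5)
  expect_equal(half$accuracy, half$agreement)
  expect_identical(sum(half$confusion), 4L)
  # rows are actual, columns predicted
  expect_identical(half$confusion["3", "2"], 1L)
  # agreement = trace / n and denominators match row/column sums against
  # a brute-force per-record tally
  set.seed(13)
  pred <- sample(1:3, 200, replace = TRUE)
  act <- sample(1:3, 200, replace = TRUE)
  rep <- evaluate_agreement(pred, act)
  expect_equal(rep$agreement, sum(diag(rep$confusion)) / 200)
  for (c3 in 1:3) {
    tp <- sum(pred == c3 & act == c3)
    expect_equal(rep$per_category$precision[c3],
                 if (sum(pred == c3) > 0) tp / sum(pred == c3) else 0)
    expect_equal(rep$per_category$sensitivity[c3],
                 if (sum(act == c3) > 0) tp / sum(act == c3) else 0)
  }
  expect_equal(rep$overall_precision, mean(rep$per_category$precision))
  expect_equal(rep$overall_sensitivity,
               mean(rep$per_category$sensitivity))
  # a category never predicted scores precision 0, not NaN
  skew <- evaluate_agreement(c(1, 1, 1), c(1, 2, 3))
  expect_equal(skew$per_category$precision, c(1 / 3, 0, 0))
  expect_error(evaluate_agreement(integer(0), integer(0)), "no results")
  expect_error(evaluate_agreement(c(1, 4), c(1, 2)), "1, 2 or 3")
})

test_that("evaluate joins results to historical categories by referral id", {
  res <- data.frame(referral_id = c("a", "b"), category = c(1L, 2L),
                    stringsAsFactors = FALSE)
  rep <- evaluate(res, data.frame(referral_id = c("b", "a"),
                                  category = c(2L, 3L)))
  expect_equal(rep$agreement, 0.5)
  expect_error(evaluate(res, c(a = 1L)), "missing historical")
  report_path <- tempfile(fileext = ".json")
  write_agreement_report(rep, report_path)
  back <- jsonlite::fromJSON(report_path)
  expect_equal(back$agreement, rep$agreement)
  expect_equal(dim(back$confusion), c(3L, 3L))
})
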