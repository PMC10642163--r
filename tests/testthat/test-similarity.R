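test_that("cosine similarity matches hand-computed values and conventions", {
  expect_equal(cosine_sim(c("a", "b"), c("a", "b")), 1)
  expect_equal(cosine_sim(c("a"), c("b")), 0)
  expect_equal(cosine_sim(c("x", "y"), c("x", "z")), 0.5)
  expect_equal(cosine_sim(character(0), c("x")), 0)
})

test_that("euclidean distance on raw count vectors", {
  expect_equal(euclidean_dist(c("a", "b"), c("a", "b")), 0)
  expect_equal(euclidean_dist(rep("x", 3), rep("y", 4)), 5)
  expect_equal(euclidean_dist(character(0), c("x", "x")), 2)
})

test_that("jaccard similarity of token sets", {
  expect_equal(jaccard_sim(c("a", "b"), c("b", "a", "a")), 1)
  expect_equal(jaccard_sim(c("a"), c("b")), 0)
  expect_equal(jaccard_sim(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_sim(character(0), character(0)), 0)
})

test_that("levenshtein DP kernel matches pinned values and the naive oracle", {
  expect_identical(levenshtein_dist("abc", "abc"), 0L)
  expect_identical(levenshtein_dist("", "abc"), 3L)
  expect_identical(levenshtein_dist("kitten", "sitting"), 3L)
  set.seed(5)
  for (i in 1:60) {
    a <- random_string(5)
    b <- random_string(5)
    expect_identical(levenshtein_dist(a, b), lev_ref(a, b))
  }
})

test_that("similarity metrics are symmetric, bounded, and satisfy triangle inequalities", {
  set.seed(9)
  for (i in 1:40) {
    a <- random_tokens(sample(0:6, 1))
    b <- random_tokens(sample(0:6, 1))
    cc <- random_tokens(sample(0:6, 1))
    expect_equal(cosine_sim(a, b), cosine_sim(b, a))
    expect_gte(cosine_sim(a, b), 0); expect_lte(cosine_sim(a, b), 1 + 1e-12)
    expect_equal(jaccard_sim(a, b), jaccard_sim(b, a))
    expect_gte(jaccard_sim(a, b), 0); expect_lte(jaccard_sim(a, b), 1)
    expect_equal(euclidean_dist(a, b), euclidean_dist(b, a))
    expect_lte(euclidean_dist(a, cc),
               euclidean_dist(a, b) + euclidean_dist(b, cc) + 1e-12)
    sa <- random_string(8); sb <- random_string(8); sc <- random_string(8)
    expect_identical(levenshtein_dist(sa, sb), levenshtein_dist(sb, sa))
    expect_lte(levenshtein_dist(sa, sc),
               levenshtein_dist(sa, sb) + levenshtein_dist(sb, sc))
    nl <- normalized_levenshtein(sa, sb)
    expect_gte(nl, 0); expect_lte(nl, 1)
    ns <- normalized_levenshtein(sa, sb, "sum_len")
    expect_gte(ns, 0); expect_lt(ns, 1 + 1e-12)
  }
})

test_that("normalised levenshtein supports both denominators", {
  expect_equal(normalized_levenshtein("same", "same"), 0)
  expect_equal(normalized_levenshtein("", ""), 0)
  expect_equal(normalized_levenshtein("kitten", "sitting"), 3 / 7)
  expect_equal(normalized_levenshtein("kitten", "sitting", "sum_len"),
               3 / 13)
})

test_that("token-level levenshtein aggregates per-token best matches", {
  expect_equal(token_levenshtein_dist(c("hear", "loss"),
                                      c("hear", "loss")), 0)
  expect_equal(token_levenshtein_dist(character(0), character(0)), 0)
  expect_equal(token_levenshtein_dist(c("hear"), character(0)), 1)
  # a typo'd token stays close at token granularity
  clean <- token_levenshtein_dist(c("blocked", "nose"),
                                  c("blocked", "nose", "sinus"))
  typo <- token_levenshtein_dist(c("blockednose", "nose"),
                                 c("blocked", "nose", "sinus"))
  far <- token_levenshtein_dist(c("vertigo", "dizzy"),
                                c("blocked", "nose", "sinus"))
  expect_lt(clean, typo)
  expect_lt(typo, far)
  expect_gte(typo, 0); expect_lte(typo, 1)
})

test_that("ensemble score composes the four metrics with signed weights", {
  a <- c("hear", "loss")
  b <- c("hear", "loss", "tinnitus")
  expect_equal(ensemble_score(a, b, similarity_weights(1, 0, 0, 0)),
               cosine_sim(a, b))
  expect_equal(ensemble_score(a, b, similarity_weights(0, 0, 0, 0)), 0)
  full <- ensemble_score(a, b, similarity_weights(1, 1, 1, 1))
  expect_equal(full,
               cosine_sim(a, b) + jaccard_sim(a, b) -
                 euclidean_dist(a, b) -
                 normalized_levenshtein("hear loss",
                                        "hear loss tinnitus"))
  # monotone in each component: weight on a similarity raises the score,
  # weight on a distance lowers it (here all components are non-zero)
  expect_gt(ensemble_score(a, b, similarity_weights(2, 1, 1, 1)), full)
  expect_lt(ensemble_score(a, b, similarity_weights(1, 2, 1, 1)), full)
  expect_gt(ensemble_score(a, b, similarity_weights(1, 1, 2, 1)), full)
  expect_lt(ensemble_score(a, b, similarity_weights(1, 1, 1, 2)), full)
})

test_that("similarity CPC prediction takes the argmax with ascending-id ties", {
  cat0 <- make_test_catalog()
  # referral identical to one CPC's combined text with cos+jac weights
  toks <- cpc_text(cat0, "ad-tinnitus", "adult", "keywords")
  got <- predict_cpc_by_similarity(toks, cat0, "adult", "keywords",
                                   similarity_weights(1, 0, 1, 0))
  expect_identical(got$cpc_id, "ad-tinnitus")
  expect_equal(unname(got$scores["ad-tinnitus"]), 2)
  expect_length(got$scores, 3L)
  # referral sharing terms only with one CPC
  got2 <- predict_cpc_by_similarity(c("ring", "noise"), cat0, "adult",
                                    "keywords",
                                    similarity_weights(1, 1, 1, 1))
  expect_identical(got2$cpc_id, "ad-tinnitus")
  # exact ties break toward the lexicographically smaller cpc_id
  twin <- cpc_catalog(list(
    cpc_definition("b-cpc", "adult", "b",
                   list(keywords = list(`1` = c("x", "y")))),
    cpc_definition("a-cpc", "adult", "a",
                   list(keywords = list(`1` = c("x", "y"))))))
  tied <- predict_cpc_by_similarity(c("x"), twin, "adult", "keywords")
  expect_identical(tied$cpc_id, "a-cpc")
  expect_error(predict_cpc_by_similarity(c("x"), cat0, "adult", "keywords",
                                         similarity_weights(0, 0, 0, 0)),
               "positive")
})

test_that("levenshtein-only weights rank identically to ascending normalised distance", {
  cat0 <- make_test_catalog()
  toks <- c("ring", "ear", "loss")
  got <- predict_cpc_by_similarity(toks, cat0, "adult", "keywords",
                                   similarity_weights(0, 0, 0, 2))
  dists <- vapply(names(got$scores), function(id) {
    normalized_levenshtein(paste(toks, collapse = " "),
                           paste(cpc_text(cat0, id, "adult", "keywords"),
                                 collapse = " "))
  }, numeric(1))
  expect_identical(order(got$scores, decreasing = TRUE), order(dists))
  expect_identical(got$cpc_id, names(which.min(dists)))
})

test_that("single-metric CPC ranking agrees with the per-metric oracles", {
  cat0 <- make_test_catalog()
  toks <- c("ring", "noise", "chronic")
  for (m in c("cosine", "jaccard", "levenshtein_token")) {
    expect_identical(
      predict_cpc_by_metric(toks, cat0, "adult", "keywords", m)$cpc_id,
      "ad-tinnitus")
  }
})

test_that("weights persist to JSON and validate", {
  w <- similarity_weights(0.5, 0.51, 0.4, 0.54)
  path <- tempfile(fileext = ".json")
  write_weights(w, path)
  expect_equal(read_weights(path), w)
  expect_error(similarity_weights(-1, 0, 0, 0), "non-negative")
})

test_that("weight estimation returns per-metric category accuracies", {
  cat0 <- make_test_catalog()
  # terms identical to the category-1 unit: every metric assigns 1
  terms <- replicate(10, c("hear", "loss", "sudden"), simplify = FALSE)
  ref <- make_prepared(terms, cpc_label = "hearing loss",
                       category = c(rep(1L, 5), rep(2L, 5)))
  w <- estimate_weights(ref, cat0)
  # 5 of 10 historical categories match each metric's assignment
  expect_equal(unlist(w, use.names = FALSE), rep(0.5, 4))
  perfect <- estimate_weights(
    make_prepared(terms, cpc_label = "hearing loss",
                  category = rep(1L, 10)), cat0)
  expect_equal(unlist(perfect, use.names = FALSE), rep(1, 4))
  expect_warning(
    none <- estimate_weights(
      make_prepared(terms, cpc_label = "hearing loss",
                    category = rep(3L, 10)), cat0),
    "zero accuracy")
  expect_equal(unlist(none, use.names = FALSE), rep(0, 4))
  expect_error(estimate_weights(ref[0, ], cat0), "empty")
  expect_error(estimate_weights(
    make_prepared(terms, cpc_label = "unknown thing", category = 1L),
    cat0), "valid")
})
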