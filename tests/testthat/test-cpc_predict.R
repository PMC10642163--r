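test_that("feature building counts n-grams and filters by document frequency", {
  docs <- c(replicate(9, c("common", "term"), simplify = FALSE),
            list(c("hear", "loss")))
  # "common" and "term" occur in 9 of 10 docs: more than 80% -> dropped
  fm <- build_features(docs, min_doc_count = 1L, max_doc_fraction = 0.8)
  expect_false(any(c("common", "term") %in% fm$vocab))
  expect_true(all(c("hear", "loss", "hear loss") %in% fm$vocab))
  # min_doc_count 30 drops a term in only 2 docs; 1 keeps it
  docs2 <- c(list(c("rare", "a"), c("rare", "b")),
             replicate(3, c("x", "y"), simplify = FALSE))
  expect_error(build_features(docs2, min_doc_count = 30L), "filtered")
  fm2 <- build_features(docs2, min_doc_count = 1L)
  expect_true("rare" %in% fm2$vocab)
  fm3 <- build_features(docs2, min_doc_count = 3L)
  expect_false("rare" %in% fm3$vocab)
  # bigram column with count 1, lexicographic column order
  fm4 <- build_features(list(c("hear", "loss")), min_doc_count = 1L,
                        max_doc_fraction = 1)
  expect_identical(fm4$vocab, sort(fm4$vocab))
  expect_equal(as.numeric(fm4$matrix[1, "hear loss"]), 1)
  # unigram-only range has no bigrams
  fm5 <- build_features(list(c("hear", "loss")), min_doc_count = 1L,
                        max_doc_fraction = 1, ngram_range = 1L)
  expect_false("hear loss" %in% fm5$vocab)
})

test_that("feature matrices round-trip through MatrixMarket", {
  fm <- build_features(list(c("a", "b", "a"), c("b", "c")),
                       min_doc_count = 1L, max_doc_fraction = 1)
  base <- file.path(tempdir(), "feat")
  write_features(fm, base)
  re <- read_features(base)
  expect_equal(as.matrix(re$matrix), as.matrix(fm$matrix))
})

test_that("euclidean similarity is exp(-distance)", {
  expect_equal(euc_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(euc_similarity(0, log(2)), 0.5)
  expect_equal(euc_similarity(c(0, 0), c(3, 4)), exp(-5))
})

test_that("knn vote weighs neighbours by similarity and breaks ties by cpc_id", {
  # 1-D layout giving similarities 0.5 + 0.4 for CPC a vs 0.6 for CPC b
  labeled <- matrix(c(-log(0.5), -log(0.4), -log(0.6)), ncol = 1)
  labels <- c("cpc-a", "cpc-a", "cpc-b")
  got <- knn_predict(0, labeled, labels, k = 10)
  expect_identical(got$cpc_id, "cpc-a")
  expect_equal(unname(got$votes), c(0.9, 0.6))
  # k = 1 takes the single nearest neighbour
  expect_identical(knn_predict(0, labeled, labels, k = 1)$cpc_id, "cpc-b")
  # unanimity
  expect_identical(
    knn_predict(0, labeled, rep("cpc-z", 3), k = 10)$cpc_id, "cpc-z")
  expect_error(knn_predict(0, labeled, labels, k = 0), "at least 1")
  # similarities underflowing to zero leave no qualifying neighbour
  far <- knn_predict(0, matrix(1e6, 1, 1), "cpc-a", k = 5)
  expect_identical(far$cpc_id, NA_character_)
  expect_length(far$votes, 0L)
})

test_that("knn vote weights are positive and the winner's weight is maximal", {
  set.seed(21)
  for (i in 1:10) {
    lab <- matrix(rnorm(40), ncol = 4)
    labels <- sample(c("a", "b", "c"), 10, replace = TRUE)
    got <- knn_predict(rnorm(4), lab, labels, k = 10)
    expect_true(all(got$votes > 0 & got$votes <= 10))
    expect_gte(got$votes[got$cpc_id], max(got$votes) - 1e-12)
  }
})

test_that("supervised training is deterministic and fits separable data", {
  # two classes with disjoint vocabularies
  docs <- c(replicate(6, c("hear", "loss"), simplify = FALSE),
            replicate(6, c("throat", "sore"), simplify = FALSE))
  y <- rep(c("cpc-ear", "cpc-throat"), each = 6)
  fm <- build_features(docs, min_doc_count = 1L, max_doc_fraction = 1)
  model <- train_supervised(fm, y, seed = 7)
  expect_identical(predict(model, fm), y)
  conf <- predict_confidence(model, fm)
  expect_equal(unname(rowSums(conf)), rep(1, 12))
  expect_true(all(conf >= 0 & conf <= 1))
  model2 <- train_supervised(fm, y, seed = 7)
  expect_identical(predict(model2, fm), predict(model, fm))
  expect_error(train_supervised(fm, rep("one", 12)), "two distinct")
})

test_that("multiclass strategies build the expected binary problems", {
  set.seed(3)
  n_class <- 20L
  docs <- unlist(lapply(seq_len(n_class), function(k) {
    replicate(2, c(sprintf("w%02da", k), sprintf("w%02db", k)),
              simplify = FALSE)
  }), recursive = FALSE)
  y <- rep(sprintf("cpc%02d", seq_len(n_class)), each = 2)
  fm <- build_features(docs, min_doc_count = 1L, max_doc_fraction = 1)
  ovo <- train_supervised(fm, y, classifier_spec(multiclass_strategy = "ovo"),
                          seed = 1)
  expect_identical(ovo$meta$n_binary, as.integer(n_class * (n_class - 1) / 2))
  expect_identical(ovo$meta$n_binary, 190L)
  # error-correcting codes are unique per class
  small <- build_features(docs[1:8], min_doc_count = 1L,
                          max_doc_fraction = 1)
  ecoc <- train_supervised(small, y[1:8],
                           classifier_spec(multiclass_strategy =
                                             "error_correcting"), seed = 1)
  codes <- ecoc$meta$codes
  expect_identical(anyDuplicated(apply(codes, 1, paste, collapse = "")), 0L)
  expect_identical(predict(ecoc, small), y[1:8])
  ovr <- train_supervised(small, y[1:8],
                          classifier_spec(multiclass_strategy = "ovr"),
                          seed = 1)
  expect_identical(ovr$meta$n_binary, 4L)
  expect_identical(predict(ovr, small), y[1:8])
})

test_that("stratified folds balance classes and reproduce the 338-row test fold", {
  # 1,689 rows across three imbalanced classes, 5 folds
  labels <- rep(c("1", "2", "3"), c(338, 507, 844))
  fold <- stratified_folds(labels, folds = 5, seed = 2)
  sizes <- tabulate(fold, 5)
  expect_identical(max(sizes), 338L)
  expect_identical(sum(sizes), 1689L)
  expect_true(max(sizes) - min(sizes) <= 1L)
  # per-class counts differ by at most one across folds
  for (cl in unique(labels)) {
    per <- tabulate(fold[labels == cl], 5)
    expect_true(max(per) - min(per) <= 1L)
  }
  # 10 rows, 2 balanced classes, 5 folds: every fold holds one of each
  lab10 <- rep(c("a", "b"), 5)
  f10 <- stratified_folds(lab10, folds = 5, seed = 1)
  for (f in 1:5) {
    expect_identical(sort(lab10[f10 == f]), c("a", "b"))
  }
  expect_error(stratified_folds(lab10, folds = 11), "folds")
})

test_that("stratified CV tests every row exactly once and pools accuracy exactly", {
  docs <- c(replicate(10, c("hear", "loss"), simplify = FALSE),
            replicate(10, c("throat", "sore"), simplify = FALSE))
  y <- rep(c("ear", "throat"), each = 10)
  fm <- build_features(docs, min_doc_count = 1L, max_doc_fraction = 1)
  cv <- stratified_cv(fm, y, folds = 5, seed = 4)
  expect_identical(sort(unique(cv$folds)), 1:5)
  expect_length(cv$predictions, 20L)
  expect_equal(cv$accuracy, mean(cv$predictions == y))
  expect_equal(cv$accuracy, 1)
})

test_that("self-training honours its stopping rules and pool monotonicity", {
  docs_l <- c(replicate(5, c("hear", "loss"), simplify = FALSE),
              replicate(5, c("throat", "sore"), simplify = FALSE))
  y <- rep(c("ear", "throat"), each = 5)
  fm <- build_features(c(docs_l, list(c("hear", "loss", "hear"),
                                      c("sore", "throat", "sore"),
                                      c("hear", "throat"))),
                       min_doc_count = 1L, max_doc_fraction = 1)
  xl <- fm$matrix[1:10, ]
  xu <- fm$matrix[11:13, ]
  # empty unlabeled set reduces to plain supervised training
  st0 <- self_train(xl, y, xu[0, , drop = FALSE], seed = 5)
  expect_identical(predict(st0$model, xl),
                   predict(train_supervised(xl, y, seed = 5), xl))
  expect_identical(nrow(st0$log), 0L)
  # separable unlabeled points inherit the generator's true labels
  st <- self_train(xl, y, xu[1:2, ], threshold = 0.75, seed = 5)
  expect_identical(st$log$pseudo_label[order(st$log$row)],
                   c("ear", "throat"))
  expect_true(all(st$log$confidence >= 0.75))
  # pool growth equals the log length, iterations bounded
  expect_lte(st$iterations, 10L)
  # an ambiguous-only pool adds nothing and stops after one iteration
  st2 <- self_train(xl, y, xu[3, , drop = FALSE], threshold = 0.999,
                    seed = 5)
  expect_identical(nrow(st2$log), 0L)
  expect_identical(st2$iterations, 1L)
  expect_error(self_train(xl, y, xu, threshold = 0.4), "0.5")
})

test_that("seeded k-means converges on its fixed point in one iteration", {
  x <- rbind(c(0, 1), c(10, 10), c(0, 1), c(10, 10))
  seeds <- rbind(`cpc-a` = c(0, 1), `cpc-b` = c(10, 10))
  km <- seeded_kmeans(x, seeds)
  expect_identical(km$iterations, 1L)
  expect_true(km$converged)
  expect_identical(km$assignments, c("cpc-a", "cpc-b", "cpc-a", "cpc-b"))
  # token seeds absent from the feature vocabulary are a named error
  fm <- build_features(list(c("hear", "loss"), c("hear", "aid")),
                       min_doc_count = 1L, max_doc_fraction = 1)
  expect_error(
    seeded_kmeans(fm, list(`cpc-a` = "hear", `cpc-z` = "absent")),
    "zero vector.*cpc-z")
})

test_that("seeded k-means runs hand-checkable Lloyd iterations", {
  x <- rbind(c(1, 0), c(9, 10))
  seeds <- rbind(a = c(0, 0), b = c(10, 10))
  km <- seeded_kmeans(x, seeds)
  expect_identical(km$assignments, c("a", "b"))
  expect_equal(unname(km$centroids), rbind(c(1, 0), c(9, 10)))
  expect_equal(km$objective_trace[1], 2)  # each row one unit from its seed
  expect_equal(km$objective_trace[length(km$objective_trace)], 0)
})

test_that("k-means objective trace is non-increasing and empty clusters freeze", {
  set.seed(31)
  for (i in 1:20) {
    x <- matrix(rnorm(30 * 4), ncol = 4)
    seeds <- matrix(rnorm(3 * 4), ncol = 4,
                    dimnames = list(c("a", "b", "c"), NULL))
    km <- seeded_kmeans(x, seeds, max_iter = 50)
    expect_true(all(diff(km$objective_trace) <= 1e-8))
  }
  # a seed far from every row keeps its centroid frozen
  x2 <- matrix(runif(20, 0, 1), ncol = 2)
  seeds2 <- rbind(near = c(0.5, 0.5), far = c(100, 100))
  km2 <- seeded_kmeans(x2, seeds2)
  expect_equal(unname(km2$centroids["far", ]), c(100, 100))
  expect_identical(unique(km2$assignments), "near")
  expect_identical(km2$k, 2L)
})

test_that("all predictor families recover true CPCs on a noise-free corpus", {
  cfg <- generator_config(seed = 77, n_referrals = 600,
                          signal_fraction = 1, typo_rate = 0,
                          historical_noise = 0)
  corp <- generate_corpus(cfg)
  prep <- prepare_referrals(corp$referrals, entities = corp$entities)
  for (p in c("similarity", "knn", "supervised", "kmeans")) {
    tc <- triage_config(predictor = p, metric = "cosine",
                        min_doc_count = 2L, seed = 1)
    res <- suppressWarnings(triage_batch(prep, corp$catalog, tc))
    expect_gte(cpc_agreement(res, corp$truth), 0.9)
  }
})
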