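#' Describe a trainable multiclass classifier
#'
#' The supervised CPC predictors treat the underlying learner as an
#' opaque contract: anything that can be fitted to a count feature
#' matrix and produce per-class confidence scores. Available base
#' learners: `"glmnet"` (regularised (multinomial) logistic regression,
#' the default), `"svm_linear"` (linear support vector machine, needs
#' the e1071 package) and `"random_forest"` (needs the ranger package).
#' Multiclass strategies: `"native"` uses the learner's own multiclass
#' handling; `"ovr"` fits one binary problem per class; `"ovo"` fits one
#' per unordered class pair (`n(n-1)/2` problems); `"error_correcting"`
#' assigns each class a unique binary code and fits one problem per code
#' bit.
#'
#' @param algorithm Base learner identifier.
#' @param multiclass_strategy One of `native`, `ovr`, `ovo`,
#'   `error_correcting`.
#' @param hyperparameters Named list of learner settings (for glmnet:
#'   `lambda`, `alpha`; for ranger: `num.trees`; for svm: `cost`).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("glmnet", "svm_linear",
                                          "random_forest"),
                            multiclass_strategy = c("native", "ovr", "ovo",
                                                    "error_correcting"),
                            hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  multiclass_strategy <- match.arg(multiclass_strategy)
  stopifnot(is.list(hyperparameters))
  structure(list(algorithm = algorithm,
                 multiclass_strategy = multiclass_strategy,
                 hyperparameters = hyperparameters),
            class = "classifier_spec")
}

.feat_matrix <- function(features) {
  if (inherits(features, "feature_matrix")) return(features$matrix)
  features
}

# glmnet needs >= 2 predictor columns; remember any zero padding
.pad2 <- function(x) {
  if (ncol(x) >= 2L) return(list(x = x, padded = FALSE))
  list(x = cbind(x, `..pad..` = 0), padded = TRUE)
}

.hyp <- function(hyper, name, default) {
  if (!is.null(hyper[[name]])) hyper[[name]] else default
}

.fit_base <- function(x, y, algorithm, hyper, seed, binary) {
  y <- factor(y)
  set.seed(seed)
  if (algorithm == "glmnet") {
    # the regularised fit needs >= 2 observations per class; duplicate
    # singleton-class rows (deterministic, preserves the geometry)
    singles <- names(which(table(y) < 2L))
    if (length(singles)) {
      dup <- which(as.character(y) %in% singles)
      x <- rbind(x, x[dup, , drop = FALSE])
      y <- factor(c(as.character(y), as.character(y)[dup]))
    }
    p <- .pad2(x)
    lambda <- .hyp(hyper, "lambda", 0.01)
    alpha <- .hyp(hyper, "alpha", 0)
    # no class intercepts by default: with a small, heavily imbalanced
    # labelled pool, intercepts act as class priors and swamp rare
    # conditions that are perfectly identified by their own vocabulary
    intercept <- .hyp(hyper, "intercept", FALSE)
    fam <- if (binary) "binomial" else "multinomial"
    # glmnet's own regularisation path (warm starts); the requested
    # lambda is interpolated at prediction time
    fit <- suppressWarnings(
      glmnet::glmnet(p$x, y, family = fam, alpha = alpha,
                     intercept = intercept))
    return(list(kind = "glmnet", fit = fit, lambda = lambda,
                padded = p$padded, levels = levels(y), binary = binary))
  }
  if (algorithm == "svm_linear") {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("algorithm 'svm_linear' requires the e1071 package")
    }
    fit <- e1071::svm(as.matrix(x), y, kernel = "linear",
                      cost = .hyp(hyper, "cost", 1), probability = TRUE)
    return(list(kind = "svm", fit = fit, levels = levels(y),
                binary = binary))
  }
  if (algorithm == "random_forest") {
    if (!requireNamespace("ranger", quietly = TRUE)) {
      stop("algorithm 'random_forest' requires the ranger package")
    }
    df <- data.frame(as.matrix(x), check.names = FALSE)
    df$..y.. <- y
    fit <- ranger::ranger(dependent.variable.name = "..y..", data = df,
                          probability = TRUE,
                          num.trees = .hyp(hyper, "num.trees", 200L),
                          seed = seed, num.threads = 1L)
    return(list(kind = "ranger", fit = fit, levels = levels(y),
                binary = binary))
  }
  stop("unknown algorithm '", algorithm, "'")
}

# class-probability matrix (columns = class levels) from a base fit
.prob_base <- function(obj, x) {
  if (obj$kind == "glmnet") {
    if (obj$padded) x <- cbind(x, `..pad..` = 0)
    pr <- predict(obj$fit, newx = x, s = obj$lambda, type = "response")
    if (obj$binary) {
      p1 <- as.numeric(pr)
      out <- cbind(1 - p1, p1)
      colnames(out) <- obj$levels
    } else {
      out <- pr[, , 1, drop = FALSE]
      dim(out) <- dim(pr)[1:2]
      colnames(out) <- dimnames(pr)[[2]]
    }
    return(out[, obj$levels, drop = FALSE])
  }
  if (obj$kind == "svm") {
    pr <- predict(obj$fit, as.matrix(x), probability = TRUE)
    out <- attr(pr, "probabilities")
    return(out[, obj$levels, drop = FALSE])
  }
  if (obj$kind == "ranger") {
    df <- data.frame(as.matrix(x), check.names = FALSE)
    out <- predict(obj$fit, data = df, num.threads = 1L)$predictions
    missing <- setdiff(obj$levels, colnames(out))
    for (m in missing) out <- cbind(out, setNames(data.frame(0), m))
    return(as.matrix(out)[, obj$levels, drop = FALSE])
  }
  stop("unknown base fit")
}

# unique binary codes for error-correcting output codes: binary digits of
# 1..K, constant bit columns dropped
.ecoc_codes <- function(classes) {
  k <- length(classes)
  bits <- max(1L, ceiling(log2(k + 1)))
  codes <- t(vapply(seq_len(k), function(i) {
    as.integer(intToBits(i))[seq_len(bits)]
  }, integer(bits)))
  rownames(codes) <- classes
  keep <- apply(codes, 2L, function(col) length(unique(col)) > 1L)
  codes[, keep, drop = FALSE]
}

#' Train a multiclass CPC classifier
#'
#' Fits the learner described by a [classifier_spec()] on a labelled
#' feature matrix. The returned model predicts CPC ids and per-class
#' confidence scores in `[0, 1]` summing to 1 per row, and is
#' deterministic given `seed`.
#'
#' @param features A [build_features()] result or numeric matrix.
#' @param labels Character vector of CPC ids (at least two distinct).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @return Object of class `cpc_classifier`; see
#'   [predict.cpc_classifier()].
#' @export
train_supervised <- function(features, labels, spec = classifier_spec(),
                             seed = 1L) {
  x <- .feat_matrix(features)
  stopifnot(nrow(x) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training data must contain at least two distinct CPC labels")
  }
  strategy <- spec$multiclass_strategy
  hyper <- spec$hyperparameters
  fits <- NULL
  meta <- list()
  if (strategy == "native") {
    fits <- .fit_base(x, labels, spec$algorithm, hyper, seed,
                      binary = FALSE)
    meta$n_binary <- 0L
  } else if (strategy == "ovr") {
    fits <- lapply(classes, function(cl) {
      .fit_base(x, ifelse(labels == cl, "pos", "neg"), spec$algorithm,
                hyper, seed, binary = TRUE)
    })
    names(fits) <- classes
    meta$n_binary <- length(classes)
  } else if (strategy == "ovo") {
    pairs <- utils::combn(classes, 2L, simplify = FALSE)
    fits <- lapply(pairs, function(pr) {
      idx <- labels %in% pr
      .fit_base(x[idx, , drop = FALSE], labels[idx], spec$algorithm,
                hyper, seed, binary = TRUE)
    })
    meta$pairs <- pairs
    meta$n_binary <- length(pairs)
  } else { # error_correcting
    codes <- .ecoc_codes(classes)
    fits <- lapply(seq_len(ncol(codes)), function(b) {
      bit <- codes[match(labels, classes), b]
      .fit_base(x, ifelse(bit == 1L, "one", "zero"), spec$algorithm,
                hyper, seed, binary = TRUE)
    })
    meta$codes <- codes
    meta$n_binary <- ncol(codes)
  }
  structure(list(spec = spec, classes = classes, strategy = strategy,
                 fits = fits, meta = meta, seed = seed,
                 vocab = colnames(x)),
            class = "cpc_classifier")
}

#' Per-class confidence scores of a trained classifier
#'
#' @param model A [train_supervised()] model.
#' @param features Feature matrix (same vocabulary as at training).
#' @return Numeric matrix, rows = referrals, columns = classes; each row
#'   is non-negative and sums to 1.
#' @export
predict_confidence <- function(model, features) {
  stopifnot(inherits(model, "cpc_classifier"))
  x <- .feat_matrix(features)
  classes <- model$classes
  n <- nrow(x)
  if (model$strategy == "native") {
    conf <- .prob_base(model$fits, x)
  } else if (model$strategy == "ovr") {
    conf <- vapply(classes, function(cl) {
      .prob_base(model$fits[[cl]], x)[, "pos"]
    }, numeric(n))
    conf <- matrix(conf, nrow = n, dimnames = list(NULL, classes))
  } else if (model$strategy == "ovo") {
    conf <- matrix(0, n, length(classes),
                   dimnames = list(NULL, classes))
    for (k in seq_along(model$meta$pairs)) {
      pr <- model$meta$pairs[[k]]
      p <- .prob_base(model$fits[[k]], x)
      conf[, pr[1]] <- conf[, pr[1]] + p[, pr[1]]
      conf[, pr[2]] <- conf[, pr[2]] + p[, pr[2]]
    }
  } else { # error_correcting
    codes <- model$meta$codes
    pbits <- vapply(seq_along(model$fits), function(b) {
      .prob_base(model$fits[[b]], x)[, "one"]
    }, numeric(n))
    pbits <- matrix(pbits, nrow = n)
    conf <- vapply(seq_along(classes), function(ci) {
      d <- rowSums(abs(sweep(pbits, 2L, codes[ci, ])))
      exp(-d)
    }, numeric(n))
    conf <- matrix(conf, nrow = n, dimnames = list(NULL, classes))
  }
  conf[!is.finite(conf)] <- 0
  conf <- pmax(conf, 0)
  rs <- rowSums(conf)
  zero <- rs == 0
  if (any(zero)) {
    conf[zero, ] <- 1 / length(classes)
    rs[zero] <- 1
  }
  conf / rs
}

#' Predict CPC ids (or confidences) for new referrals
#'
#' @param object A `cpc_classifier`.
#' @param features Feature matrix.
#' @param type `"class"` (default) or `"confidence"`.
#' @param ... Unused.
#' @return Character vector of CPC ids, or the confidence matrix.
#' @export
predict.cpc_classifier <- function(object, features,
                                   type = c("class", "confidence"), ...) {
  type <- match.arg(type)
  conf <- predict_confidence(object, features)
  if (type == "confidence") return(conf)
  object$classes[max.col(conf, ties.method = "first")]
}

#' Stratified fold assignment
#'
#' Deals each class's shuffled members cyclically across folds with a
#' pointer carried over between classes, so per-class fold counts differ
#' by at most one *and* total fold sizes differ by at most one.
#'
#' @param labels Character or factor class labels.
#' @param folds Number of folds, default 5.
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in `1:folds`, same length as
#'   `labels`.
#' @export
stratified_folds <- function(labels, folds = 5L, seed = 1L) {
  n <- length(labels)
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  if (folds > n) stop("more folds than rows")
  set.seed(seed)
  fold <- integer(n)
  ptr <- 0L
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    if (length(idx) > 1L) idx <- sample(idx)
    for (i in idx) {
      fold[i] <- ptr + 1L
      ptr <- (ptr + 1L) %% folds
    }
  }
  fold
}

#' Stratified k-fold cross-validated CPC classification
#'
#' Partitions the labelled referrals into stratified folds (each row is
#' tested exactly once), trains on the remaining folds and reports
#' per-fold and pooled accuracy.
#'
#' @param features A [build_features()] result or matrix.
#' @param labels Character CPC labels (every class at least one member).
#' @param folds Number of folds, default 5.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @return List with `fold_accuracy`, `accuracy` (pooled, equal to the
#'   overall fraction of correct held-out predictions), `folds`
#'   (assignment vector) and `predictions`.
#' @export
stratified_cv <- function(features, labels, folds = 5L,
                          spec = classifier_spec(), seed = 1L) {
  x <- .feat_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  fold <- stratified_folds(labels, folds = folds, seed = seed)
  preds <- character(length(labels))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    model <- train_supervised(x[!test, , drop = FALSE], labels[!test],
                              spec = spec, seed = seed)
    preds[test] <- predict(model, x[test, , drop = FALSE])
    fold_acc[f] <- mean(preds[test] == labels[test])
  }
  list(fold_accuracy = fold_acc, accuracy = mean(preds == labels),
       folds = fold, predictions = preds)
}

#' Self-training semi-supervised CPC classification
#'
#' Iteratively trains on the labelled pool, assigns pseudo-labels to the
#' unlabelled referrals whose top-class confidence reaches the cut-off
#' (default 0.75, deliberately above the plain 0.5 decision threshold),
#' moves them into the pool, and repeats until no pseudo-label is added
#' or `max_iter` is reached.
#'
#' @param x_labeled,x_unlabeled Feature matrices (same columns).
#' @param labels CPC labels for `x_labeled` (at least two classes).
#' @param spec A [classifier_spec()].
#' @param threshold Pseudo-label confidence cut-off in `(0.5, 1]`,
#'   default 0.75.
#' @param max_iter Maximum number of self-training iterations, default
#'   10.
#' @param seed Integer seed.
#' @return List with `model` (final [train_supervised()] fit), `log`
#'   (data.frame with `iteration`, `row`, `pseudo_label`, `confidence`)
#'   and `iterations`.
#' @export
self_train <- function(x_labeled, labels, x_unlabeled,
                       spec = classifier_spec(), threshold = 0.75,
                       max_iter = 10L, seed = 1L) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]")
  }
  xl <- as.matrix(.feat_matrix(x_labeled))
  xu <- as.matrix(.feat_matrix(x_unlabeled))
  labels <- as.character(labels)
  ids <- rownames(xu)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(xu)))
  log <- data.frame(iteration = integer(0), row = character(0),
                    pseudo_label = character(0), confidence = numeric(0),
                    stringsAsFactors = FALSE)
  remaining <- seq_len(nrow(xu))
  model <- train_supervised(xl, labels, spec = spec, seed = seed)
  iter <- 0L
  while (iter < max_iter && length(remaining)) {
    iter <- iter + 1L
    conf <- predict_confidence(model, xu[remaining, , drop = FALSE])
    top <- apply(conf, 1L, max)
    lab <- model$classes[max.col(conf, ties.method = "first")]
    take <- which(top >= threshold)
    if (!length(take)) break
    log <- rbind(log, data.frame(
      iteration = iter, row = ids[remaining[take]],
      pseudo_label = lab[take], confidence = top[take],
      stringsAsFactors = FALSE
    ))
    xl <- rbind(xl, xu[remaining[take], , drop = FALSE])
    labels <- c(labels, lab[take])
    remaining <- remaining[-take]
    model <- train_supervised(xl, labels, spec = spec, seed = seed)
  }
  rownames(log) <- NULL
  list(model = model, log = log, iterations = iter)
}
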