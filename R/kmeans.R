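#' Seeded k-means clustering of referrals
#'
#' Lloyd's algorithm with one cluster per CPC, centroids initialised
#' from per-CPC seed vectors (built from the CPC medical terms and
#' keywords vectorised into the referral feature space). Because every
#' cluster starts at — and stays bound to — its seeding CPC, cluster
#' assignments are CPC predictions. Iterations assign each referral to
#' its nearest centroid by Euclidean distance (ties toward the
#' lexicographically smallest `cpc_id`), then recompute centroids as
#' cluster means; a cluster that empties keeps (freezes) its previous
#' centroid. Convergence is declared when the largest centroid movement
#' falls below `tol`. The within-cluster sum of squares is recorded per
#' iteration and is non-increasing.
#'
#' @param features A [build_features()] result or numeric matrix of
#'   referrals.
#' @param seeds Either a named list of token vectors (one per CPC,
#'   vectorised with [vectorize_tokens()]) or a numeric matrix with one
#'   named row per CPC in the same column space as `features`. At least
#'   two seeds; a seed that vectorises to the zero vector is an error
#'   naming the CPC.
#' @param max_iter Maximum Lloyd iterations, default 300.
#' @param tol Convergence tolerance on centroid movement, default 1e-4.
#' @return Object of class `cluster_model`: list with `k`, `centroids`,
#'   `seed_labels`, `objective_trace`, `assignments` (CPC id per
#'   referral), `iterations` and `converged`.
#' @export
seeded_kmeans <- function(features, seeds, max_iter = 300L, tol = 1e-4) {
  x <- as.matrix(.feat_matrix(features))
  if (is.list(seeds)) {
    stopifnot(inherits(features, "feature_matrix"),
              !is.null(names(seeds)))
    seedmat <- as.matrix(vectorize_tokens(seeds, features,
                                          ids = names(seeds)))
    zero <- rowSums(abs(seedmat)) == 0
    if (any(zero)) {
      stop("seed vectorises to the zero vector for CPC: ",
           paste(rownames(seedmat)[zero], collapse = ", "))
    }
  } else {
    seedmat <- as.matrix(seeds)
  }
  if (is.null(rownames(seedmat))) {
    stop("seeds must be named by cpc_id")
  }
  if (nrow(seedmat) < 2L) stop("at least two seeds are required")
  seedmat <- seedmat[order(rownames(seedmat)), , drop = FALSE]
  k <- nrow(seedmat)
  cent <- seedmat
  n <- nrow(x)
  trace <- numeric(0)
  cl <- integer(n)
  iter <- 0L
  converged <- FALSE
  assign_rows <- function(cent) {
    d2 <- outer(rowSums(x^2), rowSums(cent^2), "+") -
      2 * (x %*% t(cent))
    d2 <- pmax(d2, 0)
    cl <- max.col(-d2, ties.method = "first")
    list(cl = cl, obj = sum(d2[cbind(seq_len(n), cl)]))
  }
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- assign_rows(cent)
    cl <- a$cl
    trace <- c(trace, a$obj)
    newcent <- cent
    for (j in seq_len(k)) {
      members <- cl == j
      if (any(members)) {
        newcent[j, ] <- colMeans(x[members, , drop = FALSE])
      } # empty cluster: centroid frozen at previous position
    }
    move <- max(sqrt(rowSums((newcent - cent)^2)))
    cent <- newcent
    if (move < tol) {
      converged <- TRUE
      break
    }
  }
  # final assignment consistent with the final centroids
  a <- assign_rows(cent)
  cl <- a$cl
  trace <- c(trace, a$obj)
  structure(
    list(k = k, centroids = cent, seed_labels = rownames(seedmat),
         objective_trace = trace,
         assignments = rownames(seedmat)[cl],
         iterations = iter, converged = converged),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, "| iterations:", x$iterations,
      "| converged:", x$converged, "\n")
  invisible(x)
}
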