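#' Per-feature normalization statistics
#'
#' Center/scale statistics (mean and standard deviation per feature) computed
#' on a reference cohort. Features are normalized before any margin-based
#' learning or distance computation; constant features get unit scale so they
#' pass through as zeros rather than NaNs.
#'
#' @param db a \linkS4class{TissueCohort} (the training database).
#' @return list with numeric vectors \code{center} and \code{scale}.
#' @export
featureStats <- function(db) {
  f <- featureMatrix(db)
  ctr <- colMeans(f)
  scl <- apply(f, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

.normalize <- function(features, stats) {
  sweep(sweep(features, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Build pairwise training instances
#'
#' One instance per unordered pair of database samples: the feature-vector
#' difference of the (normalized) pair restricted to the chosen feature
#' subset, labelled with the pair's TMS relevance. The absolute elementwise
#' difference (default) makes the representation symmetric in the pair, as
#' the two-direction rank combination assumes; the signed difference is
#' available for experimentation.
#'
#' @param db a validated \linkS4class{TissueCohort}.
#' @param sim a \linkS4class{TMSMatrix} for \code{db} (the gold-standard
#'   relevance).
#' @param subset integer indices of the features to use; default all.
#' @param difference \code{"absolute"} or \code{"signed"}.
#' @param stats normalization statistics from \code{\link{featureStats}};
#'   computed from \code{db} when omitted.
#' @return list of class \code{"PairInstances"} with elements \code{X}
#'   (pairs x features matrix of differences), \code{relevance},
#'   \code{queryId}, \code{candidateId}, \code{subset}, \code{difference},
#'   \code{center}, \code{scale}.
#' @export
makePairInstances <- function(db, sim, subset = NULL,
                              difference = c("absolute", "signed"),
                              stats = featureStats(db)) {
  difference <- match.arg(difference)
  f <- featureMatrix(db)
  if (is.null(subset)) subset <- seq_len(ncol(f))
  subset <- as.integer(subset)
  if (!length(subset)) stop("feature subset must be non-empty")
  fn <- .normalize(f, stats)[, subset, drop = FALSE]
  m <- nrow(fn)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  X <- fn[i, , drop = FALSE] - fn[j, , drop = FALSE]
  if (difference == "absolute") X <- abs(X)
  ids <- sampleIds(db)
  structure(list(
    X = X,
    relevance = tmsValues(sim)[cbind(i, j)],
    queryId = ids[i], candidateId = ids[j],
    subset = subset, difference = difference,
    center = stats$center, scale = stats$scale),
    class = "PairInstances")
}

#' Balanced sub-sampling of training pairs
#'
#' The TMS distribution of a cohort is typically dominated by mid-range
#' scores, which biases a ranker trained on all pairs. This divides the full
#' TMS range [0, 9] into \code{P} equal-width partitions, sets N_P to the
#' smallest number of pairs in a non-empty partition, and draws exactly N_P
#' pairs without replacement from each non-empty partition.
#'
#' @param instances a \code{"PairInstances"} list.
#' @param P number of equal-width partitions (>= 2); default 10.
#' @param seed integer seed making the draw reproducible.
#' @return a \code{"PairInstances"} list restricted to the balanced draw.
#' @export
sampleBalancedPairs <- function(instances, P = 10, seed = 1L) {
  if (P < 2) stop("P must be at least 2")
  rel <- instances$relevance
  width <- 9 / P
  bin <- pmin(floor(rel / width) + 1L, P)
  counts <- table(factor(bin, levels = seq_len(P)))
  nonEmpty <- which(counts > 0)
  if (length(nonEmpty) < 2)
    stop("fewer than 2 non-empty TMS partitions: no ordering signal")
  nP <- min(counts[nonEmpty])
  keep <- integer()
  rs <- .seedRNG(seed)
  on.exit(.restoreRNG(rs))
  for (b in nonEmpty) {
    inBin <- which(bin == b)
    keep <- c(keep, if (length(inBin) == 1L) inBin else
      sample(inBin, nP, replace = FALSE))
  }
  keep <- sort(keep)
  out <- instances
  out$X <- instances$X[keep, , drop = FALSE]
  out$relevance <- rel[keep]
  out$queryId <- instances$queryId[keep]
  out$candidateId <- instances$candidateId[keep]
  out
}

#' Train the pairwise ranking SVM
#'
#' Learns a linear scoring function on pair-difference vectors by the
#' pairwise margin formulation: every ordered pair of training instances with
#' strictly different relevance contributes the constraint that the
#' higher-relevance instance must score higher; instances with equal
#' relevance generate no constraint. The constraints are solved as a
#' soft-margin linear classification on the constraint difference vectors,
#' so the learned hyperplane normal is the ranking weight vector.
#'
#' The quadratic program is solved in the primal with the squared hinge loss
#' (an L2 soft-margin SVM): minimize \code{||w||^2 / 2 + C * sum_i max(0, 1 -
#' w . z_i)^2} over the constraint difference vectors \code{z_i}, by L-BFGS
#' with an analytic gradient. The solve is deterministic; no intercept is
#' fitted (the constraint set is sign-symmetric by construction).
#'
#' @param instances a \code{"PairInstances"} list (typically after
#'   \code{\link{sampleBalancedPairs}}).
#' @param regularization soft-margin cost; default 1.
#' @param seed integer recorded as the training seed.
#' @return a \linkS4class{RankingModel}.
#' @export
trainRankingSVM <- function(instances, regularization = 1, seed = 1L) {
  X <- instances$X
  rel <- instances$relevance
  if (nrow(X) < 2 || length(unique(rel)) < 2)
    stop("degenerate ordering: need at least 2 instances with distinct relevance")
  # constraints: for every pair a,b with rel[a] > rel[b], z = x_a - x_b
  pr <- which(outer(rel, rel, ">"), arr.ind = TRUE)  # row a has higher relevance
  Z <- X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE]
  w <- .solveRankSVM(Z, regularization)
  new("RankingModel",
      weights = unname(w), bias = 0,
      regularization = regularization,
      featureSubset = as.integer(instances$subset),
      center = instances$center, scale = instances$scale,
      difference = instances$difference,
      trainingSeed = as.integer(seed))
}

# primal L2-SVM on margin constraints w . z >= 1 (squared hinge, no bias)
.solveRankSVM <- function(Z, C) {
  p <- ncol(Z)
  obj <- function(w) {
    s <- 1 - drop(Z %*% w)
    v <- pmax(s, 0)
    sum(w^2) / 2 + C * sum(v^2)
  }
  grad <- function(w) {
    s <- 1 - drop(Z %*% w)
    act <- s > 0
    w - 2 * C * drop(crossprod(Z[act, , drop = FALSE], s[act]))
  }
  fit <- stats::optim(rep(0, p), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 1000, factr = 1e4))
  fit$par
}

# score of pairs (rows of A) vs (rows of B) under the model:
# S[i, j] = w . diff(A_i, B_j); A, B already normalized and subset
.pairScoreMatrix <- function(model, A, B) {
  w <- model@weights
  if (model@difference == "signed") {
    outer(drop(A %*% w), drop(B %*% w), "-")
  } else {
    S <- matrix(0, nrow(A), nrow(B))
    for (k in seq_along(w))
      S <- S + w[k] * abs(outer(A[, k], B[, k], "-"))
    S
  }
}

.prepFeatures <- function(model, features) {
  .normalize(features, list(center = model@center, scale = model@scale))[,
    model@featureSubset, drop = FALSE]
}

#' Score database candidates for a query
#'
#' Applies the learned ranking function to the pair (query, candidate) for
#' every database sample; a higher score means a better match. The query must
#' not itself be a database record.
#'
#' @param model a \linkS4class{RankingModel}.
#' @param query named numeric vector of the query's raw features (full cohort
#'   feature width).
#' @param db the \linkS4class{TissueCohort} to search.
#' @param queryId optional query identifier; an error is raised if a database
#'   sample carries the same ID.
#' @return named numeric vector of scores, one per database sample.
#' @export
scoreCandidates <- function(model, query, db, queryId = NULL) {
  if (!is.null(queryId) && queryId %in% sampleIds(db))
    stop(sprintf("query '%s' is present in the database", queryId))
  Fdb <- .prepFeatures(model, featureMatrix(db))
  q <- .prepFeatures(model, matrix(query, nrow = 1,
                                   dimnames = list(NULL, names(query))))
  drop(stats::setNames(.pairScoreMatrix(model, q, Fdb)[1, ], sampleIds(db)))
}

.rankWithTies <- function(scores, ids) {
  # 1-based positions: higher score first, exact ties by ascending sample ID
  ord <- order(-scores, ids)
  pos <- integer(length(scores))
  pos[ord] <- seq_along(ord)
  pos
}

#' Symmetric two-direction retrieval ranking
#'
#' Ranks every database sample for a query by combining two directions: the
#' forward rank of the candidate when all database samples are scored against
#' the query, and the reverse rank of the query when it takes the candidate's
#' place (the query is ranked within the database with the candidate swapped
#' out). The combined rank is their sum; candidates similar to the query but
#' dissimilar to the rest of the database are boosted, generic matches are
#' penalized. Ties in the combined rank are resolved by the forward rank —
#' the retrieval is done for the query.
#'
#' @param model a \linkS4class{RankingModel}.
#' @param query named numeric vector of raw query features.
#' @param db the \linkS4class{TissueCohort} to search (m >= 3).
#' @param queryId identifier for the query (used for error checking and
#'   tie-breaks); default \code{"query"}.
#' @param relevance optional named numeric vector of TMS relevances of the
#'   database samples to the query, attached to the result.
#' @param dbScores optional precomputed m x m matrix of pair scores among
#'   database samples (row i = scores from sample i's perspective); computed
#'   when omitted.
#' @return a \linkS4class{RetrievalResult} over all m candidates.
#' @export
symmetricRanking <- function(model, query, db, queryId = "query",
                             relevance = NULL, dbScores = NULL) {
  m <- nSamples(db)
  if (m < 3) stop("symmetric ranking requires at least 3 database samples")
  ids <- sampleIds(db)
  if (queryId %in% ids)
    stop(sprintf("query '%s' is present in the database", queryId))
  Fdb <- .prepFeatures(model, featureMatrix(db))
  q <- .prepFeatures(model, matrix(query, nrow = 1,
                                   dimnames = list(NULL, names(query))))
  fwdScores <- .pairScoreMatrix(model, q, Fdb)[1, ]
  rankFwd <- .rankWithTies(fwdScores, ids)
  if (is.null(dbScores)) dbScores <- .pairScoreMatrix(model, Fdb, Fdb)
  # reverse direction: candidate d_i plays the query; its candidate set is
  # (D \ d_i) + q, and we record the position of q in that ranking
  revScores <- .pairScoreMatrix(model, Fdb, q)[, 1]
  rankRev <- integer(m)
  for (i in seq_len(m)) {
    sc <- dbScores[i, -i]
    cid <- ids[-i]
    sq <- revScores[i]
    rankRev[i] <- 1L + sum(sc > sq) + sum(sc == sq & cid < queryId)
  }
  combined <- rankFwd + rankRev
  ord <- order(combined, rankFwd)
  cand <- data.frame(
    candidate_id = ids[ord],
    rank_forward = rankFwd[ord],
    rank_reverse = rankRev[ord],
    rank_combined = combined[ord],
    score = fwdScores[ord],
    tms_relevance = if (is.null(relevance)) NA_real_ else
      unname(relevance[ids[ord]]),
    stringsAsFactors = FALSE)
  new("RetrievalResult", queryId = queryId, candidates = cand,
      T = NA_integer_)
}

#' Truncate a retrieval result to the top T candidates
#'
#' @param result a \linkS4class{RetrievalResult}.
#' @param T number of samples to retrieve (>= 1); the study setting is T = 5.
#' @return the result truncated to its first \code{min(T, m)} candidates (a
#'   prefix of the full ordering).
#' @export
retrieveTopT <- function(result, T = 5) {
  if (T < 1) stop("T must be at least 1")
  keep <- seq_len(min(T, nrow(result@candidates)))
  initialize(result, candidates = result@candidates[keep, , drop = FALSE],
             T = as.integer(T))
}

#' k-nearest-neighbour retrieval baseline
#'
#' Ranks database samples by ascending Euclidean distance to the query on the
#' normalized selected features, ties broken by ascending sample ID. Serves
#' as the distance-based baseline against the learned ranker.
#'
#' @param query named numeric vector of raw query features.
#' @param db the \linkS4class{TissueCohort} to search.
#' @param k number of neighbours to retrieve; default 5.
#' @param subset integer feature indices; default all.
#' @param stats normalization statistics (\code{\link{featureStats}});
#'   computed from \code{db} when omitted.
#' @param queryId identifier for the query.
#' @param relevance optional named numeric vector of TMS relevances.
#' @return a \linkS4class{RetrievalResult} truncated to \code{k} candidates.
#' @export
knnRetrieve <- function(query, db, k = 5, subset = NULL,
                        stats = featureStats(db), queryId = "query",
                        relevance = NULL) {
  if (k < 1) stop("k must be at least 1")
  ids <- sampleIds(db)
  f <- .normalize(featureMatrix(db), stats)
  q <- .normalize(matrix(query, nrow = 1, dimnames = list(NULL, names(query))),
                  stats)
  if (is.null(subset)) subset <- seq_len(ncol(f))
  f <- f[, subset, drop = FALSE]; q <- q[, subset, drop = FALSE]
  d <- sqrt(rowSums(sweep(f, 2, q[1, ], "-")^2))
  pos <- integer(length(d))
  pos[order(d, ids)] <- seq_along(d)
  ord <- order(pos)
  cand <- data.frame(
    candidate_id = ids[ord],
    rank_forward = pos[ord],
    rank_reverse = NA_integer_,
    rank_combined = pos[ord],
    score = -d[ord],
    tms_relevance = if (is.null(relevance)) NA_real_ else
      unname(relevance[ids[ord]]),
    stringsAsFactors = FALSE)
  retrieveTopT(new("RetrievalResult", queryId = queryId, candidates = cand,
                   T = NA_integer_), k)
}
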