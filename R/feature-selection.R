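# inner-CV NDCG evaluator used by every stage of the feature search:
# trains the ranker on inner-training folds and averages NDCG@T over the
# held-out inner queries
.makeSubsetEvaluator <- function(db, sim, config, seed) {
  cfg <- config
  folds <- .assignFolds(db, cfg$innerFolds, .deriveSeed(seed, 17),
                        stratify = isTRUE(cfg$stratifyGleason))
  allF <- featureMatrix(db)
  allScores <- criterionScores(db)
  force(sim)
  function(subset) {
    subset <- as.integer(subset)
    vals <- c()
    for (kk in seq_len(cfg$innerFolds)) {
      test <- which(folds == kk)
      if (!length(test) || length(test) >= nSamples(db) - 2) next
      train <- db[, -test]
      hists <- buildHistograms(train)
      tsim <- similarityMatrix(train, hists)
      stats <- featureStats(train)
      inst <- makePairInstances(train, tsim, subset = subset,
                                difference = cfg$difference, stats = stats)
      bal <- sampleBalancedPairs(inst, P = cfg$P,
                                 seed = .deriveSeed(seed, 23 + kk))
      model <- tryCatch(
        trainRankingSVM(bal, regularization = cfg$regularization,
                        seed = .deriveSeed(seed, 31 + kk)),
        error = function(e) NULL)
      if (is.null(model)) {
        # degenerate subset (e.g. constant feature): deterministic zero-weight
        # ordering, evaluated as-is
        warning("degenerate training for subset; using zero-weight model")
        model <- new("RankingModel",
                     weights = rep(0, length(subset)), bias = 0,
                     regularization = cfg$regularization,
                     featureSubset = subset,
                     center = stats$center, scale = stats$scale,
                     difference = cfg$difference, trainingSeed = 0L)
      }
      Fdb <- .prepFeatures(model, featureMatrix(train))
      dbScores <- .pairScoreMatrix(model, Fdb, Fdb)
      trainScores <- criterionScores(train)
      for (qi in test) {
        rel <- .relevanceVector(hists, allScores[qi, ], trainScores)
        names(rel) <- sampleIds(train)
        full <- symmetricRanking(model, allF[qi, ], train,
                                 queryId = sampleIds(db)[qi],
                                 relevance = rel, dbScores = dbScores)
        top <- retrieveTopT(full, cfg$T)
        vals <- c(vals, ndcg(top@candidates$tms_relevance, rel, cfg$T))
      }
    }
    mean(vals)
  }
}

#' Individual retrieval performance of each feature
#'
#' Scores every feature alone: the ranker is trained and evaluated by inner
#' cross-validation using only that feature, and the mean NDCG at the
#' retrieval cutoff is returned. This ordering seeds the first stage of the
#' feature search.
#'
#' @param db training \linkS4class{TissueCohort}.
#' @param sim \linkS4class{TMSMatrix} of \code{db}.
#' @param config evaluation settings (\code{\link{evalConfig}});
#'   \code{innerFolds} controls the inner cross-validation.
#' @param seed integer seed (inner folds and sampling).
#' @param evaluator optional evaluator function \code{subset -> NDCG}
#'   (injected mainly for testing).
#' @return numeric vector of per-feature NDCG values, one per cohort feature.
#' @export
individualFeatureNDCG <- function(db, sim, config = evalConfig(), seed = 1L,
                                  evaluator = NULL) {
  if (config$innerFolds < 2) stop("inner cross-validation needs >= 2 folds")
  if (is.null(evaluator))
    evaluator <- .makeSubsetEvaluator(db, sim, config, seed)
  nf <- ncol(featureMatrix(db))
  vapply(seq_len(nf), function(j) evaluator(j), numeric(1))
}

#' Stage 1: forward scan over the individual-performance ordering
#'
#' Evaluates the feature prefixes of length 1..F of the supplied ordering
#' (features sorted by individual NDCG, best first) and returns the prefix
#' with maximal NDCG; the earliest prefix wins ties.
#'
#' @param orderedFeatures integer feature indices, best individual performer
#'   first.
#' @param evaluator function mapping a feature index vector to an NDCG value.
#' @return list with \code{best} (the winning prefix), \code{curve} (NDCG per
#'   prefix length) and \code{order} (the input ordering).
#' @export
stage1ForwardScan <- function(orderedFeatures, evaluator) {
  curve <- vapply(seq_along(orderedFeatures), function(L)
    evaluator(orderedFeatures[seq_len(L)]), numeric(1))
  best <- which.max(curve)  # earliest maximum on ties
  list(best = orderedFeatures[seq_len(best)], curve = curve,
       order = orderedFeatures)
}

#' Stage 2: sequential floating forward selection
#'
#' Classic SFFS starting from the stage-1 best prefix: repeatedly add the
#' best-improving excluded feature, then conditionally delete already
#' selected features while deletion strictly improves the NDCG. Only strict
#' improvements (beyond a small tolerance) are accepted, so the accepted-step
#' NDCG sequence is strictly increasing; the search stops when no addition
#' improves or the iteration budget is exhausted.
#'
#' @param startSubset integer feature indices to start from.
#' @param evaluator function mapping a feature index vector to NDCG.
#' @param allFeatures integer vector of all candidate feature indices.
#' @param maxIter iteration safety bound; default \code{2 * length(allFeatures)}.
#' @param tol strict-improvement tolerance; default 1e-9.
#' @return list with \code{subset}, \code{ndcg} and \code{steps} (data.frame
#'   of accepted actions).
#' @export
stage2SFFS <- function(startSubset, evaluator, allFeatures,
                       maxIter = 2 * length(allFeatures), tol = 1e-9) {
  if (maxIter < 1) stop("maxIter must be at least 1")
  current <- as.integer(startSubset)
  best <- evaluator(current)
  steps <- data.frame(action = character(), feature = integer(),
                      ndcg = numeric(), stringsAsFactors = FALSE)
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > maxIter) break
    excluded <- setdiff(allFeatures, current)
    if (!length(excluded)) break
    addVals <- vapply(excluded, function(f) evaluator(c(current, f)),
                      numeric(1))
    if (max(addVals) <= best + tol) break  # no improving addition
    f <- excluded[which.max(addVals)]
    current <- c(current, f)
    best <- max(addVals)
    steps <- rbind(steps, data.frame(action = "add", feature = f,
                                     ndcg = best))
    # conditional deletions while strictly improving
    while (length(current) > 1) {
      delVals <- vapply(seq_along(current), function(i)
        evaluator(current[-i]), numeric(1))
      if (max(delVals) <= best + tol) break
      i <- which.max(delVals)
      fdel <- current[i]
      current <- current[-i]
      best <- max(delVals)
      steps <- rbind(steps, data.frame(action = "remove", feature = fdel,
                                       ndcg = best))
    }
  }
  list(subset = current, ndcg = best, steps = steps)
}

#' Two-stage NDCG-driven feature selection
#'
#' Runs the complete wrapper search on a training cohort: (1) order the
#' features by individual cross-validated retrieval NDCG and scan prefixes of
#' that ordering for the best-performing starting set; (2) refine it by
#' sequential floating forward selection. Every candidate subset is scored by
#' retraining the ranker under inner cross-validation, so the selection
#' optimizes the deployed metric (NDCG at the retrieval cutoff).
#'
#' @param db training \linkS4class{TissueCohort}.
#' @param sim \linkS4class{TMSMatrix} of \code{db}; computed when omitted.
#' @param config evaluation settings (\code{\link{evalConfig}}).
#' @param seed integer seed.
#' @param maxIter SFFS iteration budget; default twice the feature count.
#' @param evaluator optional evaluator override (testing).
#' @return a \linkS4class{SelectionTrace}.
#' @export
selectFeatures <- function(db, sim = similarityMatrix(db),
                           config = evalConfig(), seed = 1L,
                           maxIter = NULL, evaluator = NULL) {
  nf <- ncol(featureMatrix(db))
  if (is.null(maxIter)) maxIter <- 2L * nf
  if (is.null(evaluator))
    evaluator <- .makeSubsetEvaluator(db, sim, config, seed)
  indiv <- individualFeatureNDCG(db, sim, config, seed, evaluator = evaluator)
  ord <- order(indiv, decreasing = TRUE)
  s1 <- stage1ForwardScan(ord, evaluator)
  s2 <- stage2SFFS(s1$best, evaluator, allFeatures = seq_len(nf),
                   maxIter = maxIter)
  new("SelectionTrace",
      stage1Order = as.integer(ord), stage1Curve = s1$curve,
      stage1Best = as.integer(s1$best),
      steps = s2$steps, finalSubset = as.integer(s2$subset),
      finalNDCG = s2$ndcg,
      cvFolds = as.integer(config$innerFolds), seed = as.integer(seed))
}
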