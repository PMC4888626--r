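#' Discounted cumulative gain of a retrieved list
#'
#' Graded-relevance retrieval gain: the sum over rank positions t = 1..T of
#' \code{(2^rel - 1) / log2(1 + t)}, where \code{rel} is the TMS relevance of
#' the sample retrieved at position t. Highly relevant samples are worth more,
#' and worth most when retrieved early.
#'
#' @param relevances numeric vector of relevances in retrieved rank order.
#' @param T truncation rank; default the full list length.
#' @return numeric DCG value.
#' @examples
#' dcg(c(3, 2, 1))  # 7 + 3/log2(3) + 1/2
#' @export
dcg <- function(relevances, T = length(relevances)) {
  if (T > length(relevances)) stop("T exceeds the list length")
  if (any(relevances < 0)) stop("negative relevance: TMS is non-negative")
  r <- relevances[seq_len(T)]
  sum((2^r - 1) / log2(1 + seq_len(T)))
}

#' Normalized discounted cumulative gain
#'
#' DCG of the retrieved order divided by the ideal DCG — the DCG of the T
#' most relevant candidates sorted in decreasing relevance. Equals 1 exactly
#' when the retrieval achieves the ideal top-T ordering; always lies in
#' [0, 1]. When every candidate has zero relevance the ideal DCG is 0 and
#' the NDCG is defined as 0 (with a warning).
#'
#' @param relevances numeric relevances of the retrieved samples, in rank
#'   order (length >= T).
#' @param allRelevances relevances of the full candidate set, from which the
#'   ideal ordering is taken.
#' @param T truncation rank; default \code{length(relevances)}.
#' @return numeric NDCG in [0, 1].
#' @examples
#' ndcg(c(3, 2, 1), c(1, 2, 3))        # ideal order -> 1
#' ndcg(c(1, 2, 3), c(1, 2, 3))        # reversed    -> 0.6806
#' @export
ndcg <- function(relevances, allRelevances, T = length(relevances)) {
  idcg <- dcg(sort(allRelevances, decreasing = TRUE),
              min(T, length(allRelevances)))
  if (idcg == 0) {
    warning("all candidate relevances are zero; NDCG defined as 0")
    return(0)
  }
  dcg(relevances, T) / idcg
}

#' Exact random-chance probability of a good-match count
#'
#' Probability that a uniformly random retrieval of T samples from a database
#' of \code{Ns} samples, \code{Nss} of which are good matches to the query,
#' contains at least \code{NG} good matches — the hypergeometric upper tail.
#'
#' @param Ns database size.
#' @param Nss number of database samples that are good matches (TMS with the
#'   query at or above the threshold).
#' @param T number of retrieved samples.
#' @param NG required number of good matches (0..T).
#' @return exact tail probability.
#' @examples
#' randomChance(Ns = 10, Nss = 5, T = 5, NG = 5)  # 1/252
#' @export
randomChance <- function(Ns, Nss, T, NG) {
  if (Nss < 0 || Nss > Ns) stop("need 0 <= Nss <= Ns")
  if (T < 1 || T > Ns) stop("need 1 <= T <= Ns")
  if (NG < 0 || NG > T) stop("need 0 <= NG <= T")
  if (NG == 0) return(1)
  stats::phyper(NG - 1, Nss, Ns - Nss, T, lower.tail = FALSE)
}

#' Binomial significance of an observed good-match count
#'
#' Treating each query's success (retrieving at least N_G good matches) as a
#' Bernoulli trial with the random-chance probability \code{pChance}, the
#' p-value is the exact binomial upper-tail probability of observing at least
#' \code{Nq} successes among \code{mQueries} queries.
#'
#' @param mQueries number of queries.
#' @param pChance per-query chance probability.
#' @param Nq observed number of successful queries.
#' @return exact binomial tail probability.
#' @examples
#' binomialSignificance(10, 0.5, 10)  # 0.5^10
#' @export
binomialSignificance <- function(mQueries, pChance, Nq) {
  if (Nq < 0 || Nq > mQueries) stop("need 0 <= Nq <= mQueries")
  if (pChance < 0 || pChance > 1) stop("pChance must lie in [0, 1]")
  if (Nq == 0) return(1)
  stats::pbinom(Nq - 1, mQueries, pChance, lower.tail = FALSE)
}

#' Good-match fraction curves over a threshold grid
#'
#' For each similarity threshold th_s and each good-match count N_G in 1..T,
#' the fraction of queries whose top-T retrieval contains at least N_G
#' candidates with TMS relevance >= th_s. Equivalent to the fraction of
#' queries achieving precision at least N_G / T.
#'
#' @param results list of \linkS4class{RetrievalResult} objects, each
#'   truncated to T and carrying TMS relevances.
#' @param thSGrid numeric thresholds; default 0:8.
#' @param T retrieval cutoff; default taken from the first result.
#' @return data.frame with columns \code{th_s}, \code{N_G}, \code{fraction},
#'   plus a \code{"precision"} attribute holding the per-query good-match
#'   counts (queries x thresholds).
#' @export
goodMatchCurve <- function(results, thSGrid = 0:8, T = results[[1]]@T) {
  if (is.na(T)) T <- nrow(results[[1]]@candidates)
  counts <- vapply(results, function(r) {
    rel <- r@candidates$tms_relevance[seq_len(min(T, nrow(r@candidates)))]
    vapply(thSGrid, function(th) sum(rel >= th), numeric(1))
  }, numeric(length(thSGrid)))
  counts <- matrix(counts, nrow = length(thSGrid))  # thresholds x queries
  grid <- expand.grid(N_G = seq_len(T), th_s = thSGrid)[, 2:1]
  grid$fraction <- mapply(function(th, g)
    mean(counts[match(th, thSGrid), ] >= g), grid$th_s, grid$N_G)
  rownames(grid) <- NULL
  nq <- ncol(counts)
  attr(grid, "precision") <- matrix(t(counts) / T, nrow = nq,
    dimnames = list(vapply(results, function(r) r@queryId, character(1)),
                    as.character(thSGrid)))
  grid
}

# ---- cross-validation harness ----------------------------------------------

#' Default evaluation configuration
#'
#' Bundles the tunable settings of the cross-validated evaluation pipeline.
#' Defaults follow the study conditions: T = 5 retrieved samples, K = 10
#' outer folds, P = 10 balanced-training partitions, k = 5 for the kNN
#' baseline, similarity thresholds 0..8.
#'
#' @param T retrieval cutoff.
#' @param K outer cross-validation folds.
#' @param P balanced-training partitions.
#' @param k neighbours for the kNN baseline.
#' @param thSGrid similarity threshold grid.
#' @param regularization ranking-SVM soft-margin cost.
#' @param difference feature-difference representation.
#' @param selectFeatures logical; run the two-stage NDCG feature selection on
#'   each training fold.
#' @param innerFolds inner cross-validation folds for feature selection.
#' @param stratifyGleason logical; assign outer folds stratified by Gleason
#'   sum instead of uniformly at random.
#' @param knnBaseline logical; also evaluate the kNN baseline.
#' @return named list of settings.
#' @export
evalConfig <- function(T = 5, K = 10, P = 10, k = 5, thSGrid = 0:8,
                       regularization = 1, difference = "absolute",
                       selectFeatures = FALSE, innerFolds = 5,
                       stratifyGleason = FALSE, knnBaseline = TRUE) {
  list(T = T, K = K, P = P, k = k, thSGrid = thSGrid,
       regularization = regularization, difference = difference,
       selectFeatures = selectFeatures, innerFolds = innerFolds,
       stratifyGleason = stratifyGleason, knnBaseline = knnBaseline)
}

.assignFolds <- function(db, K, seed, stratify = FALSE) {
  m <- nSamples(db)
  rs <- .seedRNG(seed)
  on.exit(.restoreRNG(rs))
  if (stratify) {
    g <- gleasonSum(db)
    fold <- integer(m)
    for (lev in unique(g)) {
      idx <- sample(which(g == lev))
      fold[idx] <- rep_len(sample(K), length(idx))
    }
    fold
  } else {
    sample(rep_len(seq_len(K), m))
  }
}

# TMS of one query against every row of a score table (vectorized over rows)
.relevanceVector <- function(hists, qscores, scoreTab) {
  qscores <- unlist(qscores)
  total <- numeric(nrow(scoreTab))
  for (nm in names(hists@histograms)) {
    h <- hists@histograms[[nm]]
    rng <- as.integer(names(h))
    lut <- vapply(rng, function(s) tmsCriterion(hists, nm, qscores[[nm]], s),
                  numeric(1))
    total <- total + lut[match(scoreTab[[nm]], rng)]
  }
  total
}

# evaluate one set of queries against a training cohort; returns per-query
# rows and the top-T retrieval results for both methods
.evaluateQueries <- function(train, queryFeatures, queryScores, queryIds,
                             model, cfg, hists, knnStats = NULL,
                             knnSubset = NULL) {
  Fdb <- .prepFeatures(model, featureMatrix(train))
  dbScores <- .pairScoreMatrix(model, Fdb, Fdb)
  trainScores <- criterionScores(train)
  out <- list(rows = NULL, svm = list(), knn = list(), chance = NULL)
  for (qi in seq_along(queryIds)) {
    qid <- queryIds[qi]
    rel <- .relevanceVector(hists, queryScores[qi, ], trainScores)
    names(rel) <- sampleIds(train)
    full <- symmetricRanking(model, queryFeatures[qi, ], train,
                             queryId = qid, relevance = rel,
                             dbScores = dbScores)
    top <- retrieveTopT(full, cfg$T)
    nd5 <- ndcg(top@candidates$tms_relevance, rel, cfg$T)
    ndf <- ndcg(full@candidates$tms_relevance, rel)
    rows <- data.frame(query_id = qid, method = "RankingSVM",
                       ndcg_at_T = nd5, ndcg_full = ndf,
                       stringsAsFactors = FALSE)
    out$svm[[qid]] <- top
    if (isTRUE(cfg$knnBaseline)) {
      kf <- knnRetrieve(queryFeatures[qi, ], train, k = nSamples(train),
                        subset = knnSubset, stats = knnStats,
                        queryId = qid, relevance = rel)
      ktop <- retrieveTopT(kf, cfg$T)
      rows <- rbind(rows, data.frame(
        query_id = qid, method = "kNN",
        ndcg_at_T = ndcg(ktop@candidates$tms_relevance, rel, cfg$T),
        ndcg_full = ndcg(kf@candidates$tms_relevance, rel),
        stringsAsFactors = FALSE))
      out$knn[[qid]] <- retrieveTopT(kf, cfg$k)
    }
    out$rows <- rbind(out$rows, rows)
    out$rel[[qid]] <- rel
    out$chance <- rbind(out$chance, data.frame(
      query_id = qid, Ns = nSamples(train),
      th_s = cfg$thSGrid,
      Nss = vapply(cfg$thSGrid, function(th) sum(rel >= th), numeric(1)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Cross-validated evaluation of the retrieval pipeline
#'
#' The complete leakage-safe evaluation harness. The cohort is split into K
#' roughly equal folds; in each repetition the held-out fold's samples are
#' the queries and the union of the remaining folds is the database. Score
#' histograms, feature normalization, balanced pair sampling, optional
#' feature selection and ranker training are all fit on the training folds
#' only. Reports per-query NDCG at the cutoff T and over the full list,
#' good-match fraction curves across the similarity-threshold grid, exact
#' hypergeometric chance baselines and binomial significance, for the learned
#' ranker and (optionally) the kNN baseline.
#'
#' @param db a validated \linkS4class{TissueCohort} with m >= 2K.
#' @param config a list from \code{\link{evalConfig}}.
#' @param seed integer seed controlling fold assignment and all sampling.
#' @return an \linkS4class{EvaluationReport}.
#' @export
kfoldCrossValidate <- function(db, config = evalConfig(), seed = 1L) {
  cfg <- config
  K <- cfg$K
  m <- nSamples(db)
  if (K > m) stop("K exceeds the cohort size")
  if (m < 2 * K) stop("cohort must contain at least 2K samples")
  fold <- .assignFolds(db, K, .deriveSeed(seed, 1),
                       stratify = isTRUE(cfg$stratifyGleason))
  perQuery <- NULL
  svmTops <- list(); knnTops <- list()
  chanceRows <- NULL; relList <- list()
  allF <- featureMatrix(db)
  allScores <- criterionScores(db)
  for (kk in seq_len(K)) {
    test <- which(fold == kk)
    if (!length(test)) next
    train <- db[, -test]
    hists <- buildHistograms(train)
    sim <- similarityMatrix(train, hists)
    stats <- featureStats(train)
    subset <- seq_len(ncol(allF))
    if (isTRUE(cfg$selectFeatures)) {
      trace <- selectFeatures(train, sim = sim, config = cfg,
                              seed = .deriveSeed(seed, 100 + kk))
      subset <- trace@finalSubset
    }
    inst <- makePairInstances(train, sim, subset = subset,
                              difference = cfg$difference, stats = stats)
    bal <- sampleBalancedPairs(inst, P = cfg$P,
                               seed = .deriveSeed(seed, 200 + kk))
    model <- trainRankingSVM(bal, regularization = cfg$regularization,
                             seed = .deriveSeed(seed, 300 + kk))
    res <- .evaluateQueries(train, allF[test, , drop = FALSE],
                            allScores[test, , drop = FALSE],
                            sampleIds(db)[test], model, cfg, hists,
                            knnStats = stats, knnSubset = subset)
    res$rows$fold <- kk
    perQuery <- rbind(perQuery, res$rows)
    svmTops <- c(svmTops, res$svm)
    knnTops <- c(knnTops, res$knn)
    chanceRows <- rbind(chanceRows, res$chance)
    relList <- c(relList, res$rel)
  }
  .buildReport(perQuery, svmTops, knnTops, chanceRows, relList, cfg, seed)
}

.buildReport <- function(perQuery, svmTops, knnTops, chanceRows, relList,
                         cfg, seed) {
  summaries <- do.call(rbind, lapply(split(perQuery, perQuery$method),
    function(d) data.frame(
      method = d$method[1],
      metric = c("ndcg_at_T", "ndcg_full"),
      mean = c(mean(d$ndcg_at_T), mean(d$ndcg_full)),
      sd = c(stats::sd(d$ndcg_at_T), stats::sd(d$ndcg_full)),
      stringsAsFactors = FALSE)))
  rownames(summaries) <- NULL
  curves <- NULL
  methods <- list(RankingSVM = svmTops)
  if (length(knnTops)) methods$kNN <- knnTops
  for (nm in names(methods)) {
    cu <- goodMatchCurve(methods[[nm]], thSGrid = cfg$thSGrid, T = cfg$T)
    cu <- cbind(method = nm, cu)
    attr(cu, "precision") <- NULL
    curves <- rbind(curves, cu)
  }
  # shared chance probability per (th_s, N_G): the mean over queries of the
  # exact per-query hypergeometric tail
  chance <- NULL
  for (th in cfg$thSGrid) {
    sub <- chanceRows[chanceRows$th_s == th, ]
    for (g in seq_len(cfg$T)) {
      p <- mean(mapply(function(ns, nss) randomChance(ns, nss, cfg$T, g),
                       sub$Ns, sub$Nss))
      chance <- rbind(chance, data.frame(th_s = th, N_G = g, p = p))
    }
  }
  nq <- length(svmTops)
  signif <- NULL
  for (nm in names(methods)) {
    cu <- curves[curves$method == nm, ]
    for (r in seq_len(nrow(cu))) {
      pch <- chance$p[chance$th_s == cu$th_s[r] & chance$N_G == cu$N_G[r]]
      Nq <- round(cu$fraction[r] * nq)
      signif <- rbind(signif, data.frame(
        method = nm, th_s = cu$th_s[r], N_G = cu$N_G[r], N_q = Nq,
        p_value = binomialSignificance(nq, pch, Nq),
        stringsAsFactors = FALSE))
    }
  }
  new("EvaluationReport",
      perQuery = perQuery[, c("fold", "query_id", "method",
                              "ndcg_at_T", "ndcg_full")],
      summaries = summaries, curves = curves, chance = chance,
      significance = signif, relevances = relList,
      config = c(cfg, list(seed = as.integer(seed), n_queries = nq)))
}

#' Evaluation report accessors
#'
#' @param x an \linkS4class{EvaluationReport}.
#' @return \code{reportSummaries}: the mean +/- sd NDCG table;
#'   \code{reportCurves}: the good-match fraction curves;
#'   \code{reportChance}: the hypergeometric chance baselines;
#'   \code{reportSignificance}: the binomial significance table;
#'   \code{reportPerQuery}: per-query NDCG values.
#' @export
reportSummaries <- function(x) x@summaries

#' @rdname reportSummaries
#' @export
reportCurves <- function(x) x@curves

#' @rdname reportSummaries
#' @export
reportChance <- function(x) x@chance

#' @rdname reportSummaries
#' @export
reportSignificance <- function(x) x@significance

#' @rdname reportSummaries
#' @export
reportPerQuery <- function(x) x@perQuery

#' @rdname reportSummaries
#' @export
reportRelevances <- function(x) x@relevances
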