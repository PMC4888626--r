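test_that("DCG matches hand evaluation of the gain/discount sum", {
  expect_equal(dcg(c(3, 2, 1)), 7 + 3 / log2(3) + 1 / 2, tolerance = 1e-12)
  expect_equal(dcg(c(3, 2, 1)), 9.392789, tolerance = 1e-6)
  expect_equal(dcg(c(0, 0, 0)), 0)
  expect_equal(dcg(5.5, 1), 2^5.5 - 1)  # single item: log2(2) = 1
  expect_error(dcg(c(1, -0.1)), "negative")
  expect_error(dcg(c(1, 2), T = 3), "exceeds")
})

test_that("NDCG is 1 exactly for the ideal ordering and bounded by it", {
  expect_equal(ndcg(c(3, 2, 1), c(1, 2, 3)), 1)
  expect_equal(ndcg(c(1, 2, 3), c(3, 2, 1)), 6.392789 / 9.392789,
               tolerance = 1e-6)
  # exhaustive permutations: no ordering exceeds the ideal one
  for (rels in list(c(0, 1, 2.5, 4), c(2, 2, 5), c(0.3, 1.1, 1.1, 6, 2, 3))) {
    vals <- vapply(allPerms(length(rels)), function(p)
      ndcg(rels[p], rels), numeric(1))
    expect_lte(max(vals), 1 + 1e-12)
    expect_equal(ndcg(sort(rels, decreasing = TRUE), rels), 1)
  }
  expect_warning(z <- ndcg(c(0, 0), c(0, 0)), "zero")
  expect_equal(z, 0)
})

test_that("hypergeometric chance equals exact enumeration", {
  # spot value: all five of five good, 5 good in a database of 10
  expect_equal(randomChance(10, 5, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-14)
  expect_equal(randomChance(10, 5, 5, 0), 1)
  expect_equal(randomChance(12, 12, 5, 4), 1)
  # agreement with direct binomial-coefficient sums over the full support
  for (cs in list(c(20, 7, 5), c(15, 3, 6), c(9, 9, 4))) {
    Ns <- cs[1]; Nss <- cs[2]; T <- cs[3]
    direct <- function(g) {
      hi <- min(T, Nss)
      if (g > hi) return(0)
      xs <- max(0, g):hi
      sum(choose(Nss, xs) * choose(Ns - Nss, T - xs)) / choose(Ns, T)
    }
    for (g in 0:T)
      expect_equal(randomChance(Ns, Nss, T, g), direct(g), tolerance = 1e-12)
    # point masses sum to one
    pm <- vapply(0:T, function(x) {
      if (x > Nss || T - x > Ns - Nss) 0 else
        choose(Nss, x) * choose(Ns - Nss, T - x) / choose(Ns, T)
    }, numeric(1))
    expect_equal(sum(pm), 1, tolerance = 1e-12)
  }
  expect_error(randomChance(10, 11, 5, 1), "Nss")
  expect_error(randomChance(10, 5, 11, 1), "T")
})

test_that("binomial significance equals the exact upper tail", {
  expect_equal(binomialSignificance(10, 0.5, 10), 0.5^10, tolerance = 1e-14)
  expect_equal(binomialSignificance(10, 0.5, 0), 1)
  expect_equal(binomialSignificance(7, 1, 5), 1)
  m <- 14; p <- 0.23
  direct <- function(nq) sum(choose(m, nq:m) * p^(nq:m) * (1 - p)^(m - nq:m))
  for (nq in 0:m)
    expect_equal(binomialSignificance(m, p, nq), direct(nq),
                 tolerance = 1e-12)
  # monotone: non-increasing in N_q, non-decreasing in p
  vals <- vapply(0:m, function(nq) binomialSignificance(m, p, nq), numeric(1))
  expect_true(all(diff(vals) <= 1e-14))
  ps <- seq(0.05, 0.95, by = 0.1)
  vp <- vapply(ps, function(pp) binomialSignificance(m, pp, 6), numeric(1))
  expect_true(all(diff(vp) >= -1e-14))
  expect_error(binomialSignificance(10, 0.5, 11), "Nq")
})

test_that("good-match curves reproduce a hand tally and are monotone", {
  mk <- function(rels, qid) new("RetrievalResult", queryId = qid,
    candidates = data.frame(candidate_id = paste0("c", seq_along(rels)),
                            rank_forward = seq_along(rels),
                            rank_reverse = seq_along(rels),
                            rank_combined = 2 * seq_along(rels),
                            score = -seq_along(rels), tms_relevance = rels),
    T = length(rels))
  # three queries, T = 3, hand-labelled good matches at th_s = 5:
  #   q1: relevances 6,6,2 -> 2 good; q2: 5,3,1 -> 1; q3: 7,6,5 -> 3
  res <- list(mk(c(6, 6, 2), "q1"), mk(c(5, 3, 1), "q2"), mk(c(7, 6, 5), "q3"))
  cu <- goodMatchCurve(res, thSGrid = c(0, 5), T = 3)
  at5 <- cu[cu$th_s == 5, ]
  expect_equal(at5$fraction[at5$N_G == 1], 1)          # all three have >= 1
  expect_equal(at5$fraction[at5$N_G == 2], 2 / 3)      # q1 and q3
  expect_equal(at5$fraction[at5$N_G == 3], 1 / 3)      # q3 only
  expect_true(all(cu$fraction[cu$th_s == 0] == 1))
  # non-increasing in N_G at every threshold
  for (th in unique(cu$th_s))
    expect_true(all(diff(cu$fraction[cu$th_s == th]) <= 0))
  prec <- attr(cu, "precision")
  expect_equal(unname(prec[, "5"]), c(2, 1, 3) / 3)
})

test_that("cross-validation partitions are disjoint and leakage-free", {
  db <- simulateCohort(simConfig(m = 24, nFeatures = 3, seed = 15))
  rep <- kfoldCrossValidate(db, evalConfig(K = 4, knnBaseline = FALSE),
                            seed = 3)
  pq <- reportPerQuery(rep)
  # every sample is a query exactly once across folds
  expect_setequal(pq$query_id, sampleIds(db))
  expect_equal(nrow(pq), 24)
  # a query never appears among its own candidates
  rels <- reportRelevances(rep)
  for (qid in names(rels))
    expect_false(qid %in% names(rels[[qid]]))
  expect_error(kfoldCrossValidate(db, evalConfig(K = 13)), "2K")
})

test_that("query scores only affect evaluation, never the ranked order", {
  # the trained model and hence the retrieval order depend on the database
  # alone: changing a held-out query's criterion scores can change relevance
  # labels, but not the candidate ordering
  db <- simulateCohort(simConfig(m = 15, nFeatures = 3, seed = 4))
  model <- trainOnCohort(db, seed = 1)
  hists <- buildHistograms(db)
  set.seed(2)
  q <- rnorm(3); names(q) <- featureNames(db)
  relA <- TissueRetrieval:::.relevanceVector(hists,
    criterionScores(fixtureCohort("tiny-6"))[1, ], criterionScores(db))
  relB <- TissueRetrieval:::.relevanceVector(hists,
    criterionScores(fixtureCohort("tiny-6"))[5, ], criterionScores(db))
  names(relA) <- names(relB) <- sampleIds(db)
  rA <- symmetricRanking(model, q, db, queryId = "Q", relevance = relA)
  rB <- symmetricRanking(model, q, db, queryId = "Q", relevance = relB)
  expect_identical(rA@candidates$candidate_id, rB@candidates$candidate_id)
  expect_identical(rA@candidates$rank_combined, rB@candidates$rank_combined)
})

test_that("the learned ranker beats random orderings on a noise-free cohort", {
  db <- simulateCohort(simConfig(m = 24, nFeatures = 4, coupling = 2,
                                 noiseSd = 0, informativeFraction = 1,
                                 seed = 31))
  rep <- kfoldCrossValidate(db, evalConfig(K = 4, knnBaseline = FALSE),
                            seed = 8)
  pq <- reportPerQuery(rep)
  obs <- mean(pq$ndcg_at_T)
  rels <- reportRelevances(rep)
  set.seed(99)
  nullMeans <- replicate(100, mean(vapply(rels, function(r)
    ndcg(sample(r, 5), r, 5), numeric(1))))
  expect_gt(obs, max(nullMeans))
})
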