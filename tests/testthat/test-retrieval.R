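test_that("pair instances enumerate unordered pairs with TMS relevance", {
  db <- randomCohort(4, nFeatures = 3, seed = 1)
  sim <- similarityMatrix(db)
  inst <- makePairInstances(db, sim)
  expect_equal(nrow(inst$X), 6)  # 4*3/2
  v <- tmsValues(sim)
  for (r in seq_len(6))
    expect_identical(inst$relevance[r], v[inst$queryId[r], inst$candidateId[r]])
  # identical feature vectors give a zero difference vector
  sc <- criterionScores(db)
  twin <- TissueCohort(matrix(1, 3, 2), sc[c(1, 1, 2), ], c("A", "B", "C"))
  ti <- makePairInstances(twin, similarityMatrix(twin))
  expect_true(all(ti$X == 0))
  expect_error(makePairInstances(db, sim, subset = integer(0)), "non-empty")
})

test_that("balanced sampling draws N_P pairs from each non-empty partition", {
  # constructed bin counts {10, 3, 7}: rel 0.1 (bin 1), 1.0 (bin 2), 2.0 (bin 3)
  rel <- c(rep(0.1, 10), rep(1.0, 3), rep(2.0, 7))
  inst <- structure(list(
    X = matrix(seq_along(rel), ncol = 1), relevance = rel,
    queryId = paste0("q", seq_along(rel)),
    candidateId = paste0("c", seq_along(rel)),
    subset = 1L, difference = "absolute", center = 0, scale = 1),
    class = "PairInstances")
  bal <- sampleBalancedPairs(inst, P = 10, seed = 4)
  expect_equal(nrow(bal$X), 9)  # N_P = 3 from each of 3 non-empty bins
  expect_equal(as.integer(table(bal$relevance)), rep(3L, 3))
  # determinism and partition membership
  bal2 <- sampleBalancedPairs(inst, P = 10, seed = 4)
  expect_identical(bal$X, bal2$X)
  width <- 9 / 10
  expect_true(all(floor(bal$relevance / width) %in% (c(1, 2, 3) - 1)))
  # fewer than two non-empty partitions is degenerate
  flat <- inst; flat$relevance <- rep(5, 20)
  expect_error(sampleBalancedPairs(flat, P = 10, seed = 1), "non-empty")
})

test_that("the trained ranker reproduces a perfectly anti-monotone ordering", {
  # 1-D feature whose |difference| is strictly anti-monotone with TMS
  ps <- fixtureCohort("perfect-signal")
  model <- trainOnCohort(ps, seed = 2)
  expect_lt(model@weights, 0)
  sim <- similarityMatrix(ps)
  inst <- makePairInstances(ps, sim)
  scores <- drop(inst$X %*% model@weights)
  # every strict relevance ordering is reproduced by the learned scores
  for (a in seq_len(nrow(inst$X))) {
    better <- inst$relevance > inst$relevance[a]
    expect_true(all(scores[better] > scores[a]))
  }
})

test_that("duplicating every instance leaves the learned ordering unchanged", {
  ps <- fixtureCohort("perfect-signal")
  sim <- similarityMatrix(ps)
  inst <- makePairInstances(ps, sim)
  m1 <- trainRankingSVM(inst, 1, 1)
  dup <- inst
  dup$X <- rbind(inst$X, inst$X)
  dup$relevance <- c(inst$relevance, inst$relevance)
  m2 <- trainRankingSVM(dup, 1, 1)
  expect_identical(sign(m1@weights), sign(m2@weights))
  expect_identical(order(inst$X %*% m1@weights), order(inst$X %*% m2@weights))
  # all-equal relevance has no ordering signal
  flat <- inst; flat$relevance <- rep(1, length(inst$relevance))
  expect_error(trainRankingSVM(flat, 1, 1), "degenerate")
})

test_that("primal solve agrees with the libsvm dual on a separable problem", {
  skip_if_not_installed("e1071")
  set.seed(8)
  n <- 40
  X <- cbind(runif(n, 0, 2), runif(n, 0, 2))
  rel <- -(2 * X[, 1] + X[, 2]) + 9  # relevance decreasing in both columns
  inst <- structure(list(X = X, relevance = rel,
                         queryId = paste0("q", 1:n),
                         candidateId = paste0("c", 1:n),
                         subset = 1:2, difference = "absolute",
                         center = c(0, 0), scale = c(1, 1)),
                    class = "PairInstances")
  mod <- trainRankingSVM(inst, 1, 1)
  pr <- which(outer(rel, rel, ">"), arr.ind = TRUE)
  Z <- X[pr[, 1], ] - X[pr[, 2], ]
  fit <- e1071::svm(x = rbind(Z, -Z),
                    y = factor(rep(c("pos", "neg"), each = nrow(Z)),
                               levels = c("pos", "neg")),
                    kernel = "linear", cost = 1, scale = FALSE)
  wd <- drop(t(fit$coefs) %*% fit$SV)
  # the two solvers optimize slightly different losses; on a separable
  # problem their directions agree closely
  cosine <- sum(mod@weights * wd) /
    sqrt(sum(mod@weights^2) * sum(wd^2))
  expect_gt(cosine, 0.99)
  expect_gt(cor(drop(X %*% mod@weights), drop(X %*% wd)), 0.999)
})

test_that("candidate scoring is deterministic and peaks at zero difference", {
  db <- randomCohort(6, nFeatures = 3, seed = 9)
  model <- new("RankingModel", weights = c(-1, -0.5, -2), bias = 0,
               regularization = 1, featureSubset = 1:3,
               center = rep(0, 3), scale = rep(1, 3),
               difference = "absolute", trainingSeed = 1L)
  q <- featureMatrix(db)[2, ]  # identical to candidate 2 in feature space
  s <- scoreCandidates(model, q, db)
  expect_equal(unname(which.max(s)), 2)
  expect_equal(unname(s[2]), 0)
  # invariant to candidate ordering
  perm <- c(4, 2, 6, 1, 3, 5)
  s2 <- scoreCandidates(model, q, db[, perm])
  expect_equal(s2[names(s)], s)
  # zero weights tie every candidate
  z <- model; z@weights <- rep(0, 3)
  expect_equal(unname(range(scoreCandidates(z, q, db))), c(0, 0))
  expect_error(scoreCandidates(model, q, db, queryId = sampleIds(db)[1]),
               "present in the database")
})

test_that("symmetric combination follows the combined-then-forward rule", {
  db <- randomCohort(6, nFeatures = 2, seed = 13)
  model <- trainOnCohort(db, seed = 1)
  q <- rnorm(2); names(q) <- featureNames(db)
  res <- symmetricRanking(model, q, db, queryId = "Q")
  cand <- res@candidates
  # the forward ranks are a permutation of 1..m; each reverse rank is a
  # position within its own swapped candidate set, hence in 1..m
  expect_setequal(cand$rank_forward, 1:6)
  expect_true(all(cand$rank_reverse >= 1 & cand$rank_reverse <= 6))
  expect_identical(cand$rank_combined, cand$rank_forward + cand$rank_reverse)
  key <- order(cand$rank_combined, cand$rank_forward)
  expect_identical(key, seq_len(6))
  expect_error(symmetricRanking(model, q, db[, 1:2], queryId = "Q"),
               "at least 3")
})

test_that("combined ranking matches the brute-force oracle across seeds", {
  for (seed in 1:12) {
    m <- 5 + seed %% 4
    db <- randomCohort(m, nFeatures = 3, seed = seed)
    model <- trainOnCohort(db, seed = seed)
    set.seed(1000 + seed)
    q <- rnorm(3); names(q) <- featureNames(db)
    res <- symmetricRanking(model, q, db, queryId = "Q")
    expect_identical(res@candidates$candidate_id,
                     bruteSymmetricOrder(model, q, db, "Q"),
                     info = sprintf("seed %d", seed))
  }
})

test_that("top-T retrieval is a prefix of the full ordering", {
  db <- randomCohort(8, nFeatures = 2, seed = 3)
  model <- trainOnCohort(db, seed = 3)
  q <- c(feat_1 = 0.5, feat_2 = -0.5)
  full <- symmetricRanking(model, q, db, queryId = "Q")
  top5 <- retrieveTopT(full, 5)
  expect_equal(nrow(top5@candidates), 5)
  expect_identical(top5@candidates, full@candidates[1:5, ])
  expect_identical(retrieveTopT(full, 100)@candidates, full@candidates)
  expect_error(retrieveTopT(full, 0), "at least 1")
})

test_that("kNN baseline sorts by normalized Euclidean distance", {
  db <- randomCohort(7, nFeatures = 3, seed = 21)
  q <- featureMatrix(db)[4, ]
  res <- knnRetrieve(q, db, k = 7)
  cand <- res@candidates
  expect_identical(cand$candidate_id[1], sampleIds(db)[4])  # distance 0
  expect_equal(cand$score[1], 0)
  # brute-force distance sort oracle
  st <- featureStats(db)
  fn <- scale(featureMatrix(db), st$center, st$scale)
  qn <- (q - st$center) / st$scale
  d <- sqrt(rowSums(sweep(fn, 2, qn, "-")^2))
  expect_identical(cand$candidate_id,
                   sampleIds(db)[order(d, sampleIds(db))])
  # shared rescaling of every record leaves the ordering unchanged
  db2 <- TissueCohort(featureMatrix(db) * 2, criterionScores(db),
                      sampleIds(db))
  res2 <- knnRetrieve(featureMatrix(db2)[4, ], db2, k = 7)
  expect_identical(res2@candidates$candidate_id, cand$candidate_id)
})

test_that("retrieval is reproducible under a fixed seed", {
  db <- simulateCohort(simConfig(m = 20, nFeatures = 4, seed = 6))
  m1 <- trainOnCohort(db, seed = 5)
  m2 <- trainOnCohort(db, seed = 5)
  expect_identical(m1@weights, m2@weights)
  q <- rnorm(4); names(q) <- featureNames(db)
  r1 <- symmetricRanking(m1, q, db, queryId = "Q")
  r2 <- symmetricRanking(m2, q, db, queryId = "Q")
  expect_identical(r1@candidates, r2@candidates)
})
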