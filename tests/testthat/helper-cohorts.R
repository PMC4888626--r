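# Shared fixtures and independent brute-force oracles for the suite.
# The oracles re-derive every quantity from its definition with plain loops,
# never through the package's own computational path.

# random cohort with uniform scores and standard-normal features
randomCohort <- function(m, nFeatures = 3, seed = 1) {
  schema <- defaultSchema()
  set.seed(seed)
  scores <- as.data.frame(lapply(seq_len(nrow(schema)), function(i)
    sample(seq.int(schema$score_min[i], schema$score_max[i]), m,
           replace = TRUE)), check.names = FALSE)
  names(scores) <- schema$name
  TissueCohort(features = matrix(rnorm(m * nFeatures), m,
                                 dimnames = list(NULL,
                                   paste0("feat_", seq_len(nFeatures)))),
               scores = scores, sampleIds = sprintf("R%03d", seq_len(m)),
               schema = schema)
}

# brute-force TMS between two score rows, straight from the definition:
# per criterion, count samples strictly between the two scores plus half the
# counts at the endpoints, normalize by z, subtract from 1, and sum
bruteTMS <- function(scoreTab, schema, i, j, z = nrow(scoreTab)) {
  total <- 0
  for (k in seq_len(nrow(schema))) {
    nm <- schema$name[k]
    s1 <- scoreTab[[nm]][i]; s2 <- scoreTab[[nm]][j]
    lo <- min(s1, s2); hi <- max(s1, s2)
    num <- 0
    if (lo == hi) {
      num <- sum(scoreTab[[nm]] == lo)
    } else {
      for (s in seq.int(lo, hi)) {
        cnt <- sum(scoreTab[[nm]] == s)
        num <- num + if (s == lo || s == hi) cnt / 2 else cnt
      }
    }
    total <- total + 1 - num / z
  }
  total
}

bruteTMSMatrix <- function(db) {
  scoreTab <- criterionScores(db)
  schema <- cohortSchema(db)
  m <- nrow(scoreTab)
  v <- matrix(0, m, m, dimnames = list(sampleIds(db), sampleIds(db)))
  for (i in seq_len(m)) for (j in seq_len(m))
    v[i, j] <- bruteTMS(scoreTab, schema, i, j)
  v
}

# brute-force symmetric two-direction ranking: naive loops over candidates,
# explicit rank counting with ID tie-breaks
bruteSymmetricOrder <- function(model, query, db, queryId = "Q") {
  ids <- sampleIds(db)
  m <- length(ids)
  feats <- featureMatrix(db)
  sc <- function(a, b) {  # model score of a pair of raw feature vectors
    an <- (a - model@center) / model@scale
    bn <- (b - model@center) / model@scale
    d <- an[model@featureSubset] - bn[model@featureSubset]
    if (model@difference == "absolute") d <- abs(d)
    sum(model@weights * d)
  }
  fwd <- vapply(seq_len(m), function(i) sc(query, feats[i, ]), numeric(1))
  rankOf <- function(scores, labels, target) {
    # 1-based position of `target` when sorting by score desc, ID asc
    s0 <- scores[labels == target]
    1L + sum(scores > s0) + sum(scores == s0 & labels < target)
  }
  rankFwd <- vapply(ids, function(id) rankOf(fwd, ids, id), integer(1))
  rankRev <- integer(m)
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    labs <- c(ids[others], queryId)
    scs <- c(vapply(others, function(j) sc(feats[i, ], feats[j, ]),
                    numeric(1)),
             sc(feats[i, ], query))
    rankRev[i] <- rankOf(scs, labs, queryId)
  }
  comb <- rankFwd + rankRev
  ids[order(comb, rankFwd)]
}

# all permutations of 1..n (n small)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1)
  }
  out
}

# quick pipeline: train a ranker on a full cohort with balanced pairs;
# tiny random cohorts can have all pairs in one TMS partition (or all-equal
# relevance), in which case training falls back to a fixed deterministic model
trainOnCohort <- function(db, subset = NULL, P = 10, seed = 1,
                          difference = "absolute") {
  sim <- similarityMatrix(db)
  inst <- makePairInstances(db, sim, subset = subset, difference = difference)
  tryCatch({
    bal <- sampleBalancedPairs(inst, P = P, seed = seed)
    trainRankingSVM(bal, regularization = 1, seed = seed)
  }, error = function(e) {
    set.seed(seed)
    new("RankingModel", weights = -abs(rnorm(ncol(inst$X))), bias = 0,
        regularization = 1, featureSubset = inst$subset,
        center = inst$center, scale = inst$scale,
        difference = difference, trainingSeed = as.integer(seed))
  })
}
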