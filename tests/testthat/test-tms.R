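test_that("histograms tally the score distribution with Z = m", {
  db <- fixtureCohort("tiny-6")
  h <- buildHistograms(db)
  expect_equal(h@z, 6)
  expect_equal(unname(h@histograms[["Gland crowding"]]),
               c(2L, 2L, 2L, 0L))
  expect_equal(unname(h@histograms[["Gleason score"]]),
               c(2L, 2L, 2L, 0L, 0L))
  # conservation: counts always sum to m
  for (seed in 1:5) {
    db <- randomCohort(11, seed = seed)
    h <- buildHistograms(db)
    for (cnt in h@histograms) expect_equal(sum(cnt), 11)
  }
  expect_error(buildHistograms(db[, 1]), "at least 2")
})

test_that("per-criterion similarity matches the hand-worked cases", {
  h <- buildHistograms(fixtureCohort("tiny-6"))  # counts (2,2,2), Z = 6
  # extreme scores: 1 - (2 + (2+2)/2)/6 = 1/3
  expect_equal(tmsCriterion(h, "Gland crowding", 0, 2), 1 / 3,
               tolerance = 1e-14)
  # adjacent scores, empty between-sum: 1 - (0 + (2+2)/2)/6 = 2/3
  expect_equal(tmsCriterion(h, "Gland crowding", 0, 1), 2 / 3,
               tolerance = 1e-14)
  # same score: 1 - h(s)/Z
  expect_equal(tmsCriterion(h, "Gland crowding", 1, 1), 1 - 2 / 6,
               tolerance = 1e-14)
  # symmetry and range checks
  expect_identical(tmsCriterion(h, "Gleason score", 6, 8),
                   tmsCriterion(h, "Gleason score", 8, 6))
  expect_error(tmsCriterion(h, "Gland crowding", 0, 4), "outside range")
  expect_error(tmsCriterion(h, "no such", 0, 1), "unknown criterion")
})

test_that("pair TMS sums the nine per-criterion similarities", {
  db <- fixtureCohort("tiny-6")
  h <- buildHistograms(db)
  sc <- criterionScores(db)
  # all 9 criteria give 2/3 for a same-group pair -> TMS = 6
  expect_equal(tms(h, sc[1, ], sc[2, ]), 6, tolerance = 1e-12)
  expect_equal(tms(h, sc[1, ], sc[5, ]), 3, tolerance = 1e-12)
  # symmetry and bounds on random cohorts
  for (seed in 1:5) {
    rdb <- randomCohort(9, seed = seed)
    rh <- buildHistograms(rdb)
    rsc <- criterionScores(rdb)
    v12 <- tms(rh, rsc[3, ], rsc[7, ])
    expect_identical(v12, tms(rh, rsc[7, ], rsc[3, ]))
    expect_gte(v12, 0); expect_lte(v12, 9)
  }
})

test_that("similarity matrix equals the brute-force double loop", {
  for (seed in 1:3) {
    db <- randomCohort(6, seed = seed)
    sim <- similarityMatrix(db, perCriterion = TRUE)
    expect_equal(tmsValues(sim), bruteTMSMatrix(db), tolerance = 1e-12)
    pc <- tmsPerCriterion(sim)
    expect_equal(dim(pc), c(6, 6, 9))
    expect_gte(min(pc), 0); expect_lte(max(pc), 1)
  }
  # permuting record order permutes rows/columns consistently
  db <- randomCohort(7, seed = 11)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  v1 <- tmsValues(similarityMatrix(db))
  v2 <- tmsValues(similarityMatrix(db[, perm]))
  expect_equal(v2, v1[perm, perm], tolerance = 1e-12)
  # identical records give a constant matrix
  sc <- criterionScores(db)[rep(1, 5), ]
  same <- TissueCohort(matrix(1, 5, 2), sc, sprintf("C%d", 1:5))
  vs <- tmsValues(similarityMatrix(same))
  expect_equal(max(vs) - min(vs), 0)
})

test_that("similarity weakly decreases as scores move apart in the distribution", {
  db <- randomCohort(20, seed = 5)
  h <- buildHistograms(db)
  for (nm in cohortSchema(db)$name) {
    rng <- as.integer(names(h@histograms[[nm]]))
    for (s1 in rng) {
      vals <- vapply(rng[rng >= s1], function(s2)
        tmsCriterion(h, nm, s1, s2), numeric(1))
      if (length(vals) > 2)  # beyond the same-score endpoint case
        expect_true(all(diff(vals[-1]) <= 1e-12),
                    info = sprintf("%s from s1=%d", nm, s1))
    }
  }
})

test_that("mass between two scores strictly lowers their similarity", {
  schema <- defaultSchema()
  base <- fixtureCohort("tiny-6")
  sc <- criterionScores(base)
  h0 <- buildHistograms(base, z = 8)
  # add two samples scoring strictly between 0 and 2 on every criterion
  mid <- sc[3:4, ]  # the middle-group rows
  db2 <- TissueCohort(rbind(featureMatrix(base), featureMatrix(base)[3:4, ]),
                      rbind(sc, mid), c(sampleIds(base), "X1", "X2"))
  h1 <- buildHistograms(db2, z = 8)  # same Z isolates the between-mass effect
  for (nm in schema$name[schema$name != "Gleason score"]) {
    expect_lt(tmsCriterion(h1, nm, 0, 2), tmsCriterion(h0, nm, 0, 2))
  }
})

test_that("good-match labels threshold the similarity matrix elementwise", {
  db <- fixtureCohort("tiny-6")
  sim <- similarityMatrix(db)
  expect_true(all(goodMatchLabels(sim, 0)))
  expect_false(any(goodMatchLabels(sim, 9)))  # max pair TMS is 6 here
  lab <- goodMatchLabels(sim, 5)
  expect_identical(lab, tmsValues(sim) >= 5)
  expect_identical(lab, t(lab))
  expect_error(goodMatchLabels(sim, 9.5), "0, 9")
})
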