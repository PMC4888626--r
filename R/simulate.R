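#' Simulation configuration for synthetic cohorts
#'
#' Bundles the parameters of the synthetic cohort generator: cohort size,
#' feature width, strength of the linear map coupling criterion scores to
#' features, Gaussian feature noise, per-criterion score marginals and the
#' fraction of features that actually carry signal. Defaults give a generic
#' mid-skewed cohort; \code{\link{defaultStudyConfig}} reproduces the
#' published study's cohort structure.
#'
#' @param m number of samples (>= 2).
#' @param nFeatures number of morphological features.
#' @param coupling strength (>= 0) of the linear map from centered criterion
#'   scores to the informative features; 0 decouples features from scores.
#' @param noiseSd standard deviation of the additive Gaussian feature noise.
#' @param scoreMarginals named list of per-criterion probability vectors over
#'   each criterion's score range; defaults to mid-skewed marginals.
#' @param informativeFraction fraction in (0, 1] of features coupled to the
#'   scores; the rest are pure noise.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @param schema criterion schema; see \code{\link{defaultSchema}}.
#' @return named list of class \code{"SimConfig"}.
#' @export
simConfig <- function(m = 60, nFeatures = 20, coupling = 1, noiseSd = 1,
                      scoreMarginals = NULL, informativeFraction = 0.25,
                      seed = 1L, schema = defaultSchema()) {
  .checkSchema(schema)
  if (m < 2) stop("m must be at least 2")
  if (coupling < 0 || noiseSd < 0)
    stop("coupling and noiseSd must be non-negative")
  if (informativeFraction <= 0 || informativeFraction > 1)
    stop("informativeFraction must lie in (0, 1]")
  if (is.null(scoreMarginals)) scoreMarginals <- .defaultMarginals(schema)
  for (nm in schema$name) {
    p <- scoreMarginals[[nm]]
    if (is.null(p)) stop(sprintf("missing marginal for criterion '%s'", nm))
    if (length(p) != length(scoreRange(schema, nm)))
      stop(sprintf("marginal length mismatch for '%s'", nm))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(sprintf("marginal for '%s' must be a probability vector", nm))
  }
  structure(list(m = as.integer(m), nFeatures = as.integer(nFeatures),
                 coupling = coupling, noiseSd = noiseSd,
                 scoreMarginals = scoreMarginals,
                 informativeFraction = informativeFraction,
                 seed = as.integer(seed), schema = schema),
            class = "SimConfig")
}

# mid-skewed marginals: most samples sit at the middle score levels, as real
# pathologist scoring concentrates away from the extremes
.defaultMarginals <- function(schema) {
  out <- lapply(seq_len(nrow(schema)), function(i) {
    n <- schema$score_max[i] - schema$score_min[i] + 1L
    switch(as.character(n),
           "3" = c(0.2, 0.55, 0.25),
           "4" = c(0.1, 0.35, 0.4, 0.15),
           "5" = c(0.15, 0.25, 0.2, 0.1, 0.3),
           rep(1 / n, n))
  })
  names(out) <- schema$name
  out
}

#' Study-structured simulation configuration
#'
#' Configuration emulating the published study's cohort: 114 samples with 308
#' morphological features, the Gleason-sum marginal proportional to the
#' study's counts (19, 26, 22, 10, 37 samples at Gleason 6-10), and the
#' remaining criteria skewed toward mid scores so that the pairwise TMS
#' distribution is dominated by mid-range values (5-6) with high scores
#' (>= 8) rare.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to \code{\link{simConfig}} (e.g.
#'   \code{noiseSd}).
#' @return a \code{"SimConfig"} list.
#' @export
defaultStudyConfig <- function(seed = 1L, ...) {
  schema <- defaultSchema()
  marg <- .defaultMarginals(schema)
  marg[["Gleason score"]] <- c(19, 26, 22, 10, 37) / 114
  args <- list(m = 114, nFeatures = 308, coupling = 1, noiseSd = 1,
               scoreMarginals = marg, informativeFraction = 0.25,
               seed = seed, schema = schema)
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

#' Generate a synthetic tissue cohort
#'
#' Draws criterion scores independently per criterion from the configured
#' marginals, then builds feature vectors: the informative features are
#' row-wise linear combinations of the centered criterion scores under a
#' fixed random loading matrix (one loading matrix per seed, so the
#' feature-to-criterion map is stationary across samples) scaled by
#' \code{coupling}, plus Gaussian noise; the remaining features are pure
#' noise. Fully reproducible: the same configuration yields a bit-identical
#' cohort.
#'
#' @param cfg a \code{"SimConfig"} from \code{\link{simConfig}}.
#' @return a validated \linkS4class{TissueCohort}.
#' @examples
#' db <- simulateCohort(simConfig(m = 20, nFeatures = 6, seed = 7))
#' nSamples(db)
#' @export
simulateCohort <- function(cfg) {
  if (!inherits(cfg, "SimConfig")) stop("cfg must come from simConfig()")
  schema <- cfg$schema
  rs <- .seedRNG(cfg$seed)
  on.exit(.restoreRNG(rs))
  scores <- as.data.frame(lapply(schema$name, function(nm) {
    rng <- scoreRange(schema, nm)
    sample(rng, cfg$m, replace = TRUE, prob = cfg$scoreMarginals[[nm]])
  }), check.names = FALSE)
  names(scores) <- schema$name
  S <- scale(as.matrix(scores), center = TRUE, scale = FALSE)
  nInf <- max(1L, ceiling(cfg$informativeFraction * cfg$nFeatures))
  nInf <- min(nInf, cfg$nFeatures)
  L <- matrix(stats::rnorm(nInf * ncol(S)), nrow = nInf)
  Finf <- cfg$coupling * (S %*% t(L)) +
    matrix(stats::rnorm(cfg$m * nInf, sd = cfg$noiseSd), nrow = cfg$m)
  nNoise <- cfg$nFeatures - nInf
  Fnoise <- if (nNoise > 0)
    matrix(stats::rnorm(cfg$m * nNoise), nrow = cfg$m)
  features <- cbind(Finf, Fnoise)
  colnames(features) <- paste0("feat_", seq_len(cfg$nFeatures))
  TissueCohort(features = features, scores = scores,
               sampleIds = sprintf("S%03d", seq_len(cfg$m)),
               schema = schema)
}

# ---- fixture registry -------------------------------------------------------

.fixtureRegistry <- c("tiny-6", "perfect-signal", "pure-noise", "study-like")

#' Canned synthetic fixtures
#'
#' Deterministic cohorts used throughout the test suite and worked examples:
#' \describe{
#'   \item{tiny-6}{six samples in three score groups of two; every criterion
#'     has counts (2, 2, 2) over its used levels, so the per-criterion
#'     similarities take the hand-computable values 2/3 (same or adjacent
#'     score) and 1/3 (extreme scores), and pair TMS is 6 or 3.}
#'   \item{perfect-signal}{thirty samples in three equal groups whose single
#'     feature equals the group label; all nine criteria are injective in the
#'     group, making the feature's absolute difference perfectly
#'     anti-monotone with TMS. Used for parameter-recovery tests.}
#'   \item{pure-noise}{thirty samples whose features are independent of the
#'     criterion scores (zero coupling).}
#'   \item{study-like}{the \code{\link{defaultStudyConfig}} cohort.}
#' }
#'
#' @param name fixture name (see above).
#' @param seed integer seed for the stochastic fixtures.
#' @return a \linkS4class{TissueCohort}.
#' @export
fixtureCohort <- function(name, seed = 20160601L) {
  if (!name %in% .fixtureRegistry)
    stop(sprintf("unknown fixture '%s'; registry: %s", name,
                 paste(.fixtureRegistry, collapse = ", ")))
  schema <- defaultSchema()
  if (name == "tiny-6") {
    g <- c(0L, 0L, 1L, 1L, 2L, 2L)
    scores <- as.data.frame(lapply(schema$name, function(nm)
      if (nm == .gleasonName) 6L + g else g), check.names = FALSE)
    names(scores) <- schema$name
    TissueCohort(features = cbind(feat_1 = as.numeric(g),
                                  feat_2 = as.numeric(seq_along(g))),
                 scores = scores, sampleIds = sprintf("T%02d", seq_along(g)),
                 schema = schema)
  } else if (name == "perfect-signal") {
    g <- rep(0:2, each = 10)
    scores <- as.data.frame(lapply(schema$name, function(nm)
      if (nm == .gleasonName) 6L + g else g), check.names = FALSE)
    names(scores) <- schema$name
    TissueCohort(features = cbind(feat_1 = as.numeric(g)),
                 scores = scores, sampleIds = sprintf("P%03d", seq_along(g)),
                 schema = schema)
  } else if (name == "pure-noise") {
    simulateCohort(simConfig(m = 30, nFeatures = 5, coupling = 0,
                             noiseSd = 1, seed = seed))
  } else {
    simulateCohort(defaultStudyConfig(seed = seed))
  }
}

#' Write a fixture cohort (and its expected values) to disk
#'
#' Materializes a registry fixture as a cohort CSV; for \code{tiny-6} an
#' expected-value JSON with the hand-derived TMS matrix (pair TMS 6 for
#' samples zero or one score level apart, 3 for two levels apart, computed
#' from the histogram formula by hand, independent of the package's own
#' similarity code) is written alongside.
#'
#' @param name registry fixture name.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the stochastic fixtures.
#' @return character vector of written file paths.
#' @export
makeFixture <- function(name, outDir, seed = 20160601L) {
  db <- fixtureCohort(name, seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(outDir, paste0(name, ".csv"))
  writeCohort(db, csv, format = "csv")
  paths <- csv
  if (name == "tiny-6") {
    g <- c(0, 0, 1, 1, 2, 2)
    expected <- list(
      tms_matrix = 6 - 3 * (abs(outer(g, g, "-")) == 2),
      sample_ids = sampleIds(db),
      criterion_cases = list(
        extreme_scores = 1 / 3,    # counts (2,2,2), Z=6, scores 0 vs 2
        adjacent_scores = 2 / 3,   # scores 0 vs 1: empty between-sum
        same_score = 2 / 3))       # 1 - h(s)/Z = 1 - 2/6
    json <- file.path(outDir, paste0(name, "-expected.json"))
    jsonlite::write_json(expected, json, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, json)
  }
  paths
}
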