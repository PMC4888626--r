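#' Build per-criterion score histograms
#'
#' Tallies, for each morphologic criterion, how many cohort samples carry each
#' score of the criterion's range. These histograms drive the
#' distribution-weighted similarity: two samples far apart in the score
#' distribution of a criterion are dissimilar with respect to it, regardless
#' of the absolute score difference. The normalization factor Z defaults to
#' the cohort size m, which bounds every per-criterion similarity in [0, 1].
#'
#' @param db a validated \linkS4class{TissueCohort} with m >= 2.
#' @param z normalization factor; default \code{nSamples(db)}.
#' @return a \linkS4class{ScoreHistogramSet}.
#' @examples
#' db <- simulateCohort(simConfig(m = 12, nFeatures = 3, seed = 1))
#' buildHistograms(db)
#' @export
buildHistograms <- function(db, z = nSamples(db)) {
  m <- nSamples(db)
  if (m < 2L) stop("histograms require at least 2 samples")
  schema <- cohortSchema(db)
  scores <- criterionScores(db)
  hists <- lapply(seq_len(nrow(schema)), function(i) {
    rng <- seq.int(schema$score_min[i], schema$score_max[i])
    tab <- tabulate(match(scores[[schema$name[i]]], rng), nbins = length(rng))
    stats::setNames(as.integer(tab), as.character(rng))
  })
  names(hists) <- schema$name
  new("ScoreHistogramSet", histograms = hists, z = as.numeric(z),
      m = as.integer(m), schema = schema)
}

#' Per-criterion distribution-weighted similarity
#'
#' Similarity of two scores under one criterion's histogram: one minus the
#' (normalized) number of samples lying between the two scores in the score
#' distribution, counting samples at the two endpoint scores half each. Equal
#' scores give \code{1 - h(s)/Z}. Symmetric in its two score arguments and
#' bounded in [0, 1] when Z is at least the cohort size.
#'
#' @param hists a \linkS4class{ScoreHistogramSet}.
#' @param criterion criterion name.
#' @param s1,s2 integer scores within the criterion's range.
#' @return numeric similarity in [0, 1].
#' @examples
#' db <- simulateCohort(simConfig(m = 12, nFeatures = 3, seed = 1))
#' h <- buildHistograms(db)
#' tmsCriterion(h, "Gleason score", 6, 8)
#' @export
tmsCriterion <- function(hists, criterion, s1, s2) {
  h <- hists@histograms[[criterion]]
  if (is.null(h)) stop(sprintf("unknown criterion '%s'", criterion))
  rng <- as.integer(names(h))
  if (!(s1 %in% rng) || !(s2 %in% rng))
    stop(sprintf("score outside range of criterion '%s'", criterion))
  lo <- min(s1, s2); hi <- max(s1, s2)
  if (lo == hi) {
    num <- h[[as.character(lo)]]
  } else {
    between <- rng > lo & rng < hi
    num <- sum(h[between]) + (h[[as.character(lo)]] + h[[as.character(hi)]]) / 2
  }
  1 - num / hists@z
}

#' Tissue morphologic similarity of two samples
#'
#' The TMS score of a pair of samples: the sum of the per-criterion
#' distribution-weighted similarities over all nine criteria. Ranges from 0 to
#' 9 and is symmetric in its two arguments. TMS is the gold-standard relevance
#' for retrieval: the histograms must come from the reference database the
#' similarity is judged against.
#'
#' @param hists a \linkS4class{ScoreHistogramSet} built from the reference
#'   database.
#' @param scores1,scores2 named numeric vectors (or single-row data.frames) of
#'   criterion scores for the two samples, names matching the schema.
#' @return numeric TMS in [0, 9].
#' @examples
#' db <- simulateCohort(simConfig(m = 12, nFeatures = 3, seed = 1))
#' h <- buildHistograms(db)
#' sc <- criterionScores(db)
#' tms(h, sc[1, ], sc[2, ])
#' @export
tms <- function(hists, scores1, scores2) {
  scores1 <- unlist(scores1); scores2 <- unlist(scores2)
  nms <- names(hists@histograms)
  if (!all(nms %in% names(scores1)) || !all(nms %in% names(scores2)))
    stop("score vectors do not match the histogram schema")
  sum(vapply(nms, function(nm)
    tmsCriterion(hists, nm, scores1[[nm]], scores2[[nm]]), numeric(1)))
}

#' All-pairs TMS similarity matrix
#'
#' Computes the tissue morphologic similarity for every pair of cohort
#' samples (including the diagonal, evaluated by the same formula), returning
#' a symmetric m x m matrix — the gold standard of retrieval relevance.
#'
#' @param db a validated \linkS4class{TissueCohort}.
#' @param hists optional \linkS4class{ScoreHistogramSet}; defaults to
#'   histograms of \code{db} itself. Pass training-database histograms to
#'   score held-out samples against a reference cohort.
#' @param perCriterion logical; also keep the m x m x 9 per-criterion
#'   decomposition.
#' @return a \linkS4class{TMSMatrix}.
#' @examples
#' db <- simulateCohort(simConfig(m = 8, nFeatures = 3, seed = 1))
#' sim <- similarityMatrix(db)
#' tmsValues(sim)[1:3, 1:3]
#' @export
similarityMatrix <- function(db, hists = buildHistograms(db),
                             perCriterion = FALSE) {
  scores <- criterionScores(db)
  ids <- sampleIds(db)
  m <- nrow(scores)
  nms <- names(hists@histograms)
  perC <- if (perCriterion)
    array(0, dim = c(m, m, length(nms)), dimnames = list(ids, ids, nms))
  values <- matrix(0, m, m, dimnames = list(ids, ids))
  for (k in seq_along(nms)) {
    nm <- nms[k]
    h <- hists@histograms[[nm]]
    rng <- as.integer(names(h))
    # pairwise per-criterion similarity via the score-pair lookup table
    lut <- outer(rng, rng, Vectorize(function(a, b)
      tmsCriterion(hists, nm, a, b)))
    idx <- match(scores[[nm]], rng)
    slice <- lut[idx, idx, drop = FALSE]
    values <- values + slice
    if (perCriterion) perC[, , k] <- slice
  }
  new("TMSMatrix", values = values, perCriterion = perC)
}

#' TMS matrix accessors
#'
#' \code{tmsValues} returns the symmetric numeric matrix of TMS scores;
#' \code{tmsPerCriterion} the optional m x m x 9 per-criterion decomposition
#' (or \code{NULL}).
#'
#' @param x a \linkS4class{TMSMatrix}.
#' @return see description.
#' @export
tmsValues <- function(x) x@values

#' @rdname tmsValues
#' @export
tmsPerCriterion <- function(x) x@perCriterion

#' Good-match labels at a similarity threshold
#'
#' A retrieved sample is a good match (relevant) to a query when their TMS
#' score is at least \code{thS}. Returns the full m x m logical label matrix.
#'
#' @param sim a \linkS4class{TMSMatrix}.
#' @param thS similarity threshold in [0, 9].
#' @return logical symmetric matrix; entry is \code{TRUE} iff TMS >= thS.
#' @export
goodMatchLabels <- function(sim, thS) {
  if (thS < 0 || thS > 9) stop("thS must lie in [0, 9]")
  tmsValues(sim) >= thS
}
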