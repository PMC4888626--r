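#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' TissueCohort: a graded tissue cohort with morphological features
#'
#' An S4 container for a cohort of tissue samples, each carrying a continuous
#' morphological feature vector, integer scores for the nine pathologist
#' criteria, and a Gleason sum. Extends
#' \linkS4class{SummarizedExperiment}: the \code{"features"} assay holds the
#' feature matrix (features in rows, samples in columns), \code{colData} holds
#' the criterion scores, the Gleason sum and any clinical metadata, and the
#' criterion schema travels in \code{metadata(x)$schema}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#'
#' @seealso \code{\link{TissueCohort}} (constructor), \code{\link{readCohort}},
#'   \code{\link{defaultSchema}}
#' @export
setClass("TissueCohort", contains = "SummarizedExperiment")

setValidity("TissueCohort", function(object) {
  schema <- metadata(object)$schema
  tab <- tryCatch(as.data.frame(colData(object), optional = TRUE),
                  error = function(e) NULL)
  if (is.null(tab)) return("colData cannot be coerced to a data.frame")
  msgs <- validateCohortTable(
    cbind(sample_id = colnames(object), tab),
    schema = schema, features = t(assay(object, "features"))
  )
  if (length(msgs)) msgs else TRUE
})

#' ScoreHistogramSet: per-criterion score histograms and normalizer
#'
#' Holds, for each morphologic criterion, the count of cohort samples at each
#' score value of the criterion's range (the score histogram driving the
#' distribution-weighted similarity), together with the shared normalization
#' factor Z.
#'
#' @slot histograms named list, one named integer vector of counts per
#'   criterion; names of each vector are the score values of the criterion
#'   range.
#' @slot z positive numeric normalization factor (defaults to the cohort size
#'   so each per-criterion similarity lies in [0, 1]).
#' @slot m integer, number of samples tallied.
#' @slot schema the criterion schema data.frame the histograms conform to.
#' @export
setClass("ScoreHistogramSet",
  representation(histograms = "list", z = "numeric", m = "integer",
                 schema = "data.frame"))

setValidity("ScoreHistogramSet", function(object) {
  msgs <- character()
  if (length(object@z) != 1L || object@z <= 0)
    msgs <- c(msgs, "z must be a single positive number")
  for (nm in names(object@histograms)) {
    h <- object@histograms[[nm]]
    if (any(h < 0)) msgs <- c(msgs, sprintf("negative count in '%s'", nm))
    if (sum(h) != object@m)
      msgs <- c(msgs, sprintf("counts for '%s' do not sum to m = %d", nm, object@m))
  }
  if (length(msgs)) msgs else TRUE
})

#' TMSMatrix: all-pairs tissue morphologic similarity
#'
#' Symmetric matrix of TMS values for every pair of cohort samples, with an
#' optional per-criterion decomposition. TMS values lie in [0, 9]; the matrix
#' is the gold-standard relevance used for training and evaluating retrieval.
#'
#' @slot values numeric m x m symmetric matrix with sample IDs as dimnames.
#' @slot perCriterion either \code{NULL} or an m x m x 9 array of the
#'   per-criterion similarities.
#' @export
setClass("TMSMatrix",
  representation(values = "matrix", perCriterion = "ANY"))

setValidity("TMSMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (is.null(dimnames(v)[[1]]) || !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "values must carry identical row/column sample IDs")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-10)))
    msgs <- c(msgs, "values must be symmetric")
  if (any(v < -1e-12 | v > 9 + 1e-12))
    msgs <- c(msgs, "TMS values must lie in [0, 9]")
  if (length(msgs)) msgs else TRUE
})

#' RankingModel: a learned pairwise ranking function
#'
#' The linear scoring function learned by the ranking SVM on feature-vector
#' differences, together with everything needed to apply it to a new query:
#' the feature subset, per-feature normalization statistics and the training
#' configuration.
#'
#' @slot weights numeric weight vector, one entry per selected feature.
#' @slot bias numeric scalar (irrelevant to ranking order, kept for record).
#' @slot regularization positive soft-margin cost used in training.
#' @slot featureSubset integer indices of features used, relative to the
#'   cohort feature order.
#' @slot center,scale numeric per-feature normalization statistics computed on
#'   the training cohort (full feature width; subsetting happens after
#'   normalization).
#' @slot difference \code{"absolute"} or \code{"signed"} feature-difference
#'   representation.
#' @slot trainingSeed integer seed used for balanced pair sampling.
#' @export
setClass("RankingModel",
  representation(weights = "numeric", bias = "numeric",
                 regularization = "numeric", featureSubset = "integer",
                 center = "numeric", scale = "numeric",
                 difference = "character", trainingSeed = "integer"))

setValidity("RankingModel", function(object) {
  msgs <- character()
  if (length(object@weights) != length(object@featureSubset))
    msgs <- c(msgs, "weights length must equal featureSubset length")
  if (length(object@regularization) != 1L || object@regularization <= 0)
    msgs <- c(msgs, "regularization must be a single positive number")
  if (!object@difference %in% c("absolute", "signed"))
    msgs <- c(msgs, "difference must be 'absolute' or 'signed'")
  if (length(msgs)) msgs else TRUE
})

#' RetrievalResult: ordered candidates for one query
#'
#' Per-query retrieval outcome: every candidate with its forward rank (rank of
#' the candidate for the query), reverse rank (rank of the query when the two
#' are swapped), combined rank and, when a similarity matrix is supplied, the
#' TMS relevance of the pair. Candidates are sorted by combined rank
#' ascending, ties broken by forward rank.
#'
#' @slot queryId character scalar.
#' @slot candidates data.frame with columns \code{candidate_id},
#'   \code{rank_forward}, \code{rank_reverse}, \code{rank_combined},
#'   \code{score}, \code{tms_relevance}.
#' @slot T integer truncation used (number of retrieved samples); \code{NA}
#'   for a full-list result.
#' @export
setClass("RetrievalResult",
  representation(queryId = "character", candidates = "data.frame",
                 T = "integer"))

setValidity("RetrievalResult", function(object) {
  cand <- object@candidates
  need <- c("candidate_id", "rank_forward", "rank_reverse", "rank_combined",
            "score", "tms_relevance")
  if (!all(need %in% names(cand)))
    return(paste("candidates must have columns:", paste(need, collapse = ", ")))
  key <- order(cand$rank_combined, cand$rank_forward)
  if (is.unsorted(key, strictly = FALSE) && !identical(key, seq_len(nrow(cand))))
    return("candidates must be sorted by combined rank, ties by forward rank")
  TRUE
})

#' SelectionTrace: record of the two-stage feature search
#'
#' Trace of the NDCG-driven feature selection: the individual-performance
#' ordering, the stage-1 prefix curve and best prefix, every accepted
#' add/remove step of the floating search, and the final subset.
#'
#' @slot stage1Order integer feature indices ordered by individual NDCG,
#'   descending.
#' @slot stage1Curve numeric NDCG per prefix length (same order).
#' @slot stage1Best integer indices of the best stage-1 prefix.
#' @slot steps data.frame with columns \code{action} ("add"/"remove"),
#'   \code{feature}, \code{ndcg} — accepted steps only.
#' @slot finalSubset integer indices of the selected subset.
#' @slot finalNDCG numeric NDCG of the final subset.
#' @slot cvFolds,seed integers recording the inner evaluation setup.
#' @export
setClass("SelectionTrace",
  representation(stage1Order = "integer", stage1Curve = "numeric",
                 stage1Best = "integer", steps = "data.frame",
                 finalSubset = "integer", finalNDCG = "numeric",
                 cvFolds = "integer", seed = "integer"))

setValidity("SelectionTrace", function(object) {
  msgs <- character()
  if (length(object@finalSubset) < 1L)
    msgs <- c(msgs, "final subset must be non-empty")
  if (anyDuplicated(object@finalSubset))
    msgs <- c(msgs, "final subset must be duplicate-free")
  if (nrow(object@steps) &&
      is.unsorted(object@steps$ndcg, strictly = TRUE))
    msgs <- c(msgs, "accepted-step NDCG must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: cross-validated retrieval assessment
#'
#' Everything the evaluation harness measures: per-query NDCG at the retrieval
#' cutoff and over the full candidate list, good-match precision curves over a
#' grid of similarity thresholds, exact hypergeometric chance baselines and
#' binomial significance of the observed good-match counts, for the learned
#' ranker and the kNN baseline.
#'
#' @slot perQuery data.frame: \code{fold}, \code{query_id}, \code{method},
#'   \code{ndcg_at_T}, \code{ndcg_full}.
#' @slot summaries data.frame: \code{method}, \code{metric}, \code{mean},
#'   \code{sd}.
#' @slot curves data.frame: \code{method}, \code{th_s}, \code{N_G},
#'   \code{fraction} of queries retrieving at least \code{N_G} good matches.
#' @slot chance data.frame: \code{th_s}, \code{N_G}, \code{p} — random-chance
#'   probability of retrieving at least \code{N_G} good matches.
#' @slot significance data.frame: \code{method}, \code{th_s}, \code{N_G},
#'   \code{N_q}, \code{p_value} — binomial upper-tail significance.
#' @slot relevances named list: for every query, the numeric vector of TMS
#'   relevances of all its fold-database candidates (used for permutation
#'   null bands and ideal-ordering checks).
#' @slot config list of evaluation settings used.
#' @export
setClass("EvaluationReport",
  representation(perQuery = "data.frame", summaries = "data.frame",
                 curves = "data.frame", chance = "data.frame",
                 significance = "data.frame", relevances = "list",
                 config = "list"))
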