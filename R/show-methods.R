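#' @describeIn TissueCohort-class compact cohort summary
#' @param object object to display.
#' @export
setMethod("show", "TissueCohort", function(object) {
  cat(sprintf("TissueCohort: %d samples, %d features, %d criteria\n",
              ncol(object), nrow(object), nrow(cohortSchema(object))))
  gs <- table(gleasonSum(object))
  cat("Gleason sums:",
      paste(sprintf("%s:%d", names(gs), as.integer(gs)), collapse = "  "),
      "\n")
})

#' @describeIn ScoreHistogramSet-class per-criterion count display
#' @param object object to display.
#' @export
setMethod("show", "ScoreHistogramSet", function(object) {
  cat(sprintf("ScoreHistogramSet: m = %d, Z = %g\n", object@m, object@z))
  for (nm in names(object@histograms)) {
    h <- object@histograms[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                paste(sprintf("%s:%d", names(h), h), collapse = " ")))
  }
})

#' @describeIn TMSMatrix-class similarity summary
#' @param object object to display.
#' @export
setMethod("show", "TMSMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("TMSMatrix: %d samples; pair TMS range [%.2f, %.2f], mean %.2f\n",
              nrow(v), min(off), max(off), mean(off)))
  if (!is.null(object@perCriterion))
    cat("  per-criterion decomposition attached\n")
})

#' @describeIn RankingModel-class model summary
#' @param object object to display.
#' @export
setMethod("show", "RankingModel", function(object) {
  cat(sprintf(
    "RankingModel: %d features (%s difference), cost %g, |w| = %.4g\n",
    length(object@weights), object@difference, object@regularization,
    sqrt(sum(object@weights^2))))
})

#' @describeIn RetrievalResult-class retrieved candidate listing
#' @param object object to display.
#' @export
setMethod("show", "RetrievalResult", function(object) {
  cat(sprintf("RetrievalResult for query '%s'%s\n", object@queryId,
              if (is.na(object@T)) " (full list)" else
                sprintf(" (top %d)", object@T)))
  print(utils::head(object@candidates, 10), row.names = FALSE)
  if (nrow(object@candidates) > 10)
    cat(sprintf("  ... %d more candidates\n", nrow(object@candidates) - 10))
})

#' @describeIn SelectionTrace-class selection summary
#' @param object object to display.
#' @export
setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf(
    "SelectionTrace: stage-1 best prefix %d feature(s); %d accepted SFFS step(s)\n",
    length(object@stage1Best), nrow(object@steps)))
  cat(sprintf("  final subset (%d): %s  [NDCG %.4f]\n",
              length(object@finalSubset),
              paste(object@finalSubset, collapse = ", "), object@finalNDCG))
})

#' @describeIn EvaluationReport-class evaluation summary table
#' @param object object to display.
#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d queries, T = %d, K = %d\n",
              object@config$n_queries, object@config$T, object@config$K))
  s <- object@summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %-9s %.2f +/- %.2f\n", s$method[i], s$metric[i],
                s$mean[i], s$sd[i]))
})

#' @export
print.PairInstances <- function(x, ...) {
  cat(sprintf(
    "PairInstances: %d pairs, %d features (%s difference), TMS range [%.2f, %.2f]\n",
    nrow(x$X), ncol(x$X), x$difference, min(x$relevance), max(x$relevance)))
  invisible(x)
}
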