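#' Construct a TissueCohort
#'
#' Assembles a validated cohort from a feature matrix and a table of criterion
#' scores. The Gleason sum is the \code{"Gleason score"} criterion; a
#' \code{gleason_sum} column is derived from it.
#'
#' @param features numeric matrix, samples in rows, features in columns.
#'   Column names become feature names (\code{feat_1}, ... if absent).
#' @param scores data.frame of integer criterion scores, one column per schema
#'   criterion (exact names), one row per sample.
#' @param sampleIds character vector of unique sample identifiers.
#' @param metadata optional data.frame of clinical metadata (age, surgery
#'   type, ...), one row per sample.
#' @param schema criterion schema; see \code{\link{defaultSchema}}.
#' @return a \linkS4class{TissueCohort}.
#' @examples
#' db <- simulateCohort(simConfig(m = 10, nFeatures = 4, seed = 1))
#' nSamples(db)
#' @export
TissueCohort <- function(features, scores, sampleIds,
                         metadata = NULL, schema = defaultSchema()) {
  .checkSchema(schema)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  rownames(features) <- NULL
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feat_", seq_len(ncol(features)))
  sampleIds <- as.character(sampleIds)
  if (nrow(features) != length(sampleIds) || nrow(scores) != length(sampleIds))
    stop("features, scores and sampleIds must agree on the number of samples")
  scores <- as.data.frame(scores)
  cd <- S4Vectors::DataFrame(scores[, schema$name, drop = FALSE],
                             check.names = FALSE)
  if (.gleasonName %in% schema$name)
    cd$gleason_sum <- as.integer(scores[[.gleasonName]])
  metaCols <- character()
  if (!is.null(metadata) && ncol(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(sampleIds))
      stop("metadata must have one row per sample")
    metaCols <- names(metadata)
    for (nm in metaCols) cd[[nm]] <- as.character(metadata[[nm]])
  }
  rownames(cd) <- sampleIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    colData = cd)
  colnames(se) <- sampleIds
  S4Vectors::metadata(se)$schema <- schema
  S4Vectors::metadata(se)$metadataCols <- metaCols
  new("TissueCohort", se)
}

# ---- accessors --------------------------------------------------------------

#' Cohort accessors
#'
#' \code{nSamples} returns the cohort size m; \code{sampleIds} the sample
#' identifiers; \code{featureMatrix} the samples x features numeric matrix;
#' \code{criterionScores} the integer score table (samples x criteria);
#' \code{gleasonSum} the per-sample Gleason sums; \code{cohortSchema} the
#' criterion schema; \code{sampleMetadata} the clinical metadata columns.
#'
#' @param x a \linkS4class{TissueCohort}.
#' @return see description.
#' @name cohort-accessors
#' @aliases nSamples sampleIds featureMatrix criterionScores gleasonSum
#'   cohortSchema sampleMetadata
NULL

#' @rdname cohort-accessors
#' @export
nSamples <- function(x) ncol(x)

#' @rdname cohort-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname cohort-accessors
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @rdname cohort-accessors
#' @export
criterionScores <- function(x) {
  schema <- cohortSchema(x)
  df <- as.data.frame(SummarizedExperiment::colData(x)[, schema$name,
                                                       drop = FALSE],
                      optional = TRUE)
  names(df) <- schema$name
  rownames(df) <- colnames(x)
  df
}

#' @rdname cohort-accessors
#' @export
gleasonSum <- function(x) {
  gs <- SummarizedExperiment::colData(x)$gleason_sum
  stats::setNames(as.integer(gs), colnames(x))
}

#' @rdname cohort-accessors
#' @export
cohortSchema <- function(x) S4Vectors::metadata(x)$schema

#' @rdname cohort-accessors
#' @export
sampleMetadata <- function(x) {
  cols <- S4Vectors::metadata(x)$metadataCols
  df <- as.data.frame(SummarizedExperiment::colData(x)[, cols, drop = FALSE],
                      optional = TRUE)
  rownames(df) <- colnames(x)
  df
}

#' Feature names of a cohort
#' @param x a \linkS4class{TissueCohort}.
#' @return character vector of feature names, in order.
#' @export
featureNames <- function(x) rownames(SummarizedExperiment::assay(x, "features"))

# ---- validation -------------------------------------------------------------

#' Validate a cohort table against the criterion schema
#'
#' Low-level validator used by the readers and by the class validity method.
#' Checks sample-ID uniqueness, presence of every schema criterion, integer
#' scores within each criterion's range, agreement of \code{gleason_sum} with
#' the Gleason-score criterion, and a well-formed numeric feature block.
#'
#' @param tab data.frame with a \code{sample_id} column and one column per
#'   criterion (exact schema names); may carry a \code{gleason_sum} column.
#' @param schema criterion schema data.frame.
#' @param features optional numeric matrix of features (samples in rows).
#' @return character vector of violation descriptions; empty when the table
#'   conforms. Each violation names the sample, field and rule.
#' @export
validateCohortTable <- function(tab, schema = defaultSchema(), features = NULL) {
  msgs <- character()
  if (is.null(schema)) return("cohort carries no criterion schema")
  if (!"sample_id" %in% names(tab)) return("missing 'sample_id' column")
  ids <- as.character(tab$sample_id)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup)
    msgs <- c(msgs, sprintf("sample '%s': sample_id violates uniqueness", d))
  missing <- setdiff(schema$name, names(tab))
  for (m in missing)
    msgs <- c(msgs, sprintf("schema: missing criterion column '%s'", m))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (nm %in% missing) next
    v <- tab[[nm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      bad <- ids[is.na(suppressWarnings(as.numeric(v))) |
                 suppressWarnings(as.numeric(v)) != round(suppressWarnings(as.numeric(v)))]
      msgs <- c(msgs, sprintf("sample '%s': criterion '%s' score is not an integer",
                              bad, nm))
      next
    }
    out <- v < schema$score_min[i] | v > schema$score_max[i]
    for (j in which(out))
      msgs <- c(msgs, sprintf(
        "sample '%s': criterion '%s' score %s outside range %d-%d",
        ids[j], nm, format(v[j]), schema$score_min[i], schema$score_max[i]))
  }
  if ("gleason_sum" %in% names(tab) && .gleasonName %in% names(tab)) {
    bad <- which(tab$gleason_sum != tab[[.gleasonName]])
    for (j in bad)
      msgs <- c(msgs, sprintf(
        "sample '%s': gleason_sum %s must equal the Gleason-score criterion (%s)",
        ids[j], format(tab$gleason_sum[j]), format(tab[[.gleasonName]][j])))
  }
  if (!is.null(features)) {
    if (!is.numeric(features))
      msgs <- c(msgs, "feature block is not numeric")
    else if (any(!is.finite(features)))
      msgs <- c(msgs, "feature block contains non-finite values")
    if (nrow(features) != nrow(tab))
      msgs <- c(msgs, "feature block row count differs from sample count")
  }
  msgs
}

#' List invariant violations of a cohort
#'
#' Returns descriptions of every violated cohort invariant (duplicate IDs,
#' scores outside the schema ranges, Gleason mismatch, malformed features).
#' A validly constructed \linkS4class{TissueCohort} always yields an empty
#' result; the function exists to audit cohorts assembled or edited by hand.
#'
#' @param db a \linkS4class{TissueCohort}.
#' @return character vector of violations; empty iff all invariants hold.
#' @export
validateCohort <- function(db) {
  tab <- cbind(sample_id = sampleIds(db),
               as.data.frame(SummarizedExperiment::colData(db),
                             optional = TRUE))
  names(tab) <- c("sample_id", colnames(SummarizedExperiment::colData(db)))
  msgs <- validateCohortTable(tab, schema = cohortSchema(db),
                              features = featureMatrix(db))
  if (nSamples(db) < 2L)
    msgs <- c(msgs, "cohort must contain at least 2 samples")
  msgs
}
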