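#' Read a tissue cohort from CSV or JSON
#'
#' CSV dialect: comma-separated UTF-8 with a header row; one row per sample.
#' Columns: \code{sample_id}, the criterion columns identified by their exact
#' schema names, the feature columns prefixed \code{feat_}, and any remaining
#' columns kept verbatim as clinical metadata. JSON files are those written by
#' \code{\link{writeCohort}} (schema, feature names and per-record scores,
#' features and metadata).
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"json"}; guessed from the file
#'   extension when omitted.
#' @param schema criterion schema used for validation (CSV only; JSON files
#'   embed their schema).
#' @return a validated \linkS4class{TissueCohort}; row order preserved.
#' @examples
#' db <- simulateCohort(simConfig(m = 6, nFeatures = 3, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' writeCohort(db, f)
#' db2 <- readCohort(f)
#' stopifnot(identical(sampleIds(db), sampleIds(db2)))
#' @export
readCohort <- function(path, format = c("guess", "csv", "json"),
                       schema = defaultSchema()) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") .readCohortCSV(path, schema) else .readCohortJSON(path)
}

.readCohortCSV <- function(path, schema) {
  .checkSchema(schema)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(schema$name, names(tab))
  if (length(missing))
    stop(sprintf("schema error: missing criterion column(s): %s",
                 paste(missing, collapse = ", ")))
  featCols <- grep("^feat_", names(tab), value = TRUE)
  if (!length(featCols)) stop("no feature columns (prefix 'feat_') found")
  features <- as.matrix(tab[, featCols, drop = FALSE])
  if (!is.numeric(features)) stop("format error: non-numeric feature column")
  msgs <- validateCohortTable(tab, schema, features)
  if (length(msgs))
    stop(paste(c("cohort validation failed:", msgs), collapse = "\n  "))
  metaCols <- setdiff(names(tab),
                      c("sample_id", "gleason_sum", schema$name, featCols))
  TissueCohort(features = features,
               scores = tab[, schema$name, drop = FALSE],
               sampleIds = tab$sample_id,
               metadata = if (length(metaCols)) tab[, metaCols, drop = FALSE],
               schema = schema)
}

.readCohortJSON <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  schema <- as.data.frame(x$schema)
  .checkSchema(schema)
  recs <- x$records
  scores <- as.data.frame(recs$scores, check.names = FALSE)
  features <- recs$features
  if (is.list(features)) {
    if (length(unique(lengths(features))) != 1L)
      stop("format error: ragged feature vectors")
    features <- do.call(rbind, features)
  }
  if (!is.numeric(features))
    stop("format error: non-numeric feature vectors")
  colnames(features) <- x$feature_names
  meta <- NULL
  if (!is.null(recs$metadata) && length(recs$metadata))
    meta <- as.data.frame(recs$metadata, check.names = FALSE)
  tab <- cbind(sample_id = recs$sample_id, scores)
  msgs <- validateCohortTable(tab, schema, features)
  if (length(msgs))
    stop(paste(c("cohort validation failed:", msgs), collapse = "\n  "))
  TissueCohort(features = features, scores = scores,
               sampleIds = recs$sample_id, metadata = meta, schema = schema)
}

#' Write a tissue cohort to CSV or JSON
#'
#' Inverse of \code{\link{readCohort}}: \code{readCohort(writeCohort(db))} is
#' the identity on records (criterion scores bit-identical, features to full
#' double precision).
#'
#' @param db a validated \linkS4class{TissueCohort} with at least 2 samples.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}; guessed from the extension.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(db, path, format = c("guess", "csv", "json")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (nSamples(db) < 2L)
    stop("cohort must contain at least 2 samples")
  msgs <- validateCohort(db)
  if (length(msgs))
    stop(paste(c("refusing to write invalid cohort:", msgs), collapse = "\n  "))
  if (format == "csv") {
    tab <- cbind(sample_id = sampleIds(db), criterionScores(db),
                 gleason_sum = unname(gleasonSum(db)))
    meta <- sampleMetadata(db)
    if (ncol(meta)) tab <- cbind(tab, meta)
    feats <- featureMatrix(db)
    colnames(feats) <- ifelse(grepl("^feat_", colnames(feats)),
                              colnames(feats), paste0("feat_", colnames(feats)))
    tab <- cbind(tab, as.data.frame(feats, check.names = FALSE))
    utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    feats <- featureMatrix(db)
    meta <- sampleMetadata(db)
    rownames(meta) <- NULL
    scoresTab <- criterionScores(db)
    rownames(scoresTab) <- NULL
    out <- list(
      schema = cohortSchema(db),
      feature_names = colnames(feats),
      records = list(
        sample_id = sampleIds(db),
        scores = scoresTab,
        gleason_sum = unname(gleasonSum(db)),
        features = lapply(seq_len(nrow(feats)), function(i) unname(feats[i, ])),
        metadata = if (ncol(meta)) meta else NULL))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}
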