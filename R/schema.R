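#' Default nine-criterion scoring schema
#'
#' Returns the default schema of the nine morphologic criteria a pathologist
#' scores on an H&E image: four criteria scored 0-2 (stromal reaction, clefts,
#' gland continuity, cell separation), four scored 0-3 (gland crowding, gland
#' roundness, nuclear grade, lumen/gland ratio), and the Gleason sum ranging
#' 6-10. Score ranges are inclusive integer intervals; individual criteria can
#' be overridden by editing the returned data.frame (every reader/validator
#' accepts a custom schema).
#'
#' @return data.frame with columns \code{name}, \code{score_min},
#'   \code{score_max}, \code{description}, one row per criterion, in the
#'   canonical order.
#' @examples
#' defaultSchema()
#' @export
defaultSchema <- function() {
  data.frame(
    name = c("Gland crowding", "Gland roundness", "Stromal reaction",
             "Nuclear grade", "Clefts", "Lumen/gland ratio",
             "Gland continuity", "Cell separation", "Gleason score"),
    score_min = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 6L),
    score_max = c(3L, 3L, 2L, 3L, 2L, 3L, 2L, 2L, 10L),
    description = c(
      "Gland tightness and cohesiveness",
      "Roundness of external perimeter of gland",
      "Swollen, plump cells in stroma and splayed collagen fibers",
      "Prominent nucleoli, variation in nuclear diameter and chromatin",
      "Cleft formation or retraction artifact around cancer glands",
      "Ratio between lumen area and total gland area",
      "Continuous sheets of cells",
      "Individual cells separated by stroma",
      "Sum of predominant and secondary Gleason patterns"),
    stringsAsFactors = FALSE
  )
}

.gleasonName <- "Gleason score"

.checkSchema <- function(schema) {
  if (!is.data.frame(schema) ||
      !all(c("name", "score_min", "score_max") %in% names(schema)))
    stop("schema must be a data.frame with columns name, score_min, score_max")
  if (anyDuplicated(schema$name))
    stop("schema criterion names must be unique")
  if (any(schema$score_min > schema$score_max))
    stop("schema has score_min > score_max")
  if (any(schema$score_min != round(schema$score_min)) ||
      any(schema$score_max != round(schema$score_max)))
    stop("schema score bounds must be integers")
  invisible(schema)
}

#' Score range of one criterion
#' @param schema a criterion schema data.frame.
#' @param criterion criterion name.
#' @return integer vector of admissible scores.
#' @keywords internal
scoreRange <- function(schema, criterion) {
  i <- match(criterion, schema$name)
  if (is.na(i)) stop(sprintf("unknown criterion '%s'", criterion))
  seq.int(schema$score_min[i], schema$score_max[i])
}
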