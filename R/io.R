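# CSV input/output for response matrices, score tables and study results.

.MISSING_TOKENS <- c("", "na", "nan")

#' Read a wide-format response CSV
#'
#' Expects a header row `respondent_id, item_1, ..., item_n` and cells in
#' \{`0`, `1`, empty\}; empty strings, `NA` and `NaN` (case-insensitive) are
#' read as missing. Respondent ids are opaque strings and must be unique;
#' row order is preserved.
#'
#' @param path CSV path.
#' @return Integer response matrix with respondent ids as rownames.
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0)) # keep literal "NA" cells
  if (ncol(df) < 2L || names(df)[1L] != "respondent_id") {
    stop("responses CSV must start with a 'respondent_id' column")
  }
  n_items <- ncol(df) - 1L
  expected <- paste0("item_", seq_len(n_items))
  if (!identical(names(df)[-1L], expected)) {
    stop("item columns must be named item_1..item_", n_items, " in order")
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate respondent_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  X <- matrix(NA_integer_, nrow(df), n_items,
              dimnames = list(ids, expected))
  for (j in seq_len(n_items)) {
    cell <- trimws(df[[j + 1L]])
    miss <- tolower(cell) %in% .MISSING_TOKENS
    bad <- !miss & !cell %in% c("0", "1")
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("unparseable cell '%s' at row %d, column item_%d (want 0, 1 or empty)",
                   cell[i], i, j))
    }
    X[!miss, j] <- as.integer(cell[!miss])
  }
  X
}

#' Write a response matrix as wide-format CSV
#'
#' Inverse of [read_responses_csv()]; missing cells are written as empty
#' fields, so a write-read round trip is the identity.
#'
#' @param matrix response matrix (rownames used as respondent ids).
#' @param path output path.
#' @export
write_responses_csv <- function(matrix, path) {
  X <- as.matrix(matrix)
  if (is.null(rownames(X))) rownames(X) <- paste0("R", seq_len(nrow(X)))
  colnames(X) <- paste0("item_", seq_len(ncol(X)))
  df <- data.frame(respondent_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write a score table as CSV
#'
#' Columns are the fixed [score_cohort()] layout; undefined values are
#' written as empty fields.
#'
#' @param scores score table.
#' @param path output path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write a study summary table as CSV
#'
#' @param study an `mcq_study` from [run_study()] (or its `table`).
#' @param path output path.
#' @export
write_metrics_csv <- function(study, path) {
  tab <- if (inherits(study, "mcq_study")) study$table else study
  utils::write.csv(tab, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# run manifest written alongside CLI outputs: seed, package version and the
# resolved configuration (no timestamps, so reruns are byte-identical)
.write_manifest <- function(path, seed, config) {
  jsonlite::write_json(
    list(package = "mcqimpute",
         version = as.character(utils::packageVersion("mcqimpute")),
         seed = seed, config = config),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
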