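# The four missing-response handling approaches.
#
# 1. mode       -- per-item mode substitution
# 2. ggm        -- group geometric mean: no item fill; the composite k is
#                  relaxed to the geometric mean of whichever set ks exist
# 3. inn        -- item nearest neighbour: fill from congruent responses to
#                  the same-k items of the other amount sets; unresolved
#                  cells stay missing and the composite falls back to the
#                  relaxed rule
# 4. inn_random -- as 3, then fair random 0/1 for every unresolved cell

.new_fills <- function() {
  data.frame(respondent = character(0), item = integer(0),
             value = integer(0), provenance = character(0),
             tie = logical(0), stringsAsFactors = FALSE)
}

.bind_fills <- function(lst) {
  keep <- vapply(lst, function(d) is.data.frame(d) && nrow(d) > 0L, logical(1))
  lst <- lst[keep]
  if (!length(lst)) return(.new_fills())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Mode imputation of missing MCQ responses
#'
#' Replaces every missing cell with the mode of the non-missing responses to
#' the same item, computed from the matrix at hand. Ties are broken toward
#' the delayed choice (1) -- a fixed, RNG-free convention -- and flagged in
#' the fill log.
#'
#' @param matrix respondent x item matrix of 0/1/NA.
#' @return List with `matrix` (completed), `fills` (one row per filled cell:
#'   respondent, item, value, provenance, tie flag) and
#'   `residual_missing_cells` (always 0).
#' @export
mode_impute <- function(matrix) {
  X <- as.matrix(matrix)
  storage.mode(X) <- "integer"
  bad <- !is.na(X) & !(X %in% c(0L, 1L))
  if (any(bad)) stop("responses must be 0, 1 or NA")
  if (is.null(rownames(X))) rownames(X) <- paste0("R", seq_len(nrow(X)))
  fills <- vector("list", ncol(X))
  for (j in which(colSums(is.na(X)) > 0L)) {
    obs <- X[!is.na(X[, j]), j]
    if (!length(obs)) {
      stop(sprintf("item %d has no observed responses; its mode is undefined", j))
    }
    ones <- sum(obs == 1L)
    zeros <- length(obs) - ones
    fill <- if (ones >= zeros) 1L else 0L # tie -> delayed
    rows <- which(is.na(X[, j]))
    X[rows, j] <- fill
    fills[[j]] <- data.frame(respondent = rownames(X)[rows], item = j,
                             value = fill, provenance = "mode",
                             tie = ones == zeros, stringsAsFactors = FALSE)
  }
  list(matrix = X, fills = .bind_fills(fills), residual_missing_cells = 0L)
}

#' Relaxed (group geometric mean) composite k
#'
#' The strict composite k requires all three amount-set ks. The GGM
#' relaxation computes the geometric mean of whichever set ks are defined, so
#' a respondent remains scorable as long as at least one amount set is fully
#' observed; the composite is undefined only when all three set ks are.
#'
#' @param small_k,medium_k,large_k set k estimates; `NA` where undefined.
#'   Vectors are recycled cell-wise.
#' @return Geometric mean of the defined set ks per respondent (`NA` when
#'   none are defined).
#' @examples
#' relaxed_composite(NA, 0.01, 0.04)  # 0.02
#' relaxed_composite(NA, NA, 0.1)     # 0.1
#' @export
relaxed_composite <- function(small_k, medium_k, large_k) {
  ks <- cbind(small_k, medium_k, large_k)
  out <- exp(rowMeans(log(ks), na.rm = TRUE)) # all-NA rows -> NaN
  out[is.nan(out)] <- NA_real_
  unname(out)
}

#' Item-nearest-neighbour imputation
#'
#' Each MCQ item has two "nearest neighbours": the items of the other two
#' amount sets sharing its nominal k value (the same within-set rank). For
#' every missing cell, the non-missing neighbour responses *in the original
#' input matrix* are consulted: two congruent references copy their shared
#' value; two incongruent references leave the cell missing; a single
#' reference is copied; no references leave the cell missing. With
#' `fill_random = TRUE`, every cell still missing afterwards is filled with
#' an independent fair draw from \{0, 1\} (uses R's RNG; seed upstream for
#' reproducibility).
#'
#' References are always read from the pre-imputation matrix, so fills never
#' cascade and the result is independent of processing order.
#'
#' @param matrix respondent x item matrix of 0/1/NA aligned to `bank`.
#' @param bank an `mcq_bank`.
#' @param fill_random backfill unresolved cells with fair random responses?
#' @return List with `matrix`, `fills` (provenance one of `congruent-copy`,
#'   `single-ref-copy`, `random`) and `residual_missing_cells` (0 when
#'   `fill_random = TRUE`).
#' @export
inn_impute <- function(matrix, bank, fill_random = FALSE) {
  X0 <- .check_matrix(bank, matrix)
  X <- X0
  it <- bank$items
  fills <- vector("list", ncol(X) + 1L)
  for (j in which(colSums(is.na(X0)) > 0L)) {
    partners <- it$item_id[it$k_rank == it$k_rank[j] & it$set_label != it$set_label[j]]
    rows <- which(is.na(X0[, j]))
    a <- X0[rows, partners[1L]]
    b <- X0[rows, partners[2L]]
    val <- rep(NA_integer_, length(rows))
    prov <- rep(NA_character_, length(rows))
    congruent <- !is.na(a) & !is.na(b) & a == b
    val[congruent] <- a[congruent]
    prov[congruent] <- "congruent-copy"
    only_a <- !is.na(a) & is.na(b)
    val[only_a] <- a[only_a]
    prov[only_a] <- "single-ref-copy"
    only_b <- is.na(a) & !is.na(b)
    val[only_b] <- b[only_b]
    prov[only_b] <- "single-ref-copy"
    filled <- !is.na(val)
    if (any(filled)) {
      X[rows[filled], j] <- val[filled]
      fills[[j]] <- data.frame(respondent = rownames(X)[rows[filled]],
                               item = j, value = val[filled],
                               provenance = prov[filled], tie = FALSE,
                               stringsAsFactors = FALSE)
    }
  }
  if (isTRUE(fill_random)) {
    rem <- which(is.na(X), arr.ind = TRUE) # column-major: deterministic order
    if (nrow(rem)) {
      draws <- stats::rbinom(nrow(rem), 1L, 0.5)
      X[rem] <- draws
      fills[[ncol(X) + 1L]] <- data.frame(
        respondent = rownames(X)[rem[, 1L]], item = as.integer(rem[, 2L]),
        value = as.integer(draws), provenance = "random", tie = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  list(matrix = X, fills = .bind_fills(fills),
       residual_missing_cells = sum(is.na(X)))
}

#' Apply one missing-response approach and score the result
#'
#' Runs a full imputation-plus-scoring pipeline:
#' \describe{
#'   \item{`mode`}{[mode_impute()], then strict scoring.}
#'   \item{`ggm`}{no item-level fill; strict set scoring of the raw matrix,
#'     composite via [relaxed_composite()].}
#'   \item{`inn`}{[inn_impute()] without random backfill, then set scoring
#'     with the relaxed composite (unresolved cells may still block a set;
#'     the remaining complete sets carry the composite).}
#'   \item{`inn_random`}{[inn_impute()] with random backfill, then strict
#'     scoring (the matrix is complete).}
#' }
#'
#' @param matrix respondent x item matrix of 0/1/NA.
#' @param bank an `mcq_bank`.
#' @param method one of `"mode"`, `"ggm"`, `"inn"`, `"inn_random"`.
#' @return List with `scores` (the [score_cohort()] table, composite column
#'   per the approach), `matrix` (the post-imputation matrix) and `report`
#'   (an `mcq_imputation_report`: method, fill log, residual missing cells,
#'   and `unimputable_respondents`, the rows left without a composite k).
#' @export
apply_approach <- function(matrix, bank,
                           method = c("mode", "ggm", "inn", "inn_random")) {
  method <- match.arg(method)
  X <- .check_matrix(bank, matrix)
  if (method == "mode") {
    imp <- mode_impute(X)
    scores <- score_cohort(bank, imp$matrix)
  } else if (method == "ggm") {
    imp <- list(matrix = X, fills = .new_fills(),
                residual_missing_cells = sum(is.na(X)))
    scores <- score_cohort(bank, X)
    scores <- .relax_scores(scores)
  } else if (method == "inn") {
    imp <- inn_impute(X, bank, fill_random = FALSE)
    scores <- score_cohort(bank, imp$matrix)
    scores <- .relax_scores(scores)
  } else {
    imp <- inn_impute(X, bank, fill_random = TRUE)
    scores <- score_cohort(bank, imp$matrix)
  }
  report <- structure(
    list(method = method, fills = imp$fills,
         residual_missing_cells = imp$residual_missing_cells,
         unimputable_respondents = sum(is.na(scores$composite_k))),
    class = "mcq_imputation_report")
  list(scores = scores, matrix = imp$matrix, report = report)
}

# swap the strict composite for the GGM relaxation
.relax_scores <- function(scores) {
  scores$composite_k <- relaxed_composite(scores$small_k, scores$medium_k,
                                          scores$large_k)
  scores$ln_composite_k <- log(scores$composite_k)
  scores$log10_composite_k <- log10(scores$composite_k)
  scores
}

#' @export
print.mcq_imputation_report <- function(x, ...) {
  cat(sprintf("MCQ imputation report: method '%s'\n", x$method))
  cat(sprintf("  cells filled: %d  residual missing cells: %d\n",
              nrow(x$fills), x$residual_missing_cells))
  cat(sprintf("  respondents without composite k: %d\n",
              x$unimputable_respondents))
  if (nrow(x$fills)) {
    cat("  fill provenance:\n")
    print(table(x$fills$provenance))
  }
  invisible(x)
}
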