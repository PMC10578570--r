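# Consistency-score estimation of the discount rate k from MCQ responses.
#
# Response coding throughout: 0 = chose the smaller immediate reward,
# 1 = chose the larger delayed reward, NA = missing.

# validate a ternary response vector
.check_responses <- function(responses) {
  responses <- as.integer(responses)
  bad <- !is.na(responses) & !responses %in% c(0L, 1L)
  if (any(bad)) {
    stop("responses must be 0 (immediate), 1 (delayed) or NA (missing); ",
         "offending position(s): ", paste(which(bad), collapse = ", "))
  }
  responses
}

# validate a respondent x item matrix against a bank; returns an integer
# matrix with columns in administered order and rownames set
.check_matrix <- function(bank, matrix) {
  stopifnot(inherits(bank, "mcq_bank"))
  X <- as.matrix(matrix)
  if (ncol(X) != bank$version) {
    stop(sprintf("response matrix has %d columns; bank has %d items",
                 ncol(X), bank$version))
  }
  expected <- paste0("item_", seq_len(bank$version))
  if (!is.null(colnames(X)) && all(colnames(X) %in% expected)) {
    if (anyDuplicated(colnames(X))) stop("duplicated item columns")
    X <- X[, expected[expected %in% colnames(X)], drop = FALSE]
  }
  storage.mode(X) <- "integer"
  bad <- !is.na(X) & !(X %in% c(0L, 1L))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("responses must be 0, 1 or NA; first offending cell: row %d, column %d",
                 idx[1L], idx[2L]))
  }
  if (is.null(rownames(X)) && nrow(X) > 0L) {
    rownames(X) <- paste0("R", seq_len(nrow(X)))
  }
  colnames(X) <- expected
  X
}

# row-wise cumulative sums of M prefixed with a zero column, via a
# triangular matrix product (fast for the small item counts involved)
.cummat <- function(M) {
  n <- ncol(M)
  L <- matrix(0, n, n)
  L[upper.tri(L, diag = TRUE)] <- 1 # L[j, s] = 1 iff j <= s
  cbind(0, M %*% L)
}

# consistency counts for every candidate switch position.
# X: complete 0/1 matrix over k-ascending items. Returns an
# nrow(X) x (ncol(X) + 1) matrix whose column s+1 counts, for switch
# position s (0..n), immediate choices among the first s items plus delayed
# choices among the rest.
.profile_counts <- function(X) {
  imm <- (X == 0L) * 1
  del <- (X == 1L) * 1
  c_imm <- .cummat(imm)
  c_del <- .cummat(del)
  c_imm + (c_del[, ncol(c_del)] - c_del)
}

# candidate ln-k assigned to each switch position over a k-ascending ladder:
# position 0 -> min k, position n -> max k, interior s -> geometric mean of
# the bracketing item ks
.candidate_ln_k <- function(k_values) {
  lk <- log(k_values)
  n <- length(lk)
  if (n == 1L) return(c(lk, lk))
  c(lk[1L], (lk[-n] + lk[-1L]) / 2, lk[n])
}

# vectorised scoring of one item scope; rows with any NA in the scope get NA
.score_scope <- function(X, k_values) {
  n_resp <- nrow(X)
  n <- length(k_values)
  k <- rep(NA_real_, n_resp)
  consistency <- rep(NA_real_, n_resp)
  ok <- rowSums(is.na(X)) == 0L
  if (any(ok)) {
    counts <- .profile_counts(X[ok, , drop = FALSE])
    cand <- .candidate_ln_k(k_values)
    mx <- apply(counts, 1L, max)
    tied <- (counts == mx) * 1 # counts are integer-valued: exact comparison
    k[ok] <- exp(drop(tied %*% cand) / rowSums(tied))
    consistency[ok] <- mx / n
  }
  list(k = k, consistency = consistency)
}

#' Consistency profile of a complete response pattern
#'
#' For a response pattern over items ordered by ascending k, candidate switch
#' position `s` (0..n) hypothesises that the respondent prefers the immediate
#' reward on the first `s` items and the delayed reward from item `s + 1`
#' onward. Its consistency score is the proportion of responses agreeing with
#' that hypothesis. A single-switch-point pattern attains 1.0 at exactly one
#' position; noisier patterns spread their maximum.
#'
#' @param responses complete 0/1 vector over k-ascending items.
#' @return Numeric vector of length `length(responses) + 1`: the consistency
#'   proportion at switch positions 0..n.
#' @examples
#' consistency_profile(c(0, 0, 0, 1, 1, 1, 1, 1, 1)) # max 1 at position 3
#' @export
consistency_profile <- function(responses) {
  responses <- .check_responses(responses)
  if (length(responses) == 0L) stop("empty response vector")
  if (anyNA(responses)) {
    stop("responses contain missing values; impute them before scoring")
  }
  drop(.profile_counts(matrix(responses, nrow = 1L))) / length(responses)
}

#' Estimate k from a consistency profile
#'
#' Maps each maximally consistent switch position to a k value -- the
#' geometric mean of the bracketing items' nominal ks for interior positions,
#' the scope's minimum (all-delayed) or maximum (all-immediate) nominal k at
#' the boundaries -- and returns the geometric mean over all tied positions,
#' following the convention of the Kaplan et al. scorer.
#'
#' @param profile consistency proportions from [consistency_profile()].
#' @param k_values ascending nominal k values of the same items.
#' @return List with `k` (the estimate) and `consistency` (the maximal
#'   profile value).
#' @examples
#' p <- consistency_profile(c(0, 1))
#' estimate_k_from_profile(p, c(0.01, 0.04)) # k = 0.02
#' @export
estimate_k_from_profile <- function(profile, k_values) {
  if (length(k_values) == 0L) stop("empty item list")
  if (is.unsorted(k_values)) stop("k_values must be ascending")
  n <- length(k_values)
  if (length(profile) != n + 1L) {
    stop("profile must have length(k_values) + 1 entries")
  }
  mx <- max(profile)
  tied <- which(profile >= mx - 1e-12)
  cand <- .candidate_ln_k(k_values)
  list(k = exp(mean(cand[tied])), consistency = mx)
}

#' Proportion of delayed choices
#'
#' Myerson et al.'s scoring alternative to k: the proportion of non-missing
#' items on which the larger delayed reward was chosen.
#'
#' @param responses ternary response vector (0/1/NA).
#' @return Proportion in \[0, 1\]; `NA` when every response is missing.
#' @export
proportion_delayed <- function(responses) {
  responses <- .check_responses(responses)
  n_obs <- sum(!is.na(responses))
  if (n_obs == 0L) return(NA_real_)
  sum(responses == 1L, na.rm = TRUE) / n_obs
}

#' Score a cohort of MCQ respondents
#'
#' Applies the consistency-score procedure to every row of a respondent x
#' item response matrix, producing the five k estimates of the standard
#' scoring convention: the overall k (all items ordered by ascending nominal
#' k), one k per amount set (small, medium, large), and the composite k, the
#' geometric mean of the three set ks. Each estimate is computed only when
#' its item scope is fully observed ("strict" rule); the composite therefore
#' requires all three set ks. The relaxed composite used by the GGM
#' imputation approach lives in [relaxed_composite()].
#'
#' @param bank an `mcq_bank`.
#' @param matrix respondent x item matrix of 0/1/NA, columns in administered
#'   order (or named `item_1..item_n`).
#' @return Data frame with one row per respondent: `respondent_id`,
#'   `overall_k`, `small_k`, `medium_k`, `large_k`, `composite_k`,
#'   `ln_composite_k`, `log10_composite_k`, `consistency_overall`,
#'   `consistency_small/medium/large`, `proportion_delayed`, `n_missing`.
#'   Undefined estimates are `NA`.
#' @examples
#' bank <- mcq_item_bank(27)
#' X <- matrix(1L, nrow = 2, ncol = 27) # two all-delayed respondents
#' score_cohort(bank, X)[, c("composite_k", "consistency_overall")]
#' @export
score_cohort <- function(bank, matrix) {
  X <- .check_matrix(bank, matrix)
  n_resp <- nrow(X)
  empty <- rep(NA_real_, n_resp)
  if (n_resp == 0L) {
    res <- data.frame(respondent_id = character(0))
  } else {
    res <- data.frame(respondent_id = rownames(X), stringsAsFactors = FALSE)
  }

  ov <- overall_order(bank)
  scopes <- c(list(overall = ov),
              stats::setNames(lapply(.SET_LEVELS, .set_items, bank = bank),
                              .SET_LEVELS))
  est <- lapply(scopes, function(it) {
    if (n_resp == 0L) return(list(k = numeric(0), consistency = numeric(0)))
    .score_scope(X[, it$item_id, drop = FALSE], it$k_nominal)
  })

  res$overall_k <- est$overall$k
  res$small_k <- est$small$k
  res$medium_k <- est$medium$k
  res$large_k <- est$large$k
  set_ks <- cbind(res$small_k, res$medium_k, res$large_k)
  res$composite_k <- exp(rowMeans(log(set_ks))) # strict: NA if any set NA
  res$ln_composite_k <- log(res$composite_k)
  res$log10_composite_k <- log10(res$composite_k)
  res$consistency_overall <- est$overall$consistency
  res$consistency_small <- est$small$consistency
  res$consistency_medium <- est$medium$consistency
  res$consistency_large <- est$large$consistency
  n_obs <- rowSums(!is.na(X))
  pd <- rowSums(X == 1L, na.rm = TRUE) / n_obs
  pd[n_obs == 0L] <- NA_real_
  res$proportion_delayed <- if (n_resp) pd else numeric(0)
  res$n_missing <- if (n_resp) as.integer(rowSums(is.na(X))) else integer(0)
  res
}

#' Score a single respondent
#'
#' @param bank an `mcq_bank`.
#' @param responses ternary response vector aligned to the bank's
#'   administered item order.
#' @return One-row data frame in the [score_cohort()] layout.
#' @export
score_respondent <- function(bank, responses) {
  responses <- .check_responses(responses)
  if (length(responses) != bank$version) {
    stop(sprintf("response vector has %d entries; bank has %d items",
                 length(responses), bank$version))
  }
  score_cohort(bank, matrix(responses, nrow = 1L))
}
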