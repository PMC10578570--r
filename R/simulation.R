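# Monte Carlo evaluation harness: inject MCAR missingness into a complete
# cohort, apply each approach, and measure recovery of the composite k.

.METRIC_COLS <- c("mean_difference", "rmsd", "corr_true", "n_unimputable",
                  "delta_corr_covariate")

#' Performance measures for one imputed score table
#'
#' Compares composite k estimates after imputation against those from the
#' complete data, on the raw k scale: `mean_difference` (group-level bias),
#' `rmsd` (individual-level deviation) and `corr_true` (Pearson correlation),
#' all over respondents whose imputed composite is defined; `n_unimputable`
#' counts the rest. `delta_corr_covariate` is the change in the Pearson
#' correlation between the natural-log composite k and an external covariate
#' relative to the complete data (the one measure taken on the ln scale, to
#' approximate normality).
#'
#' @param true_scores score table from the complete matrix; its composite k
#'   must be defined for every respondent.
#' @param imputed_scores aligned score table after an imputation approach.
#' @param covariate optional numeric covariate per respondent.
#' @return One-row data frame of the five measures.
#' @export
compute_metrics <- function(true_scores, imputed_scores, covariate = NULL) {
  kt <- true_scores$composite_k
  ki <- imputed_scores$composite_k
  if (length(kt) != length(ki)) stop("score tables are not aligned")
  if (anyNA(kt)) stop("true composite k must be defined for all respondents")
  ok <- !is.na(ki)
  d <- ki[ok] - kt[ok]
  corr_true <- if (sum(ok) >= 3L) {
    stats::cor(ki[ok], kt[ok])
  } else {
    warning("fewer than 3 defined pairs; correlation undefined")
    NA_real_
  }
  delta <- NA_real_
  if (!is.null(covariate)) {
    if (length(covariate) != length(kt)) stop("covariate is not aligned")
    delta <- stats::cor(log(ki[ok]), covariate[ok]) -
      stats::cor(log(kt), covariate)
  }
  data.frame(mean_difference = mean(d), rmsd = sqrt(mean(d^2)),
             corr_true = corr_true, n_unimputable = sum(!ok),
             delta_corr_covariate = delta)
}

#' Analytic expectation of GGM-unimputable respondents
#'
#' Under uniform removal of exactly `r` of the `3m` responses per
#' respondent, a respondent is unimputable by the group-geometric-mean
#' approach iff every amount set loses at least one response. By
#' inclusion-exclusion over the three sets of size `m`, that probability is
#' `1 - (3*choose(2m, r) - 3*choose(m, r)) / choose(3m, r)` for `r >= 3`
#' and 0 for `r < 3` (two removals cannot hit three sets).
#'
#' @param n_respondents cohort size.
#' @param items_per_set items per amount set `m` (7 or 9 for the MCQ).
#' @param r responses removed per respondent, `1 <= r <= 3m`. Vectorised.
#' @return Expected number of unimputable respondents.
#' @examples
#' expected_ggm_failures(900, 7, 3)  # 232.1
#' expected_ggm_failures(512, 9, 7)  # 457.0
#' @export
expected_ggm_failures <- function(n_respondents, items_per_set, r) {
  m <- items_per_set
  stopifnot(n_respondents >= 1, m >= 1)
  if (any(r < 1 | r > 3 * m)) {
    stop(sprintf("r must lie in 1..%d", 3 * m))
  }
  p <- ifelse(r < 3, 0,
              1 - (3 * choose(2 * m, r) - 3 * choose(m, r)) / choose(3 * m, r))
  n_respondents * p
}

#' Run one Monte Carlo condition (method x r)
#'
#' For each iteration: remove exactly `r` responses per respondent from the
#' complete base matrix (MCAR), apply the approach, and measure against the
#' base-matrix scores. Iterations are independent; a master seed spawns one
#' substream per iteration so any iteration can be reproduced.
#'
#' @param base_matrix complete response matrix.
#' @param bank an `mcq_bank`.
#' @param method one of `"mode"`, `"ggm"`, `"inn"`, `"inn_random"`.
#' @param r responses removed per respondent.
#' @param iterations Monte Carlo iterations (the study design uses 1000; use
#'   fewer for quick checks and widen tolerances accordingly).
#' @param covariate optional per-respondent covariate.
#' @param seed optional master seed.
#' @param true_scores optional precomputed [score_cohort()] table of
#'   `base_matrix` (saves recomputation across conditions).
#' @return List with `per_iteration` (one metric row per iteration), `mean`
#'   and `sd` (named vectors over the five measures).
#' @export
run_condition <- function(base_matrix, bank, method, r, iterations = 1000L,
                          covariate = NULL, seed = NULL, true_scores = NULL) {
  X <- .check_matrix(bank, base_matrix)
  if (anyNA(X)) stop("base matrix must be complete")
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, iterations)
  if (is.null(true_scores)) true_scores <- score_cohort(bank, X)
  rows <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    set.seed(iter_seeds[it])
    Xm <- inject_missing(X, r)
    app <- apply_approach(Xm, bank, method)
    rows[[it]] <- compute_metrics(true_scores, app$scores, covariate)
  }
  per <- do.call(rbind, rows)
  per <- cbind(iteration = seq_len(iterations), per)
  list(per_iteration = per,
       mean = colMeans(per[.METRIC_COLS]),
       sd = vapply(per[.METRIC_COLS], stats::sd, numeric(1)))
}

#' Run the full Monte Carlo evaluation grid
#'
#' Evaluates every requested approach at every `r`, mirroring the layout of
#' the study's summary tables: per-condition means with across-iteration
#' standard deviations, plus one "overall" row per method (the unweighted
#' mean over `r`, with the standard deviation of all iterations pooled
#' across `r`).
#'
#' @param base_matrix complete response matrix.
#' @param bank an `mcq_bank`.
#' @param methods subset of `c("mode", "ggm", "inn", "inn_random")`.
#' @param r_values numbers of removed responses; default `1:5` (21-item) or
#'   `1:7` (27-item), about 25% of the items. Larger values trigger a
#'   warning.
#' @param iterations Monte Carlo iterations per condition (default 1000).
#' @param covariate optional per-respondent covariate.
#' @param seed optional master seed; spawns one substream per condition.
#' @return An `mcq_study`: list with `table` (long-format summary: method, r,
#'   each measure and its sd) and `per_iteration` (the full archive).
#' @export
run_study <- function(base_matrix, bank,
                      methods = c("mode", "ggm", "inn", "inn_random"),
                      r_values = NULL, iterations = 1000L, covariate = NULL,
                      seed = NULL) {
  X <- .check_matrix(bank, base_matrix)
  if (anyNA(X)) stop("base matrix must be complete")
  methods <- match.arg(methods, c("mode", "ggm", "inn", "inn_random"),
                       several.ok = TRUE)
  if (is.null(r_values)) {
    r_values <- seq_len(if (bank$version == 21L) 5L else 7L)
  }
  r_values <- as.integer(r_values)
  if (max(r_values) > ceiling(0.25 * bank$version)) {
    warning("max(r_values) exceeds ~25% of the items; beyond the design ",
            "range of the evaluation study")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(method = methods, r = r_values,
                      stringsAsFactors = FALSE)
  cond_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  true_scores <- score_cohort(bank, X)

  per_list <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cond <- run_condition(X, bank, grid$method[g], grid$r[g], iterations,
                          covariate, seed = cond_seeds[g],
                          true_scores = true_scores)
    per_list[[g]] <- cbind(method = grid$method[g], r = grid$r[g],
                           cond$per_iteration)
  }
  per <- do.call(rbind, per_list)

  summarise <- function(sub, r_label) {
    means <- colMeans(sub[.METRIC_COLS])
    sds <- vapply(sub[.METRIC_COLS], stats::sd, numeric(1))
    row <- data.frame(method = sub$method[1L], r = r_label)
    for (mcol in .METRIC_COLS) {
      row[[mcol]] <- means[[mcol]]
      row[[paste0(mcol, "_sd")]] <- sds[[mcol]]
    }
    row
  }
  tab <- list()
  for (method in methods) {
    for (r in r_values) {
      tab[[length(tab) + 1L]] <-
        summarise(per[per$method == method & per$r == r, ], as.character(r))
    }
    # overall: mean over r of the condition means = mean of all iterations
    # (equal counts); sd pooled over all iterations across r
    tab[[length(tab) + 1L]] <- summarise(per[per$method == method, ],
                                         "overall")
  }
  structure(list(table = do.call(rbind, tab), per_iteration = per,
                 iterations = iterations, bank_version = bank$version),
            class = "mcq_study")
}

#' @export
print.mcq_study <- function(x, digits = 4, ...) {
  cat(sprintf("MCQ imputation study: %d-item bank, %d iterations/condition\n",
              x$bank_version, x$iterations))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
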