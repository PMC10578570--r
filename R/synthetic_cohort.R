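# Synthetic MCQ cohorts: hyperbolic discounters with heterogeneous ln k,
# logistic choice noise, and a covariate correlated with ln k (a stand-in
# for an external discounting measure such as probability discounting).

#' Configuration for a synthetic MCQ cohort
#'
#' Defaults emulate cohorts of the size used in the evaluation study: 900
#' respondents for the 21-item bank and 512 for the 27-item bank. True log
#' discount rates are normal with mean at the bank's mid-rank nominal ln k
#' and a standard deviation spanning about two rank intervals, so the cohort
#' covers the instrument's measurable range without piling up at the
#' boundaries. `noise_beta` is the inverse temperature of the logistic choice
#' rule (2 gives realistic, mostly-but-not-perfectly consistent patterns;
#' `Inf` gives deterministic single-switch respondents). `covariate_rho` is
#' the population correlation between true ln k and the external covariate.
#' These are artifact choices, not estimates of any real cohort.
#'
#' @param bank an `mcq_bank`.
#' @param n_respondents cohort size; default 900 (21-item) or 512 (27-item).
#' @param ln_k_mean,ln_k_sd normal distribution of true ln k; defaults from
#'   the bank's k ladder as described above.
#' @param noise_beta positive inverse temperature; `Inf` allowed.
#' @param covariate_rho target correlation in (-1, 1); default 0.35.
#' @return An `mcq_synth_config` list.
#' @export
synth_config <- function(bank, n_respondents = NULL, ln_k_mean = NULL,
                         ln_k_sd = NULL, noise_beta = 2,
                         covariate_rho = 0.35) {
  stopifnot(inherits(bank, "mcq_bank"))
  ladder <- .set_items(bank, "small")$k_nominal
  ln_ladder <- log(ladder)
  m <- length(ladder)
  if (is.null(n_respondents)) {
    n_respondents <- if (bank$version == 21L) 900L else 512L
  }
  n_respondents <- as.integer(n_respondents)
  if (is.null(ln_k_mean)) ln_k_mean <- ln_ladder[ceiling(m / 2)]
  if (is.null(ln_k_sd)) ln_k_sd <- 2 * mean(diff(ln_ladder))
  stopifnot(n_respondents >= 1L, is.finite(ln_k_mean), ln_k_sd > 0,
            noise_beta > 0, abs(covariate_rho) < 1)
  # the +/- 2 sd band of true ln k should span at least 3 rank intervals,
  # otherwise the instrument barely resolves the cohort
  lo <- ln_k_mean - 2 * ln_k_sd
  hi <- ln_k_mean + 2 * ln_k_sd
  covered <- sum(ln_ladder[-m] >= lo & ln_ladder[-1L] <= hi)
  if (covered < 3L) {
    warning("ln_k_mean +/- 2*ln_k_sd covers fewer than 3 rank intervals; ",
            "the cohort will be poorly resolved by this bank")
  }
  structure(list(version = bank$version, n_respondents = n_respondents,
                 ln_k_mean = ln_k_mean, ln_k_sd = ln_k_sd,
                 noise_beta = noise_beta, covariate_rho = covariate_rho),
            class = "mcq_synth_config")
}

#' Draw synthetic respondents
#'
#' True ln k is `Normal(ln_k_mean, ln_k_sd^2)`; the covariate is built from
#' the same standard-normal deviate plus independent noise so that its
#' population correlation with true ln k equals `covariate_rho` exactly.
#' Uses R's RNG: seed upstream for reproducibility.
#'
#' @param config an `mcq_synth_config`.
#' @param n number of respondents; defaults to `config$n_respondents`.
#' @return Data frame: `respondent_id`, `true_ln_k`, `covariate`.
#' @export
draw_respondents <- function(config, n = config$n_respondents) {
  stopifnot(inherits(config, "mcq_synth_config"))
  z <- stats::rnorm(n)
  e <- stats::rnorm(n)
  rho <- config$covariate_rho
  data.frame(respondent_id = sprintf("R%04d", seq_len(n)),
             true_ln_k = config$ln_k_mean + config$ln_k_sd * z,
             covariate = rho * z + sqrt(1 - rho^2) * e,
             stringsAsFactors = FALSE)
}

#' Simulate complete MCQ response patterns
#'
#' Each choice follows a logistic rule in ln k: the delayed reward is chosen
#' with probability `plogis(noise_beta * (ln k_item - true_ln_k))`, i.e. a
#' respondent prefers the delayed option on items whose indifference k
#' exceeds their own discount rate, with noise shrinking as `noise_beta`
#' grows. `noise_beta = Inf` gives the deterministic chooser: delayed iff
#' `ln k_item > true_ln_k`.
#'
#' @param bank an `mcq_bank`.
#' @param respondents data frame with `true_ln_k` (and optionally
#'   `respondent_id` used as rownames).
#' @param noise_beta positive inverse temperature, `Inf` allowed.
#' @return Complete integer response matrix (respondents x items, columns in
#'   administered order).
#' @export
simulate_responses <- function(bank, respondents, noise_beta = 2) {
  stopifnot(inherits(bank, "mcq_bank"), noise_beta > 0)
  ln_k_item <- log(bank$items$k_nominal) # administered order
  tlk <- respondents$true_ln_k
  if (is.infinite(noise_beta)) {
    X <- outer(tlk, ln_k_item, function(t, k) as.integer(k > t))
  } else {
    p <- stats::plogis(noise_beta * outer(-tlk, ln_k_item, `+`))
    X <- matrix(stats::rbinom(length(p), 1L, p), nrow = nrow(p))
  }
  storage.mode(X) <- "integer"
  rownames(X) <- if (!is.null(respondents$respondent_id)) {
    respondents$respondent_id
  } else {
    paste0("R", seq_len(nrow(X)))
  }
  colnames(X) <- paste0("item_", seq_len(ncol(X)))
  X
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: seeds the RNG (optionally), draws respondents and
#' simulates their complete response matrix.
#'
#' @param bank an `mcq_bank`.
#' @param config an `mcq_synth_config`; defaults to `synth_config(bank)`.
#' @param seed optional integer seed.
#' @return List with `responses` (complete matrix), `truth` (respondent data
#'   frame) and `config`.
#' @examples
#' cohort <- synth_cohort(mcq_item_bank(27), seed = 1)
#' dim(cohort$responses)
#' @export
synth_cohort <- function(bank, config = synth_config(bank), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_respondents(config)
  responses <- simulate_responses(bank, truth, config$noise_beta)
  list(responses = responses, truth = truth, config = config)
}

#' Remove a fixed number of responses per respondent, completely at random
#'
#' Emulates the evaluation study's missingness mechanism: exactly `r` cells
#' per row are set to missing, positions drawn uniformly without replacement
#' and independently across rows (MCAR). Uses R's RNG.
#'
#' @param matrix complete response matrix.
#' @param r number of responses to remove per row, `1 <= r <= ncol(matrix)`.
#' @return The matrix with `r` `NA`s per row.
#' @export
inject_missing <- function(matrix, r) {
  X <- as.matrix(matrix)
  n <- ncol(X)
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L || r > n) {
    stop(sprintf("r must be an integer in 1..%d", n))
  }
  idx <- vapply(seq_len(nrow(X)), function(i) sample.int(n, r), integer(r))
  cells <- cbind(rep(seq_len(nrow(X)), each = r), as.vector(idx))
  X[cells] <- NA
  X
}
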