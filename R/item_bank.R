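# Item banks: the fixed parameter tables behind the 21- and 27-item MCQ.

#' Indifference discount rate implied by a single MCQ item
#'
#' Each MCQ item offers a smaller immediate reward `V` against a larger
#' delayed reward `A` available after `D` days. Under Mazur's hyperbolic
#' model `V = A / (1 + kD)`, the two options have equal present value at
#' exactly one discount rate, obtained by solving for `k`:
#' `k = (A/V - 1) / D`. A respondent discounting more steeply than this
#' (larger personal `k`) prefers the immediate reward; one discounting less
#' steeply prefers the delayed reward.
#'
#' @param immediate_amount smaller, immediately available amount `V` (> 0).
#' @param delayed_amount larger delayed amount `A` (> `immediate_amount`).
#' @param delay_days delay `D` in days (>= 1).
#'
#' @return The indifference discount rate, in 1/day units. Vectorised over
#'   its arguments.
#'
#' @examples
#' compute_item_k(34, 35, 43)   # ~ 0.0007
#' compute_item_k(31, 85, 7)    # ~ 0.25
#' @export
compute_item_k <- function(immediate_amount, delayed_amount, delay_days) {
  if (!is.numeric(immediate_amount) || !is.numeric(delayed_amount) ||
      !is.numeric(delay_days)) {
    stop("invalid item: amounts and delay must be numeric")
  }
  if (any(!is.finite(immediate_amount)) || any(!is.finite(delayed_amount)) ||
      any(!is.finite(delay_days))) {
    stop("invalid item: amounts and delay must be finite")
  }
  if (any(immediate_amount <= 0)) {
    stop("invalid item: immediate amount must be positive")
  }
  if (any(delay_days < 1)) {
    stop("invalid item: delay must be at least 1 day")
  }
  if (any(delayed_amount <= immediate_amount)) {
    stop("invalid item: delayed amount must exceed the immediate amount ",
         "(no positive k exists)")
  }
  (delayed_amount / immediate_amount - 1) / delay_days
}

#' Build a validated MCQ item bank from an item-parameter table
#'
#' Validates an item table against the MCQ's structure and derives the
#' within-set k rank of every item. The table must contain one row per item
#' with columns `item_id` (administered position, 1..n), `set_label`
#' (`"small"`, `"medium"` or `"large"`, by the size of the delayed amount),
#' `immediate_amount`, `delayed_amount`, `delay_days`, and `k_nominal` (the
#' published rounded k the item was designed around).
#'
#' Validation enforces: the item count equals `version`; each of the three
#' amount sets holds `version/3` items; within each set the nominal k values
#' are distinct (so ranks 1..`version/3` each occur once); and every
#' `k_nominal` agrees with [compute_item_k()] within 15% relative tolerance
#' (published values are rounded to about one significant figure).
#'
#' @param table data frame (or object coercible to one) of item parameters.
#' @param version number of items, 21 or 27.
#'
#' @return An object of class `mcq_bank`: a list with elements `version` and
#'   `items` (the validated table, ordered by `item_id`, with derived
#'   `k_rank`).
#' @seealso [mcq_item_bank()] for the packaged banks.
#' @export
load_item_bank <- function(table, version) {
  version <- as.integer(version)
  if (length(version) != 1L || !version %in% c(21L, 27L)) {
    stop("version must be 21 or 27")
  }
  items <- as.data.frame(table)
  required <- c("item_id", "set_label", "immediate_amount", "delayed_amount",
                "delay_days", "k_nominal")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop("item table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  items <- items[required]
  items$item_id <- as.integer(items$item_id)
  items$set_label <- as.character(items$set_label)
  for (col in c("immediate_amount", "delayed_amount", "delay_days", "k_nominal")) {
    items[[col]] <- as.numeric(items[[col]])
  }

  if (nrow(items) != version) {
    stop(sprintf("item table has %d rows; version %d requires exactly %d",
                 nrow(items), version, version))
  }
  if (!setequal(items$item_id, seq_len(version))) {
    stop("item_id must be exactly 1..", version,
         " (administered questionnaire positions)")
  }
  items <- items[order(items$item_id), , drop = FALSE]
  rownames(items) <- NULL

  bad_label <- setdiff(unique(items$set_label), .SET_LEVELS)
  if (length(bad_label)) {
    stop("unknown set_label: ", paste(bad_label, collapse = ", "))
  }
  m <- version / 3L
  set_sizes <- table(factor(items$set_label, .SET_LEVELS))
  if (any(set_sizes != m)) {
    off <- names(set_sizes)[set_sizes != m]
    stop(sprintf("amount set(s) %s do not contain %d items each",
                 paste(off, collapse = ", "), m))
  }
  if (any(items$k_nominal <= 0)) {
    stop("k_nominal must be positive; offending item(s): ",
         paste(items$item_id[items$k_nominal <= 0], collapse = ", "))
  }

  # per-item recomputation against the published k; name the first offender
  for (i in seq_len(nrow(items))) {
    k_exact <- tryCatch(
      compute_item_k(items$immediate_amount[i], items$delayed_amount[i],
                     items$delay_days[i]),
      error = function(e) {
        stop(sprintf("item %d: %s", items$item_id[i], conditionMessage(e)),
             call. = FALSE)
      })
    rel <- abs(k_exact - items$k_nominal[i]) / items$k_nominal[i]
    if (rel > .K_TOL) {
      stop(sprintf(
        "item %d: k_nominal %.5g disagrees with computed %.5g (%.0f%% > %.0f%% tolerance)",
        items$item_id[i], items$k_nominal[i], k_exact, 100 * rel, 100 * .K_TOL))
    }
  }

  for (s in .SET_LEVELS) {
    ks <- items$k_nominal[items$set_label == s]
    if (anyDuplicated(ks)) {
      stop(sprintf("duplicate k_nominal within the %s set; ranks must be unique", s))
    }
  }
  items$k_rank <- as.integer(stats::ave(items$k_nominal, items$set_label,
                                        FUN = rank))

  structure(list(version = version, items = items), class = "mcq_bank")
}

#' Packaged MCQ item banks
#'
#' Returns one of the two item banks shipped with the package.
#'
#' The 27-item bank (`mcq27.csv`) is the published 27-item MCQ parameter
#' table (nine items per amount set spanning the nominal k ladder 0.00016 to
#' 0.25). The 21-item bank (`mcq21_synthetic.csv`) is a **synthetic
#' structural stand-in**: only its three rank-1 items (e.g. "$34 tonight or
#' $35 in 43 days", k = 0.0007) are the documented instrument items; the
#' remaining 18 were constructed to the instrument's design (three amount
#' sets of seven items sharing a geometric k ladder from 0.0007 to 0.25,
#' delayed amounts in the small/medium/large ranges 25-35, 50-60, 75-85).
#' All structural results (set combinatorics, unimputable counts, scoring
#' conventions) are unaffected by the stand-in amounts, but the 21-item bank
#' must not be used to score real 21-item MCQ data: load the genuine table
#' with [load_item_bank()] instead.
#'
#' @param version 21 or 27.
#' @return An `mcq_bank` (see [load_item_bank()]).
#' @examples
#' bank <- mcq_item_bank(27)
#' bank$items[1:3, ]
#' @export
mcq_item_bank <- function(version) {
  version <- as.integer(version)
  if (length(version) != 1L || !version %in% c(21L, 27L)) {
    stop("version must be 21 or 27")
  }
  file <- if (version == 27L) "mcq27.csv" else "mcq21_synthetic.csv"
  path <- system.file("extdata", file, package = "mcqimpute", mustWork = TRUE)
  load_item_bank(utils::read.csv(path), version)
}

#' Items in overall scoring order
#'
#' Orders the bank's items by nominal k value from smallest to largest, the
#' ordering under which the overall k is scored. Items sharing a nominal k
#' (the same rank in different amount sets) form a contiguous block ordered
#' small, medium, large; because tied items share the same k, the block
#' order is a pure convention and cannot change any consistency maximum.
#'
#' @param bank an `mcq_bank`.
#' @return The bank's `items` data frame, reordered.
#' @export
overall_order <- function(bank) {
  stopifnot(inherits(bank, "mcq_bank"))
  it <- bank$items
  it[order(it$k_nominal, match(it$set_label, .SET_LEVELS)), , drop = FALSE]
}

# items of one amount set, in ascending k order
.set_items <- function(bank, set) {
  it <- bank$items[bank$items$set_label == set, , drop = FALSE]
  it[order(it$k_rank), , drop = FALSE]
}

#' @export
print.mcq_bank <- function(x, ...) {
  cat(sprintf("MCQ item bank: %d items (3 amount sets x %d k ranks)\n",
              x$version, x$version / 3L))
  cat(sprintf("  nominal k ladder: %s\n",
              paste(format(sort(unique(x$items$k_nominal))), collapse = ", ")))
  invisible(x)
}
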