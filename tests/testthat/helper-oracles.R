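# Independent brute-force oracles, deliberately written as plain loops over
# switch positions so they share no code path with the vectorised scorer.

oracle_consistency <- function(responses) {
  n <- length(responses)
  vapply(0:n, function(s) {
    before <- if (s > 0) responses[seq_len(s)] else integer(0)
    after <- if (s < n) responses[(s + 1):n] else integer(0)
    (sum(before == 0) + sum(after == 1)) / n
  }, numeric(1))
}

oracle_estimate <- function(responses, k_values) {
  prof <- oracle_consistency(responses)
  n <- length(responses)
  tied <- which(abs(prof - max(prof)) < 1e-12) - 1L
  cand <- vapply(tied, function(s) {
    if (s == 0) k_values[1] else if (s == n) k_values[n]
    else sqrt(k_values[s] * k_values[s + 1])
  }, numeric(1))
  list(k = exp(mean(log(cand))), consistency = max(prof))
}

# a respondent is GGM-unimputable iff every amount set lost >= 1 response
oracle_ggm_unimputable <- function(missing_items, bank) {
  sets <- bank$items$set_label[bank$items$item_id %in% missing_items]
  length(unique(sets)) == 3L
}

# shared fixtures
bank21 <- mcq_item_bank(21)
bank27 <- mcq_item_bank(27)
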