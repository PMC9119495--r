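# Shared helpers for the crowdstop test suite.

default_config <- stopping_config()

# Independent scalar oracle for the decision rule, written directly from
# the rule's definition via quantile comparisons. Kept deliberately
# separate from the package's vectorised CDF implementation so the two
# routes can disagree if either is wrong.
oracle_decide <- function(n_pos, n_neg, D = 0.2, g = 0.95,
                          a0 = 0.5, b0 = 0.5) {
  a <- a0 + n_pos
  b <- b0 + n_neg
  if (qbeta(g, a, b) <= D) return("NEGATIVE")
  if (qbeta(1 - g, a, b) >= 1 - D) return("POSITIVE")
  if (qbeta((1 - g) / 2, a, b) > D && qbeta(1 - (1 - g) / 2, a, b) < 1 - D)
    return("DEADLOCK")
  "CONTINUE"
}

# outcome codes used by decision_grid(): see decide() docs
code_of <- c(CONTINUE = 0L, POSITIVE = 1L, NEGATIVE = 2L, DEADLOCK = 3L)

# a small campaign as a list of per-image rating vectors
as_campaign_df <- function(streams) {
  do.call(rbind, lapply(names(streams), function(id) {
    data.frame(image_id = id, rater_id = NA_character_,
               order_key = seq_along(streams[[id]]),
               rating = streams[[id]], stringsAsFactors = FALSE)
  }))
}
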