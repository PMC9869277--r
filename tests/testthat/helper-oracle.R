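# Independently coded brute-force rule table for fusion-trial responses.
# Deliberately structured as a flat decision table over membership booleans,
# not a priority cascade, so it is a genuinely separate encoding of the
# category definitions.
oracle_fusion_category <- function(left, right, resp_words, cluster_word) {
  in_left <- left %in% resp_words
  in_right <- right %in% resp_words
  two <- length(resp_words) == 2
  is_cluster_only <- length(resp_words) == 1 &&
    !is.na(cluster_word) && resp_words == cluster_word
  if (two && in_left && in_right) return("ideal")
  if (is_cluster_only) return("fused")
  if (in_left && !in_right) return("biased_left")
  if (in_right && !in_left) return("biased_right")
  "interference"
}

# All 120 legal responses for a corpus.
all_legal_responses <- function(corpus) {
  labs <- corpus$words$label
  pairs <- combn(labs, 2)
  c(as.list(labs), lapply(seq_len(ncol(pairs)), function(j) pairs[, j]))
}

# The 12 ordered fusible (stop-only, liquid-only) presentations.
all_fusible_orderings <- function(corpus) {
  w <- corpus$words
  out <- list()
  for (sid in unique(w$set_id)) {
    s <- w[w$set_id == sid, ]
    stopw <- s$label[s$onset_class == "stop"]
    for (lq in s$label[s$onset_class == "liquid"]) {
      out[[length(out) + 1]] <- c(stopw, lq)
      out[[length(out) + 1]] <- c(lq, stopw)
    }
  }
  out
}
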