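# Independent oracles, written in a deliberately different style from the
# implementation so the two routes stay independent.

# Exhaustive penalized least-squares DP, plain R loops, direct segment
# cost via mean(). Returns 1-based segment end indices.
oracle_segment <- function(x, penalty, min_len) {
  n <- length(x)
  seg_cost <- function(i, j) {
    v <- x[i:j]
    sum((v - mean(v))^2)
  }
  best <- rep(Inf, n + 1)
  best[1] <- -penalty
  prev <- integer(n + 1)
  for (t in seq_len(n)) {
    for (s in 0:t) {
      if (s != 0 && s < min_len) next
      if (t - s < min_len) next
      if (!is.finite(best[s + 1])) next
      cand <- best[s + 1] + seg_cost(s + 1, t) + penalty
      if (cand < best[t + 1]) {
        best[t + 1] <- cand
        prev[t + 1] <- s
      }
    }
  }
  ends <- integer(0)
  t <- n
  while (t > 0) {
    ends <- c(t, ends)
    t <- prev[t + 1]
  }
  ends
}

# Switch count by a direct pairwise scan (no run-length encoding).
oracle_switch_count <- function(states) {
  if (length(states) < 2) return(0L)
  sum(states[-1] != states[-length(states)])
}

# Fisher-type two-sided p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Probe states implied by a truth event table, for re-deriving switch
# counts independently of the generator's bookkeeping.
oracle_probe_states <- function(pos, events) {
  states <- rep(2L, length(pos))
  for (i in seq_len(nrow(events))) {
    hit <- pos > events$start[i] & pos <= events$end[i]
    states[hit] <- events$state[i]
  }
  states
}
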