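# Independent oracles used across tests.

# Exhaustive path-enumeration likelihood of one encounter history: sums the
# probability of every hidden-state path compatible with the events, using
# nothing but the supplied matrices. Deliberately naive (nested loops).
brute_force_loglik <- function(events, transitions, emission, init, first) {
  T_ <- length(events)
  S <- nrow(emission)
  if (first == T_) return(0)
  steps <- T_ - first
  states <- seq_len(S)
  total <- 0
  path <- integer(steps)
  recurse <- function(depth, prev_state, prob) {
    if (prob == 0) return()
    if (depth > steps) {
      total <<- total + prob
      return()
    }
    t <- first + depth
    for (s in states) {
      p2 <- prob * transitions[[t - 1]][prev_state, s] *
        emission[s, events[t] + 1]
      if (p2 > 0) recurse(depth + 1, s, p2)
    }
  }
  for (s0 in states) {
    if (init[s0] > 0) recurse(1, s0, init[s0])
  }
  log(total)
}

# Brute-force Krippendorff alpha from the definition in terms of pairwise
# disagreements within units, computed without a coincidence matrix.
brute_force_alpha <- function(units) {
  units <- units[lengths(units) >= 2]
  pairs_obs <- 0
  disagree_obs <- 0
  vals <- character(0)
  for (u in units) {
    m <- length(u)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        w <- 1 / (m - 1)
        pairs_obs <- pairs_obs + w
        disagree_obs <- disagree_obs + w * (u[i] != u[j])
      }
    }
    vals <- c(vals, u) # each value carries total pair weight 1
  }
  # expected disagreement: draw ordered pairs without replacement from the
  # pooled values (each value contributing weight 1)
  tab <- table(vals)
  n <- sum(tab)
  disagree_exp <- (n^2 - sum(tab^2)) / (n - 1)
  1 - disagree_obs / disagree_exp
}

# Minimal independent CJS-style simulator returning a 0/1 detection matrix;
# supports trap-dependence (p_aware/p_unaware) and a first-interval survival
# reduction delta (transience).
sim_cjs <- function(n, T_, phi = 0.8, p_aware = 0.5, p_unaware = p_aware,
                    delta = 0) {
  det <- matrix(0L, n, T_)
  first <- sample.int(max(1, T_ - 2), n, replace = TRUE)
  for (i in seq_len(n)) {
    f <- first[i]
    det[i, f] <- 1L
    seen <- TRUE
    if (f == T_) next
    for (t in f:(T_ - 1)) {
      s <- phi * (if (t == f) 1 - delta else 1)
      if (stats::runif(1) > s) break
      p <- if (seen) p_aware else p_unaware
      seen <- stats::runif(1) < p
      det[i, t + 1] <- as.integer(seen)
    }
  }
  det
}
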