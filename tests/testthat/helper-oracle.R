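# Independent oracles used across the suite.

# Per-individual microsimulation: propagates batches of simulated
# patients through per-cycle transition matrices (multinomial
# realizations of every individual transition) and accumulates
# discounted outcomes with its own arithmetic, independent of the
# cohort engine. Returns batch-mean outcomes and Monte-Carlo standard
# errors.
microsim_outcomes <- function(matrices, init, horizon, states,
                              discount_rate, drug_cost = 0,
                              n_patients = 1e6, n_batches = 20,
                              seed = 1) {
  set.seed(seed)
  S <- length(init)
  one_batch <- function(n) {
    counts <- matrix(0, horizon + 1L, S)
    counts[1L, ] <- as.numeric(stats::rmultinom(1, n, init))
    entrants <- matrix(0, horizon, S)
    for (t in seq_len(horizon)) {
      M <- matrices[[t]]
      for (s in seq_len(S)) {
        cs <- counts[t, s]
        if (cs == 0) next
        moved <- as.numeric(stats::rmultinom(1, cs, M[s, ]))
        counts[t + 1L, ] <- counts[t + 1L, ] + moved
        moved[s] <- 0
        entrants[t, ] <- entrants[t, ] + moved
      }
    }
    occ <- counts / n
    ent <- entrants / n
    df <- (1 + discount_rate)^-seq_len(horizon)
    w <- (occ[seq_len(horizon), , drop = FALSE] +
            occ[-1L, , drop = FALSE]) / 2
    alive <- rowSums(w[, states$alive, drop = FALSE])
    c(cost = sum(df * (w %*% states$annual_cost)) +
        sum(df * (ent %*% states$transition_cost)) +
        drug_cost * sum(df * alive),
      qaly = sum(df * (w %*% states$utility)),
      ly = sum(df * alive))
  }
  res <- t(vapply(seq_len(n_batches),
                  function(i) one_batch(n_patients %/% n_batches),
                  c(cost = 0, qaly = 0, ly = 0)))
  list(mean = colMeans(res),
       se = apply(res, 2, stats::sd) / sqrt(n_batches))
}

# Spreadsheet-style recomputation of the base-case cohort: rebuilds each
# cycle's transition probabilities directly from the schedule formulas
# and redistributes the cohort step by step with plain arithmetic.
brute_force_occupancy <- function(config, multipliers = c(1, 1, 1, 1)) {
  sched <- build_schedule(config)
  h <- nrow(sched)
  # EVENT_FREE, ACUTE_MI, POST_MI, ACUTE_IS, POST_IS, CV_DEATH, NONCV_DEATH
  occ <- c(1, 0, 0, 0, 0, 0, 0)
  for (t in seq_len(h)) {
    pm <- 1 - (1 - sched$non_fatal_mi[t])^multipliers[1]
    pi <- 1 - (1 - sched$non_fatal_is[t])^multipliers[2]
    pc <- 1 - (1 - sched$cv_death[t])^multipliers[3]
    pn <- 1 - (1 - sched$non_cv_death[t])^multipliers[4]
    stay <- 1 - pm - pi - pc - pn
    living <- occ[1:5]
    nxt <- numeric(7)
    nxt[2] <- sum(living) * pm                     # new acute MI
    nxt[4] <- sum(living) * pi                     # new acute IS
    nxt[6] <- occ[6] + sum(living) * pc            # CV death
    nxt[7] <- occ[7] + sum(living) * pn            # non-CV death
    nxt[1] <- occ[1] * stay                        # remain event-free
    nxt[3] <- (occ[2] + occ[3]) * stay             # settle/stay post-MI
    nxt[5] <- (occ[4] + occ[5]) * stay             # settle/stay post-IS
    occ <- nxt
  }
  occ
}

base_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- base_case_config()
    cfg
  }
})
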