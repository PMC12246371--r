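# Independent oracles used across tests; deliberately naive implementations.

# mean of Normal(mu, sd) truncated to (lo, hi)
oracle_truncnorm_mean <- function(mu, sd, lo, hi) {
  al <- (lo - mu) / sd
  be <- (hi - mu) / sd
  mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

# closed-form upper-boundary absorption probability
oracle_choice_prob <- function(v, a, z) {
  if (abs(v) < 1e-12) return(z)
  (1 - exp(-2 * v * a * z)) / (1 - exp(-2 * v * a))
}

# marginal log-likelihood of a random-intercept logistic model by brute-force
# trapezoid integration over the random effect, per cluster
oracle_glmm_loglik <- function(y, X, cluster, beta, tau00,
                               lim = 8, n_grid = 4001) {
  eta_fixed <- as.vector(X %*% beta)
  sd_b <- sqrt(tau00)
  b <- seq(-lim * sd_b, lim * sd_b, length.out = n_grid)
  db <- b[2] - b[1]
  total <- 0
  for (cl in unique(cluster)) {
    idx <- cluster == cl
    # log integrand on the grid: sum_i log Bernoulli + log Normal(b)
    lp <- vapply(b, function(bb) {
      eta <- eta_fixed[idx] + bb
      sum(ifelse(y[idx] == 1, plogis(eta, log.p = TRUE),
                 plogis(-eta, log.p = TRUE)))
    }, numeric(1)) + dnorm(b, 0, sd_b, log = TRUE)
    m <- max(lp)
    w <- exp(lp - m)
    # trapezoid rule
    total <- total + m + log((sum(w) - (w[1] + w[n_grid]) / 2) * db)
  }
  total
}

# naive per-trial WFPT summation for the likelihood oracle
oracle_trial_loglik <- function(trials, v_by_cell, a, z, t0) {
  cell <- paste0(trials$valence, ":", trials$condition)
  sum(vapply(seq_len(nrow(trials)), function(i) {
    p <- ddm_params(v_by_cell[[cell[i]]], a, z, t0)
    wfpt_log_density(trials$rt[i],
                     if (trials$response[i] == 1) "upper" else "lower", p)
  }, numeric(1)))
}

# small reusable fixtures
small_design <- function(n = 4) study_design(n_participants = n, n_blocks = 1)

# reconstruct a trial set carrying given per-cell response counts
trials_from_counts <- function(counts) {
  purrr::pmap_dfr(counts, function(condition, valence, response, n) {
    row <- tibble::tibble(
      participant_id = "P01", session = 1L, condition = condition,
      valence = valence, word = "w", block = 1L,
      response = as.integer(response), rt = 0.8)
    dplyr::slice(row, rep(1, n))
  })
}

# published per-cell response counts of the two-condition task
observed_counts <- tibble::tribble(
  ~condition, ~valence, ~response, ~n,
  "blue_enriched", "negative", 0L, 387,
  "blue_enriched", "negative", 1L, 2187,
  "blue_depleted", "negative", 0L, 448,
  "blue_depleted", "negative", 1L, 2126,
  "blue_enriched", "positive", 0L, 1864,
  "blue_enriched", "positive", 1L, 710,
  "blue_depleted", "positive", 0L, 1887,
  "blue_depleted", "positive", 1L, 687
)

tight_truth <- function() {
  group_truth(v_sd_between = 0, a_sd = 0, z_sd = 0, t_sd = 0)
}
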