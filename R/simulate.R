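#' Simulate a full SRET dataset from diffusion-model truth
#'
#' Generates trial-level choices and reaction times for the complete design:
#' participant parameters are drawn from the hierarchy, condition order is
#' counterbalanced across participants, and every trial's response and RT come
#' from the bridge-corrected diffusion simulator using that participant's
#' drift for the trial's condition-by-valence cell. Responses follow the task
#' coding: `0` = "yes, describes me" (endorse, lower boundary), `1` = "no"
#' (reject, upper boundary).
#'
#' @param truth A [group_truth()].
#' @param design A [study_design()].
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   `(truth, design, seed)`.
#' @param dt Simulator step size in seconds.
#' @return A tibble of trials with columns `participant_id`, `session`,
#'   `condition`, `valence`, `word`, `block`, `response`, `rt`, plus the
#'   participant covariates `sex` and `hue_aware`.
#' @examples
#' trials <- simulate_sret(design = study_design(n_participants = 2), seed = 1)
#' @export
simulate_sret <- function(truth = group_truth(), design = study_design(),
                          seed = 1L, dt = 1e-3) {
  stopifnot(inherits(truth, "sret_truth"), inherits(design, "sret_design"))
  set.seed(seed)
  pp <- sample_participants(truth, design)
  words <- generate_word_lists(design)
  first <- condition_orders(design$n_participants)

  grid <- tidyr::expand_grid(
    i = seq_len(design$n_participants),
    session = seq_len(design$n_sessions),
    block = seq_len(design$n_blocks),
    words
  )
  grid$condition <- ifelse(
    grid$session == 1L, first[grid$i],
    ifelse(first[grid$i] == "blue_enriched", "blue_depleted", "blue_enriched"))
  # randomize word order within each participant x session x block
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  grid <- dplyr::arrange(grid, .data$i, .data$session, .data$block)

  vcol <- paste0("v_", grid$valence, "_", grid$condition)
  vmat <- as.matrix(pp[, paste0("v_", c("positive_blue_depleted",
                                        "positive_blue_enriched",
                                        "negative_blue_depleted",
                                        "negative_blue_enriched"))])
  colnames(vmat) <- paste0("v_", c("positive_blue_depleted",
                                   "positive_blue_enriched",
                                   "negative_blue_depleted",
                                   "negative_blue_enriched"))
  v_tr <- vmat[cbind(grid$i, match(vcol, colnames(vmat)))]

  sim <- ddm_simulate_cpp(nrow(grid), v_tr, pp$a[grid$i], pp$z[grid$i],
                          pp$t0[grid$i], dt)
  tibble::tibble(
    participant_id = pp$participant_id[grid$i],
    session = as.integer(grid$session),
    condition = grid$condition,
    valence = grid$valence,
    word = grid$word,
    block = as.integer(grid$block),
    response = as.integer(sim$boundary),  # 1 = reject (upper), 0 = endorse
    rt = sim$rt,
    sex = pp$sex[grid$i],
    hue_aware = pp$hue_aware[grid$i]
  )
}

#' Simulate trial-level responses from a random-intercept logistic truth
#'
#' Generates negative-word (or positive-word) trials whose binary outcome is
#' drawn from `logit P(response = 1) = b0 + b_i + b_cond * 1[enriched] +
#' b_rt * rt`, with participant intercepts `b_i ~ Normal(0, tau00)` and
#' reaction times drawn from a lognormal matched by default to the observed
#' moments of the task (mean ~0.85 s, SD ~0.45 s). For negative words the
#' modelled `response = 1` is a rejection, i.e. a positive self-evaluation.
#'
#' @param coefs Named list/vector with elements `intercept`, `condition`
#'   (log-odds for blue-enriched vs blue-depleted) and `rt` (log-odds per
#'   second). Defaults are the reported negative-word estimates
#'   `log(12.07)`, `log(1.24)`, `log(0.68)`.
#' @param tau00 Variance of the participant random intercept (default 1.88).
#' @param design A [study_design()].
#' @param valence Which valence label the trials carry.
#' @param rt_meanlog,rt_sdlog Lognormal RT parameters.
#' @param seed Integer seed.
#' @return A tibble of trials in the same schema as [simulate_sret()].
#' @export
simulate_sret_logistic <- function(coefs = list(intercept = log(12.07),
                                                condition = log(1.24),
                                                rt = log(0.68)),
                                   tau00 = 1.88,
                                   design = study_design(),
                                   valence = "negative",
                                   rt_meanlog = NULL, rt_sdlog = NULL,
                                   seed = 1L) {
  stopifnot(inherits(design, "sret_design"), tau00 >= 0)
  stopifnot(all(c("intercept", "condition", "rt") %in% names(coefs)))
  set.seed(seed)
  # lognormal matched to mean 0.85 s, sd 0.45 s unless overridden
  if (is.null(rt_sdlog)) {
    m <- 0.85; s <- 0.45
    s2 <- log(1 + (s / m)^2)
    rt_sdlog <- sqrt(s2)
    if (is.null(rt_meanlog)) rt_meanlog <- log(m) - s2 / 2
  } else if (is.null(rt_meanlog)) {
    rt_meanlog <- log(0.85) - rt_sdlog^2 / 2
  }

  n <- design$n_participants
  b_i <- rnorm(n, 0, sqrt(tau00))
  first <- condition_orders(n)
  n_female <- round(n * 22 / 35)
  sex <- rep(c("female", "male"), c(n_female, n - n_female))
  hue <- runif(n) < design$hue_aware_rate
  words <- generate_word_lists(design)
  words <- words[words$valence == valence, ]

  grid <- tidyr::expand_grid(
    i = seq_len(n),
    session = seq_len(design$n_sessions),
    block = seq_len(design$n_blocks),
    words
  )
  grid$condition <- ifelse(
    grid$session == 1L, first[grid$i],
    ifelse(first[grid$i] == "blue_enriched", "blue_depleted", "blue_enriched"))
  rt <- rlnorm(nrow(grid), rt_meanlog, rt_sdlog)
  eta <- coefs$intercept + b_i[grid$i] +
    coefs$condition * (grid$condition == "blue_enriched") +
    coefs$rt * rt
  resp <- rbinom(nrow(grid), 1L, plogis(eta))
  tibble::tibble(
    participant_id = sprintf("P%02d", grid$i),
    session = as.integer(grid$session),
    condition = grid$condition,
    valence = valence,
    word = grid$word,
    block = as.integer(grid$block),
    response = as.integer(resp),
    rt = rt,
    sex = sex[grid$i],
    hue_aware = hue[grid$i]
  )
}
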