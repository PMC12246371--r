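test_that("word lists have the designed size and are deterministic", {
  w <- generate_word_lists(study_design())
  expect_equal(sum(w$valence == "positive"), 26)
  expect_equal(sum(w$valence == "negative"), 26)
  expect_equal(anyDuplicated(w$word), 0)
  expect_identical(w, generate_word_lists(study_design()))
  w1 <- generate_word_lists(study_design(words_per_valence = 1))
  expect_equal(nrow(w1), 2)
})

test_that("participants inherit group means exactly when SDs are zero", {
  pp <- sample_participants(tight_truth(), study_design(), seed = 1)
  expect_equal(nrow(pp), 33)
  expect_true(all(pp$a == 1.42))
  expect_true(all(pp$z == 0.49))
  expect_true(all(pp$t0 == 0.46))
  expect_true(all(pp$v_negative_blue_enriched == 1.36))
  expect_equal(sum(pp$sex == "female"), round(33 * 22 / 35))
})

test_that("sampled participants satisfy the hierarchy's truncation bounds", {
  pp <- sample_participants(group_truth(), study_design(n_participants = 500),
                            seed = 2)
  expect_true(all(pp$a > 0))
  expect_true(all(pp$z > 0.05 & pp$z < 0.95))
  expect_true(all(pp$t0 > 0.1 & pp$t0 < 1.0))
})

test_that("sampled boundary separations match the truncated-normal mean", {
  tr <- group_truth()
  pp <- sample_participants(tr, study_design(n_participants = 10000), seed = 3)
  target <- oracle_truncnorm_mean(tr$a_mean, tr$a_sd, 0, Inf)
  se <- tr$a_sd / sqrt(10000)
  expect_lt(abs(mean(pp$a) - target), 3 * se)
})

test_that("the full-scale design yields 5148 trials per valence", {
  trials <- simulate_sret(group_truth(), study_design(), seed = 4)
  expect_equal(nrow(trials), 10296)
  expect_equal(unname(table(trials$valence)["negative"]), 5148,
               ignore_attr = TRUE)
  expect_equal(unname(table(trials$valence)["positive"]), 5148,
               ignore_attr = TRUE)
  # each condition-by-valence cell holds 33 x 78 trials
  expect_true(all(table(trials$condition, trials$valence) == 2574))
})

test_that("every participant-session-valence cell holds words x blocks trials", {
  d <- study_design(n_participants = 5)
  trials <- simulate_sret(group_truth(), d, seed = 5)
  counts <- table(trials$participant_id, trials$session, trials$valence)
  expect_true(all(counts == d$words_per_valence * d$n_blocks))
})

test_that("condition order is counterbalanced to within one participant", {
  for (n in c(6, 33)) {
    trials <- simulate_sret(group_truth(), study_design(n_participants = n),
                            seed = 6)
    first <- trials |>
      dplyr::filter(session == 1) |>
      dplyr::distinct(participant_id, condition)
    imbalance <- abs(sum(first$condition == "blue_enriched") -
                       sum(first$condition == "blue_depleted"))
    expect_lte(imbalance, 1)
    # each participant sees each condition exactly once across sessions
    both <- trials |> dplyr::distinct(participant_id, session, condition)
    expect_true(all(table(both$participant_id) == 2))
    expect_true(all(tapply(both$condition, both$participant_id,
                           dplyr::n_distinct) == 2))
  }
})

test_that("generation is deterministic given seed and configuration", {
  a <- simulate_sret(group_truth(), small_design(), seed = 42)
  b <- simulate_sret(group_truth(), small_design(), seed = 42)
  expect_identical(a, b)
  c <- simulate_sret(group_truth(), small_design(), seed = 43)
  expect_false(identical(a, c))
})

test_that("a single participant, block and session yields 52 trials", {
  d <- study_design(n_participants = 1, n_blocks = 1, n_sessions = 1)
  trials <- simulate_sret(group_truth(), d, seed = 7)
  expect_equal(nrow(trials), 52)
})

test_that("strong drift makes rejection nearly certain", {
  tr <- group_truth(v_mean = c("positive:blue_depleted" = 5,
                               "positive:blue_enriched" = 5,
                               "negative:blue_depleted" = 5,
                               "negative:blue_enriched" = 5),
                    v_sd_between = 0, a_sd = 0, z_sd = 0, t_sd = 0)
  trials <- simulate_sret(tr, study_design(n_participants = 20), seed = 8)
  expect_gt(mean(trials$response == 1), 0.99)
})

test_that("aggregate rejection rate tracks the analytic choice probability", {
  trials <- simulate_sret(tight_truth(), study_design(), seed = 9)
  neg_enr <- trials$response[trials$valence == "negative" &
                               trials$condition == "blue_enriched"]
  p_true <- ddm_choice_probability(ddm_params(1.36, 1.42, 0.49, 0.46))
  mc_se <- sqrt(p_true * (1 - p_true) / length(neg_enr))
  expect_lt(abs(mean(neg_enr) - p_true), 4 * mc_se)
})

test_that("the logistic generator honours its truth", {
  # no condition effect, no heterogeneity: rate follows the inverse logit
  d <- study_design(n_participants = 40)
  beta0 <- 1.2; brt <- -0.4
  trials <- simulate_sret_logistic(
    coefs = list(intercept = beta0, condition = 0, rt = brt),
    tau00 = 0, design = d, seed = 10)
  p_hat <- mean(trials$response)
  p_expected <- mean(plogis(beta0 + brt * trials$rt))
  expect_lt(abs(p_hat - p_expected), 3 * sqrt(0.25 / nrow(trials)))

  # zero intercept variance shows up as a near-zero fitted ICC
  fit <- suppressWarnings(fit_sret_glmm(trials))
  expect_lt(fit$icc, 0.02)

  # a positive condition log-odds raises the enriched rejection rate
  trials2 <- simulate_sret_logistic(tau00 = 1.88, design = d, seed = 11)
  rates <- tapply(trials2$response, trials2$condition, mean)
  expect_gt(rates[["blue_enriched"]], rates[["blue_depleted"]])
})

test_that("trial files round-trip losslessly and are validated on read", {
  trials <- simulate_sret(group_truth(), small_design(2), seed = 12)
  schema <- trials[, c("participant_id", "session", "condition", "valence",
                       "word", "block", "response", "rt")]
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(schema))

  # header-only file for an empty record set
  empty <- schema[0, ]
  write_trials(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_trials(path)), 0L)

  # invariant enforcement names the offending line
  bad <- schema
  bad$rt[3] <- -0.2
  readr::write_csv(bad, path)
  expect_error(read_trials(path), "line 4")
})
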