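test_that("with no heterogeneity the mixed model reduces to plain logistic regression", {
  # a no-heterogeneity dataset whose variance estimate reaches the boundary
  trials <- simulate_sret_logistic(
    coefs = list(intercept = 1.5, condition = 0.3, rt = -0.5),
    tau00 = 0, design = study_design(n_participants = 30), seed = 2)
  fit <- suppressWarnings(fit_sret_glmm(trials))
  d <- data.frame(
    outcome = trials$response,
    condition = factor(trials$condition,
                       levels = c("blue_depleted", "blue_enriched")),
    rt = trials$rt)
  ref <- glm(outcome ~ condition + rt, family = binomial(), data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 1e-4)
  expect_lt(fit$tau00, 0.01)
})

test_that("the quadrature likelihood matches brute-force marginal integration", {
  set.seed(2)
  # 20-observation fixture, 4 clusters
  n <- 20
  cl <- rep(1:4, each = 5)
  b_true <- rnorm(4, 0, 1)
  rt <- rlnorm(n, -0.3, 0.4)
  cond <- rep(c(0, 1), 10)
  eta <- 0.5 + 0.8 * cond - 0.6 * rt + b_true[cl]
  y <- rbinom(n, 1, plogis(eta))
  trials <- tibble::tibble(
    participant_id = sprintf("P%02d", cl), session = 1L,
    condition = ifelse(cond == 1, "blue_enriched", "blue_depleted"),
    valence = "negative", word = "terrible", block = 1L,
    response = as.integer(y), rt = rt)
  fit <- suppressWarnings(fit_sret_glmm(trials, quadrature_nodes = 25))
  beta <- fit$coefficients$estimate
  X <- cbind(1, as.integer(trials$condition == "blue_enriched"), trials$rt)
  oracle <- oracle_glmm_loglik(y, X, cl, beta, max(fit$tau00, 1e-10))
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)
})

test_that("increasing the quadrature node count leaves estimates unchanged", {
  trials <- simulate_sret_logistic(design = study_design(n_participants = 12),
                                   seed = 3)
  f15 <- fit_sret_glmm(trials, quadrature_nodes = 15)
  f25 <- fit_sret_glmm(trials, quadrature_nodes = 25)
  expect_equal(f15$coefficients$estimate, f25$coefficients$estimate,
               tolerance = 1e-5)
})

test_that("standardization is a pure reparameterization", {
  trials <- simulate_sret_logistic(design = study_design(n_participants = 12),
                                   seed = 4)
  raw <- fit_sret_glmm(trials)
  std <- standardize_and_fit(trials)
  expect_equal(std$loglik, raw$loglik, tolerance = 1e-5)

  # rescaling RT to milliseconds changes nothing after standardization
  ms <- trials
  ms$rt <- ms$rt * 1000
  std_ms <- standardize_and_fit(ms)
  i <- match("rt", std$coefficients$term)
  expect_equal(std$coefficients$estimate[i], std_ms$coefficients$estimate[i],
               tolerance = 1e-5)

  # centering shifts the intercept by beta_rt * mean(rt)
  m_rt <- mean(trials$rt)
  s_rt <- sd(trials$rt)
  b_rt_raw <- raw$coefficients$estimate[match("rt", raw$coefficients$term)]
  b0_raw <- raw$coefficients$estimate[match("(Intercept)", raw$coefficients$term)]
  b0_std <- std$coefficients$estimate[match("(Intercept)", std$coefficients$term)]
  expect_equal(b0_std, b0_raw + b_rt_raw * m_rt, tolerance = 1e-3)
  b_rt_std <- std$coefficients$estimate[match("rt", std$coefficients$term)]
  expect_equal(b_rt_std, b_rt_raw * s_rt, tolerance = 1e-3)
})

test_that("ICC and latent-scale R2 follow their formulas", {
  trials <- simulate_sret_logistic(design = study_design(n_participants = 12),
                                   seed = 5)
  fit <- fit_sret_glmm(trials)
  r <- icc_and_r2(fit)
  expect_equal(r$icc, fit$tau00 / (fit$tau00 + pi^2 / 3), tolerance = 1e-10)
  expect_true(r$r2_marginal >= 0 && r$r2_marginal <= r$r2_conditional)
  expect_lte(r$r2_conditional, 1)
  # the reported intercept variance implies the reported ICC
  expect_equal(1.88 / (1.88 + pi^2 / 3), 0.3636, tolerance = 1e-3)
  expect_equal((pi^2 / 3) / (pi^2 / 3 + pi^2 / 3), 0.5)
})

test_that("odds ratios and Wald intervals transform the coefficients", {
  trials <- simulate_sret_logistic(design = study_design(n_participants = 12),
                                   seed = 6)
  fit <- fit_sret_glmm(trials)
  co <- fit$coefficients
  expect_equal(co$odds_ratio, exp(co$estimate))
  expect_equal(co$or_ci_lower, exp(co$estimate - 1.96 * co$std_error))
  expect_equal(co$or_ci_upper, exp(co$estimate + 1.96 * co$std_error))
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))
})

test_that("BIC comparison penalizes superfluous terms and ranks candidates", {
  trials <- simulate_sret_logistic(design = study_design(n_participants = 20),
                                   seed = 7)
  tab <- suppressWarnings(candidate_model_table(
    trials,
    candidates = list("condition + rt" = c("condition", "rt"),
                      "condition * rt" = "condition * rt",
                      "condition + rt + sex" = c("condition", "rt", "sex"))))
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$bic[tab$converged]) >= 0))
  # data generated from main effects: the main-effects model wins here
  expect_equal(tab$model[1], "condition + rt")
  expect_true(all(tab$bic_cluster[tab$converged] < tab$bic[tab$converged]))

  single <- suppressWarnings(candidate_model_table(
    trials, candidates = list("condition + rt" = c("condition", "rt"))))
  expect_equal(nrow(single), 1)
})
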