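test_that("model variants expand into the correct parameter maps", {
  v_only <- build_design(ddm_model_spec("v"))
  expect_equal(sum(v_only$parameter == "v"), 4)
  expect_equal(sum(v_only$parameter == "a"), 1)
  expect_equal(sum(v_only$parameter %in% c("z", "t")), 2)

  null <- build_design(ddm_model_spec(character(0)))
  expect_equal(nrow(null), 4) # one shared coefficient per parameter

  vz <- build_design(ddm_model_spec(c("v", "z")))
  expect_equal(sum(vz$parameter == "v"), 4)
  expect_equal(sum(vz$parameter == "z"), 4)
  expect_equal(sum(vz$parameter == "t"), 1)

  expect_error(ddm_model_spec(c("v", "a")), "fail to converge")
})

test_that("the joint likelihood is a sum of per-trial densities", {
  trials <- simulate_sret(group_truth(), small_design(2), seed = 1)
  v_cells <- list("positive:blue_depleted" = -0.73,
                  "positive:blue_enriched" = -0.71,
                  "negative:blue_depleted" = 1.13,
                  "negative:blue_enriched" = 1.36)
  params <- list(v = unlist(v_cells), a = 1.42, z = 0.49, t = 0.46)

  one <- trials[1, ]
  p1 <- ddm_params(v_cells[[paste0(one$valence, ":", one$condition)]],
                   1.42, 0.49, 0.46)
  expect_equal(hddm_log_likelihood(one, params),
               wfpt_log_density(one$rt,
                                if (one$response == 1) "upper" else "lower",
                                p1))

  sub <- trials[1:20, ]
  expect_equal(hddm_log_likelihood(sub, params),
               oracle_trial_loglik(sub, v_cells, 1.42, 0.49, 0.46),
               tolerance = 1e-10)

  doubled <- dplyr::bind_rows(sub, sub)
  expect_equal(hddm_log_likelihood(doubled, params),
               2 * hddm_log_likelihood(sub, params), tolerance = 1e-12)
})

test_that("retained draw counts follow the settings arithmetic", {
  s <- mcmc_settings() # reference protocol
  expect_equal((s$n_samples - s$burn_in) %/% s$thin, 2500)
  trials <- simulate_sret(group_truth(), small_design(3), seed = 2)
  fit <- fit_hddm(trials, ddm_model_spec("v"),
                  mcmc_settings(240, 40, 4, 2, seed = 1))
  expect_equal(nrow(fit$draws[[1]]), 50)
  expect_equal(length(fit$draws), 2)
  expect_equal(length(fit$deviance[[1]]), 50)
})

test_that("sampling is reproducible under a fixed seed", {
  trials <- simulate_sret(group_truth(), small_design(2), seed = 3)
  s <- mcmc_settings(200, 50, 3, 2, seed = 9)
  f1 <- fit_hddm(trials, ddm_model_spec("v"), s)
  f2 <- fit_hddm(trials, ddm_model_spec("v"), s)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("the sampler's internal likelihood matches the exported one", {
  trials <- simulate_sret(group_truth(), small_design(2), seed = 4)
  fit <- fit_hddm(trials, ddm_model_spec("v"),
                  mcmc_settings(200, 50, 5, 2, seed = 2))
  for (k in c(1, nrow(fit$draws[[1]]))) {
    draw <- fit$draws[[1]][k, ]
    ll <- hddm_log_likelihood(trials, sretddm:::params_from_draw(fit, draw))
    expect_equal(fit$deviance[[1]][k], -2 * ll, tolerance = 1e-8)
  }
})

test_that("prior-only sampling reproduces the prior's moments", {
  trials <- simulate_sret(group_truth(), small_design(2), seed = 5)
  fit <- fit_hddm(trials, ddm_model_spec("v"),
                  mcmc_settings(6000, 1000, 5, 2, seed = 3),
                  prior_only = TRUE)
  v_draws <- sretddm:::pooled_parameter(fit, "v[negative:blue_enriched]")
  # prior is Normal(0, 2^2); allow generous MCMC error for correlated draws
  expect_lt(abs(mean(v_draws)), 0.35)
  expect_lt(abs(sd(v_draws) - 2) / 2, 0.2)
})

test_that("split-chain R-hat flags divergent chains and passes identical ones", {
  set.seed(1)
  m1 <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("x", "y")))
  same <- gelman_rubin(list(m1, m1 + 0))
  expect_true(all(abs(same - 1) < 0.01))

  shifted <- matrix(rnorm(2000, mean = 5), 1000, 2,
                    dimnames = list(NULL, c("x", "y")))
  far <- gelman_rubin(list(m1, shifted))
  expect_true(all(far > 1.5))
  expect_error(gelman_rubin(list(m1)), "at least 2 chains")
})

test_that("autocorrelation profiles identify white noise and AR(1) draws", {
  set.seed(2)
  wn <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "x"))
  a_wn <- mcmc_autocorrelation(list(wn), max_lag = 10)
  expect_equal(a_wn$acf[a_wn$lag == 0], 1)
  expect_true(mean(abs(a_wn$acf[a_wn$lag >= 1]) < 3 / sqrt(4000)) > 0.8)

  phi <- 0.9
  x <- as.numeric(arima.sim(list(ar = phi), 20000))
  a_ar <- mcmc_autocorrelation(x, max_lag = 5)
  expect_equal(a_ar$acf[a_ar$lag == 1], phi, tolerance = 0.05)
  # thinning reduces lag-1 autocorrelation
  thinned <- x[seq(1, length(x), by = 10)]
  a_th <- mcmc_autocorrelation(thinned, max_lag = 2)
  expect_lt(a_th$acf[a_th$lag == 1], a_ar$acf[a_ar$lag == 1])
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  trials <- simulate_sret(group_truth(), small_design(2), seed = 6)
  fit <- fit_hddm(trials, ddm_model_spec("v"),
                  mcmc_settings(120, 20, 2, 2, seed = 4))
  pm <- sretddm:::posterior_mean_vector(fit)
  degenerate <- fit
  degenerate$draws <- lapply(fit$draws, function(m) {
    m[] <- rep(pm, each = nrow(m)); m
  })
  d0 <- -2 * hddm_log_likelihood(trials,
                                 sretddm:::params_from_draw(fit, pm))
  degenerate$deviance <- lapply(fit$deviance, function(d) rep(d0, length(d)))
  res <- compute_dic(degenerate)
  expect_equal(res$pD, 0, tolerance = 1e-8)
  expect_equal(res$dic, d0, tolerance = 1e-8)
})

test_that("drift-varying data favour the drift-varying model over the null", {
  trials <- simulate_sret(tight_truth(), small_design(6), seed = 7)
  tab <- select_best_model(
    trials,
    list(ddm_model_spec("v"), ddm_model_spec(character(0))),
    settings = mcmc_settings(900, 300, 3, 2, seed = 5))
  expect_equal(tab$variant[1], "v")
  expect_lt(tab$delta_dic_null[tab$variant == "v"], 0)
  expect_true(all(c("rank", "dic", "pD", "converged") %in% names(tab)))

  single <- select_best_model(trials, list(ddm_model_spec("v")),
                              settings = mcmc_settings(300, 100, 2, 2, seed = 6))
  expect_equal(nrow(single), 1)
})

test_that("the null model stays competitive on no-contrast data", {
  flat <- group_truth(v_mean = c("positive:blue_depleted" = 0.6,
                                 "positive:blue_enriched" = 0.6,
                                 "negative:blue_depleted" = 0.6,
                                 "negative:blue_enriched" = 0.6),
                      v_sd_between = 0, a_sd = 0, z_sd = 0, t_sd = 0)
  trials <- simulate_sret(flat, small_design(6), seed = 8)
  tab <- select_best_model(
    trials,
    list(ddm_model_spec("v"), ddm_model_spec(character(0))),
    settings = mcmc_settings(900, 300, 3, 2, seed = 7))
  expect_lt(abs(tab$delta_dic_null[tab$variant == "v"]), 30)
})
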