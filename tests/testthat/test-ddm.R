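test_that("first-passage density normalizes and respects the non-decision bound", {
  grid <- list(
    ddm_params(1.36, 1.42, 0.49, 0.46),
    ddm_params(-0.73, 1.42, 0.49, 0.46),
    ddm_params(0, 1.0, 0.3, 0.2),
    ddm_params(2.5, 0.8, 0.7, 0.1)
  )
  for (p in grid) {
    mass <- integrate(function(x) exp(wfpt_log_density(x, "upper", p)),
                      p$t0, Inf)$value +
      integrate(function(x) exp(wfpt_log_density(x, "lower", p)),
                p$t0, Inf)$value
    expect_equal(mass, 1, tolerance = 1e-3)
  }
  p <- ddm_params(1.36, 1.42, 0.49, 0.46)
  expect_identical(wfpt_log_density(0.3, "upper", p), -Inf)
  expect_identical(wfpt_log_density(0.46, "lower", p), -Inf)
})

test_that("lower-boundary density equals the reflected upper-boundary density", {
  rts <- seq(0.5, 3, by = 0.25)
  for (v in c(-1, 0.4, 2)) {
    for (z in c(0.3, 0.49, 0.7)) {
      p <- ddm_params(v, 1.42, z, 0.46)
      p_ref <- ddm_params(-v, 1.42, 1 - z, 0.46)
      expect_equal(wfpt_log_density(rts, "lower", p),
                   wfpt_log_density(rts, "upper", p_ref), tolerance = 1e-12)
    }
  }
})

test_that("small- and large-time series agree where both are usable", {
  # force each branch by shifting the accuracy tolerance and compare
  p <- ddm_params(1.1, 1.3, 0.45, 0)
  rts <- seq(0.15, 2.5, by = 0.05)
  loose <- wfpt_log_density(rts, "upper", p, eps = 1e-7)
  tight <- wfpt_log_density(rts, "upper", p, eps = 1e-12)
  expect_equal(loose, tight, tolerance = 1e-6)
})

test_that("choice probability matches its closed form and limits", {
  expect_equal(ddm_choice_probability(ddm_params(0, 1.42, 0.5, 0.46)), 0.5)
  p_tab <- ddm_choice_probability(ddm_params(1.36, 1.42, 0.49, 0.46))
  expect_equal(p_tab, oracle_choice_prob(1.36, 1.42, 0.49), tolerance = 1e-12)
  expect_equal(p_tab, 0.868, tolerance = 1e-3)
  expect_gt(ddm_choice_probability(ddm_params(5, 1.42, 0.49, 0.46)), 0.999)
})

test_that("choice probability is strictly increasing in drift and start point", {
  vs <- seq(-2, 2, by = 0.5)
  pv <- vapply(vs, function(v)
    ddm_choice_probability(ddm_params(v, 1.42, 0.49, 0.46)), numeric(1))
  expect_true(all(diff(pv) > 0))
  zs <- seq(0.1, 0.9, by = 0.1)
  pz <- vapply(zs, function(z)
    ddm_choice_probability(ddm_params(0.8, 1.42, z, 0.46)), numeric(1))
  expect_true(all(diff(pz) > 0))
})

test_that("simulated choice fractions match the analytic absorption probability", {
  p <- ddm_params(1.36, 1.42, 0.49, 0.46)
  n <- 1e5
  s <- ddm_simulate(p, n, seed = 101)
  p_true <- ddm_choice_probability(p)
  mc_se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(s$boundary == "upper") - p_true), 3 * mc_se)
  expect_true(all(s$rt > p$t0))
})

test_that("zero-drift unbiased diffusion is symmetric between boundaries", {
  p <- ddm_params(0, 1.2, 0.5, 0.3)
  s <- ddm_simulate(p, 4e4, seed = 7)
  expect_lt(abs(mean(s$boundary == "upper") - 0.5), 3 * sqrt(0.25 / 4e4))
  ks <- suppressWarnings(
    ks.test(s$rt[s$boundary == "upper"], s$rt[s$boundary == "lower"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("halving the step size does not shift the simulator's distribution", {
  p <- ddm_params(1.36, 1.42, 0.49, 0.46)
  s1 <- ddm_simulate(p, 3e4, dt = 2e-3, seed = 11)
  s2 <- ddm_simulate(p, 3e4, dt = 1e-3, seed = 12)
  expect_lt(abs(mean(s1$boundary == "upper") - mean(s2$boundary == "upper")),
            4 * sqrt(0.868 * 0.132 * 2 / 3e4))
  expect_lt(abs(median(s1$rt) - median(s2$rt)), 0.02)
})

test_that("simulated density matches the analytic density on a grid", {
  p <- ddm_params(1.36, 1.42, 0.49, 0.46)
  n <- 2e5
  s <- ddm_simulate(p, n, seed = 3)
  up <- s$rt[s$boundary == "upper"]
  brk <- seq(0.46, 2.5, by = 0.04)
  h <- hist(up[up < 2.5], breaks = brk, plot = FALSE)
  mid <- h$mids
  dens_analytic <- exp(wfpt_log_density(mid, "upper", p))
  # histogram approximates the joint density of (rt, upper)
  dens_sim <- h$density * mean(s$boundary == "upper") *
    mean(up < 2.5)
  expect_lt(max(abs(dens_sim - dens_analytic)), 0.06)
})

test_that("rt quantiles are computed at the requested probabilities", {
  one <- tibble::tibble(rt = 0.8, boundary = "upper")
  q1 <- rt_quantiles(one)
  expect_equal(q1$rt, rep(0.8, 5))
  expect_equal(q1$prob, c(0.1, 0.3, 0.5, 0.7, 0.9))

  s <- ddm_simulate(ddm_params(1.36, 1.42, 0.49, 0.46), 5e3, seed = 5)
  q <- rt_quantiles(s, by_boundary = TRUE)
  expect_true(all(tapply(q$rt, q$boundary, function(x) all(diff(x) >= 0))))
  expect_error(rt_quantiles(tibble::tibble(rt = numeric(0))), "no samples")
})

test_that("simulated quantiles converge to density-implied quantiles", {
  p <- ddm_params(1.36, 1.42, 0.49, 0.46)
  n <- 1e5
  s <- ddm_simulate(p, n, seed = 21)
  up <- s$rt[s$boundary == "upper"]
  # CDF of upper-boundary RTs by numerical integration of the density
  p_up <- integrate(function(x) exp(wfpt_log_density(x, "upper", p)),
                    p$t0, Inf)$value
  cdf_q <- function(prob) {
    uniroot(function(q) integrate(function(x)
      exp(wfpt_log_density(x, "upper", p)), p$t0, q)$value / p_up - prob,
      c(p$t0 + 1e-4, 10))$root
  }
  for (pr in c(0.1, 0.5, 0.9)) {
    expect_equal(unname(quantile(up, pr)), cdf_q(pr), tolerance = 0.02)
  }
})

test_that("parameter validation rejects impossible values", {
  expect_error(ddm_params(1, -1, 0.5, 0.3), "must be > 0")
  expect_error(ddm_params(1, 1, 1.2, 0.3), "\\(0, 1\\)")
  expect_error(ddm_params(1, 1, 0.5, -0.1), ">= 0")
})
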