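# Hierarchical Bayesian estimation of the diffusion-model variants by
# adaptive Metropolis-within-Gibbs. Group-level nodes: one drift coefficient
# per condition-by-valence cell (or shared), shared boundary separation, and
# shared or cell-specific starting point / non-decision time. Participant
# level: additive offsets on a, z, t with half-normal hierarchical SDs. An
# interweaving "recentering" move (shift a group mean while counter-shifting
# the offsets, leaving every participant-level value unchanged) breaks the
# group-mean/offset posterior ridge that plain random-walk updates mix
# poorly over.

hddm_prepare_data <- function(trials) {
  validate_trials(trials, "fit_hddm")
  pid <- factor(trials$participant_id)
  list(
    rt = trials$rt,
    up = as.integer(trials$response),
    cell = trial_cells(trials),
    pp = as.integer(pid),
    pid_levels = levels(pid),
    n = nrow(trials),
    n_pp = nlevels(pid),
    min_rt_pp = as.numeric(tapply(trials$rt, pid, min)),
    min_rt_all = min(trials$rt)
  )
}

# log prior for a group starting point on the probability scale
lp_z_group <- function(z, sdl) dnorm(qlogis(z), 0, sdl, log = TRUE) - log(z * (1 - z))

hddm_run_chain <- function(dat, spec, priors, settings, chain_id,
                           prior_only = FALSE, progress = FALSE) {
  set.seed(settings$seed + chain_id - 1L)
  n_pp <- dat$n_pp
  nv <- if ("v" %in% spec$varying) 4L else 1L
  nz <- if ("z" %in% spec$varying) 4L else 1L
  nt <- if ("t" %in% spec$varying) 4L else 1L

  # --- per-update-group data subsets (precomputed once) -------------------
  idx_cell <- lapply(1:4, function(c) which(dat$cell == c))
  idx_pp <- lapply(seq_len(n_pp), function(i) which(dat$pp == i))
  sub <- function(idx) list(rt = dat$rt[idx], up = dat$up[idx],
                            cell = dat$cell[idx], pp = dat$pp[idx], idx = idx)
  S_cell <- lapply(idx_cell, sub)
  S_pp <- lapply(idx_pp, sub)
  S_all <- sub(seq_len(dat$n))

  # --- initial state ------------------------------------------------------
  p_hat <- vapply(1:4, function(c) {
    u <- dat$up[idx_cell[[c]]]
    if (length(u) == 0) 0.5 else min(max(mean(u), 0.02), 0.98)
  }, numeric(1))
  a_mu <- min(max(1.5 + rnorm(1, 0, 0.05), priors$a_lower + 0.1),
              priors$a_upper - 0.1)
  v_cells <- qlogis(p_hat) / a_mu
  v <- if (nv == 4L) v_cells + rnorm(4, 0, 0.1) else
    mean(v_cells) + rnorm(1, 0, 0.1)
  zg <- rep(0.5, nz) + rnorm(nz, 0, 0.01)
  t_init <- min(0.8 * dat$min_rt_all, 0.45)
  tg <- rep(t_init, nt) + rnorm(nt, 0, 0.002)
  tg <- pmin(pmax(tg, priors$t_lower + 0.01), dat$min_rt_all - 0.01)
  sig <- c(a = 0.1, z = 0.03, t = 0.03) * exp(rnorm(3, 0, 0.1))
  da <- rep(0, n_pp); dz <- rep(0, n_pp); dt_ <- rep(0, n_pp)

  ll_of <- function(s, v., a_mu., zg., tg., da., dz., dt_.) {
    if (prior_only) return(rep(0, length(s$rt)))
    wfpt_logdens_cpp(s$rt, s$up,
                     expand_cell(v., s$cell),
                     a_mu. + da.[s$pp],
                     expand_cell(zg., s$cell) + dz.[s$pp],
                     expand_cell(tg., s$cell) + dt_.[s$pp])
  }
  ll <- ll_of(S_all, v, a_mu, zg, tg, da, dz, dt_)
  if (any(!is.finite(ll))) stop("non-finite likelihood at initial state",
                                call. = FALSE)
  ll_total <- sum(ll)

  # --- adaptive proposal scales ------------------------------------------
  upd_names <- c(paste0("v", seq_len(nv)), "a_mu", paste0("z", seq_len(nz)),
                 paste0("t", seq_len(nt)),
                 paste0("da", seq_len(n_pp)), paste0("dz", seq_len(n_pp)),
                 paste0("dt", seq_len(n_pp)),
                 "sig_a", "sig_z", "sig_t", "rc_a", "rc_z", "rc_t")
  ls <- setNames(log(c(rep(0.08, nv), 0.03, rep(0.01, nz), rep(0.008, nt),
                       rep(0.04, n_pp), rep(0.015, n_pp), rep(0.012, n_pp),
                       0.3, 0.3, 0.3, 0.03, 0.008, 0.008)), upd_names)
  n_upd <- setNames(integer(length(upd_names)), upd_names)
  acc_ct <- setNames(integer(length(upd_names)), upd_names)
  target_acc <- 0.44
  adapt <- function(nm, accepted, in_burn) {
    n_upd[[nm]] <<- n_upd[[nm]] + 1L
    if (accepted) acc_ct[[nm]] <<- acc_ct[[nm]] + 1L
    if (in_burn) {
      g <- min(0.1, 2 / sqrt(n_upd[[nm]]))
      ls[[nm]] <<- ls[[nm]] + g * ((if (accepted) 1 else 0) - target_acc)
    }
  }

  # generic MH step over a subset, with likelihood delta + prior delta
  mh_subset <- function(nm, s, dlp, v., a_mu., zg., tg., da., dz., dt_.,
                        in_burn) {
    ll_new <- ll_of(s, v., a_mu., zg., tg., da., dz., dt_.)
    d <- sum(ll_new) - sum(ll[s$idx])
    ok <- is.finite(d) && log(runif(1)) < d + dlp
    if (ok) {
      ll[s$idx] <<- ll_new
      ll_total <<- ll_total + d
    }
    adapt(nm, ok, in_burn)
    ok
  }

  n_keep <- (settings$n_samples - settings$burn_in) %/% settings$thin
  par_names <- c(
    if (nv == 4L) paste0("v[", ddm_cells, "]") else "v",
    "a",
    if (nz == 4L) paste0("z[", ddm_cells, "]") else "z",
    if (nt == 4L) paste0("t[", ddm_cells, "]") else "t",
    "sigma_a", "sigma_z", "sigma_t",
    paste0("delta_a[", dat$pid_levels, "]"),
    paste0("delta_z[", dat$pid_levels, "]"),
    paste0("delta_t[", dat$pid_levels, "]"))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  deviance <- numeric(n_keep)
  k <- 0L

  # group-level t support: each participant's effective t (group + offset) is
  # already capped by that participant's minimum RT, so the group mean only
  # needs to stay below the largest per-participant minimum
  t_upper <- max(dat$min_rt_pp) - 1e-3
  for (iter in seq_len(settings$n_samples)) {
    in_burn <- iter <= settings$burn_in

    # drift cells (or shared drift)
    for (j in seq_len(nv)) {
      nm <- paste0("v", j)
      vp <- v; vp[j] <- v[j] + rnorm(1, 0, exp(ls[[nm]]))
      s <- if (nv == 4L) S_cell[[j]] else S_all
      dlp <- dnorm(vp[j], priors$v_mean, priors$v_sd, log = TRUE) -
        dnorm(v[j], priors$v_mean, priors$v_sd, log = TRUE)
      if (mh_subset(nm, s, dlp, vp, a_mu, zg, tg, da, dz, dt_, in_burn)) v <- vp
    }

    # group boundary separation
    {
      ap <- a_mu + rnorm(1, 0, exp(ls[["a_mu"]]))
      if (ap > priors$a_lower && ap < priors$a_upper && ap + min(da) > 1e-6) {
        dlp <- dnorm(ap, priors$a_mean, priors$a_sd, log = TRUE) -
          dnorm(a_mu, priors$a_mean, priors$a_sd, log = TRUE)
        if (mh_subset("a_mu", S_all, dlp, v, ap, zg, tg, da, dz, dt_, in_burn))
          a_mu <- ap
      } else adapt("a_mu", FALSE, in_burn)
    }

    # group starting point(s)
    for (j in seq_len(nz)) {
      nm <- paste0("z", j)
      zp <- zg; zp[j] <- zg[j] + rnorm(1, 0, exp(ls[[nm]]))
      lo <- zp[j] + min(dz); hi <- zp[j] + max(dz)
      if (zp[j] > 0.01 && zp[j] < 0.99 && lo > 0.001 && hi < 0.999) {
        s <- if (nz == 4L) S_cell[[j]] else S_all
        dlp <- lp_z_group(zp[j], priors$z_logit_sd) -
          lp_z_group(zg[j], priors$z_logit_sd)
        if (mh_subset(nm, s, dlp, v, a_mu, zp, tg, da, dz, dt_, in_burn))
          zg <- zp
      } else adapt(nm, FALSE, in_burn)
    }

    # group non-decision time(s)
    for (j in seq_len(nt)) {
      nm <- paste0("t", j)
      tp <- tg; tp[j] <- tg[j] + rnorm(1, 0, exp(ls[[nm]]))
      ok_sup <- tp[j] > priors$t_lower && tp[j] < t_upper &&
        all(max(tp) + dt_ < dat$min_rt_pp - 1e-3) && min(tp) + min(dt_) > 0
      if (ok_sup) {
        s <- if (nt == 4L) S_cell[[j]] else S_all
        dlp <- dnorm(tp[j], priors$t_mean, priors$t_sd, log = TRUE) -
          dnorm(tg[j], priors$t_mean, priors$t_sd, log = TRUE)
        if (mh_subset(nm, s, dlp, v, a_mu, zg, tp, da, dz, dt_, in_burn))
          tg <- tp
      } else adapt(nm, FALSE, in_burn)
    }

    # participant offsets
    for (i in seq_len(n_pp)) {
      s <- S_pp[[i]]
      nm <- paste0("da", i)
      dp <- da[i] + rnorm(1, 0, exp(ls[[nm]]))
      if (a_mu + dp > 1e-6) {
        dap <- da; dap[i] <- dp
        dlp <- dnorm(dp, 0, sig[["a"]], log = TRUE) -
          dnorm(da[i], 0, sig[["a"]], log = TRUE)
        if (mh_subset(nm, s, dlp, v, a_mu, zg, tg, dap, dz, dt_, in_burn))
          da <- dap
      } else adapt(nm, FALSE, in_burn)

      nm <- paste0("dz", i)
      dp <- dz[i] + rnorm(1, 0, exp(ls[[nm]]))
      if (min(zg) + dp > 0.001 && max(zg) + dp < 0.999) {
        dzp <- dz; dzp[i] <- dp
        dlp <- dnorm(dp, 0, sig[["z"]], log = TRUE) -
          dnorm(dz[i], 0, sig[["z"]], log = TRUE)
        if (mh_subset(nm, s, dlp, v, a_mu, zg, tg, da, dzp, dt_, in_burn))
          dz <- dzp
      } else adapt(nm, FALSE, in_burn)

      nm <- paste0("dt", i)
      dp <- dt_[i] + rnorm(1, 0, exp(ls[[nm]]))
      if (min(tg) + dp > 0 && max(tg) + dp < dat$min_rt_pp[i] - 1e-3) {
        dtp <- dt_; dtp[i] <- dp
        dlp <- dnorm(dp, 0, sig[["t"]], log = TRUE) -
          dnorm(dt_[i], 0, sig[["t"]], log = TRUE)
        if (mh_subset(nm, s, dlp, v, a_mu, zg, tg, da, dz, dtp, in_burn))
          dt_ <- dtp
      } else adapt(nm, FALSE, in_burn)
    }

    # hierarchical SDs (log-scale random walk; prior-only, no likelihood)
    for (w in c("a", "z", "t")) {
      nm <- paste0("sig_", w)
      d <- switch(w, a = da, z = dz, t = dt_)
      sp <- sig[[w]] * exp(rnorm(1, 0, exp(ls[[nm]])))
      dlp <- dnorm(sp, 0, priors$sigma_scale, log = TRUE) + log(sp) -
        dnorm(sig[[w]], 0, priors$sigma_scale, log = TRUE) - log(sig[[w]]) +
        sum(dnorm(d, 0, sp, log = TRUE) - dnorm(d, 0, sig[[w]], log = TRUE))
      ok <- log(runif(1)) < dlp
      if (ok) sig[[w]] <- sp
      adapt(nm, ok, in_burn)
    }

    # recentering interweaves: likelihood-invariant joint shifts
    {
      eps <- rnorm(1, 0, exp(ls[["rc_a"]]))
      ap <- a_mu + eps
      if (ap > priors$a_lower && ap < priors$a_upper) {
        dlp <- dnorm(ap, priors$a_mean, priors$a_sd, log = TRUE) -
          dnorm(a_mu, priors$a_mean, priors$a_sd, log = TRUE) +
          sum(dnorm(da - eps, 0, sig[["a"]], log = TRUE) -
                dnorm(da, 0, sig[["a"]], log = TRUE))
        ok <- log(runif(1)) < dlp
        if (ok) { a_mu <- ap; da <- da - eps }
        adapt("rc_a", ok, in_burn)
      } else adapt("rc_a", FALSE, in_burn)

      eps <- rnorm(1, 0, exp(ls[["rc_z"]]))
      zp <- zg + eps
      if (all(zp > 0.01 & zp < 0.99)) {
        dlp <- sum(vapply(seq_len(nz), function(j)
          lp_z_group(zp[j], priors$z_logit_sd) -
            lp_z_group(zg[j], priors$z_logit_sd), numeric(1))) +
          sum(dnorm(dz - eps, 0, sig[["z"]], log = TRUE) -
                dnorm(dz, 0, sig[["z"]], log = TRUE))
        ok <- log(runif(1)) < dlp
        if (ok) { zg <- zp; dz <- dz - eps }
        adapt("rc_z", ok, in_burn)
      } else adapt("rc_z", FALSE, in_burn)

      eps <- rnorm(1, 0, exp(ls[["rc_t"]]))
      tp <- tg + eps
      if (all(tp > priors$t_lower & tp < t_upper)) {
        dlp <- sum(dnorm(tp, priors$t_mean, priors$t_sd, log = TRUE) -
                     dnorm(tg, priors$t_mean, priors$t_sd, log = TRUE)) +
          sum(dnorm(dt_ - eps, 0, sig[["t"]], log = TRUE) -
                dnorm(dt_, 0, sig[["t"]], log = TRUE))
        ok <- log(runif(1)) < dlp
        if (ok) { tg <- tp; dt_ <- dt_ - eps }
        adapt("rc_t", ok, in_burn)
      } else adapt("rc_t", FALSE, in_burn)
    }

    if (!in_burn && (iter - settings$burn_in) %% settings$thin == 0L) {
      k <- k + 1L
      draws[k, ] <- c(v, a_mu, zg, tg, sig, da, dz, dt_)
      deviance[k] <- -2 * ll_total
    }
    if (progress && iter %% 1000L == 0L) {
      message(sprintf("chain %d: iteration %d / %d", chain_id, iter,
                      settings$n_samples))
    }
  }

  list(draws = draws[seq_len(k), , drop = FALSE],
       deviance = deviance[seq_len(k)],
       accept_rate = acc_ct / pmax(n_upd, 1L))
}

#' Fit a hierarchical diffusion-model variant by MCMC
#'
#' Samples the joint posterior of the group-level coefficients (drift per
#' condition-by-valence cell, or shared, plus boundary separation, starting
#' point and non-decision time), the hierarchical SDs, and the
#' participant-level offsets, using adaptive Metropolis-within-Gibbs with an
#' interweaving recentering move. Chains are seeded `seed + chain - 1` and
#' are exactly reproducible. The retained-draw count per chain is
#' `(n_samples - burn_in) %/% thin`.
#'
#' @param trials Trials tibble (schema of [simulate_sret()]).
#' @param spec A [ddm_model_spec()].
#' @param settings An [mcmc_settings()]; the default is the scaled-down desk
#'   profile (3 chains of 6,000 draws, burn-in 1,000, thin 5).
#' @param priors An [hddm_priors()].
#' @param prior_only If `TRUE`, sample with the likelihood switched off
#'   (posterior equals the prior; used for prior checks).
#' @param progress Emit progress messages.
#' @return An object of class `hddm_fit` with elements `draws` (list of
#'   per-chain matrices, iterations by parameters), `deviance`, `rhat`,
#'   `dic`, `pD`, `spec`, `settings`, `priors`, `trials`, `accept_rate`.
#' @export
fit_hddm <- function(trials, spec = ddm_model_spec("v"),
                     settings = mcmc_settings(6000, 1000, 5, 3, seed = 1L),
                     priors = hddm_priors(), prior_only = FALSE,
                     progress = FALSE) {
  stopifnot(inherits(spec, "ddm_model_spec"), inherits(settings, "mcmc_settings"),
            inherits(priors, "hddm_priors"))
  dat <- hddm_prepare_data(trials)
  chains <- lapply(seq_len(settings$n_chains), function(ch)
    hddm_run_chain(dat, spec, priors, settings, ch, prior_only = prior_only,
                   progress = progress))
  fit <- structure(list(
    draws = lapply(chains, `[[`, "draws"),
    deviance = lapply(chains, `[[`, "deviance"),
    accept_rate = lapply(chains, `[[`, "accept_rate"),
    spec = spec, settings = settings, priors = priors,
    trials = trials, n_obs = nrow(trials),
    participant_ids = dat$pid_levels
  ), class = "hddm_fit")
  fit$rhat <- if (settings$n_chains >= 2) gelman_rubin(fit) else NULL
  if (!prior_only) {
    dic <- compute_dic(fit)
    fit$dic <- dic$dic
    fit$pD <- dic$pD
  }
  fit
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf("<hddm_fit> variant: %s | %d chains x %d retained draws | %d trials\n",
              spec_label(x$spec), length(x$draws), nrow(x$draws[[1]]), x$n_obs))
  if (!is.null(x$dic)) cat(sprintf("  DIC = %.1f (pD = %.1f)\n", x$dic, x$pD))
  if (!is.null(x$rhat)) cat(sprintf("  max R-hat = %.4f\n", max(x$rhat)))
  gp <- grep("^delta", colnames(x$draws[[1]]), invert = TRUE, value = TRUE)
  print(summarize_posterior(posterior_draws(x, gp)), n = length(gp))
  invisible(x)
}

#' Extract posterior draws
#'
#' @param fit An `hddm_fit`.
#' @param parameters Optional character vector of parameter names to keep.
#' @return A tidy tibble with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
posterior_draws <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "hddm_fit"))
  purrr::imap_dfr(fit$draws, function(m, ch) {
    if (!is.null(parameters)) m <- m[, intersect(parameters, colnames(m)),
                                     drop = FALSE]
    tibble::tibble(
      chain = as.integer(ch),
      iteration = rep(seq_len(nrow(m)), ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m)
    )
  })
}

# pooled draws of one parameter across chains
pooled_parameter <- function(fit, parameter) {
  unlist(lapply(fit$draws, function(m) m[, parameter]), use.names = FALSE)
}

#' @export
tidy.hddm_fit <- function(x, parameters = NULL, ...) {
  d <- posterior_draws(x, parameters)
  summarize_posterior(d)
}

#' @export
glance.hddm_fit <- function(x, ...) {
  tibble::tibble(
    variant = spec_label(x$spec),
    n_obs = x$n_obs,
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]),
    max_rhat = if (is.null(x$rhat)) NA_real_ else max(x$rhat),
    dic = x$dic %||% NA_real_,
    pD = x$pD %||% NA_real_
  )
}
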