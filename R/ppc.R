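#' Posterior-predictive reaction-time quantile check
#'
#' For every participant-by-condition-by-valence cell, simulates trials from
#' the diffusion model at that participant's posterior-mean boundary
#' separation, starting point and non-decision time combined with the
#' group-level posterior-mean drift for the cell, then pairs the simulated RT
#' quantiles with the observed ones at the 10th, 30th, 50th, 70th and 90th
#' percentiles, split by response boundary. Observed RTs are trimmed first by
#' removing values beyond 3.29 SD of the cell mean; simulated RTs are not
#' trimmed. Cells with fewer than five retained observed trials at a boundary
#' are flagged and excluded from summaries.
#'
#' @param fit An `hddm_fit`.
#' @param trials Observed trials; defaults to the trials the model was
#'   fitted to.
#' @param n_sim_per_cell Simulated trials per participant-cell.
#' @param seed Integer seed for the simulation.
#' @param probs Quantile probabilities.
#' @param trim_sd Outlier trimming threshold in SD units (observed only).
#' @return A tibble of class `sret_ppc` with columns `participant_id`,
#'   `condition`, `valence`, `boundary`, `prob`, `observed`, `simulated`,
#'   `n_obs`, `flagged`.
#' @export
ppc_quantiles <- function(fit, trials = fit$trials, n_sim_per_cell = 500,
                          seed = 1L, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          trim_sd = 3.29) {
  stopifnot(inherits(fit, "hddm_fit"))
  validate_trials(trials, "ppc_quantiles")
  set.seed(seed)
  pm <- posterior_mean_vector(fit)
  par <- params_from_draw(fit, pm)
  ids <- fit$participant_ids

  cells <- trials |>
    dplyr::distinct(.data$participant_id, .data$condition, .data$valence) |>
    dplyr::arrange(.data$participant_id, .data$condition, .data$valence)

  purrr::pmap_dfr(cells, function(participant_id, condition, valence) {
    ci <- match(paste0(valence, ":", condition), ddm_cells)
    v_cell <- if (length(par$v) == 4) par$v[ci] else par$v
    z_cell <- if (length(par$z) == 4) par$z[ci] else par$z
    t_cell <- if (length(par$t) == 4) par$t[ci] else par$t
    a_i <- par$a + par$delta_a[[participant_id]]
    z_i <- z_cell + par$delta_z[[participant_id]]
    t_i <- t_cell + par$delta_t[[participant_id]]

    obs <- trials[trials$participant_id == participant_id &
                    trials$condition == condition &
                    trials$valence == valence, ]
    keep <- abs(obs$rt - mean(obs$rt)) <= trim_sd * sd(obs$rt)
    keep[is.na(keep)] <- TRUE # sd undefined for single-trial cells
    obs <- obs[keep, ]

    sim <- ddm_simulate_cpp(as.integer(n_sim_per_cell), v_cell, a_i, z_i,
                            t_i, 1e-3)
    purrr::map_dfr(c(upper = 1L, lower = 0L), function(b) {
      o <- obs$rt[obs$response == b]
      s <- sim$rt[sim$boundary == b]
      flagged <- length(o) < 5 || length(s) < 5
      tibble::tibble(
        participant_id = participant_id,
        condition = condition,
        valence = valence,
        boundary = ifelse(b == 1L, "upper", "lower"),
        prob = probs,
        observed = if (length(o) > 0) unname(quantile(o, probs)) else NA_real_,
        simulated = if (length(s) > 0) unname(quantile(s, probs)) else NA_real_,
        n_obs = length(o),
        flagged = flagged
      )
    })
  }) |>
    structure(class = c("sret_ppc", "tbl_df", "tbl", "data.frame"))
}

#' Summarize a posterior-predictive check
#'
#' Median absolute gap between observed and simulated quantiles over
#' unflagged cells, overall and per quantile probability.
#'
#' @param ppc A table from [ppc_quantiles()].
#' @return A tibble with columns `prob`, `median_abs_gap`, `n_cells`.
#' @export
ppc_summary <- function(ppc) {
  ok <- ppc[!ppc$flagged & !is.na(ppc$observed) & !is.na(ppc$simulated), ]
  ok |>
    dplyr::group_by(.data$prob) |>
    dplyr::summarise(
      median_abs_gap = stats::median(abs(.data$observed - .data$simulated)),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}
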