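#' Reaction-time distribution plot
#'
#' Mirrored RT histograms per valence: rejections plotted on the positive
#' time axis and endorsements on the negative axis, coloured by light
#' condition — the conventional display for two-choice RT data.
#'
#' @param trials Trials tibble.
#' @param binwidth Histogram bin width in seconds.
#' @return A ggplot object.
#' @export
plot_rt_distributions <- function(trials, binwidth = 0.1) {
  validate_trials(trials, "plot_rt_distributions")
  d <- trials |>
    dplyr::mutate(signed_rt = ifelse(.data$response == 1L, .data$rt, -.data$rt))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_rt,
                                  fill = .data$condition)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.5, boundary = 0) +
    ggplot2::facet_wrap(~ valence) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "reaction time (s; rejections > 0, endorsements < 0)",
                  y = "trials", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Posterior densities of the drift-rate cells
#'
#' @param object An `hddm_fit` with cell-varying drift.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hddm_fit <- function(object, ...) {
  pars <- grep("^v\\[", colnames(object$draws[[1]]), value = TRUE)
  if (length(pars) == 0) pars <- "v"
  d <- posterior_draws(object, pars) |>
    tidyr::separate_wider_regex(
      "parameter",
      patterns = c("v\\[?", valence = "[a-z]*", ":?",
                   condition = "[a-z_]*", "\\]?"),
      too_few = "align_start")
  d$valence[d$valence == ""] <- "shared"
  d$condition[d$condition == ""] <- "shared"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, colour = .data$condition,
                                  linetype = .data$valence)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "drift rate v", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Observed versus simulated RT quantiles
#'
#' @param object A table from [ppc_quantiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sret_ppc <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!d$flagged & !is.na(d$observed) & !is.na(d$simulated), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$simulated,
                                  colour = factor(.data$prob))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_grid(valence ~ condition) +
    ggplot2::labs(x = "observed RT quantile (s)",
                  y = "simulated RT quantile (s)", colour = "percentile") +
    ggplot2::theme_minimal()
}

#' Simulated decision paths by condition
#'
#' Draws evidence-accumulation paths for the negative-word drift under both
#' light conditions, from the group-level posterior means of a fitted model
#' (or any two parameter sets).
#'
#' @param params_enriched,params_depleted [ddm_params()] for the two
#'   conditions.
#' @param n_paths Paths per condition.
#' @param seed Integer seed.
#' @return A ggplot object.
#' @export
plot_ddm_paths <- function(params_enriched, params_depleted, n_paths = 5,
                           seed = 1L) {
  set.seed(seed)
  d <- dplyr::bind_rows(
    dplyr::mutate(ddm_simulate_paths(params_enriched, n_paths, seed = NULL),
                  condition = "blue_enriched"),
    dplyr::mutate(ddm_simulate_paths(params_depleted, n_paths, seed = NULL),
                  condition = "blue_depleted")
  )
  a_max <- max(params_enriched$a, params_depleted$a)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$evidence,
                                  group = interaction(.data$condition,
                                                      .data$path_id),
                                  colour = .data$condition)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(0, a_max), linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "evidence",
                  colour = "condition") +
    ggplot2::theme_minimal()
}
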