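# rebuild a likelihood-parameter list from a named draw vector (or posterior
# means) in the fit's parameter layout
params_from_draw <- function(fit, x) {
  nm <- names(x)
  pick <- function(base) {
    cellnames <- paste0(base, "[", ddm_cells, "]")
    if (all(cellnames %in% nm)) unname(x[cellnames]) else unname(x[base])
  }
  ids <- fit$participant_ids
  list(
    v = pick("v"),
    a = unname(x["a"]),
    z = pick("z"),
    t = pick("t"),
    delta_a = setNames(unname(x[paste0("delta_a[", ids, "]")]), ids),
    delta_z = setNames(unname(x[paste0("delta_z[", ids, "]")]), ids),
    delta_t = setNames(unname(x[paste0("delta_t[", ids, "]")]), ids)
  )
}

posterior_mean_vector <- function(fit) {
  mats <- fit$draws
  cm <- Reduce(`+`, lapply(mats, colMeans)) / length(mats)
  cm
}

#' Deviance information criterion of a fitted variant
#'
#' `DIC = Dbar + pD`, where `Dbar` is the posterior mean deviance (deviance
#' tracked at every retained draw) and the effective number of parameters is
#' `pD = Dbar - D(posterior mean)` (Spiegelhalter's definition). Lower DIC
#' indicates the better fit after the complexity penalty.
#'
#' @param fit An `hddm_fit`.
#' @param trials Trials to evaluate the plug-in deviance on; defaults to the
#'   trials the model was fitted to.
#' @return A list with elements `dic`, `pD`, `dbar`, `d_at_mean`.
#' @export
compute_dic <- function(fit, trials = fit$trials) {
  stopifnot(inherits(fit, "hddm_fit"))
  dbar <- mean(unlist(fit$deviance, use.names = FALSE))
  pm <- posterior_mean_vector(fit)
  d_hat <- -2 * hddm_log_likelihood(trials, params_from_draw(fit, pm))
  pD <- dbar - d_hat
  list(dic = dbar + pD, pD = pD, dbar = dbar, d_at_mean = d_hat)
}

#' Fit and rank competing model variants by DIC
#'
#' Fits each candidate variant to the same trials and ranks them by DIC
#' (ascending; lower is better), reporting the DIC difference relative to the
#' null variant when it is among the candidates. Fits whose maximum R-hat
#' exceeds the threshold are flagged as non-converged rather than silently
#' ranked.
#'
#' @param trials Trials tibble.
#' @param specs List of [ddm_model_spec()] objects (>= 1).
#' @param settings An [mcmc_settings()].
#' @param priors An [hddm_priors()].
#' @param rhat_threshold Convergence flag threshold (default 1.1).
#' @param keep_fits Return the fitted objects in an attribute?
#' @return A tibble ranked by DIC with columns `variant`, `dic`, `pD`,
#'   `delta_dic_null`, `max_rhat`, `converged`, `rank`.
#' @export
select_best_model <- function(trials, specs,
                              settings = mcmc_settings(6000, 1000, 5, 3,
                                                       seed = 1L),
                              priors = hddm_priors(),
                              rhat_threshold = 1.1,
                              keep_fits = FALSE) {
  stopifnot(is.list(specs), length(specs) >= 1)
  fits <- purrr::map(specs, function(sp)
    fit_hddm(trials, sp, settings = settings, priors = priors))
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      variant = spec_label(f$spec),
      dic = f$dic,
      pD = f$pD,
      max_rhat = if (is.null(f$rhat)) NA_real_ else max(f$rhat),
      converged = is.null(f$rhat) || max(f$rhat) < rhat_threshold
    )
  })
  null_dic <- tab$dic[tab$variant == "null"]
  tab$delta_dic_null <- if (length(null_dic) == 1) tab$dic - null_dic else
    NA_real_
  tab <- dplyr::arrange(tab, .data$dic)
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c("rank", "variant", "dic", "pD", "delta_dic_null",
                 "max_rhat", "converged")]
  if (keep_fits) attr(tab, "fits") <- fits
  tab
}
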