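ddm_cells <- c("positive:blue_depleted", "positive:blue_enriched",
               "negative:blue_depleted", "negative:blue_enriched")

#' Model variant specification for the hierarchical diffusion fit
#'
#' A variant is defined by which parameters are allowed to differ across the
#' four condition-by-valence cells (cell-means coding, no intercept:
#' `parameter ~ 0 + condition:valence`). Any subset of `{v, z, t}` may vary;
#' the null variant (nothing varies) fits one shared value per parameter.
#' Boundary separation cannot vary: variants with cell-specific boundary
#' separation do not converge for this design and are rejected explicitly.
#'
#' @param varying Character vector, subset of `c("v", "z", "t")`.
#' @return An object of class `ddm_model_spec`.
#' @examples
#' ddm_model_spec("v")            # best-fitting variant
#' ddm_model_spec(character(0))   # null variant
#' @export
ddm_model_spec <- function(varying = "v") {
  varying <- as.character(varying)
  if ("a" %in% varying) {
    stop(paste("boundary separation `a` cannot vary by cell: such variants",
               "consistently fail to converge and are not supported"),
         call. = FALSE)
  }
  bad <- setdiff(varying, c("v", "z", "t"))
  if (length(bad) > 0) {
    stop("unknown varying parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(varying = sort(unique(varying))), class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  lab <- if (length(x$varying) == 0) "null (nothing varies)" else
    paste(x$varying, collapse = "*")
  cat("<ddm_model_spec>", lab, "\n")
  invisible(x)
}

spec_label <- function(spec) {
  if (length(spec$varying) == 0) "null" else paste(spec$varying, collapse = "*")
}

#' Expand a model spec into its group-level parameter map
#'
#' Lists the free group-level coefficients implied by a variant: four cell
#' coefficients for each varying parameter, a single shared coefficient for
#' each non-varying one, and the shared boundary separation.
#'
#' @param spec A [ddm_model_spec()].
#' @return A tibble with columns `parameter`, `cell` (`NA` for shared terms)
#'   and `name` (the sampler's parameter label).
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  rows <- purrr::map_dfr(c("v", "a", "z", "t"), function(p) {
    if (p %in% spec$varying) {
      tibble::tibble(parameter = p, cell = ddm_cells,
                     name = paste0(p, "[", ddm_cells, "]"))
    } else {
      tibble::tibble(parameter = p, cell = NA_character_, name = p)
    }
  })
  rows
}

#' MCMC settings
#'
#' Defaults mirror the reported estimation protocol: 30,000 draws per chain,
#' the first 5,000 discarded as burn-in, and every 10th retained to curb
#' autocorrelation. The scaled-down desk profile used throughout this
#' package's examples is 6,000/1,000/5.
#'
#' @param n_samples Total MCMC iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_samples = 30000, burn_in = 5000, thin = 10,
                          n_chains = 3, seed = 1L) {
  stopifnot(burn_in < n_samples, thin >= 1, n_chains >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Prior specification for the hierarchical fit
#'
#' Weakly informative priors constraining parameters to plausible ranges:
#' drift cells Normal(0, 2^2); group boundary separation Normal(1.5, 0.75^2)
#' truncated to (0.3, 4); group starting point logit-Normal(0, 0.5^2); group
#' non-decision time Normal(0.4, 0.3^2) truncated below at 0.05 and above at
#' the largest per-participant minimum RT (each participant's effective
#' non-decision time is separately capped by that participant's own minimum
#' RT); hierarchical SDs Half-Normal(0.3).
#'
#' @param v_mean,v_sd Drift-cell prior moments.
#' @param a_mean,a_sd,a_lower,a_upper Boundary-separation prior.
#' @param z_logit_sd SD of the logit-scale starting-point prior.
#' @param t_mean,t_sd,t_lower Non-decision-time prior (upper bound is the
#'   minimum observed RT, set at fit time).
#' @param sigma_scale Half-normal scale of the hierarchical SDs.
#' @return An object of class `hddm_priors`.
#' @export
hddm_priors <- function(v_mean = 0, v_sd = 2,
                        a_mean = 1.5, a_sd = 0.75, a_lower = 0.3, a_upper = 4,
                        z_logit_sd = 0.5,
                        t_mean = 0.4, t_sd = 0.3, t_lower = 0.05,
                        sigma_scale = 0.3) {
  structure(list(v_mean = v_mean, v_sd = v_sd,
                 a_mean = a_mean, a_sd = a_sd,
                 a_lower = a_lower, a_upper = a_upper,
                 z_logit_sd = z_logit_sd,
                 t_mean = t_mean, t_sd = t_sd, t_lower = t_lower,
                 sigma_scale = sigma_scale),
            class = "hddm_priors")
}
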