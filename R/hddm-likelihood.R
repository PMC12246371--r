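# internal: index trials against the four condition-by-valence cells
trial_cells <- function(trials) {
  match(paste0(trials$valence, ":", trials$condition), ddm_cells)
}

# expand a group-level value (length 1 shared, or length 4 by cell) per trial
expand_cell <- function(x, cell_idx) {
  if (length(x) == 1) rep(x, length(cell_idx)) else x[cell_idx]
}

#' Joint log likelihood of trials under the hierarchical diffusion model
#'
#' Sums the Wiener first-passage log density over trials, with `response = 1`
#' (reject) mapped to the upper boundary. Group-level parameters may be
#' shared (length 1) or cell-specific (length 4, ordered as
#' `positive:blue_depleted`, `positive:blue_enriched`,
#' `negative:blue_depleted`, `negative:blue_enriched`); participant offsets,
#' if supplied, are added to boundary separation, starting point, and
#' non-decision time per participant. Any trial with zero density (e.g.
#' `rt <= t0`) makes the result `-Inf`.
#'
#' @param trials Trials tibble (schema of [simulate_sret()]).
#' @param params List with elements `v`, `a`, `z`, `t` (each length 1 or 4 as
#'   above, `a` always length 1) and optionally `delta_a`, `delta_z`,
#'   `delta_t` (named by `participant_id`).
#' @return The scalar log likelihood.
#' @export
hddm_log_likelihood <- function(trials, params) {
  validate_trials(trials, "hddm_log_likelihood")
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  cell <- trial_cells(trials)
  pid <- trials$participant_id
  del <- function(nm) {
    d <- params[[nm]]
    if (is.null(d)) return(rep(0, nrow(trials)))
    if (is.null(names(d))) stop(sprintf("`%s` must be named by participant", nm),
                                call. = FALSE)
    unname(d[pid])
  }
  v_tr <- expand_cell(params$v, cell)
  a_tr <- rep(params$a, length.out = 1)[1] + del("delta_a")
  z_tr <- expand_cell(params$z, cell) + del("delta_z")
  t_tr <- expand_cell(params$t, cell) + del("delta_t")
  if (any(a_tr <= 0) || any(z_tr <= 0 | z_tr >= 1) || any(t_tr < 0)) {
    return(-Inf)
  }
  wfpt_loglik_sum_cpp(trials$rt, as.integer(trials$response),
                      v_tr, a_tr, z_tr, t_tr)
}
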