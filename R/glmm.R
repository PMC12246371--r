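# Outcome: positive self-evaluation. For negative words that is rejecting the
# word (response = 1); for positive words, endorsing it (response = 0).
positive_self_evaluation <- function(trials) {
  ifelse(trials$valence == "negative", trials$response, 1L - trials$response)
}

glmm_prepare <- function(trials, valence, validate = TRUE) {
  if (validate) validate_trials(trials, "fit_sret_glmm")
  d <- trials[trials$valence == valence, , drop = FALSE]
  if (nrow(d) == 0) stop("no trials of valence ", valence, call. = FALSE)
  out <- tibble::tibble(
    outcome = positive_self_evaluation(d),
    condition = factor(d$condition, levels = c("blue_depleted", "blue_enriched")),
    rt = d$rt,
    participant = factor(d$participant_id)
  )
  if ("sex" %in% names(d)) out$sex <- factor(d$sex)
  if ("hue_aware" %in% names(d)) out$hue <- factor(d$hue_aware,
                                                  levels = c(FALSE, TRUE),
                                                  labels = c("incorrect", "correct"))
  out
}

#' Random-intercept logistic model of trial-level self-evaluation
#'
#' Fits `outcome ~ fixed terms + (1 | participant)` by maximum likelihood
#' with the random intercept integrated out by adaptive Gauss-Hermite
#' quadrature (BOBYQA optimizer). The outcome is positive self-evaluation:
#' rejecting negative words, endorsing positive words; fits are run per
#' valence. Wald 95% CIs and two-sided z p-values are reported on the
#' odds-ratio scale, along with the random-intercept variance, latent-scale
#' ICC, Nakagawa marginal/conditional R-squared, BIC and log-likelihood.
#'
#' @param trials Trials tibble ([simulate_sret()] schema; `sex`/`hue_aware`
#'   columns are needed only if those terms appear in the formula).
#' @param valence Which valence subset to analyse.
#' @param fixed_terms Right-hand-side terms, e.g. `c("condition", "rt")` or
#'   `"condition * rt"`.
#' @param quadrature_nodes Number of adaptive Gauss-Hermite nodes.
#' @return An object of class `sret_glmm`.
#' @examples
#' \donttest{
#' trials <- simulate_sret_logistic(design = study_design(n_participants = 8),
#'                                  seed = 1)
#' fit <- fit_sret_glmm(trials)
#' tidy(fit)
#' }
#' @export
fit_sret_glmm <- function(trials, valence = "negative",
                          fixed_terms = c("condition", "rt"),
                          quadrature_nodes = 15, .validate = TRUE) {
  d <- glmm_prepare(trials, valence, validate = .validate)
  if (nlevels(d$participant) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  rhs <- paste(fixed_terms, collapse = " + ")
  fml <- stats::as.formula(paste("outcome ~", rhs, "+ (1 | participant)"))
  fit <- tryCatch(
    lme4::glmer(fml, data = d, family = binomial(),
                nAGQ = quadrature_nodes,
                control = lme4::glmerControl(optimizer = "bobyqa")),
    error = function(e) stop("GLMM failed to converge: ", conditionMessage(e),
                             call. = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(msgs)) warning("GLMM convergence messages: ",
                              paste(msgs, collapse = "; "), call. = FALSE)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zval <- beta / se
  pval <- 2 * pnorm(-abs(zval))
  tau00 <- as.numeric(lme4::VarCorr(fit)$participant[1, 1])
  # fixed-effects linear predictor variance on the latent scale
  X <- stats::model.matrix(fit)
  var_f <- var(as.vector(X %*% beta))
  sigma2_resid <- pi^2 / 3
  icc <- tau00 / (tau00 + sigma2_resid)
  r2m <- var_f / (var_f + tau00 + sigma2_resid)
  r2c <- (var_f + tau00) / (var_f + tau00 + sigma2_resid)

  coefs <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(zval),
    p_value = unname(pval),
    odds_ratio = exp(unname(beta)),
    or_ci_lower = exp(unname(beta - 1.96 * se)),
    or_ci_upper = exp(unname(beta + 1.96 * se))
  )
  structure(list(
    model = fit,
    coefficients = coefs,
    tau00 = tau00,
    icc = icc,
    r2_marginal = r2m,
    r2_conditional = r2c,
    bic = BIC(fit),
    loglik = as.numeric(logLik(fit)),
    n_obs = nrow(d),
    n_participants = nlevels(d$participant),
    valence = valence,
    fixed_terms = fixed_terms,
    quadrature_nodes = quadrature_nodes
  ), class = "sret_glmm")
}

#' @export
print.sret_glmm <- function(x, ...) {
  cat(sprintf("<sret_glmm> %s words: outcome ~ %s + (1 | participant)\n",
              x$valence, paste(x$fixed_terms, collapse = " + ")))
  print(x$coefficients)
  cat(sprintf("  tau00 = %.3f, ICC = %.3f, R2m = %.3f, R2c = %.3f, BIC = %.1f\n",
              x$tau00, x$icc, x$r2_marginal, x$r2_conditional, x$bic))
  cat(sprintf("  N = %d observations, %d participants\n",
              x$n_obs, x$n_participants))
  invisible(x)
}

#' @export
tidy.sret_glmm <- function(x, ...) x$coefficients

#' @export
glance.sret_glmm <- function(x, ...) {
  tibble::tibble(
    valence = x$valence,
    tau00 = x$tau00, icc = x$icc,
    r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
    bic = x$bic, loglik = x$loglik,
    n_obs = x$n_obs, n_participants = x$n_participants
  )
}

#' Fit on a standardized dataset
#'
#' Refits the model with continuous predictors centred and scaled (binary
#' factors untouched), yielding standardized coefficients. The
#' log-likelihood is unchanged by this reparameterization.
#'
#' @inheritParams fit_sret_glmm
#' @return An object of class `sret_glmm`.
#' @export
standardize_and_fit <- function(trials, valence = "negative",
                                fixed_terms = c("condition", "rt"),
                                quadrature_nodes = 15) {
  validate_trials(trials, "standardize_and_fit")
  sub <- trials[trials$valence == valence, , drop = FALSE]
  sub$rt <- as.numeric(scale(sub$rt)) # z-scored; may be <= 0 by design
  fit_sret_glmm(sub, valence, fixed_terms, quadrature_nodes,
                .validate = FALSE)
}

#' Candidate-model comparison by BIC
#'
#' Fits the candidate set of fixed-effect structures (main effects of
#' condition and RT; their interaction; additive and interactive extensions
#' with sex and hue awareness; the three-way interaction) and ranks by BIC
#' ascending. A cluster-based BIC variant using the number of participants as
#' the effective sample size is reported alongside, since the effective
#' information for between-participant terms scales with clusters rather
#' than trials.
#'
#' @param trials Trials tibble including `sex` and `hue_aware` columns.
#' @param valence Valence subset.
#' @param candidates Named list of fixed-term vectors; the default mirrors
#'   the main-effects / interaction / three-way candidate set.
#' @param quadrature_nodes Gauss-Hermite nodes per fit.
#' @return A tibble ranked by BIC with columns `rank`, `model`, `bic`,
#'   `bic_cluster`, `loglik`, `df`, `converged`.
#' @export
candidate_model_table <- function(trials, valence = "negative",
                                  candidates = NULL, quadrature_nodes = 15) {
  if (is.null(candidates)) {
    candidates <- list(
      "condition + rt" = c("condition", "rt"),
      "condition * rt" = "condition * rt",
      "condition + rt + sex" = c("condition", "rt", "sex"),
      "condition + rt + hue" = c("condition", "rt", "hue"),
      "condition * sex + rt" = c("condition * sex", "rt"),
      "condition * hue + rt" = c("condition * hue", "rt"),
      "condition * sex * hue + rt" = c("condition * sex * hue", "rt")
    )
  }
  stopifnot(length(candidates) >= 1)
  rows <- purrr::imap_dfr(candidates, function(terms, label) {
    f <- tryCatch(
      withCallingHandlers(
        fit_sret_glmm(trials, valence, terms, quadrature_nodes),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(f)) {
      return(tibble::tibble(model = label, bic = NA_real_,
                            bic_cluster = NA_real_, loglik = NA_real_,
                            df = NA_integer_, converged = FALSE))
    }
    df <- attr(logLik(f$model), "df")
    tibble::tibble(
      model = label,
      bic = f$bic,
      bic_cluster = -2 * f$loglik + df * log(f$n_participants),
      loglik = f$loglik,
      df = as.integer(df),
      converged = TRUE
    )
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$converged), .data$bic)
  rows$rank <- seq_len(nrow(rows))
  rows[, c("rank", "model", "bic", "bic_cluster", "loglik", "df", "converged")]
}

#' ICC and latent-scale R-squared of a fitted model
#'
#' Latent-scale intraclass correlation `tau00 / (tau00 + pi^2/3)` and the
#' Nakagawa marginal / conditional R-squared using the logistic residual
#' variance `pi^2/3`.
#'
#' @param fit An `sret_glmm`.
#' @return A list with `icc`, `r2_marginal`, `r2_conditional`.
#' @export
icc_and_r2 <- function(fit) {
  stopifnot(inherits(fit, "sret_glmm"))
  list(icc = fit$icc, r2_marginal = fit$r2_marginal,
       r2_conditional = fit$r2_conditional)
}
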