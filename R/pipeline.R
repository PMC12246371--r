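#' Analysis run configuration
#'
#' Bundles everything a full synthetic-study run needs: the design, the
#' generating truth, MCMC settings, the model variants to compare, and the
#' GLMM candidate terms. Defaults reproduce the package's reference analysis
#' at the scaled-down MCMC profile.
#'
#' @param seed Master seed for the run.
#' @param design A [study_design()].
#' @param truth A [group_truth()].
#' @param settings An [mcmc_settings()].
#' @param variants Character vector of model variants to fit and compare;
#'   each element is parsed as the `varying` set, `"null"` meaning nothing
#'   varies (e.g. `c("v", "null")`).
#' @param ppc_n_sim Simulated trials per participant-cell in the PPC.
#' @return A list of class `sret_config`.
#' @export
sret_config <- function(seed = 1L,
                        design = study_design(),
                        truth = group_truth(),
                        settings = mcmc_settings(6000, 1000, 5, 3, seed = seed),
                        variants = c("v", "null"),
                        ppc_n_sim = 500) {
  structure(list(seed = as.integer(seed), design = design, truth = truth,
                 settings = settings, variants = variants,
                 ppc_n_sim = ppc_n_sim),
            class = "sret_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Only fields present in the file override the defaults; the file mirrors
#' the [study_design()], [group_truth()] and [mcmc_settings()] fields under
#' keys `seed`, `design`, `truth`, `mcmc`, `variants`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sret_config`.
#' @export
read_sret_config <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  seed <- as.integer(raw$seed %||% 1L)
  design <- do.call(study_design, raw$design %||% list())
  truth_args <- raw$truth %||% list()
  if (!is.null(truth_args$v_mean)) truth_args$v_mean <- unlist(truth_args$v_mean)
  truth <- do.call(group_truth, truth_args)
  mc <- raw$mcmc %||% list()
  settings <- mcmc_settings(mc$n_samples %||% 6000, mc$burn_in %||% 1000,
                            mc$thin %||% 5, mc$n_chains %||% 3,
                            mc$seed %||% seed)
  sret_config(seed = seed, design = design, truth = truth,
              settings = settings,
              variants = raw$variants %||% c("v", "null"))
}

parse_variant <- function(x) {
  if (identical(x, "null")) ddm_model_spec(character(0)) else
    ddm_model_spec(strsplit(x, "")[[1]])
}

#' Run the full synthetic-study analysis
#'
#' End-to-end orchestration: simulate the dataset from the configured truth,
#' produce the descriptive table and paired t-tests, fit and rank the
#' configured diffusion-model variants by DIC, compute drift contrasts with
#' overlap inference and the posterior-predictive quantile check on the
#' best-fitting drift-varying model, and fit the trial-level logistic models
#' for both valences. All tables are written as CSV, summaries as JSON, and
#' a manifest (config, seed, package version) is written next to the
#' outputs; a run is reproducible from its manifest alone.
#'
#' @param config A [sret_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return A list of results (`trials`, `proportions`, `t_tests`,
#'   `model_table`, `fit`, `contrasts`, `ppc`, `glmm_negative`,
#'   `glmm_positive`), invisibly when writing.
#' @export
run_sret_study <- function(config = sret_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sret_config"))
  trials <- simulate_sret(config$truth, config$design, seed = config$seed)

  proportions <- proportion_table(trials)
  t_tests <- summary_t_tests(trials)

  specs <- lapply(config$variants, parse_variant)
  model_table <- select_best_model(trials, specs, settings = config$settings,
                                   keep_fits = TRUE)
  fits <- attr(model_table, "fits")
  v_idx <- which(vapply(fits, function(f) "v" %in% f$spec$varying, logical(1)))
  fit <- if (length(v_idx) > 0) fits[[v_idx[1]]] else fits[[1]]

  contrasts <- if ("v" %in% fit$spec$varying) drift_contrasts(fit) else NULL
  ppc <- ppc_quantiles(fit, n_sim_per_cell = config$ppc_n_sim,
                       seed = config$seed)

  glmm_neg <- fit_sret_glmm(trials, "negative")
  glmm_pos <- fit_sret_glmm(trials, "positive")

  res <- list(trials = trials, proportions = proportions, t_tests = t_tests,
              model_table = model_table, fit = fit, contrasts = contrasts,
              ppc = ppc, glmm_negative = glmm_neg, glmm_positive = glmm_pos)
  if (is.null(out_dir)) return(res)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trials(trials, p("trials.csv"))
  readr::write_csv(proportions, p("proportion_table.csv"))
  readr::write_csv(t_tests, p("t_tests.csv"))
  readr::write_csv(dplyr::select(model_table, -dplyr::any_of("fits")),
                   p("model_table.csv"))
  if (!is.null(contrasts)) readr::write_csv(contrasts, p("drift_contrasts.csv"))
  readr::write_csv(tibble::as_tibble(ppc), p("ppc_quantiles.csv"))
  readr::write_csv(posterior_draws(fit), p("posterior_draws.csv"))
  gp <- grep("^delta", colnames(fit$draws[[1]]), invert = TRUE, value = TRUE)
  jsonlite::write_json(list(
    posterior_summary = tidy(fit, parameters = gp),
    rhat = as.list(fit$rhat[gp]),
    dic = fit$dic, pD = fit$pD,
    glmm = list(negative = c(as.list(glance(glmm_neg)),
                             list(coefficients = tidy(glmm_neg))),
                positive = c(as.list(glance(glmm_pos)),
                             list(coefficients = tidy(glmm_pos))))
  ), p("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(sret_manifest(config), p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

sret_manifest <- function(config) {
  list(
    package = "sretddm",
    version = as.character(utils::packageVersion("sretddm")),
    seed = config$seed,
    design = unclass(config$design),
    truth = lapply(unclass(config$truth), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    mcmc = unclass(config$settings),
    variants = config$variants
  )
}

#' Reload the results of a written run
#'
#' Reads the tables a [run_sret_study()] call wrote to disk.
#'
#' @param run_dir Directory containing the run outputs.
#' @return A list with the manifest and the re-read tables.
#' @export
sret_report <- function(run_dir) {
  need <- file.path(run_dir, c("manifest.json", "trials.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("run directory incomplete; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  rd <- function(f) {
    fp <- file.path(run_dir, f)
    if (file.exists(fp)) readr::read_csv(fp, show_col_types = FALSE) else NULL
  }
  list(
    manifest = jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                   simplifyVector = TRUE),
    trials = read_trials(file.path(run_dir, "trials.csv")),
    proportions = rd("proportion_table.csv"),
    t_tests = rd("t_tests.csv"),
    model_table = rd("model_table.csv"),
    contrasts = rd("drift_contrasts.csv"),
    ppc = rd("ppc_quantiles.csv"),
    summary = jsonlite::read_json(file.path(run_dir, "summary.json"),
                                  simplifyVector = TRUE)
  )
}
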