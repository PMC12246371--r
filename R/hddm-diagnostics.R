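# coerce draws input: hddm_fit or list of iteration x parameter matrices
as_chain_matrices <- function(draws) {
  if (inherits(draws, "hddm_fit")) return(draws$draws)
  if (is.matrix(draws)) return(list(draws))
  if (is.list(draws) && all(vapply(draws, is.matrix, logical(1)))) return(draws)
  stop("`draws` must be an hddm_fit or a list of chain matrices", call. = FALSE)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed per parameter from the resulting half-chains; values near 1
#' indicate between-chain and within-chain variances agree (converged
#' chains). Requires at least two chains of at least 10 draws.
#'
#' @param draws An `hddm_fit` or a list of per-chain draw matrices
#'   (iterations by parameters).
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(draws) {
  ch <- as_chain_matrices(draws)
  if (length(ch) < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (any(vapply(ch, nrow, integer(1)) < 10)) {
    stop("R-hat needs at least 10 draws per chain", call. = FALSE)
  }
  halves <- list()
  for (m in ch) {
    h <- nrow(m) %/% 2L
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1L):(2L * h), , drop = FALSE]))
  }
  n_h <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(ch[[1]])))
  vars <- vapply(halves, function(m) apply(m, 2, var), numeric(ncol(ch[[1]])))
  if (is.null(dim(means))) { # single-parameter edge case
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- n_h * apply(means, 1, var)
  var_plus <- (n_h - 1) / n_h * W + B / n_h
  rhat <- sqrt(var_plus / W)
  rhat[W == 0] <- 1
  setNames(rhat, colnames(ch[[1]]))
}

#' Within-chain autocorrelation profiles
#'
#' Normalized autocorrelation (lag 0 equals 1) of each parameter's retained
#' draws, per chain. Rapid decay indicates well-thinned, well-mixing chains.
#'
#' @param draws An `hddm_fit`, a list of chain matrices, or a numeric vector.
#' @param max_lag Largest lag to report.
#' @param parameters Optional parameter subset.
#' @return A tibble with columns `parameter`, `chain`, `lag`, `acf`.
#' @export
mcmc_autocorrelation <- function(draws, max_lag = 20, parameters = NULL) {
  if (is.numeric(draws) && is.null(dim(draws))) {
    draws <- list(matrix(draws, ncol = 1, dimnames = list(NULL, "x")))
  }
  ch <- as_chain_matrices(draws)
  purrr::imap_dfr(ch, function(m, ci) {
    keep <- if (is.null(parameters)) colnames(m) else
      intersect(parameters, colnames(m))
    purrr::map_dfr(keep, function(p) {
      a <- acf(m[, p], lag.max = max_lag, plot = FALSE, demean = TRUE)
      tibble::tibble(parameter = p, chain = as.integer(ci),
                     lag = as.integer(a$lag[, 1, 1]), acf = a$acf[, 1, 1])
    })
  })
}
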