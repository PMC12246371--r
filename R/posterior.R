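#' Overlap between two posterior distributions
#'
#' Computes the overlap coefficient `OVL = integral of min(f_a, f_b)` from
#' Gaussian kernel density estimates (Silverman bandwidth) of the two draw
#' sets, evaluated on a shared 512-point grid spanning both samples. A
#' contrast is flagged significant when less than 5% of the posterior
#' probability mass overlaps. The directional probability
#' `P(a - b > 0)` (from pooled draws) is reported as an auxiliary summary.
#'
#' @param draws_a,draws_b Numeric vectors of posterior draws.
#' @param threshold Significance threshold on the overlap mass.
#' @return A list of class `overlap_result` with `overlap_mass`,
#'   `significant`, `direction` (sign of the posterior-mean difference), and
#'   `p_a_greater`.
#' @examples
#' posterior_overlap(rnorm(2000, 0, 1), rnorm(2000, 2, 1))
#' @export
posterior_overlap <- function(draws_a, draws_b, threshold = 0.05) {
  stopifnot(is.numeric(draws_a), is.numeric(draws_b),
            length(draws_a) > 1, length(draws_b) > 1)
  if (sd(draws_a) == 0 || sd(draws_b) == 0) {
    stop("degenerate (constant) draws: overlap is undefined", call. = FALSE)
  }
  bw_a <- stats::bw.nrd0(draws_a)
  bw_b <- stats::bw.nrd0(draws_b)
  lo <- min(draws_a, draws_b) - 3 * max(bw_a, bw_b)
  hi <- max(draws_a, draws_b) + 3 * max(bw_a, bw_b)
  fa <- density(draws_a, bw = bw_a, from = lo, to = hi, n = 512)
  fb <- density(draws_b, bw = bw_b, from = lo, to = hi, n = 512)
  dx <- fa$x[2] - fa$x[1]
  ovl <- sum(pmin(fa$y, fb$y)) * dx
  ovl <- min(max(ovl, 0), 1)
  na <- length(draws_a); nb <- length(draws_b)
  p_gt <- if (na == nb) mean(draws_a - draws_b > 0) else
    mean(outer(sample(draws_a, min(na, 2000)), sample(draws_b, min(nb, 2000)),
               `-`) > 0)
  structure(list(
    overlap_mass = ovl,
    significant = ovl < threshold,
    direction = sign(mean(draws_a) - mean(draws_b)),
    p_a_greater = p_gt
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> overlap = %.3f (%ssignificant at <5%%), direction %s, P(a>b) = %.3f\n",
              x$overlap_mass, if (x$significant) "" else "not ",
              ifelse(x$direction >= 0, "+", "-"), x$p_a_greater))
  invisible(x)
}

#' Summarize posterior draws
#'
#' Mean, SD and central 95% credible interval per parameter.
#'
#' @param draws A tidy draws tibble (columns `parameter`, `value`), a named
#'   list of numeric vectors, or a single numeric vector.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`.
#' @export
summarize_posterior <- function(draws) {
  if (is.numeric(draws) && is.null(dim(draws))) {
    draws <- tibble::tibble(parameter = "value", value = draws)
  } else if (is.list(draws) && !is.data.frame(draws)) {
    draws <- purrr::imap_dfr(draws, ~ tibble::tibble(parameter = .y,
                                                     value = .x))
  }
  stopifnot(is.data.frame(draws), all(c("parameter", "value") %in% names(draws)))
  if (nrow(draws) == 0) stop("no draws to summarize", call. = FALSE)
  draws |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      ci_lower = unname(quantile(.data$value, 0.025)),
      ci_upper = unname(quantile(.data$value, 0.975)),
      .groups = "drop"
    )
}

#' Drift-rate contrasts with overlap inference
#'
#' For a drift-varying fit: the light-condition contrast within each valence
#' (enriched vs depleted), and the speed comparison of negative-word versus
#' positive-word drift magnitudes within each condition (negative drifts are
#' rejection-directed and positive-word drifts endorsement-directed, so the
#' magnitude comparison uses `|v|`).
#'
#' @param fit An `hddm_fit` of a variant in which `v` varies.
#' @return A tibble with columns `contrast`, `mean_a`, `mean_b`,
#'   `difference`, `overlap_mass`, `significant`, `direction`,
#'   `p_a_greater`.
#' @export
drift_contrasts <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (!"v" %in% fit$spec$varying) {
    stop("drift contrasts need a fit in which `v` varies by cell", call. = FALSE)
  }
  v <- lapply(ddm_cells, function(cl) pooled_parameter(fit, paste0("v[", cl, "]")))
  names(v) <- ddm_cells
  pairs <- list(
    list(name = "v negative: enriched vs depleted",
         a = v[["negative:blue_enriched"]], b = v[["negative:blue_depleted"]]),
    list(name = "v positive: enriched vs depleted",
         a = v[["positive:blue_enriched"]], b = v[["positive:blue_depleted"]]),
    list(name = "|v| negative vs positive (enriched)",
         a = abs(v[["negative:blue_enriched"]]),
         b = abs(v[["positive:blue_enriched"]])),
    list(name = "|v| negative vs positive (depleted)",
         a = abs(v[["negative:blue_depleted"]]),
         b = abs(v[["positive:blue_depleted"]]))
  )
  purrr::map_dfr(pairs, function(p) {
    ov <- posterior_overlap(p$a, p$b)
    tibble::tibble(
      contrast = p$name,
      mean_a = mean(p$a), mean_b = mean(p$b),
      difference = mean(p$a) - mean(p$b),
      overlap_mass = ov$overlap_mass,
      significant = ov$significant,
      direction = ov$direction,
      p_a_greater = ov$p_a_greater
    )
  })
}
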