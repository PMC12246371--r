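# round half-up to `digits` decimals (base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Descriptive response-type table
#'
#' Counts, percentages (one decimal, half-up) and RT mean (SD) per
#' condition-by-valence-by-response cell. Within each condition-by-valence
#' cell the counts sum to the cell total; percentages are computed on exact
#' counts before rounding.
#'
#' @param trials Trials tibble.
#' @return A tibble with columns `condition`, `valence`, `response_type`
#'   (`endorse`/`reject`), `n_trials`, `percent`, `rt_mean`, `rt_sd`.
#' @export
proportion_table <- function(trials) {
  validate_trials(trials, "proportion_table")
  full <- tidyr::expand_grid(
    condition = c("blue_enriched", "blue_depleted"),
    valence = c("negative", "positive"),
    response_type = c("endorse", "reject")
  )
  tab <- trials |>
    dplyr::mutate(response_type = ifelse(.data$response == 1L, "reject",
                                         "endorse")) |>
    dplyr::group_by(.data$condition, .data$valence, .data$response_type) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      rt_mean = mean(.data$rt),
      rt_sd = sd(.data$rt),
      .groups = "drop"
    )
  full |>
    dplyr::left_join(tab, by = c("condition", "valence", "response_type")) |>
    dplyr::mutate(n_trials = dplyr::coalesce(.data$n_trials, 0L)) |>
    dplyr::group_by(.data$condition, .data$valence) |>
    dplyr::mutate(
      percent = round_half_up(
        100 * .data$n_trials / max(sum(.data$n_trials), 1L), 1)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("condition", "valence", "response_type", "n_trials",
                  "percent", "rt_mean", "rt_sd")
}

#' Per-participant response proportions
#'
#' The proportion of trials of the given valence answered with the given
#' response type, per participant and condition — the quantities compared
#' between light conditions by the paired one-tailed t-tests.
#'
#' @param trials Trials tibble.
#' @param valence `"positive"` or `"negative"`.
#' @param response_type `"endorse"` or `"reject"`.
#' @return A tibble with columns `participant_id`, `condition`, `n_trials`,
#'   `proportion`, and a logical `complete` flag per participant marking
#'   participants observed under both conditions.
#' @export
per_participant_proportions <- function(trials, valence,
                                        response_type = c("reject", "endorse")) {
  validate_trials(trials, "per_participant_proportions")
  response_type <- match.arg(response_type)
  target <- if (response_type == "reject") 1L else 0L
  d <- trials[trials$valence == valence, , drop = FALSE]
  if (nrow(d) == 0) stop("no trials of valence ", valence, call. = FALSE)
  out <- d |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      proportion = mean(.data$response == target),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(complete = dplyr::n_distinct(.data$condition) == 2) |>
    dplyr::ungroup()
  out
}

#' Paired one-tailed t-test
#'
#' Paired t statistic with `df = n - 1` and a one-tailed p-value in the
#' stated direction.
#'
#' @param x,y Equal-length paired numeric vectors (n >= 2).
#' @param direction `"greater"` tests x > y, `"less"` tests x < y.
#' @return A tibble with columns `t`, `df`, `p_value`, `mean_difference`,
#'   `direction`.
#' @export
paired_t_one_tailed <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must be paired (equal length)",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) {
    stop("zero variance of paired differences: t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = direction)
  tibble::tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_difference = mean(d),
    direction = direction
  )
}

#' Condition comparison of response proportions
#'
#' Convenience wrapper running the two aggregate tests: proportion of
#' negative words rejected and positive words endorsed, each compared
#' between conditions with a one-tailed paired t-test expecting the larger
#' proportion under blue-enriched light.
#'
#' @param trials Trials tibble.
#' @return A tibble with one row per test.
#' @export
summary_t_tests <- function(trials) {
  run_one <- function(valence, response_type) {
    p <- per_participant_proportions(trials, valence, response_type)
    p <- p[p$complete, ]
    w <- tidyr::pivot_wider(p[, c("participant_id", "condition", "proportion")],
                            names_from = "condition",
                            values_from = "proportion")
    res <- paired_t_one_tailed(w$blue_enriched, w$blue_depleted, "greater")
    dplyr::bind_cols(
      tibble::tibble(test = paste(response_type, valence, "words"),
                     n_participants = nrow(w)),
      res
    )
  }
  dplyr::bind_rows(
    run_one("negative", "reject"),
    run_one("positive", "endorse")
  )
}
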