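# Packaged adjective lexicon for the self-referential encoding task. Styled on
# the standard SRET stimulus sets (26 words per valence); word identity carries
# no effect in generation, valence does.
.sret_lexicon <- list(
  positive = c(
    "good", "joyful", "gentle", "funny", "kind", "happy", "friendly", "warm",
    "capable", "honest", "caring", "bright", "loyal", "calm", "generous",
    "confident", "creative", "patient", "cheerful", "thoughtful", "strong",
    "reliable", "helpful", "lively", "graceful", "optimistic"
  ),
  negative = c(
    "terrible", "alone", "dumb", "disloyal", "useless", "hopeless", "weak",
    "boring", "lazy", "selfish", "bitter", "gloomy", "clumsy", "foolish",
    "unwanted", "worthless", "cold", "careless", "anxious", "miserable",
    "helpless", "inferior", "dull", "awkward", "unlovable", "pathetic"
  )
)

#' Study design for a two-session light-exposure SRET experiment
#'
#' Describes the within-subject design: each participant completes the task in
#' two sessions, once under blue-enriched and once under blue-depleted light,
#' with condition order counterbalanced across participants. A session shows
#' `words_per_valence` positive and `words_per_valence` negative adjectives in
#' each of `n_blocks` blocks (156 trials per session at defaults). A fixed
#' fraction of participants is flagged as able to tell the two hues apart.
#'
#' @param n_participants Number of analysed participants (default 33).
#' @param words_per_valence Adjectives per valence (default 26).
#' @param n_blocks Blocks per session (default 3).
#' @param n_sessions Sessions per participant (default 2; must be 2 for the
#'   counterbalanced two-condition design, 1 for single-session subsets).
#' @param hue_aware_rate Probability a participant correctly identifies the
#'   hue difference between sessions (default 0.26).
#' @return An object of class `sret_design`.
#' @examples
#' d <- study_design()
#' d$trials_per_session # 156
#' @export
study_design <- function(n_participants = 33, words_per_valence = 26,
                         n_blocks = 3, n_sessions = 2, hue_aware_rate = 0.26) {
  stopifnot(n_participants >= 1, words_per_valence >= 1, n_blocks >= 1,
            n_sessions %in% c(1, 2),
            hue_aware_rate >= 0, hue_aware_rate <= 1)
  structure(list(
    n_participants = as.integer(n_participants),
    words_per_valence = as.integer(words_per_valence),
    n_blocks = as.integer(n_blocks),
    n_sessions = as.integer(n_sessions),
    conditions = c("blue_enriched", "blue_depleted"),
    counterbalanced = TRUE,
    hue_aware_rate = hue_aware_rate,
    trials_per_session = as.integer(2 * words_per_valence * n_blocks)
  ), class = "sret_design")
}

#' @export
print.sret_design <- function(x, ...) {
  cat(sprintf(
    "<sret_design> %d participants, %d sessions x %d trials (%d words/valence x %d blocks x 2)\n",
    x$n_participants, x$n_sessions, x$trials_per_session,
    x$words_per_valence, x$n_blocks))
  invisible(x)
}

#' Group-level generating truth for the hierarchical diffusion model
#'
#' Group means of the diffusion parameters, one drift rate per
#' condition-by-valence cell, plus between-participant standard deviations.
#' Defaults place the drift cells at the reported best-fit group posterior
#' means (-0.73 and -0.71 for positive words under depleted/enriched light;
#' 1.13 and 1.36 for negative words) with shared a = 1.42, z = 0.49,
#' t0 = 0.46. Between-participant SDs are not reported for this design and
#' default to plausible magnitudes relative to those means; they are
#' configurable.
#'
#' @param v_mean Named numeric of length 4, names
#'   `positive:blue_depleted`, `positive:blue_enriched`,
#'   `negative:blue_depleted`, `negative:blue_enriched`.
#' @param v_sd_between Between-participant SD of each drift cell.
#' @param a_mean,a_sd Boundary separation mean (> 0) and SD.
#' @param z_mean,z_sd Starting point mean (in (0, 1)) and SD.
#' @param t_mean,t_sd Non-decision time mean (seconds, >= 0) and SD.
#' @return An object of class `sret_truth`.
#' @export
group_truth <- function(v_mean = c("positive:blue_depleted" = -0.73,
                                   "positive:blue_enriched" = -0.71,
                                   "negative:blue_depleted" = 1.13,
                                   "negative:blue_enriched" = 1.36),
                        v_sd_between = 0.25,
                        a_mean = 1.42, a_sd = 0.20,
                        z_mean = 0.49, z_sd = 0.04,
                        t_mean = 0.46, t_sd = 0.05) {
  cells <- c("positive:blue_depleted", "positive:blue_enriched",
             "negative:blue_depleted", "negative:blue_enriched")
  if (is.null(names(v_mean))) names(v_mean) <- cells
  if (!setequal(names(v_mean), cells)) {
    stop("`v_mean` must be named with the four condition-by-valence cells",
         call. = FALSE)
  }
  if (!(a_mean > 0)) stop("`a_mean` must be > 0", call. = FALSE)
  if (!(z_mean > 0 && z_mean < 1)) stop("`z_mean` must lie in (0, 1)", call. = FALSE)
  if (!(t_mean >= 0)) stop("`t_mean` must be >= 0", call. = FALSE)
  if (any(c(v_sd_between, a_sd, z_sd, t_sd) < 0)) {
    stop("between-participant SDs must be >= 0", call. = FALSE)
  }
  structure(list(
    v_mean = v_mean[cells], v_sd_between = v_sd_between,
    a_mean = a_mean, a_sd = a_sd,
    z_mean = z_mean, z_sd = z_sd,
    t_mean = t_mean, t_sd = t_sd
  ), class = "sret_truth")
}

#' @export
print.sret_truth <- function(x, ...) {
  cat("<sret_truth>\n  drift cells:\n")
  for (nm in names(x$v_mean)) cat(sprintf("    %-26s %6.2f\n", nm, x$v_mean[[nm]]))
  cat(sprintf("  a = %.2f (sd %.2f), z = %.2f (sd %.2f), t0 = %.2f (sd %.2f), v sd %.2f\n",
              x$a_mean, x$a_sd, x$z_mean, x$z_sd, x$t_mean, x$t_sd,
              x$v_sd_between))
  invisible(x)
}

#' Word lists for a design
#'
#' Returns the positive and negative adjective lists used for the task,
#' drawn deterministically from the packaged lexicon.
#'
#' @param design A [study_design()].
#' @return A tibble with columns `word` and `valence`.
#' @export
generate_word_lists <- function(design = study_design()) {
  stopifnot(inherits(design, "sret_design"))
  k <- design$words_per_valence
  if (k > length(.sret_lexicon$positive)) {
    # extend deterministically with numbered variants beyond the lexicon
    ext <- function(base) c(base, paste0(base[1], "_", seq_len(k - length(base))))
    pos <- ext(.sret_lexicon$positive)[seq_len(k)]
    neg <- ext(.sret_lexicon$negative)[seq_len(k)]
  } else {
    pos <- .sret_lexicon$positive[seq_len(k)]
    neg <- .sret_lexicon$negative[seq_len(k)]
  }
  tibble::tibble(
    word = c(pos, neg),
    valence = rep(c("positive", "negative"), each = k)
  )
}

# mean of a normal truncated to (lo, hi); used as the sampling oracle target
truncnorm_mean <- function(mu, sd, lo, hi) {
  if (sd == 0) return(mu)
  al <- (lo - mu) / sd; be <- (hi - mu) / sd
  mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

# draw from a normal truncated to (lo, hi) by resampling (avoids boundary atoms)
rtrunc_norm <- function(n, mu, sd, lo, hi) {
  if (sd == 0) return(rep(mu, n))
  out <- rnorm(n, mu, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

#' Draw participant-level parameters from the hierarchy
#'
#' Samples each participant's drift rates (one per condition-by-valence cell),
#' boundary separation, starting point, and non-decision time from normal
#' distributions centred on the group means, truncated by resampling to
#' a > 0, z in (0.05, 0.95), t0 in (0.1, 1.0). Hue awareness is Bernoulli at
#' the design rate; sex is assigned proportionally to a 22:13 female:male
#' split.
#'
#' @param truth A [group_truth()].
#' @param design A [study_design()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant: `participant_id`, the four
#'   drift columns `v_positive_blue_depleted` ... `v_negative_blue_enriched`,
#'   `a`, `z`, `t0`, `hue_aware`, `sex`.
#' @export
sample_participants <- function(truth = group_truth(), design = study_design(),
                                seed = NULL) {
  stopifnot(inherits(truth, "sret_truth"), inherits(design, "sret_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_participants
  vs <- purrr::map(truth$v_mean,
                   ~ rnorm(n, .x, truth$v_sd_between))
  names(vs) <- paste0("v_", gsub(":", "_", names(truth$v_mean)))
  n_female <- round(n * 22 / 35)
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    !!!vs,
    a = rtrunc_norm(n, truth$a_mean, truth$a_sd, 0, Inf),
    z = rtrunc_norm(n, truth$z_mean, truth$z_sd, 0.05, 0.95),
    t0 = rtrunc_norm(n, truth$t_mean, truth$t_sd, 0.1, 1.0),
    hue_aware = runif(n) < design$hue_aware_rate,
    sex = rep(c("female", "male"), c(n_female, n - n_female))
  )
}

# balanced condition-order assignment: enriched-first for half the sample
# (|#enriched-first - #depleted-first| <= 1), order shuffled
condition_orders <- function(n) {
  first <- rep(c("blue_enriched", "blue_depleted"), length.out = n)
  sample(first)
}
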