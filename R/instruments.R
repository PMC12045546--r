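#' Epsilon-tolerant midranks of a preference vector
#'
#' Ranks in descending order of value (1 = most preferred); values whose
#' consecutive sorted gaps are within `epsilon` form a tie cluster and share
#' their midrank.
#' @keywords internal
midrank_desc <- function(values, epsilon = 0) {
  k <- length(values)
  ord <- order(-values, seq_len(k))
  sorted <- values[ord]
  cluster <- cumsum(c(1, diff(sorted) < -epsilon))
  pos <- seq_len(k)
  mid <- stats::ave(pos, cluster, FUN = mean)
  ranks <- numeric(k)
  ranks[ord] <- mid
  ranks
}

#' Card-ranking instrument
#'
#' Ranks the presented cards from most preferred (1) to least preferred
#' (9, or 10 with the death card), by descending latent utility perturbed
#' by the profile's rating noise.  Cards whose perturbed utilities tie
#' within `tie_epsilon` receive midranks.  Deterministic at zero noise.
#'
#' @param profile A [latent_profile()].
#' @param deck A deck from [build_deck()].
#' @param include_death Rank the 10-card deck including death?
#' @param tie_epsilon Utility difference treated as a tie.
#' @return A list of class `ranking_record`: `participant_id`,
#'   `include_death`, `rank` (named numeric).
#' @export
rank_cards <- function(profile, deck, include_death = FALSE,
                       tie_epsilon = 0) {
  stopifnot(inherits(profile, "latent_profile"))
  ids <- deck_state_ids(deck, include_death = include_death)
  u <- profile$utilities[ids]
  if (anyNA(u)) {
    stop("profile lacks utilities for deck state(s): ",
         paste(ids[is.na(u)], collapse = ", "), call. = FALSE)
  }
  if (profile$vas_noise_sd > 0) {
    u <- u + stats::rnorm(length(u), 0, profile$vas_noise_sd / 100)
  }
  structure(
    list(participant_id = profile$participant_id,
         include_death = include_death,
         rank = stats::setNames(midrank_desc(unname(u), tie_epsilon), ids)),
    class = "ranking_record")
}

#' Visual-analog-scale ("feeling thermometer") instrument
#'
#' Ratings are the min-max rescaling of the noisy latent utilities over the
#' presented card set to 0-100, snapped to a rounding grid.  Without the
#' death card the participant's most and least preferred cards anchor at
#' 100 and 0; adding the death card puts death in the rescaling set, which
#' compresses the reconstruction states toward 100 when death anchors the
#' bottom.  If all perturbed utilities are equal, every card is rated 50.
#'
#' @param profile A [latent_profile()].
#' @param deck A deck from [build_deck()].
#' @param include_death Rate the 10-card deck including death?
#' @param rounding Grid size: one of 0 (off), 0.5, 1, 2.5, 5.
#' @return A list of class `vas_record`: `participant_id`,
#'   `include_death`, `rating` (named numeric on 0-100).
#' @export
vas_rate <- function(profile, deck, include_death = FALSE, rounding = 2.5) {
  stopifnot(inherits(profile, "latent_profile"))
  if (!is.numeric(rounding) || length(rounding) != 1 ||
      !rounding %in% c(0, 0.5, 1, 2.5, 5)) {
    stop("rounding grid must be one of 0, 0.5, 1, 2.5, 5", call. = FALSE)
  }
  ids <- deck_state_ids(deck, include_death = include_death)
  u <- profile$utilities[ids]
  if (anyNA(u)) {
    stop("profile lacks utilities for deck state(s): ",
         paste(ids[is.na(u)], collapse = ", "), call. = FALSE)
  }
  if (profile$vas_noise_sd > 0) {
    u <- u + stats::rnorm(length(u), 0, profile$vas_noise_sd / 100)
  }
  rng <- max(u) - min(u)
  rating <- if (rng < 1e-12) {
    rep(50, length(u))
  } else {
    (u - min(u)) / rng * 100
  }
  if (rounding > 0) rating <- round(rating / rounding) * rounding
  structure(
    list(participant_id = profile$participant_id,
         include_death = include_death,
         rating = stats::setNames(unname(rating), ids)),
    class = "vas_record")
}

#' Flag an unexpected card ranking
#'
#' A ranking is unexpected when any fair or poor reconstruction state sits
#' in the participant's top three, or any excellent state sits in the
#' bottom three of the nine-card (no-death) ranking.
#'
#' @param record A `ranking_record` produced without the death card.
#' @param deck The deck the record was produced from.
#' @return List with `flag` (logical) and `reasons` (character).
#' @export
flag_unexpected <- function(record, deck) {
  stopifnot(inherits(record, "ranking_record"))
  if (isTRUE(record$include_death)) {
    stop("unexpected rankings are defined on the 9-card (no-death) ranking",
         call. = FALSE)
  }
  states <- health_states(FALSE)
  ranks <- record$rank[states$state_id]
  n <- length(ranks)
  reasons <- character(0)
  low <- states$state_id[states$quality %in% c("fair", "poor")]
  for (s in low) {
    if (!is.na(ranks[s]) && ranks[s] <= 3) {
      reasons <- c(reasons, sprintf("%s ranked %.1f (top 3)", s, ranks[s]))
    }
  }
  high <- states$state_id[states$quality == "excellent"]
  for (s in high) {
    if (!is.na(ranks[s]) && ranks[s] >= n - 2) {
      reasons <- c(reasons, sprintf("%s ranked %.1f (bottom 3)", s, ranks[s]))
    }
  }
  list(flag = length(reasons) > 0, reasons = reasons)
}

#' Run the ranking and rating instruments over a cohort
#'
#' Applies card ranking and visual-analog rating, each with and without the
#' death card, to every participant.  Decks are case-matched to each
#' participant's BMI category and laterality.  Noise streams are derived
#' from `(seed, participant_id, instrument)`.
#'
#' @param profiles List of [latent_profile()]s.
#' @param covariates Cohort table from [sample_covariates()] (supplies the
#'   case-matching columns).
#' @param config A [generator_config()] (rounding grid, tie epsilon).
#' @param seed Integer seed.
#' @return List with `records`, a long tibble (`participant_id`,
#'   `instrument`, `include_death`, `state_id`, `value`) where instrument is
#'   one of `rank`, `rank_death`, `vas`, `vas_death`; and `unexpected`, a
#'   tibble of per-participant flags from [flag_unexpected()].
#' @export
collect_instruments <- function(profiles, covariates, config,
                                seed = config$rng_seed) {
  config <- validate_config(config)
  cov <- covariates[match(vapply(profiles, function(p) p$participant_id, numeric(1)),
                          covariates$participant_id), ]
  recs <- vector("list", length(profiles))
  flags <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    deck9 <- build_deck(as.character(cov$bmi_category[i]),
                        as.character(cov$laterality[i]), include_death = FALSE)
    deck10 <- build_deck(as.character(cov$bmi_category[i]),
                         as.character(cov$laterality[i]), include_death = TRUE)
    set.seed(participant_seed(seed, p$participant_id, op = 4L))
    r9 <- rank_cards(p, deck9, include_death = FALSE,
                     tie_epsilon = config$tie_epsilon)
    set.seed(participant_seed(seed, p$participant_id, op = 5L))
    r10 <- rank_cards(p, deck10, include_death = TRUE,
                      tie_epsilon = config$tie_epsilon)
    set.seed(participant_seed(seed, p$participant_id, op = 6L))
    v9 <- vas_rate(p, deck9, include_death = FALSE,
                   rounding = config$vas_rounding)
    set.seed(participant_seed(seed, p$participant_id, op = 7L))
    v10 <- vas_rate(p, deck10, include_death = TRUE,
                    rounding = config$vas_rounding)
    long <- function(x, instrument, values) {
      tibble::tibble(participant_id = p$participant_id,
                     instrument = instrument,
                     include_death = x$include_death,
                     state_id = names(values),
                     value = unname(values))
    }
    recs[[i]] <- dplyr::bind_rows(
      long(r9, "rank", r9$rank),
      long(r10, "rank_death", r10$rank),
      long(v9, "vas", v9$rating),
      long(v10, "vas_death", v10$rating))
    fl <- flag_unexpected(r9, deck9)
    flags[[i]] <- tibble::tibble(participant_id = p$participant_id,
                                 unexpected = fl$flag,
                                 reasons = paste(fl$reasons, collapse = "; "))
  }
  list(records = dplyr::bind_rows(recs),
       unexpected = dplyr::bind_rows(flags))
}
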