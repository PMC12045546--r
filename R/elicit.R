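#' Chained-gamble utility composition
#'
#' Composes the two stages of the chained standard gamble: `p1` is the
#' indifference probability of a state gambled against the respondent's best
#' and worst non-death outcomes, `p2` anchors the worst outcome against
#' death, and the death-anchored utility is
#' `u = p1 + (1 - p1) * p2`, equivalently the expected utility
#' `p1 * u(best) + (1 - p1) * u(worst)` with `u(best) = 1` and
#' `u(worst) = p2`.
#'
#' @param p1,p2 Probabilities in `[0, 1]` (vectorized, recycled).
#' @return Utility in `[p2, 1]`.
#' @examples
#' chain_utility(0.95, 0.80)  # 0.99
#' @export
chain_utility <- function(p1, p2) {
  if (!is.numeric(p1) || !is.numeric(p2) ||
      anyNA(p1) || anyNA(p2) ||
      any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    stop("p1 and p2 must be probabilities in [0, 1]", call. = FALSE)
  }
  p1 + (1 - p1) * p2
}

#' Probability-weighting function of the respondent
#'
#' One-parameter inverse-S weighting (Tversky-Kahneman form); the identity
#' when `gamma = 1`, which is the default expected-utility respondent.
#' @param p Probability vector.
#' @param gamma Weighting exponent (> 0).
#' @export
prob_weight <- function(p, gamma = 1) {
  stopifnot(gamma > 0)
  if (gamma == 1) return(p)
  p^gamma / (p^gamma + (1 - p)^gamma)^(1 / gamma)
}

#' A single gamble offer
#'
#' @param certain_state,best_state,worst_state State ids; the certain state
#'   must differ from both gamble arms.
#' @param p_best Probability of the best outcome in the gamble.
#' @return A list of class `gamble_offer`.
#' @export
gamble_offer <- function(certain_state, best_state, worst_state, p_best) {
  if (!is.numeric(p_best) || length(p_best) != 1 || is.na(p_best) ||
      p_best < 0 || p_best > 1) {
    stop("p_best must be a probability in [0, 1]", call. = FALSE)
  }
  if (certain_state %in% c(best_state, worst_state)) {
    stop("certain_state must differ from both gamble arms", call. = FALSE)
  }
  structure(list(certain_state = certain_state, best_state = best_state,
                 worst_state = worst_state, p_best = p_best),
            class = "gamble_offer")
}

#' Respondent's choice between a certainty and a gamble
#'
#' With zero choice noise the respondent takes the gamble iff its (possibly
#' probability-weighted) expected utility strictly exceeds the certain
#' state's utility; exact indifference resolves to the certainty.  With
#' positive noise the choice is logistic in the expected-utility difference
#' with temperature `choice_noise` (drawn from the current RNG stream).
#'
#' @param offer A [gamble_offer()].
#' @param profile A [latent_profile()].
#' @return `"gamble"` or `"certainty"`.
#' @export
respond <- function(offer, profile) {
  stopifnot(inherits(profile, "latent_profile"))
  u <- profile$utilities
  needed <- c(offer$certain_state, offer$best_state, offer$worst_state)
  missing <- setdiff(needed, names(u))
  if (length(missing)) {
    stop("unknown state(s) in offer: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- prob_weight(offer$p_best, profile$weighting_gamma)
  du <- w * u[[offer$best_state]] + (1 - w) * u[[offer$worst_state]] -
    u[[offer$certain_state]]
  if (profile$choice_noise <= 0) {
    if (du > 0) "gamble" else "certainty"
  } else {
    if (stats::runif(1) < stats::plogis(du / profile$choice_noise)) {
      "gamble"
    } else {
      "certainty"
    }
  }
}

#' Standard-gamble probability titration
#'
#' Offers the gamble at `p_best = 1.00, 1.00 - step, 1.00 - 2 step, ...`
#' (down to and including 0) until the respondent first selects the
#' certainty.  The indifference probability is the midpoint of the
#' bracketing interval (last gamble choice, first certainty choice).  A
#' respondent who selects the certainty at the very first offer is flagged
#' `"high"` and assigned `1 - step / 2`; one who never switches is flagged
#' `"low"` and assigned `step / 2`.
#'
#' @param profile A [latent_profile()].
#' @param certain_state,best_state,worst_state State ids of the offer.
#' @param step Probability decrement in `(0, 0.25]`.
#' @return An object of class `titration_trace`: fields `state_id`,
#'   `offers` (tibble of `p_best`, `choice`), `p_indifference`, `p_low`,
#'   `p_high`, `degenerate` (`"none"`, `"high"` or `"low"`).
#' @export
titrate <- function(profile, certain_state, best_state, worst_state,
                    step = 0.05) {
  if (!is.numeric(step) || length(step) != 1 || is.na(step) ||
      step <= 0 || step > 0.25) {
    stop("step must lie in (0, 0.25]", call. = FALSE)
  }
  ps <- round(1 - 0:ceiling(1 / step - 1e-9) * step, 10)
  ps <- pmax(ps, 0)
  if (ps[length(ps)] > 0) ps <- c(ps, 0)

  u <- profile$utilities
  needed <- c(certain_state, best_state, worst_state)
  missing <- setdiff(needed, names(u))
  if (length(missing)) {
    stop("unknown state(s) in offer: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (certain_state %in% c(best_state, worst_state)) {
    stop("certain_state must differ from both gamble arms", call. = FALSE)
  }
  ub <- u[[best_state]]; uw <- u[[worst_state]]; uc <- u[[certain_state]]
  noise <- profile$choice_noise
  gamma <- profile$weighting_gamma

  # same choice rule as respond(), inlined over the offer schedule
  n_off <- 0L
  choices <- character(length(ps))
  switched_at <- NA_real_
  for (p in ps) {
    w <- prob_weight(p, gamma)
    du <- w * ub + (1 - w) * uw - uc
    ch <- if (noise <= 0) {
      if (du > 0) "gamble" else "certainty"
    } else if (stats::runif(1) < stats::plogis(du / noise)) {
      "gamble"
    } else {
      "certainty"
    }
    n_off <- n_off + 1L
    choices[n_off] <- ch
    if (ch == "certainty") {
      switched_at <- p
      break
    }
  }
  offered <- ps[seq_len(n_off)]
  choices <- choices[seq_len(n_off)]

  if (is.na(switched_at)) {
    degenerate <- "low"
    p_low <- 0
    p_high <- step
    p_ind <- step / 2
  } else if (length(offered) == 1L) {
    degenerate <- "high"
    p_low <- 1 - step
    p_high <- 1
    p_ind <- 1 - step / 2
  } else {
    degenerate <- "none"
    p_low <- switched_at
    p_high <- offered[length(offered) - 1L]
    p_ind <- (p_low + p_high) / 2
  }

  structure(
    list(state_id = certain_state,
         best_state = best_state,
         worst_state = worst_state,
         offers = tibble::tibble(p_best = offered, choice = choices),
         p_indifference = p_ind,
         p_low = p_low,
         p_high = p_high,
         degenerate = degenerate),
    class = "titration_trace")
}

#' @export
print.titration_trace <- function(x, ...) {
  cat("<titration_trace>", x$state_id, "vs (", x$best_state, ",",
      x$worst_state, ")\n")
  cat("offers:", paste(sprintf("%.2f:%s", x$offers$p_best,
                               substr(x$offers$choice, 1, 1)),
                       collapse = " "), "\n")
  cat("p_indifference =", x$p_indifference,
      " bracket [", x$p_low, ",", x$p_high, "]",
      " degenerate:", x$degenerate, "\n")
  invisible(x)
}

#' Full chained-gamble interview of one participant
#'
#' Identifies the participant's most and least preferred non-death states
#' (noiseless comparison of latent utilities, ties broken by deck order),
#' titrates every intermediate state against that (best, worst) pair to get
#' its stage-1 indifference probability P1, anchors the least preferred
#' state against death to get P2, and composes death-anchored utilities via
#' [chain_utility()].  The best state receives utility 1 and the least
#' preferred state receives P2.
#'
#' @param profile A [latent_profile()].
#' @param deck A deck containing a death state (see [build_deck()]).
#' @param step Titration decrement.
#' @return List with `records` (tibble: `participant_id`, `state_id`, `p1`,
#'   `p2`, `utility`, `degenerate`) and `traces` (list with `stage1`, a
#'   named list of [titrate()] traces, and `stage2`, the P2 trace).
#' @export
elicit_participant <- function(profile, deck, step = 0.05) {
  stopifnot(inherits(profile, "latent_profile"))
  ids <- deck_state_ids(deck)
  if (!"death" %in% ids) {
    stop("deck must include a death state: the chained-gamble anchor is ",
         "undefined without it", call. = FALSE)
  }
  nd <- setdiff(ids, "death")
  if (length(nd) < 3) {
    stop("deck must contain at least 3 non-death states", call. = FALSE)
  }
  u <- profile$utilities[nd]
  best <- nd[which.max(u)]
  worst <- nd[which.min(u)]
  if (best == worst) worst <- nd[length(nd)]  # all-tied profile
  intermediates <- setdiff(nd, c(best, worst))

  stage1 <- lapply(intermediates, function(s) {
    titrate(profile, s, best, worst, step = step)
  })
  names(stage1) <- intermediates
  stage2 <- titrate(profile, worst, best, "death", step = step)
  p2 <- stage2$p_indifference

  p1 <- vapply(stage1, function(tr) tr$p_indifference, numeric(1))
  deg1 <- vapply(stage1, function(tr) tr$degenerate, character(1))

  p1_col <- stats::setNames(rep(NA_real_, length(nd)), nd)
  p1_col[intermediates] <- p1[intermediates]
  util <- stats::setNames(numeric(length(nd)), nd)
  util[best] <- 1
  util[worst] <- p2
  if (length(intermediates)) {
    util[intermediates] <- chain_utility(p1[intermediates], p2)
  }
  deg <- stats::setNames(rep("none", length(nd)), nd)
  deg[worst] <- stage2$degenerate
  deg[intermediates] <- deg1[intermediates]

  records <- tibble::tibble(
    participant_id = profile$participant_id,
    state_id = nd,
    p1 = unname(p1_col),
    p2 = p2,
    utility = unname(util),
    degenerate = unname(deg)
  )
  list(records = records, traces = list(stage1 = stage1, stage2 = stage2))
}

#' Run the chained-gamble interview over a cohort
#'
#' @param profiles List of [latent_profile()]s.
#' @param step Titration decrement.
#' @param seed Integer seed; each participant's choice-noise stream is
#'   derived from `(seed, participant_id)`.
#' @param keep_traces Keep every titration trace (memory-heavy)?
#' @return List with `records` (row-bound participant records) and, when
#'   requested, `traces` (a list keyed by participant).
#' @export
elicit_cohort <- function(profiles, step = 0.05, seed = 1L,
                          keep_traces = FALSE) {
  recs <- vector("list", length(profiles))
  traces <- if (keep_traces) vector("list", length(profiles)) else NULL
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    set.seed(participant_seed(seed, p$participant_id, op = 3L))
    deck <- health_states(include_death = TRUE)
    res <- elicit_participant(p, deck, step = step)
    recs[[i]] <- res$records
    if (keep_traces) traces[[i]] <- res$traces
  }
  out <- list(records = dplyr::bind_rows(recs))
  if (keep_traces) out$traces <- traces
  out
}
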