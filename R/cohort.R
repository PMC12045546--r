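#' Derive a participant-level RNG seed
#'
#' One stream per (seed, participant, operation) keeps the cohort
#' bit-stable under reordering and subsetting of participants.
#' @keywords internal
participant_seed <- function(seed, id, op) {
  s <- (abs(as.numeric(seed)) %% 1e9) + 1000003 * op + 8191 * as.numeric(id)
  as.integer(s %% 2147483646) + 1L
}

#' Sample participant covariates
#'
#' Draws one row per participant: continuous covariates from clipped
#' normals (clip bounds at the configured min/max; the pre-clip location is
#' adjusted so the post-clip mean equals the configured mean), categorical
#' covariates from the configured category probabilities.  Draws for
#' participant `i` depend only on `(seed, i)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed, defaulting to `config$rng_seed`.
#' @return A tibble with `participant_id` and one column per covariate;
#'   categorical covariates are factors with their configured level sets.
#' @export
sample_covariates <- function(config, seed = config$rng_seed) {
  config <- validate_config(config)
  n <- config$n_participants
  spec <- config$covariates
  cols <- stats::setNames(vector("list", length(spec)), names(spec))
  for (nm in names(spec)) {
    cols[[nm]] <- if (identical(spec[[nm]]$type, "continuous")) {
      numeric(n)
    } else {
      character(n)
    }
  }
  for (i in seq_len(n)) {
    set.seed(participant_seed(seed, i, op = 1L))
    for (nm in names(spec)) {
      s <- spec[[nm]]
      if (identical(s$type, "continuous")) {
        x <- if (s$sd == 0) s$mean else stats::rnorm(1, s$mu_adj, s$sd)
        cols[[nm]][i] <- min(max(x, s$min), s$max)
      } else {
        cols[[nm]][i] <- sample(s$levels, 1L, prob = s$probs)
      }
    }
  }
  for (nm in names(spec)) {
    if (identical(spec[[nm]]$type, "categorical")) {
      cols[[nm]] <- factor(cols[[nm]], levels = spec[[nm]]$levels)
    }
  }
  tibble::as_tibble(c(list(participant_id = seq_len(n)), cols))
}

#' Per-state covariate effect matrix on the latent 0-1 scale
#'
#' @return n x 9 matrix, columns in `health_states(FALSE)` order.
#' @keywords internal
effect_matrix <- function(covariates, config) {
  states <- health_states(FALSE)
  groups <- option_groups()
  n <- nrow(covariates)
  E <- matrix(0, n, nrow(states), dimnames = list(NULL, states$state_id))
  eff <- config$effects
  for (i in seq_len(nrow(eff))) {
    cov_nm <- eff$covariate[i]
    spec <- config$covariates[[cov_nm]]
    x <- covariates[[cov_nm]]
    contrib <- if (identical(spec$type, "continuous")) {
      (x - spec$mean) * eff$effect[i] / 100
    } else {
      (as.character(x) == eff$level[i]) * eff$effect[i] / 100
    }
    E[, groups[[eff$group[i]]]] <- E[, groups[[eff$group[i]]], drop = FALSE] +
      contrib
  }
  E
}

#' Order-preserving soft ceiling at 1
#'
#' Identity below the shoulder `c`; above it, values are compressed into
#' `(c, 1)` by `1 - (1 - c) * exp(-(x - c) / (1 - c))`, which is strictly
#' increasing and continuously differentiable at the shoulder.  Ceiling
#' effects therefore compress preferences instead of piling them up in a
#' tie at exactly 1.
#' @keywords internal
soft_ceiling <- function(x, shoulder = 0.99) {
  hi <- x > shoulder
  x[hi] <- 1 - (1 - shoulder) * exp(-(x[hi] - shoulder) / (1 - shoulder))
  x
}

#' A respondent's latent preference profile
#'
#' @param utilities Named numeric utilities in `[0, 1]` on a death = 0
#'   scale; a death entry of 0 is appended if absent.
#' @param choice_noise,weighting_gamma,vas_noise_sd Respondent parameters:
#'   logistic choice temperature, probability-weighting exponent (1 = none),
#'   and rating noise SD on the 0-100 scale.
#' @param participant_id Optional identifier.
#' @param latent_index Optional unclipped linear index per state (defaults
#'   to the utilities).
#' @return An object of class `latent_profile`.
#' @export
latent_profile <- function(utilities, choice_noise = 0, weighting_gamma = 1,
                           vas_noise_sd = 0, participant_id = NA_integer_,
                           latent_index = NULL) {
  if (is.null(names(utilities)) || any(!nzchar(names(utilities)))) {
    stop("utilities must be a named vector of state utilities", call. = FALSE)
  }
  if (!"death" %in% names(utilities)) {
    utilities <- c(utilities, death = 0)
  }
  if (abs(utilities[["death"]]) > 0) {
    stop("latent utility of death must be exactly 0", call. = FALSE)
  }
  if (any(utilities < 0 | utilities > 1)) {
    stop("latent utilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(choice_noise >= 0, weighting_gamma > 0, vas_noise_sd >= 0)
  if (is.null(latent_index)) latent_index <- utilities
  structure(
    list(participant_id = participant_id,
         utilities = utilities,
         latent_index = latent_index,
         choice_noise = choice_noise,
         weighting_gamma = weighting_gamma,
         vas_noise_sd = vas_noise_sd,
         unexpected = FALSE,
         equipoise = FALSE),
    class = "latent_profile")
}

#' @export
print.latent_profile <- function(x, ...) {
  cat("<latent_profile> participant", x$participant_id, "\n")
  print(round(x$utilities, 3))
  cat("choice_noise =", x$choice_noise,
      " weighting_gamma =", x$weighting_gamma,
      " vas_noise_sd =", x$vas_noise_sd, "\n")
  invisible(x)
}

#' Generate latent utility profiles for a cohort
#'
#' Each participant's latent utility for a state is the base utility of its
#' (modality, quality) cell, plus the configured covariate effects (VAS-scale
#' coefficients divided by 100), plus per-state Gaussian noise, bounded to
#' `[0, 1)` by a hard floor at 0 and a strictly increasing soft ceiling that
#' compresses values above 0.99 toward 1 without creating ties at the
#' boundary (so at most one state, the death-anchored maximum, can sit at
#' exactly 1).  With probability `equipoise_fraction` the non-excellent
#' utilities are then compressed toward their mean; with probability
#' `unexpected_rank_fraction` a random fair/poor state is promoted into the
#' participant's top three by swapping utility values (a local permutation
#' that always violates at least one within-modality quality ordering).
#' The unclipped, unperturbed linear index is kept alongside (field
#' `latent_index`) as the generating truth for effect-recovery analyses.
#'
#' @param covariates Output of [sample_covariates()].
#' @param config A [generator_config()].
#' @param seed Integer seed, defaulting to `config$rng_seed`.
#' @return A list of [latent_profile()] objects, one per participant.
#' @export
generate_latent_profiles <- function(covariates, config,
                                     seed = config$rng_seed) {
  config <- validate_config(config)
  if (!is.data.frame(covariates) || nrow(covariates) == 0) {
    stop("covariates table must be non-empty", call. = FALSE)
  }
  states <- health_states(FALSE)
  ids <- states$state_id
  base <- config$base_utilities[ids]
  E <- effect_matrix(covariates, config)
  fairpoor <- ids[states$quality %in% c("fair", "poor")]

  profiles <- vector("list", nrow(covariates))
  for (i in seq_len(nrow(covariates))) {
    pid <- covariates$participant_id[i]
    set.seed(participant_seed(seed, pid, op = 2L))
    noise <- if (config$latent_noise_sd > 0) {
      stats::rnorm(length(ids), 0, config$latent_noise_sd)
    } else {
      rep(0, length(ids))
    }
    index <- base + E[i, ] + noise
    u <- soft_ceiling(pmax(index, 0))
    equipoise <- stats::runif(1) < config$equipoise_fraction
    unexpected <- stats::runif(1) < config$unexpected_rank_fraction
    if (equipoise) {
      non_exc <- states$quality != "excellent"
      m <- mean(u[non_exc])
      u[non_exc] <- m + config$equipoise_compression * (u[non_exc] - m)
    }
    if (unexpected) {
      promote <- sample(fairpoor, 1L)
      top3 <- ids[order(-u, seq_along(u))][1:3]
      target <- sample(top3, 1L)
      if (target != promote) {
        u[c(promote, target)] <- u[c(target, promote)]
      }
    }
    prof <- latent_profile(
      utilities = u,
      choice_noise = config$choice_noise,
      weighting_gamma = config$weighting_gamma,
      vas_noise_sd = config$vas_noise_sd,
      participant_id = pid,
      latent_index = c(index, death = 0))
    prof$unexpected <- unexpected
    prof$equipoise <- equipoise
    profiles[[i]] <- prof
  }
  profiles
}

#' Long-format table of a profile list
#'
#' @param profiles List of [latent_profile()]s.
#' @return Tibble with columns `participant_id`, `state_id`,
#'   `latent_utility`, `latent_index`, respondent parameters and behavior
#'   flags (repeated per state so that the table round-trips through CSV).
#' @export
profiles_to_table <- function(profiles) {
  dplyr::bind_rows(lapply(profiles, function(p) {
    ids <- names(p$utilities)
    tibble::tibble(
      participant_id = p$participant_id,
      state_id = ids,
      latent_utility = unname(p$utilities),
      latent_index = unname(p$latent_index[ids]),
      choice_noise = p$choice_noise,
      weighting_gamma = p$weighting_gamma,
      vas_noise_sd = p$vas_noise_sd,
      unexpected = p$unexpected,
      equipoise = p$equipoise)
  }))
}

#' Rebuild a profile list from its long-format table
#'
#' @param tbl Output of [profiles_to_table()] (possibly read back from CSV).
#' @return List of [latent_profile()]s.
#' @export
profiles_from_table <- function(tbl) {
  out <- lapply(split(tbl, tbl$participant_id), function(d) {
    prof <- latent_profile(
      utilities = stats::setNames(d$latent_utility, d$state_id),
      choice_noise = d$choice_noise[1],
      weighting_gamma = d$weighting_gamma[1],
      vas_noise_sd = d$vas_noise_sd[1],
      participant_id = d$participant_id[1],
      latent_index = stats::setNames(d$latent_index, d$state_id))
    prof$unexpected <- d$unexpected[1]
    prof$equipoise <- d$equipoise[1]
    prof
  })
  unname(out[order(as.numeric(names(out)))])
}

#' Per-participant option-group scores of the latent linear index
#'
#' Group means of the unclipped latent index, rescaled to the 0-100 VAS
#' scale on which covariate effects are configured.  This is the generating
#' truth against which regression recovery is assessed.
#'
#' @param profiles List of [latent_profile()]s.
#' @return Tibble with columns `participant_id`, `any`, `implant`, `tissue`,
#'   `none` (scores in VAS points).
#' @export
latent_group_scores <- function(profiles) {
  groups <- option_groups()
  ids <- health_states(FALSE)$state_id
  M <- vapply(profiles, function(p) p$latent_index[ids],
              numeric(length(ids)))  # states x participants
  rownames(M) <- ids
  tibble::tibble(
    participant_id = vapply(profiles, function(p) p$participant_id,
                            numeric(1)),
    any = 100 * colMeans(M[groups$any, , drop = FALSE]),
    implant = 100 * colMeans(M[groups$implant, , drop = FALSE]),
    tissue = 100 * colMeans(M[groups$tissue, , drop = FALSE]),
    none = 100 * M["none", ])
}
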