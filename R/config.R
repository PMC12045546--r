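#' Default covariate distributions for the synthetic cohort
#'
#' Means, SDs and clip bounds for continuous covariates and category
#' probabilities for categorical covariates, matching the published cohort
#' characteristics of the 40-woman breast reconstruction interview sample
#' (age 51.65 +/- 11.66 y; 30/40/30% normal/overweight/obese; 40/60%
#' unilateral/bilateral; ASI-R and BREAST-Q subscale means and SDs).
#'
#' @return Named list of covariate specifications.  Continuous entries have
#'   `type = "continuous"` with `mean`, `sd`, `min`, `max`; categorical
#'   entries have `type = "categorical"` with `levels` and `probs`.
#' @export
default_covariate_spec <- function() {
  cont <- function(mean, sd, min, max) {
    list(type = "continuous", mean = mean, sd = sd, min = min, max = max)
  }
  cat_ <- function(levels, probs) {
    list(type = "categorical", levels = levels, probs = probs)
  }
  list(
    age        = cont(51.65, 11.66, 27, 68),
    race       = cat_(c("white", "asian", "black", "other"),
                      c(0.925, 0.025, 0.025, 0.025)),
    ethnicity  = cat_(c("hispanic", "non_hispanic"), c(0.225, 0.775)),
    married    = cat_(c("yes", "no"), c(0.775, 0.225)),
    education  = cat_(c("high_school_or_some_college",
                        "college_graduate_or_higher"), c(0.325, 0.675)),
    indication = cat_(c("cancer_one_breast", "cancer_both", "prophylactic"),
                      c(0.75, 0.125, 0.125)),
    laterality = cat_(LATERALITIES, c(0.40, 0.60)),
    bmi_category = cat_(BMI_CATEGORIES, c(0.30, 0.40, 0.30)),
    timing     = cat_(c("pre_mastectomy", "post_mastectomy"), c(0.5, 0.5)),
    asir_total           = cont(3.28, 0.59, 1.95, 4.45),
    asir_behavior        = cont(3.76, 0.63, 2.14, 5.00),
    asir_self_evaluation = cont(2.97, 0.77, 1.25, 4.50),
    asir_control         = cont(3.09, 0.65, 1.80, 4.40),
    breastq_breast       = cont(54.11, 9.90, 35.75, 74.00),
    breastq_outcome      = cont(57.99, 13.68, 32.00, 80.00)
  )
}

#' Default latent base utilities per health state
#'
#' Defaults follow the published median standard-gamble utilities so that
#' synthetic cohorts resemble the study cohort on average (implant-excellent
#' 0.99, no reconstruction 0.86, ...).  The implant-poor default is 0.93, one
#' printed-precision step below implant-fair, so that within-modality
#' utilities are strictly ordered at zero noise.  Death is always 0.
#'
#' @return Named numeric vector over the nine non-death states.
#' @export
default_base_utilities <- function() {
  c(implant_excellent = 0.99, implant_good = 0.96,
    implant_fair = 0.94, implant_poor = 0.93,
    tissue_excellent = 0.97, tissue_good = 0.95,
    tissue_fair = 0.94, tissue_poor = 0.92,
    none = 0.86)
}

#' Default covariate effects on the latent utility scale
#'
#' Effects are expressed in visual-analog-scale points (0-100) per unit of
#' the covariate (continuous covariates are centered at their configured
#' means) or per indicator level, and are divided by 100 when applied to the
#' 0-1 latent scale.  `group` names the states the effect acts on
#' ("any" = all eight reconstruction states).  Defaults encode the published
#' multivariable coefficients for the without-death visual-analog-scale
#' models: BREAST-Q breast +0.46/point on implant states, BREAST-Q outcome
#' -0.25/point on no reconstruction, ASI-R behavior +4.20 and ASI-R
#' self-evaluation -6.96 per scale point on all reconstruction states, and
#' obesity -16.15 on implant / +10.59 on tissue states.
#'
#' @return A tibble with columns `covariate`, `level` (NA for continuous),
#'   `group`, `effect`.
#' @export
default_effects <- function() {
  tibble::tribble(
    ~covariate,             ~level,   ~group,    ~effect,
    "breastq_breast",        NA,      "implant",  0.46,
    "breastq_outcome",       NA,      "none",    -0.25,
    "asir_behavior",         NA,      "any",      4.20,
    "asir_self_evaluation",  NA,      "any",     -6.96,
    "bmi_category",          "obese", "implant", -16.15,
    "bmi_category",          "obese", "tissue",   10.59
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the generative model: cohort size, covariate
#' distributions, base utilities per state, covariate effects, noise levels
#' of the stochastic respondent, and the prevalences of the two documented
#' special response behaviors (unexpected rankings and equipoise).
#'
#' @param n_participants Cohort size (default 40, the study sample).
#' @param rng_seed Integer seed; every random draw is derived from
#'   `(rng_seed, participant_id, operation)` so cohorts are stable under
#'   reordering and subsetting.
#' @param covariates Covariate specification, see [default_covariate_spec()].
#' @param base_utilities Named base utility per non-death state.
#' @param effects Covariate effect table, see [default_effects()].
#' @param latent_noise_sd SD of the per-state participant-level noise on the
#'   0-1 latent scale (default 0.005; the latent deck spans only about 0.13,
#'   so larger values swamp the quality ordering).
#' @param unexpected_rank_fraction Probability that a participant's quality
#'   ordering is additionally permuted by promoting a random fair/poor state
#'   into their top three (default 0.05).  Most unexpected rankings in a
#'   default cohort arise from the covariate effects themselves (obesity
#'   reverses the implant/tissue blocks), not from this dial; see the
#'   methods vignette.
#' @param equipoise_fraction Probability that a participant's non-excellent
#'   utilities are compressed toward their mean (default 0.25, the reported
#'   prevalence of verbalized equipoise).
#' @param equipoise_compression Residual spread factor applied to
#'   non-excellent utilities of equipoise participants (default 0.2).
#' @param choice_noise Logistic temperature of the stochastic gamble choice
#'   rule; 0 gives the deterministic expected-utility respondent.
#' @param weighting_gamma Probability-weighting parameter of the respondent
#'   (1 = expected-utility, no distortion).
#' @param vas_noise_sd Rating noise SD in points of the death-anchored
#'   0-100 scale (latent utility times 100), shared by the ranking and
#'   rating instruments (default 0.5).
#' @param vas_rounding Grid the visual-analog ratings snap to; one of
#'   0 (off), 0.5, 1, 2.5, 5.
#' @param sg_step Probability decrement of the standard-gamble titration.
#' @param tie_epsilon Utility difference below which ranked cards tie.
#' @return A validated list of class `reconpref_config`.
#' @export
generator_config <- function(n_participants = 40,
                             rng_seed = 1L,
                             covariates = default_covariate_spec(),
                             base_utilities = default_base_utilities(),
                             effects = default_effects(),
                             latent_noise_sd = 0.005,
                             unexpected_rank_fraction = 0.05,
                             equipoise_fraction = 0.25,
                             equipoise_compression = 0.2,
                             choice_noise = 0.005,
                             weighting_gamma = 1,
                             vas_noise_sd = 0.5,
                             vas_rounding = 2.5,
                             sg_step = 0.05,
                             tie_epsilon = 1e-8) {
  config <- list(
    n_participants = n_participants,
    rng_seed = as.integer(rng_seed),
    covariates = covariates,
    base_utilities = base_utilities,
    effects = tibble::as_tibble(effects),
    latent_noise_sd = latent_noise_sd,
    unexpected_rank_fraction = unexpected_rank_fraction,
    equipoise_fraction = equipoise_fraction,
    equipoise_compression = equipoise_compression,
    choice_noise = choice_noise,
    weighting_gamma = weighting_gamma,
    vas_noise_sd = vas_noise_sd,
    vas_rounding = vas_rounding,
    sg_step = sg_step,
    tie_epsilon = tie_epsilon
  )
  class(config) <- "reconpref_config"
  validate_config(config)
}

#' @keywords internal
validate_config <- function(config) {
  stopifnot(inherits(config, "reconpref_config"))
  if (!is.numeric(config$n_participants) || length(config$n_participants) != 1 ||
      is.na(config$n_participants) || config$n_participants < 1) {
    stop("n_participants must be at least 1", call. = FALSE)
  }
  config$n_participants <- as.integer(config$n_participants)

  for (nm in names(config$covariates)) {
    spec <- config$covariates[[nm]]
    if (identical(spec$type, "categorical")) {
      if (length(spec$levels) != length(spec$probs)) {
        stop("covariate '", nm, "': levels and probs differ in length",
             call. = FALSE)
      }
      if (any(spec$probs < 0) || abs(sum(spec$probs) - 1) > 1e-8) {
        stop("covariate '", nm, "': category probabilities must sum to 1",
             call. = FALSE)
      }
    } else if (identical(spec$type, "continuous")) {
      if (spec$sd < 0 || spec$min > spec$max) {
        stop("covariate '", nm, "': invalid continuous specification",
             call. = FALSE)
      }
      # location adjusted so the post-clip mean equals the configured mean
      config$covariates[[nm]]$mu_adj <-
        censored_normal_location(spec$mean, spec$sd, spec$min, spec$max)
    } else {
      stop("covariate '", nm, "': unknown type", call. = FALSE)
    }
  }

  bu <- config$base_utilities
  need <- health_states(FALSE)$state_id
  if (!all(need %in% names(bu))) {
    stop("base_utilities must name every non-death state", call. = FALSE)
  }
  if (any(bu < 0 | bu > 1)) {
    stop("base_utilities must lie in [0, 1]", call. = FALSE)
  }

  eff <- config$effects
  if (nrow(eff)) {
    stopifnot(all(c("covariate", "level", "group", "effect") %in% names(eff)))
    unknown <- setdiff(eff$covariate, names(config$covariates))
    if (length(unknown)) {
      stop("effects reference unknown covariate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad_group <- setdiff(eff$group, c("any", "implant", "tissue", "none"))
    if (length(bad_group)) {
      stop("effects reference unknown group(s): ",
           paste(bad_group, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(eff))) {
      spec <- config$covariates[[eff$covariate[i]]]
      if (identical(spec$type, "categorical")) {
        if (is.na(eff$level[i]) || !eff$level[i] %in% spec$levels) {
          stop("effect on categorical covariate '", eff$covariate[i],
               "' must name one of its levels", call. = FALSE)
        }
      } else if (!is.na(eff$level[i])) {
        stop("effect on continuous covariate '", eff$covariate[i],
             "' must have level = NA", call. = FALSE)
      }
    }
  }

  stopifnot(config$latent_noise_sd >= 0, config$choice_noise >= 0,
            config$weighting_gamma > 0, config$vas_noise_sd >= 0)
  for (frac in c("unexpected_rank_fraction", "equipoise_fraction")) {
    if (config[[frac]] < 0 || config[[frac]] > 1) {
      stop(frac, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!config$vas_rounding %in% c(0, 0.5, 1, 2.5, 5)) {
    stop("vas_rounding must be one of 0, 0.5, 1, 2.5, 5", call. = FALSE)
  }
  if (config$sg_step <= 0 || config$sg_step > 0.25) {
    stop("sg_step must lie in (0, 0.25]", call. = FALSE)
  }
  config
}

#' Mean of a normal distribution censored at [lo, hi]
#' @keywords internal
censored_normal_mean <- function(mu, sd, lo, hi) {
  if (sd == 0) return(min(max(mu, lo), hi))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * stats::pnorm(b, lower.tail = FALSE) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a))
}

#' Pre-clip location whose censored mean equals `target`
#' @keywords internal
censored_normal_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  f <- function(mu) censored_normal_mean(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = target - 5 * sd, upper = target + 5 * sd,
                 tol = 1e-10)$root
}

#' Read a generator configuration from a YAML file
#'
#' Scalar fields override [generator_config()] defaults; `covariates` entries
#' are merged into the default specification, and `effects` (a list of
#' records with fields covariate, level, group, effect) replaces the default
#' effect table when present.
#'
#' @param path Path to a YAML file.
#' @return A `reconpref_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("n_participants", "rng_seed", "latent_noise_sd",
               "unexpected_rank_fraction", "equipoise_fraction",
               "equipoise_compression", "choice_noise", "weighting_gamma",
               "vas_noise_sd", "vas_rounding", "sg_step", "tie_epsilon")
  for (nm in intersect(scalars, names(raw))) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$base_utilities)) {
    args$base_utilities <- unlist(raw$base_utilities)
  }
  if (!is.null(raw$covariates)) {
    cov <- default_covariate_spec()
    for (nm in names(raw$covariates)) {
      spec <- raw$covariates[[nm]]
      if (!is.null(spec$levels)) spec$type <- "categorical"
      if (!is.null(spec$mean)) spec$type <- "continuous"
      cov[[nm]] <- utils::modifyList(cov[[nm]] %||% list(), spec)
    }
    args$covariates <- cov
  }
  if (!is.null(raw$effects)) {
    args$effects <- dplyr::bind_rows(lapply(raw$effects, function(e) {
      tibble::tibble(covariate = e$covariate,
                     level = e$level %||% NA_character_,
                     group = e$group, effect = e$effect)
    }))
  }
  do.call(generator_config, args)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
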