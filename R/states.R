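#' @keywords internal
MODALITIES <- c("implant", "tissue", "none", "death")

#' @keywords internal
QUALITIES <- c("excellent", "good", "fair", "poor", "not_applicable")

#' @keywords internal
BMI_CATEGORIES <- c("normal", "overweight", "obese")

#' @keywords internal
LATERALITIES <- c("unilateral", "bilateral")

#' Reconstruction outcome groups used throughout the analysis
#'
#' "any" pools the eight reconstruction states; "implant" and "tissue" their
#' four quality levels each; "none" is the single no-reconstruction state.
#' @return Named list of character vectors of state ids.
#' @export
option_groups <- function() {
  recon <- as.vector(outer(c("implant", "tissue"),
                           c("excellent", "good", "fair", "poor"),
                           paste, sep = "_"))
  list(
    any     = sort(recon),
    implant = paste("implant", c("excellent", "good", "fair", "poor"), sep = "_"),
    tissue  = paste("tissue",  c("excellent", "good", "fair", "poor"), sep = "_"),
    none    = "none"
  )
}

#' Metadata for every health state
#'
#' @param include_death Append the death state?
#' @return A tibble with columns `state_id`, `modality`, `quality`.
#' @export
health_states <- function(include_death = FALSE) {
  qual <- c("excellent", "good", "fair", "poor")
  out <- tibble::tibble(
    state_id = c(paste("implant", qual, sep = "_"),
                 paste("tissue", qual, sep = "_"),
                 "none"),
    modality = c(rep("implant", 4), rep("tissue", 4), "none"),
    quality  = c(qual, qual, "not_applicable")
  )
  if (isTRUE(include_death)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      state_id = "death", modality = "death", quality = "not_applicable"))
  }
  out
}

#' Build the card deck presented to a participant
#'
#' The deck holds nine outcome cards case-matched to the participant's BMI
#' category and reconstruction laterality: four implant-based qualities
#' (excellent, good, fair, poor), four tissue-based qualities, and one
#' no-reconstruction card.  A death card is appended only for the
#' with-death instruments and for the chained-gamble anchor.
#'
#' @param bmi_category One of `"normal"`, `"overweight"`, `"obese"`.
#' @param laterality One of `"unilateral"`, `"bilateral"`.
#' @param include_death Append the death card?
#' @return A tibble of health states (see [health_states()]) with
#'   attributes `bmi_category` and `laterality` recording the case match.
#' @examples
#' build_deck("normal", "bilateral")
#' build_deck("obese", "unilateral", include_death = TRUE)
#' @export
build_deck <- function(bmi_category, laterality, include_death = FALSE) {
  if (!is.character(bmi_category) || length(bmi_category) != 1L ||
      !bmi_category %in% BMI_CATEGORIES) {
    stop("invalid bmi_category: '", paste(bmi_category, collapse = ","),
         "' (expected one of ", paste(BMI_CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.character(laterality) || length(laterality) != 1L ||
      !laterality %in% LATERALITIES) {
    stop("invalid laterality: '", paste(laterality, collapse = ","),
         "' (expected one of ", paste(LATERALITIES, collapse = ", "), ")",
         call. = FALSE)
  }
  deck <- health_states(include_death = include_death)
  attr(deck, "bmi_category") <- bmi_category
  attr(deck, "laterality") <- laterality
  deck
}

#' @keywords internal
deck_state_ids <- function(deck, include_death = NULL) {
  ids <- deck$state_id
  if (isTRUE(include_death)) {
    if (!"death" %in% ids) {
      stop("deck does not contain a death state", call. = FALSE)
    }
  } else if (isFALSE(include_death)) {
    ids <- setdiff(ids, "death")
  }
  ids
}
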