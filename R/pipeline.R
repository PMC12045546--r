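#' Combine elicited and instrument records into one long table
#' @keywords internal
combine_records <- function(sg_records, instrument_records) {
  sg <- tibble::tibble(participant_id = sg_records$participant_id,
                       instrument = "utility",
                       include_death = TRUE,
                       state_id = sg_records$state_id,
                       value = sg_records$utility)
  dplyr::bind_rows(instrument_records, sg)
}

#' @keywords internal
pipeline_tests <- function(records, covariates) {
  groups <- c("any", "implant", "tissue", "none")
  score_of <- function(instr, grp, qual = "pooled") {
    d <- records[records$instrument == instr & records$state_id != "death", ]
    s <- participant_group_scores(d)
    s <- s[s$option_group == grp & s$quality == qual, ]
    s$score[match(sort(unique(records$participant_id)), s$participant_id)]
  }
  out <- list()

  # per-row correlation of with-death VAS ratings against gamble utilities
  for (g in groups) {
    quals <- if (g == "none") "pooled" else
      c("pooled", "excellent", "good", "fair", "poor")
    for (q in quals) {
      x <- score_of("vas_death", g, q)
      y <- score_of("utility", g, q)
      if (sum(stats::complete.cases(x, y)) >= 3 &&
          stats::sd(x, na.rm = TRUE) > 0 && stats::sd(y, na.rm = TRUE) > 0) {
        out[[length(out) + 1]] <- rank_utility_correlation(
          x, y, grouping = paste0("vas_death vs utility: ", g, "/", q))
      }
    }
  }

  # paired contrasts within each instrument
  for (instr in c("rank", "vas", "vas_death", "utility")) {
    any_s <- score_of(instr, "any")
    none_s <- score_of(instr, "none")
    imp_s <- score_of(instr, "implant")
    tis_s <- score_of(instr, "tissue")
    out[[length(out) + 1]] <- paired_compare(
      any_s, none_s, grouping = paste0(instr, ": reconstruction vs none"))
    out[[length(out) + 1]] <- paired_compare(
      imp_s, tis_s, grouping = paste0(instr, ": implant vs tissue"))
  }

  # ratings across BMI categories
  ids <- sort(unique(records$participant_id))
  bmi <- covariates$bmi_category[match(ids, covariates$participant_id)]
  for (g in c("implant", "tissue")) {
    v <- score_of("vas", g)
    out[[length(out) + 1]] <- bmi_compare(
      v, bmi, grouping = paste0("vas ", g, " by BMI category"))
  }
  dplyr::bind_rows(out)
}

#' @keywords internal
pipeline_models <- function(records, covariates,
                            candidates = c("breastq_breast", "breastq_outcome",
                                           "asir_behavior",
                                           "asir_self_evaluation",
                                           "indication", "bmi_category",
                                           "timing")) {
  groups <- c("any", "implant", "tissue", "none")
  instruments <- c("vas", "vas_death", "utility")
  models <- list()
  coefs <- list()
  screens <- list()
  for (instr in instruments) {
    d <- records[records$instrument == instr & records$state_id != "death", ]
    scores <- participant_group_scores(d)
    for (g in groups) {
      s <- scores[scores$option_group == g & scores$quality == "pooled", ]
      dat <- dplyr::inner_join(
        s[, c("participant_id", "score")], covariates, by = "participant_id")
      key <- paste(instr, g, sep = ".")
      scr <- univariate_screen(dat, "score", candidates)
      kept <- scr$covariate[scr$retained]
      mod <- backward_aic(dat, "score", kept)
      mod$instrument <- instr
      mod$option_group <- g
      models[[key]] <- mod
      screens[[key]] <- tibble::tibble(instrument = instr, option_group = g,
                                       scr)
      ct <- mod$coefficients
      coefs[[key]] <- tibble::tibble(instrument = instr, option_group = g, ct)
    }
  }
  list(models = models,
       coefficients = dplyr::bind_rows(coefs),
       screen = dplyr::bind_rows(screens))
}

#' Median/IQR figure for one instrument
#'
#' Point-and-interval display of the summary table (median with first and
#' third quartiles) across option groups and qualities, the shape used for
#' the study's rating and utility figures.
#'
#' @param summary_tbl Output of [summarize_preferences()].
#' @param instruments Instruments to facet (default: VAS with/without
#'   death).
#' @return A ggplot object.
#' @export
plot_summary <- function(summary_tbl,
                         instruments = c("vas", "vas_death")) {
  d <- summary_tbl[summary_tbl$instrument %in% instruments, ]
  d$cell <- factor(paste(d$option_group, d$quality, sep = "\n"),
                   levels = unique(paste(d$option_group, d$quality,
                                         sep = "\n")))
  ggplot2::ggplot(d, ggplot2::aes(x = cell, y = median,
                                  color = instrument)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = q1, ymax = q3),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "median (IQR)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Ratings of implant- and tissue-based reconstruction by BMI category
#'
#' @param records Long record table (see [combine_records()]).
#' @param covariates Cohort table.
#' @return A ggplot object.
#' @export
plot_bmi_ratings <- function(records, covariates) {
  d <- records[records$instrument == "vas" & records$state_id != "death", ]
  scores <- participant_group_scores(d)
  scores <- scores[scores$option_group %in% c("implant", "tissue") &
                     scores$quality == "pooled", ]
  scores$bmi_category <- covariates$bmi_category[
    match(scores$participant_id, covariates$participant_id)]
  ggplot2::ggplot(scores, ggplot2::aes(x = bmi_category, y = score)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~option_group) +
    ggplot2::labs(x = "BMI category", y = "VAS rating (no death)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @keywords internal
save_figure <- function(plot, path, width = 7, height = 4) {
  ok <- tryCatch({
    if (isTRUE(capabilities("cairo"))) {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = 150, type = "cairo")
    } else {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = 150)
    }
    print(plot)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (!ok) {
    pdf_path <- sub("\\.png$", ".pdf", path)
    grDevices::pdf(pdf_path, width = width, height = height)
    print(plot)
    grDevices::dev.off()
  }
  invisible(ok)
}

#' Run the full simulation and analysis pipeline
#'
#' One call regenerates everything from a configuration: cohort covariates,
#' latent profiles, chained standard-gamble elicitation, card rankings and
#' visual-analog ratings (with and without death), the median/IQR summary
#' table, instrument correlations and paired contrasts, BMI comparisons,
#' and the 12 backward-AIC regression models (three instruments by four
#' option groups).  With `output_dir` set, all tables are written as CSV
#' and the summary figures as PNG.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed overriding `config$rng_seed`.
#' @param output_dir Directory for CSV/figure output (created if missing);
#'   `NULL` skips writing.
#' @param write_figures Write the figures when `output_dir` is set?
#' @return Object of class `reconpref_results` with fields `config`,
#'   `cohort`, `profiles`, `gamble_records`, `records`, `unexpected`,
#'   `summary`, `tests`, `models`, `model_coefficients`, `screen`,
#'   `exclusions`, `seed`.
#' @export
run_pipeline <- function(config = generator_config(),
                         seed = config$rng_seed,
                         output_dir = NULL,
                         write_figures = TRUE) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("cohort", sample_covariates(config, seed = seed))
  profiles <- stage("profiles",
                    generate_latent_profiles(cohort, config, seed = seed))
  sg <- stage("elicitation",
              elicit_cohort(profiles, step = config$sg_step, seed = seed))
  inst <- stage("instruments",
                collect_instruments(profiles, cohort, config, seed = seed))
  records <- combine_records(sg$records, inst$records)
  summary_tbl <- stage("summary", summarize_preferences(records))
  tests <- stage("tests", pipeline_tests(records, cohort))
  mods <- stage("models", pipeline_models(records, cohort))

  # listwise exclusion log per instrument (cohort conservation audit)
  n_total <- nrow(cohort)
  exclusions <- dplyr::summarise(
    dplyr::group_by(records[records$state_id != "death", ], instrument),
    n_complete = length(unique(participant_id[!is.na(value)])),
    n_excluded = n_total - n_complete,
    .groups = "drop")

  res <- structure(
    list(config = config,
         seed = seed,
         cohort = cohort,
         profiles = profiles,
         gamble_records = sg$records,
         records = records,
         unexpected = inst$unexpected,
         summary = summary_tbl,
         tests = tests,
         models = mods$models,
         model_coefficients = mods$coefficients,
         screen = mods$screen,
         exclusions = exclusions),
    class = "reconpref_results")

  if (!is.null(output_dir)) {
    write_results(res, output_dir, write_figures = write_figures)
  }
  res
}

#' Write pipeline results to CSV (and figures to PNG)
#'
#' @param results A `reconpref_results` object.
#' @param output_dir Target directory (created if missing).
#' @param write_figures Also write the summary figures?
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, output_dir, write_figures = TRUE) {
  stopifnot(inherits(results, "reconpref_results"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  readr::write_csv(results$cohort, p("cohort.csv"))
  readr::write_csv(profiles_to_table(results$profiles),
                   p("latent_profiles.csv"))
  readr::write_csv(results$gamble_records, p("gamble_records.csv"))
  readr::write_csv(results$records, p("instrument_records.csv"))
  readr::write_csv(results$unexpected, p("unexpected_rankings.csv"))
  readr::write_csv(results$summary, p("summary_table.csv"))
  readr::write_csv(results$tests, p("test_results.csv"))
  readr::write_csv(results$model_coefficients, p("model_coefficients.csv"))
  readr::write_csv(results$screen, p("univariate_screen.csv"))
  readr::write_csv(results$exclusions, p("exclusions.csv"))
  if (write_figures) {
    save_figure(plot_summary(results$summary, c("vas", "vas_death")),
                p("fig_vas_medians.png"))
    save_figure(plot_summary(results$summary, "utility"),
                p("fig_utility_medians.png"))
    save_figure(plot_bmi_ratings(results$records, results$cohort),
                p("fig_bmi_ratings.png"))
  }
  invisible(list.files(output_dir, full.names = TRUE))
}

#' @export
print.reconpref_results <- function(x, ...) {
  cat("<reconpref_results> n =", nrow(x$cohort),
      " seed =", x$seed, "\n")
  cat("unexpected rankings:", sum(x$unexpected$unexpected), "/",
      nrow(x$unexpected), "\n")
  cat("summary rows:", nrow(x$summary),
      " tests:", nrow(x$tests),
      " models:", length(x$models), "\n")
  invisible(x)
}
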