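#' Per-participant option-group scores
#'
#' Collapses per-state instrument values to one score per participant per
#' (option-group, quality) cell: the mean over that cell's states ("any"
#' pools all eight reconstruction states; "implant"/"tissue" their four;
#' quality rows take the matching states within the group).  A participant
#' missing any state of a cell is excluded from that cell (listwise per
#' column).
#'
#' @param tbl Long tibble with columns `participant_id`, `state_id`, `value`.
#' @param agg Within-participant aggregator, `"mean"` (default) or
#'   `"median"`.
#' @return Tibble `participant_id`, `option_group`, `quality`, `score`.
#' @export
participant_group_scores <- function(tbl, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  f <- if (agg == "mean") mean else stats::median
  states <- health_states(FALSE)
  groups <- option_groups()
  qualities <- c("pooled", "excellent", "good", "fair", "poor")

  cells <- list()
  for (g in names(groups)) {
    quals <- if (g == "none") "pooled" else qualities
    for (q in quals) {
      sel <- groups[[g]]
      if (q != "pooled") {
        sel <- intersect(sel, states$state_id[states$quality == q])
      }
      cells[[paste(g, q, sep = ".")]] <-
        list(group = g, quality = q, states = sel)
    }
  }

  wide <- tidyr::pivot_wider(tbl[, c("participant_id", "state_id", "value")],
                             names_from = "state_id", values_from = "value")
  out <- lapply(cells, function(cell) {
    cols <- intersect(cell$states, names(wide))
    score <- if (length(cols) < length(cell$states)) {
      rep(NA_real_, nrow(wide))
    } else {
      apply(as.matrix(wide[, cols, drop = FALSE]), 1, function(x) {
        if (anyNA(x)) NA_real_ else f(x)
      })
    }
    tibble::tibble(participant_id = wide$participant_id,
                   option_group = cell$group,
                   quality = cell$quality,
                   score = score)
  })
  dplyr::bind_rows(out)
}

#' Median/IQR summary of rankings, ratings, and utilities
#'
#' Builds the study-shaped summary: one row per (option-group, quality)
#' cell and instrument, with the across-participant median, quartiles, IQR
#' and cell n of the per-participant group scores.  Empty cells are
#' reported with `n = 0` and missing medians, never as zero.
#'
#' @param records Long tibble with columns `participant_id`, `instrument`,
#'   `state_id`, `value` (non-death states).
#' @param agg Within-participant aggregation, see
#'   [participant_group_scores()].
#' @return Tibble `instrument`, `option_group`, `quality`, `n`, `median`,
#'   `q1`, `q3`, `iqr`.
#' @export
summarize_preferences <- function(records, agg = "mean") {
  stopifnot(all(c("participant_id", "instrument", "state_id", "value")
                %in% names(records)))
  records <- records[records$state_id != "death", ]
  safe_stat <- function(z, f) {
    z <- z[!is.na(z)]
    if (length(z) == 0) NA_real_ else f(z)
  }
  out <- lapply(split(records, records$instrument), function(d) {
    scores <- participant_group_scores(d, agg = agg)
    dplyr::summarise(
      dplyr::group_by(scores, option_group, quality),
      n = sum(!is.na(score)),
      median = safe_stat(score, stats::median),
      q1 = safe_stat(score, function(z)
        stats::quantile(z, 0.25, names = FALSE)),
      q3 = safe_stat(score, function(z)
        stats::quantile(z, 0.75, names = FALSE)),
      .groups = "drop")
  })
  res <- dplyr::bind_rows(out, .id = "instrument")
  res$iqr <- res$q3 - res$q1
  grp_order <- c(any = 1, implant = 2, tissue = 3, none = 4)
  q_order <- c(pooled = 1, excellent = 2, good = 3, fair = 4, poor = 5)
  res[order(res$instrument, grp_order[res$option_group],
            q_order[res$quality]), ]
}

#' @keywords internal
test_result <- function(test, statistic, p_value, n, paired = FALSE,
                        degenerate = FALSE, grouping = "") {
  tibble::tibble(test = test, statistic = statistic, p_value = p_value,
                 n = n, paired = paired, degenerate = degenerate,
                 grouping = grouping)
}

#' Spearman rank correlation between two paired score vectors
#'
#' Midranks handle ties; the p-value is two-sided (exact for small n
#' without ties, asymptotic otherwise, as in [stats::cor.test()]).  A
#' constant vector leaves the correlation undefined: it is reported as
#' missing with a warning.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @param grouping Label describing what was correlated.
#' @return One-row test-result tibble (statistic = rho).
#' @export
rank_utility_correlation <- function(x, y, grouping = "") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(test_result("spearman_rho", NA_real_, NA_real_, n,
                       degenerate = TRUE, grouping = grouping))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  test_result("spearman_rho", unname(ct$estimate), ct$p.value, n,
              grouping = grouping)
}

#' Wilcoxon signed-rank comparison of paired scores
#'
#' Two-sided; zero differences are dropped (classical convention).  The
#' exact null distribution is used for 25 or fewer nonzero differences
#' without ties, the normal approximation with continuity correction
#' otherwise.  If every difference is zero the comparison is degenerate and
#' reported with p = 1.
#'
#' @param x,y Paired numeric vectors.
#' @param grouping Label describing the contrast.
#' @return One-row test-result tibble (statistic = V).
#' @export
paired_compare <- function(x, y, grouping = "") {
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  n_all <- length(d)
  d <- d[d != 0]
  if (length(d) == 0) {
    return(test_result("wilcoxon_signed_rank", NA_real_, 1, n_all,
                       paired = TRUE, degenerate = TRUE,
                       grouping = grouping))
  }
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = use_exact, correct = TRUE))
  test_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value,
              length(d), paired = TRUE, grouping = grouping)
}

#' Kruskal-Wallis comparison of scores across BMI categories
#'
#' @param values Numeric scores.
#' @param groups Grouping factor (e.g. BMI category); at least two
#'   non-empty groups are required.
#' @param grouping Label describing the comparison.
#' @return One-row test-result tibble (statistic = H).
#' @export
bmi_compare <- function(values, groups, grouping = "") {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  kt <- stats::kruskal.test(values, groups)
  test_result("kruskal_wallis", unname(kt$statistic), kt$p.value,
              length(values), grouping = grouping)
}

#' Optional multiplicity adjustment of a test-result table
#'
#' The pipeline reports unadjusted p-values by default (each test is
#' interpreted against a two-sided 0.05 level on its own); this helper
#' applies a family-wise correction across a set of results when one is
#' wanted.
#'
#' @param tests A test-result tibble (rows from
#'   [rank_utility_correlation()], [paired_compare()], [bmi_compare()]).
#' @param method Adjustment method passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return The table with an added `p_adjusted` column.
#' @export
adjust_test_results <- function(tests, method = "holm") {
  tests$p_adjusted <- stats::p.adjust(tests$p_value, method = method)
  tests
}

#' Univariate covariate screen
#'
#' Fits one single-covariate linear model per candidate and retains those
#' with p < `threshold` (default 0.2).  Categorical covariates enter as
#' indicator sets and are screened by their joint F test.  Zero-variance
#' covariates are excluded with a warning.
#'
#' @param data Data frame holding the outcome and candidate columns.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate covariate names.
#' @param threshold Retention threshold on the univariate p-value.
#' @return Tibble `covariate`, `p_value`, `retained`.
#' @export
univariate_screen <- function(data, outcome, candidates, threshold = 0.2) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  rows <- lapply(candidates, function(cv) {
    x <- data[[cv]]
    x_ok <- x[!is.na(x)]
    constant <- if (is.numeric(x)) {
      stats::var(x_ok) == 0
    } else {
      length(unique(x_ok)) < 2
    }
    if (constant) {
      warning("covariate '", cv, "' has zero variance; excluded from screen",
              call. = FALSE)
      return(tibble::tibble(covariate = cv, p_value = NA_real_,
                            retained = FALSE))
    }
    m <- stats::lm(stats::reformulate(cv, response = outcome), data = data)
    p <- stats::anova(m)[1, "Pr(>F)"]
    tibble::tibble(covariate = cv, p_value = p, retained = p < threshold)
  })
  dplyr::bind_rows(rows)
}

#' Backward model selection by Akaike information criterion
#'
#' Starts from the linear model containing every screened covariate and
#' repeatedly removes the single covariate whose removal most reduces the
#' AIC, stopping when no removal reduces it.  Removal ties are broken
#' toward the covariate with the larger F-test p-value.  Perfectly
#' collinear covariates are dropped (smallest univariate contribution
#' first) with a warning before selection starts.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of screened covariate names.
#' @param conf_level Confidence level of the Wald-type intervals.
#' @return Object of class `preference_model`: `outcome`, `retained`,
#'   `coefficients` (tibble: `term`, `estimate`, `conf_low`, `conf_high`,
#'   `p_value`), `aic`, `n`, and the fitted `model`.
#' @export
backward_aic <- function(data, outcome, covariates, conf_level = 0.95) {
  stopifnot(outcome %in% names(data))
  data <- data[stats::complete.cases(data[, c(outcome, covariates),
                                          drop = FALSE]), ]
  current <- covariates
  fit <- function(terms) {
    f <- if (length(terms)) {
      stats::reformulate(terms, response = outcome)
    } else {
      stats::as.formula(paste(outcome, "~ 1"))
    }
    stats::lm(f, data = data)
  }
  m <- fit(current)

  # drop aliased (perfectly collinear) covariates before selection
  while (length(current) && anyNA(stats::coef(m))) {
    labels <- attr(stats::terms(m), "term.labels")
    na_terms <- unique(labels[m$assign[is.na(stats::coef(m))]])
    scr <- univariate_screen(data, outcome, na_terms, threshold = 1)
    drop_term <- scr$covariate[which.max(scr$p_value)]
    warning("dropping collinear covariate '", drop_term, "'", call. = FALSE)
    current <- setdiff(current, drop_term)
    m <- fit(current)
  }

  repeat {
    if (!length(current)) break
    d1 <- stats::drop1(m, test = "F")
    terms <- rownames(d1)[-1]
    aic_none <- d1["<none>", "AIC"]
    aic_drop <- d1$AIC[-1]
    p_drop <- d1[["Pr(>F)"]][-1]
    reducers <- which(aic_drop < aic_none - 1e-10)
    if (!length(reducers)) break
    best_aic <- min(aic_drop[reducers])
    tied <- reducers[aic_drop[reducers] <= best_aic + 1e-8]
    pick <- tied[which.max(p_drop[tied])]
    current <- setdiff(current, terms[pick])
    m <- fit(current)
  }

  cf <- summary(m)$coefficients
  ci <- stats::confint(m, level = conf_level)
  coef_tbl <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    conf_low = unname(ci[rownames(cf), 1]),
    conf_high = unname(ci[rownames(cf), 2]),
    p_value = unname(cf[, "Pr(>|t|)"]))

  structure(
    list(outcome = outcome,
         retained = current,
         screened = covariates,
         coefficients = coef_tbl,
         aic = stats::AIC(m),
         n = stats::nobs(m),
         model = m),
    class = "preference_model")
}

#' @export
print.preference_model <- function(x, ...) {
  cat("<preference_model>", x$outcome, " n =", x$n,
      " AIC =", round(x$aic, 2), "\n")
  cat("retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}
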