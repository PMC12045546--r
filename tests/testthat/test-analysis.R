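make_records <- function(values_by_participant, instrument = "utility") {
  dplyr::bind_rows(lapply(seq_along(values_by_participant), function(i) {
    v <- values_by_participant[[i]]
    tibble::tibble(participant_id = i, instrument = instrument,
                   state_id = names(v), value = unname(v))
  }))
}

test_that("group scores average a cell's states and exclude incomplete cells", {
  rec <- make_records(list(c(implant_excellent = 1.0, implant_good = 0.9,
                             implant_fair = 1.0, implant_poor = 0.9)))
  s <- summarize_preferences(rec)
  imp <- s[s$option_group == "implant" & s$quality == "pooled", ]
  expect_equal(imp$median, 0.95)
  expect_equal(imp$iqr, 0)
  expect_equal(imp$n, 1L)
  # the participant lacks tissue states: "any" cell is empty, not zero
  any_row <- s[s$option_group == "any" & s$quality == "pooled", ]
  expect_equal(any_row$n, 0L)
  expect_true(is.na(any_row$median))
})

test_that("a cohort unanimous about no reconstruction yields a zero none row", {
  states <- health_states(FALSE)$state_id
  rec <- make_records(lapply(1:12, function(i) {
    v <- setNames(runif(9, 40, 90), states)
    v["none"] <- 0
    v
  }), instrument = "vas")
  s <- summarize_preferences(rec)
  none <- s[s$option_group == "none", ]
  expect_equal(none$median, 0)
  expect_equal(none$iqr, 0)
})

test_that("summary medians round-trip the configured base utilities", {
  cfg <- generator_config(n_participants = 800, rng_seed = 12,
                          latent_noise_sd = 0.005, choice_noise = 0,
                          unexpected_rank_fraction = 0,
                          equipoise_fraction = 0,
                          effects = zero_effects())
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  sg <- elicit_cohort(profs, step = 0.05, seed = 12)
  rec <- tibble::tibble(participant_id = sg$records$participant_id,
                        instrument = "utility",
                        state_id = sg$records$state_id,
                        value = sg$records$utility)
  s <- summarize_preferences(rec)
  base <- default_base_utilities()
  for (m in c("implant", "tissue")) {
    for (q in c("excellent", "good", "fair", "poor")) {
      med <- s$median[s$option_group == m & s$quality == q]
      expect_lt(abs(med - base[paste(m, q, sep = "_")]), 0.02)
    }
  }
  expect_lt(abs(s$median[s$option_group == "none"] - base["none"]), 0.02)
})

test_that("Spearman correlation handles perfect monotone, ties, and constants", {
  expect_equal(rank_utility_correlation(1:9, seq(0.9, 0.1, by = -0.1))$statistic,
               -1)
  expect_warning(out <- rank_utility_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$statistic))
  expect_true(out$degenerate)
  expect_error(rank_utility_correlation(1:2, 1:2), "3")

  # midrank ties match a rank-then-Pearson oracle
  x <- c(1, 2, 2, 4, 5, 6, 8, 8)
  y <- c(10, 9, 7, 7, 5, 6, 2, 1)
  got <- rank_utility_correlation(x, y)$statistic
  expect_equal(got, cor(rank(x), rank(y)))
})

test_that("independent vectors rarely show Spearman correlation beyond 0.1", {
  set.seed(8)
  hits <- replicate(200, {
    abs(rank_utility_correlation(rnorm(1000), rnorm(1000))$statistic) < 0.1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("paired comparisons drop zeros, detect shifts, and flag degeneracy", {
  x <- c(1, 2, 3, 4)
  out <- paired_compare(x, x)
  expect_true(out$degenerate)
  expect_equal(out$p_value, 1)

  set.seed(4)
  x <- rnorm(20)
  out2 <- paired_compare(x + 1, x)
  expect_lt(out2$p_value, 0.001)

  # matches the sign-flip enumeration oracle at small n
  set.seed(14)
  for (i in 1:5) {
    d <- sample(setdiff(-40:40, 0), 8)
    while (any(duplicated(abs(d)))) d <- sample(setdiff(-40:40, 0), 8)
    got <- paired_compare(d, rep(0, 8))
    oracle <- wilcoxon_enum(d)
    expect_equal(got$statistic, oracle$V)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis handles balanced null groups and reduces to Mann-Whitney", {
  vals <- rep(c(1, 2, 3), 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  out <- bmi_compare(vals, grp)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(bmi_compare(1:5, rep("a", 5)), "2")

  # two-group case equals the Mann-Whitney normal approximation
  set.seed(21)
  v <- rnorm(14)
  g <- rep(c("x", "y"), times = c(6, 8))
  kw <- bmi_compare(v, g)
  mw <- wilcox.test(v[g == "x"], v[g == "y"], exact = FALSE,
                    correct = FALSE)
  expect_equal(kw$p_value, mw$p.value, tolerance = 1e-12)
})

test_that("the univariate screen keeps signal, drops constants, applies p < 0.2", {
  set.seed(6)
  n <- 300
  dat <- data.frame(y = rnorm(n), x_true = rnorm(n), x_const = 1,
                    grp = factor(sample(c("a", "b", "c"), n, TRUE)))
  dat$y <- dat$y + 2 * dat$x_true
  expect_warning(scr <- univariate_screen(dat, "y",
                                          c("x_true", "x_const", "grp")),
                 "zero variance")
  expect_true(scr$retained[scr$covariate == "x_true"])
  expect_false(scr$retained[scr$covariate == "x_const"])
  expect_equal(scr$retained[scr$covariate == "grp"],
               scr$p_value[scr$covariate == "grp"] < 0.2)
})

test_that("backward AIC selection recovers noise-free coefficients exactly", {
  set.seed(2)
  n <- 60
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$y <- 3 + 1.5 * dat$x1 - 2 * dat$x2  # exact linear, no noise
  # R warns about selection on a perfect fit; exactness is the point here
  mod <- suppressWarnings(backward_aic(dat, "y", c("x1", "x2", "x3")))
  expect_setequal(mod$retained, c("x1", "x2"))
  cf <- mod$coefficients
  expect_equal(cf$estimate[cf$term == "x1"], 1.5, tolerance = 1e-9)
  expect_equal(cf$estimate[cf$term == "x2"], -2, tolerance = 1e-9)
  expect_true(all(cf$conf_low <= cf$estimate & cf$estimate <= cf$conf_high))
})

test_that("backward AIC matches stats::step and prefers dropping weak signals", {
  set.seed(11)
  for (i in 1:8) {
    n <- 120
    dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      x4 = rnorm(n))
    dat$y <- 0.8 * dat$x1 + rnorm(n)
    mod <- backward_aic(dat, "y", paste0("x", 1:4))
    ref <- stats::step(lm(y ~ x1 + x2 + x3 + x4, data = dat),
                       direction = "backward", trace = 0)
    expect_setequal(mod$retained, attr(terms(ref), "term.labels"))
  }

  # a zero-effect covariate is usually removed (AIC penalty)
  set.seed(12)
  drops <- replicate(40, {
    dat <- data.frame(x = rnorm(400))
    dat$y <- rnorm(400)
    length(backward_aic(dat, "y", "x")$retained) == 0
  })
  expect_gt(mean(drops), 0.5)
})

test_that("perfectly collinear covariates are removed before selection", {
  set.seed(9)
  dat <- data.frame(x1 = rnorm(50))
  dat$x2 <- 2 * dat$x1
  dat$y <- dat$x1 + rnorm(50, sd = 0.1)
  expect_warning(mod <- backward_aic(dat, "y", c("x1", "x2")), "collinear")
  expect_length(mod$retained, 1L)
})
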