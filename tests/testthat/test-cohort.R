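test_that("large cohorts match the configured covariate distributions", {
  cfg <- generator_config(n_participants = 4000, rng_seed = 42)
  cov <- sample_covariates(cfg)
  expect_equal(nrow(cov), 4000L)
  expect_lt(abs(mean(cov$age) - 51.65), 0.5)
  props <- as.numeric(table(cov$bmi_category) / nrow(cov))
  expect_true(all(abs(props - c(0.30, 0.40, 0.30)) < 0.02))
  expect_true(all(cov$age >= 27 & cov$age <= 68))
  expect_true(all(cov$asir_self_evaluation >= 1.25 &
                    cov$asir_self_evaluation <= 4.50))
  expect_true(all(cov$breastq_breast >= 35.75 & cov$breastq_breast <= 74))
})

test_that("sampling is deterministic and stable under cohort subsetting", {
  cfg1 <- generator_config(n_participants = 1, rng_seed = 9)
  expect_identical(sample_covariates(cfg1), sample_covariates(cfg1))

  cfg10 <- generator_config(n_participants = 10, rng_seed = 9)
  cfg5 <- generator_config(n_participants = 5, rng_seed = 9)
  big <- sample_covariates(cfg10)
  small <- sample_covariates(cfg5)
  expect_identical(big[1:5, ], small)

  other <- sample_covariates(cfg10, seed = 10)
  expect_false(identical(big, other))
})

test_that("zero-SD continuous covariates collapse to their means", {
  spec <- default_covariate_spec()
  for (nm in names(spec)) {
    if (identical(spec[[nm]]$type, "continuous")) spec[[nm]]$sd <- 0
  }
  cov <- sample_covariates(generator_config(n_participants = 6,
                                            covariates = spec))
  expect_true(all(cov$age == 51.65))
  expect_true(all(cov$breastq_outcome == 57.99))
})

test_that("degenerate generator reproduces base utilities and orderings", {
  cfg <- noiseless_config(n_participants = 5, effects = zero_effects())
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  base <- default_base_utilities()
  for (p in profs) {
    expect_equal(p$utilities[names(base)], base)
    expect_identical(unname(p$utilities["death"]), 0)
    for (m in c("implant", "tissue")) {
      u <- p$utilities[paste(m, c("excellent", "good", "fair", "poor"),
                             sep = "_")]
      expect_true(all(diff(u) < 0))  # strict quality ordering
      expect_true(all(u > p$utilities["none"]))
    }
  }
})

test_that("latent utilities stay in [0,1] and effects carry their signs", {
  cfg <- generator_config(n_participants = 1200, rng_seed = 17)
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  tbl <- profiles_to_table(profs)
  expect_true(all(tbl$latent_utility >= 0 & tbl$latent_utility <= 1))
  expect_true(all(tbl$latent_utility[tbl$state_id == "death"] == 0))

  sc <- latent_group_scores(profs)
  sc$bmi <- cov$bmi_category[match(sc$participant_id, cov$participant_id)]
  obese <- sc$bmi == "obese"
  normal <- sc$bmi == "normal"
  expect_lt(mean(sc$implant[obese]), mean(sc$implant[normal]))
  expect_gt(mean(sc$tissue[obese]), mean(sc$tissue[normal]))
})

test_that("forced unexpected rankings break a quality ordering every time", {
  cfg <- noiseless_config(n_participants = 60,
                          unexpected_rank_fraction = 1,
                          equipoise_fraction = 0,
                          effects = zero_effects())
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  violated <- vapply(profs, function(p) {
    any(vapply(c("implant", "tissue"), function(m) {
      u <- p$utilities[paste(m, c("excellent", "good", "fair", "poor"),
                             sep = "_")]
      any(diff(u) > 0)
    }, logical(1)))
  }, logical(1))
  expect_true(all(violated))
  expect_true(all(vapply(profs, function(p) p$unexpected, logical(1))))
})

test_that("effects referencing unknown covariates or levels are rejected", {
  bad <- tibble::tibble(covariate = "shoe_size", level = NA_character_,
                        group = "any", effect = 1)
  expect_error(generator_config(effects = bad), "shoe_size")
  bad2 <- tibble::tibble(covariate = "bmi_category", level = "giant",
                         group = "any", effect = 1)
  expect_error(generator_config(effects = bad2), "level")
  bad3 <- tibble::tibble(covariate = "age", level = NA_character_,
                         group = "everything", effect = 1)
  expect_error(generator_config(effects = bad3), "group")
})

test_that("a single large cohort recovers the generating coefficients", {
  cfg <- generator_config(n_participants = 2000, rng_seed = 23)
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  sc <- latent_group_scores(profs)
  dat <- dplyr::inner_join(sc, cov, by = "participant_id")
  m <- lm(implant ~ breastq_breast + asir_behavior + asir_self_evaluation +
            bmi_category, data = dat)
  ci <- confint(m)
  expect_true(ci["breastq_breast", 1] <= 0.46 &&
                0.46 <= ci["breastq_breast", 2])
  expect_true(ci["bmi_categoryobese", 1] <= -16.15 &&
                -16.15 <= ci["bmi_categoryobese", 2])
  expect_true(ci["asir_self_evaluation", 1] <= -6.96 &&
                -6.96 <= ci["asir_self_evaluation", 2])
})

test_that("profile tables round-trip through their long format", {
  cfg <- generator_config(n_participants = 7, rng_seed = 3)
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  back <- profiles_from_table(profiles_to_table(profs))
  expect_equal(length(back), 7L)
  for (i in seq_along(profs)) {
    expect_equal(back[[i]]$utilities, profs[[i]]$utilities)
    expect_equal(back[[i]]$latent_index, profs[[i]]$latent_index)
  }
})
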