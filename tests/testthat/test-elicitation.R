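test_that("the noiseless respondent follows expected utility with ties to certainty", {
  pr <- three_state_profile(0, 0.95, 1)
  offer <- function(p) gamble_offer("mid", "best", "worst", p)
  expect_equal(respond(offer(1.0), pr), "gamble")     # 1.00 > 0.95
  expect_equal(respond(offer(0.90), pr), "certainty") # 0.90 < 0.95
  expect_equal(respond(offer(0.95), pr), "certainty") # exact indifference

  expect_error(respond(gamble_offer("mid", "best", "nowhere", 0.5), pr),
               "nowhere")
  expect_error(gamble_offer("mid", "mid", "worst", 0.5), "differ")
  expect_error(gamble_offer("mid", "best", "worst", 1.2), "probability")
})

test_that("choice probabilities converge to the deterministic rule as noise vanishes", {
  freqs <- sapply(c(0.2, 0.02, 0.002), function(tau) {
    pr <- three_state_profile(0, 0.90, 1)
    pr$choice_noise <- tau
    set.seed(99)
    mean(replicate(300, respond(gamble_offer("mid", "best", "worst", 1), pr))
         == "gamble")
  })
  # deterministic choice at p_best = 1 is "gamble" (du = +0.10)
  expect_true(all(diff(freqs) >= 0))
  expect_equal(freqs[3], 1)
  expect_gt(freqs[1], 0.5)
})

test_that("titration brackets the indifference point at half a step", {
  pr <- three_state_profile(0, 0.93, 1)
  tr <- titrate(pr, "mid", "best", "worst", step = 0.05)
  expect_equal(tr$offers$p_best, c(1.00, 0.95, 0.90))
  expect_equal(tr$offers$choice, c("gamble", "gamble", "certainty"))
  expect_equal(tr$p_indifference, 0.925)
  expect_equal(tr$degenerate, "none")

  tr2 <- titrate(three_state_profile(0, 0.999, 1), "mid", "best", "worst",
                 step = 0.05)
  expect_equal(tr2$p_indifference, 0.975)

  # brute force over a grid of relative utilities and step sizes
  for (s in c(0.05, 0.07, 0.1, 0.25)) {
    for (v in seq(0.013, 0.987, length.out = 41)) {
      tr <- titrate(three_state_profile(0, v, 1), "mid", "best", "worst",
                    step = s)
      expect_lte(abs(tr$p_indifference - v), s / 2 + 1e-9)
      expect_true(tr$p_indifference >= tr$p_low - 1e-12 &&
                    tr$p_indifference <= tr$p_high + 1e-12)
      expect_true(all(diff(tr$offers$p_best) < 0))
      expect_lte(sum(tr$offers$choice == "certainty"), 1L)
    }
  }
})

test_that("degenerate titrations are flagged and assigned boundary midpoints", {
  # certainty at the very first offer: certain state at least as good as best
  hi <- latent_profile(c(worst = 0, mid = 0.8, best = 0.8, death = 0))
  tr <- titrate(hi, "mid", "best", "worst", step = 0.05)
  expect_equal(tr$degenerate, "high")
  expect_equal(tr$p_indifference, 0.975)

  # never switches: certain state worse than the worst gamble arm
  lo <- latent_profile(c(worst = 0.5, mid = 0.3, best = 1, death = 0))
  tr2 <- titrate(lo, "mid", "best", "worst", step = 0.05)
  expect_equal(tr2$degenerate, "low")
  expect_equal(tr2$p_indifference, 0.025)

  expect_error(titrate(hi, "mid", "best", "worst", step = 0.3), "step")
  expect_error(titrate(hi, "mid", "best", "worst", step = 0), "step")
})

test_that("chain_utility reproduces the two-stage composition", {
  expect_equal(chain_utility(1.0, 0.37), 1.0)
  expect_equal(chain_utility(0.0, 0.86), 0.86)
  expect_equal(chain_utility(0.95, 0.80), 0.99)
  expect_error(chain_utility(-0.1, 0.5), "probabilities")
  expect_error(chain_utility(0.5, 1.3), "probabilities")

  # equals p1 * u(best) + (1 - p1) * u(worst) with u(best)=1, u(worst)=p2
  p1 <- runif(20); p2 <- runif(20)
  expect_equal(chain_utility(p1, p2), p1 * 1 + (1 - p1) * p2)
})

test_that("elicited utilities converge to rescaled latent utilities as the step shrinks", {
  base <- default_base_utilities()
  pr <- deck_profile(base)
  truth <- base / max(base)
  errs <- sapply(c(0.05, 0.01, 0.002), function(s) {
    rec <- elicit_participant(pr, health_states(TRUE), step = s)$records
    max(abs(rec$utility - truth[rec$state_id]))
  })
  expect_true(all(errs <= c(0.05, 0.01, 0.002) + 1e-9))
  expect_true(all(diff(errs) < 0))
})

test_that("all-tied profiles elicit degenerate traces without crashing", {
  pr <- latent_profile(setNames(c(rep(0.9, 9), 0),
                                c(health_states(FALSE)$state_id, "death")))
  res <- elicit_participant(pr, health_states(TRUE), step = 0.05)
  expect_equal(nrow(res$records), 9L)
  inter <- res$records[!is.na(res$records$p1), ]
  expect_true(all(inter$degenerate != "none"))
  expect_true(all(res$records$utility >= 0 & res$records$utility <= 1))
})

test_that("elicitation requires a death anchor and enough states", {
  pr <- deck_profile(default_base_utilities())
  expect_error(elicit_participant(pr, health_states(FALSE)), "death")
})

test_that("cohort elicitation is reproducible and respects utility bounds", {
  cfg <- generator_config(n_participants = 12, rng_seed = 5)
  cov <- sample_covariates(cfg)
  profs <- generate_latent_profiles(cov, cfg)
  a <- elicit_cohort(profs, step = 0.05, seed = 5)$records
  b <- elicit_cohort(profs, step = 0.05, seed = 5)$records
  expect_identical(a, b)
  expect_equal(nrow(a), 12L * 9L)
  expect_true(all(a$utility >= 0 & a$utility <= 1))
  expect_true(all(a$utility >= a$p2 - 1e-12))  # weakly ordered vs the anchor
})
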