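test_that("choice datasets flag one outcome per trial and log exclusions", {
  ev <- simulate_trials(sim_config(n_trials = 74, seed = 2))
  s <- score_trials(ev)
  cd <- build_choice_data(s, "attempt")
  n_kept <- dplyr::n_distinct(cd$trial_id)
  expect_equal(nrow(cd), 4 * n_kept)
  expect_equal(sum(cd$choice), n_kept)
  expect_equal(n_kept + attr(cd, "n_excluded"), 74)
  expect_true(all(tapply(cd$choice, cd$trial_id, sum) == 1))

  # a trial in which nothing was attempted is excluded with a count
  s2 <- score_trial(empty_trial(), trial_id = "E1") |>
    dplyr::bind_rows(score_trial(trial_log(
      list(1, "ATTEMPT", "bread"), list(2, "CHOICE", "bread"),
      trial_id = "K1"
    )))
  cd2 <- build_choice_data(s2, "attempt")
  expect_equal(attr(cd2, "n_excluded"), 1L)
  expect_equal(unique(cd2$trial_id), "K1")

  # ... and for the choice set, a trial where nothing was eaten
  cd3 <- build_choice_data(
    dplyr::mutate(s2, fc = ifelse(trial_id == "K1", 1L, fc)), "choice"
  )
  expect_equal(attr(cd3, "n_excluded"), 2L)

  # two foods sharing the top score is malformed
  bad <- s2
  bad$fa[bad$trial_id == "K1"] <- c(5L, 5L, 1L, 1L)
  expect_error(build_choice_data(bad, "attempt"), "share the top")
})

test_that("the conditional-logit likelihood matches closed forms", {
  cd <- choice_data_from_counts(c(10, 5, 3, 2))
  n <- sum(c(10, 5, 3, 2))
  expect_equal(mlogit_loglik(rep(0, 3), cd), n * log(1 / 4))

  # single trial, utilities (log 2, 0, 0, 0), outcome = bread
  cd1 <- choice_data_from_counts(c(1, 0, 0, 0))
  # reference peanuts so bread has a free contrast
  expect_equal(
    mlogit_loglik(c(log(2), 0, 0), cd1, reference = "peanuts"),
    log(2 / 5)
  )
  expect_error(mlogit_loglik(rep(0, 5), cd1), "length")
})

test_that("symmetric choice counts give zero contrasts", {
  fit <- fit_mlogit(choice_data_from_counts(c(25, 25, 25, 25)))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), rep(0, 3), tolerance = 1e-8)
  expect_equal(fit$loglik, 100 * log(1 / 4))
})

test_that("ASC-only maximum likelihood equals log count ratios", {
  # the worked case: counts (40, 20, 20, 20) with reference brinjal
  fit <- fit_mlogit(choice_data_from_counts(c(40, 20, 20, 20)),
                    reference = "brinjal")
  expect_equal(coef(fit)[["bread"]], log(40 / 20), tolerance = 1e-6)

  # property: random all-positive count configurations
  for (seed in 1:8) {
    counts <- withr::with_seed(seed, sample(1:40, 4, replace = TRUE))
    fit <- fit_mlogit(choice_data_from_counts(counts))
    expect_true(fit$converged)
    expect_equal(
      unname(coef(fit)[food_names()[-1]]),
      log(counts[-1] / counts[1]),
      tolerance = 1e-6
    )
    # fitted shares equal empirical shares
    expect_equal(unname(choice_shares(fit)), counts / sum(counts),
                 tolerance = 1e-6)
    # the MLE dominates the equal-shares null
    expect_gte(fit$loglik, fit$loglik_null)
  }
})

test_that("Newton-Raphson matches a dense likelihood grid on small problems", {
  foods3 <- c("a", "b", "c")
  grid_mle <- function(counts) {
    # independent oracle: brute-force over contrasts in [-3, 3], step 0.01
    b <- seq(-3, 3, by = 0.01)
    gg <- expand.grid(b1 = b, b2 = b)
    ll <- counts[2] * gg$b1 + counts[3] * gg$b2 -
      sum(counts) * log(1 + exp(gg$b1) + exp(gg$b2))
    unlist(gg[which.max(ll), ])
  }
  for (counts in list(c(3, 2, 1), c(2, 2, 2), c(4, 1, 1), c(1, 2, 3))) {
    cd <- choice_data_from_counts(counts, foods = foods3)
    fit <- fit_mlogit(cd, reference = "a")
    expect_true(fit$converged)
    oracle <- grid_mle(counts)
    expect_lt(max(abs(unname(coef(fit)) - unname(oracle))), 0.02)
  }
})

test_that("the fit agrees with an independent multinomial regression", {
  skip_if_not_installed("nnet")
  ev <- simulate_trials(sim_config(n_trials = 200, seed = 13))
  cd <- build_choice_data(score_trials(ev), "attempt")
  fit <- fit_mlogit(cd)
  chosen <- factor(cd$food[cd$choice == 1], levels = food_names())
  ref <- nnet::multinom(chosen ~ 1, trace = FALSE, reltol = 1e-12)
  expect_equal(unname(coef(fit)), as.numeric(coef(ref)), tolerance = 1e-4)
})

test_that("a never-chosen alternative is reported as separation", {
  expect_warning(
    fit <- fit_mlogit(choice_data_from_counts(c(5, 5, 0, 5))),
    "separation"
  )
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_error(loco_report(fit), "non-converged")
})

test_that("alternative-varying covariates enter the model", {
  ev <- simulate_trials(sim_config(n_trials = 120, seed = 19))
  cd <- build_choice_data(score_trials(ev), "choice")
  asc <- fit_mlogit(cd)
  full <- fit_mlogit(cd, covariates = c("rj", "delay_score"))
  expect_true(full$converged)
  expect_true(all(is.finite(coef(full))))
  expect_named(coef(full), c("brinjal", "cauliflower", "peanuts",
                             "rj", "delay_score"))
  expect_gte(full$loglik, asc$loglik)  # nested models
  # heavy rejection loads against being the eaten-first food
  expect_lt(coef(full)[["rj"]], 0)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_mlogit(choice_data_from_counts(c(30, 20, 15, 10)))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_equal(td$p.value, 2 * pnorm(-abs(td$statistic)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 75)
})
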