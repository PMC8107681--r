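make_scores <- function(fa, fc, rj, ag, delay_score) {
  tibble::tibble(
    trial_id = sprintf("T%03d", seq_along(fa)),
    food = rep(food_names(), length.out = length(fa)),
    fa = fa, fc = fc, rj = rj, ag = ag, delay_score = delay_score
  )
}

test_that("correlations follow the product-moment formula", {
  s <- make_scores(
    fa = c(1, 2, 3, 4), fc = c(2, 4, 6, 8), rj = c(4, 3, 2, 1),
    ag = c(0, 1, 0, 1), delay_score = c(1, 3, 2, 5)
  )
  cm <- corr_matrix(s)
  get_r <- function(a, b) cm$r[cm$var1 == a & cm$var2 == b]
  expect_equal(get_r("fa", "fa"), 1)          # identity
  expect_equal(get_r("fa", "fc"), 1)          # exact linearity
  expect_equal(get_r("fa", "rj"), -1)         # x vs -x
  expect_equal(cm$p[cm$var1 == "fa" & cm$var2 == "fc"], 0)
  # symmetry with unit diagonal
  for (i in seq_len(nrow(cm))) {
    expect_equal(cm$r[i], get_r(cm$var2[i], cm$var1[i]))
  }
  # p-values match the classical t-test route
  r <- get_r("fa", "delay_score")
  ct <- stats::cor.test(s$fa, s$delay_score)
  expect_equal(r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p[cm$var1 == "fa" & cm$var2 == "delay_score"],
               ct$p.value, tolerance = 1e-12)
})

test_that("zero-variance descriptors yield NA correlations with a warning", {
  s <- make_scores(
    fa = c(1, 2, 3, 5), fc = c(2, 4, 3, 8), rj = c(4, 3, 2, 1),
    ag = c(0, 0, 0, 0), delay_score = c(1, 3, 2, 5)
  )
  expect_warning(cm <- corr_matrix(s), "zero-variance")
  expect_true(all(is.na(cm$r[cm$var1 == "ag"])))
  expect_false(anyNA(cm$r[cm$var1 != "ag" & cm$var2 != "ag"]))
})

test_that("per-food correlation matrices are computed on subsets", {
  ev <- simulate_trials(sim_config(n_trials = 60, seed = 31))
  s <- score_trials(ev)
  cm <- suppressWarnings(corr_matrix(s, by_food = TRUE))
  expect_true("food" %in% names(cm))
  expect_setequal(unique(cm$food), food_names())
  expect_equal(nrow(cm), 4 * 25)
})

test_that("Poisson IRLS recovers closed-form fits", {
  # intercept-only: the MLE of a constant mean is log(mean(y))
  fit0 <- fit_poisson_glm(tibble::tibble(fc = c(1, 2, 3)),
                          predictors = character())
  expect_equal(unname(coef(fit0)), log(2), tolerance = 1e-10)

  # constant unit response: zero slopes and zero intercept
  s1 <- make_scores(
    fa = c(1, 2, 3, 4, 5, 2), fc = rep(1, 6), rj = c(0, 1, 2, 0, 1, 3),
    ag = c(0, 1, 0, 1, 0, 0), delay_score = c(0, 1, 2, 3, 4, 5)
  )
  fit1 <- fit_poisson_glm(s1)
  expect_equal(unname(coef(fit1)), rep(0, 5), tolerance = 1e-8)

  # validation
  expect_error(
    fit_poisson_glm(dplyr::mutate(s1, fc = fc + 0.5)), "nonnegative integers"
  )
  expect_error(
    fit_poisson_glm(dplyr::mutate(s1, rj = fa), ), "rank-deficient"
  )
})

test_that("the Poisson fit matches the reference GLM implementation", {
  for (seed in 1:20) {
    s <- score_trials(simulate_trials(sim_config(n_trials = 30, seed = seed)))
    fit <- fit_poisson_glm(s)
    ref <- stats::glm(fc ~ fa + rj + delay_score + ag, data = s,
                      family = stats::poisson(),
                      control = stats::glm.control(epsilon = 1e-14))
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-6)
    expect_equal(unname(residuals(fit)),
                 unname(stats::residuals(ref, type = "deviance")),
                 tolerance = 1e-6)
    expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
  }
})

test_that("PCA eigenstructure matches two-variable closed forms", {
  # sample correlation exactly 0.8 by construction
  x <- rep(c(1, -1), 10)
  z <- rep(c(1, 1, -1, -1), 5)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * z
  d <- tibble::tibble(a = x, b = y)
  pca <- pca_descriptors(d, cols = c("a", "b"))
  expect_equal(pca$proportion, c(0.9, 0.1), tolerance = 1e-12)

  # perfectly correlated pair: rank 1
  d2 <- tibble::tibble(a = x, b = 2 * x)
  pca2 <- pca_descriptors(d2, cols = c("a", "b"))
  expect_equal(pca2$proportion, c(1, 0), tolerance = 1e-12)
})

test_that("PCA bookkeeping and reconstruction hold on simulated scores", {
  s <- score_trials(simulate_trials(sim_config(n_trials = 80, seed = 41)))
  for (mode in c("correlation", "covariance")) {
    pca <- pca_descriptors(s, mode = mode)
    expect_equal(sum(pca$proportion), 1, tolerance = 1e-9)
    expect_true(all(diff(pca$cumulative) >= -1e-12))
    expect_equal(pca$cumulative[5], 1, tolerance = 1e-9)
    # orthonormal loadings and spectral reconstruction of the input matrix
    expect_equal(crossprod(pca$loadings), diag(5), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(
      pca$loadings %*% diag(pca$eigenvalues) %*% t(pca$loadings),
      pca$matrix, tolerance = 1e-9, ignore_attr = TRUE
    )
    # sign convention: dominant loading of each component is positive
    for (j in 1:5) {
      expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
    }
  }
  # eigenvalues agree with the standard PCA route
  pr <- stats::prcomp(
    as.matrix(as.data.frame(s)[, c("fa", "fc", "rj", "ag", "delay_score")]),
    scale. = TRUE
  )
  expect_equal(pca_descriptors(s)$eigenvalues, unname(pr$sdev^2),
               tolerance = 1e-9)

  # zero-variance column is refused by name in correlation mode
  s0 <- dplyr::mutate(s, ag = 0L)
  expect_error(pca_descriptors(s0), "ag")
})

test_that("chi-square statistics follow the Pearson formulas", {
  ct <- chi_square_contingency(rbind(c(10, 0), c(0, 10)))
  expect_equal(ct$statistic, 20)
  expect_equal(ct$df, 1)
  expect_equal(ct$p.value,
               stats::pchisq(20, 1, lower.tail = FALSE))

  # identical rows: exact independence
  expect_equal(chi_square_contingency(rbind(c(5, 15), c(5, 15)))$statistic, 0)
  expect_error(chi_square_contingency(matrix(5)), "2x2")
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))), "margin")

  # agreement with the uncorrected classical test
  tab <- rbind(c(83, 17), c(16, 84), c(18, 82))
  ref <- stats::chisq.test(tab, correct = FALSE)
  got <- chi_square_contingency(tab)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("goodness-of-fit chi-square compares counts to proportions", {
  expect_equal(chi_square_gof(c(10, 10, 10, 10))$statistic, 0)
  g <- chi_square_gof(c(20, 0), c(0.5, 0.5))
  expect_equal(g$statistic, 20)
  expect_equal(g$df, 1)
  expect_error(chi_square_gof(c(1, 2), c(0.5, 0.6)), "sum to 1")
  expect_error(chi_square_gof(c(1, 2, 3), c(0.5, 0.5)), "same length")

  obs <- c(31, 32, 23, 14)
  ref <- stats::chisq.test(obs, p = rep(0.25, 4))
  got <- chi_square_gof(obs)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("default-config replicates reproduce the qualitative GLM signs", {
  # FA positive, RJ negative, delay negative on final choice
  signs <- vapply(1:100, function(seed) {
    s <- score_trials(simulate_trials(sim_config(seed = seed)))
    co <- coef(fit_poisson_glm(s))
    c(co[["fa"]] > 0, co[["rj"]] < 0, co[["delay_score"]] < 0)
  }, logical(3))
  expect_gte(sum(colSums(signs) == 3), 90)
})
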