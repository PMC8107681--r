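descriptor_cols <- function() c("fa", "fc", "rj", "ag", "delay_score")

get_descriptor_matrix <- function(scores, cols = descriptor_cols()) {
  stopifnot(is.data.frame(scores))
  miss <- setdiff(cols, names(scores))
  if (length(miss) > 0L) {
    abort(paste0("missing descriptor column(s): ", paste(miss, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(scores)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("descriptor matrix must have no missing cells")
  m
}

#' Pairwise Pearson correlations of the descriptor scores
#'
#' Product-moment correlations between the five per-food descriptors
#' (FA, FC, RJ, AG, delay score) across all trial-by-food observations,
#' with two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' With `by_food = TRUE` the matrix is computed within each food subset
#' (the per-food correlogram presentation). P-values are unadjusted by
#' default; `adjust = "holm"` applies a Holm correction across the
#' distinct pairs.
#'
#' @param scores A score table ([score_trials()]).
#' @param by_food Compute separately within each food?
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble with columns `var1, var2, r, p` (plus `food` when
#'   `by_food`), covering all ordered pairs including the unit diagonal.
#'   A zero-variance column yields `NA` correlations with a warning.
#' @examples
#' cfg <- sim_config(n_trials = 30, seed = 4)
#' corr_matrix(score_trials(simulate_trials(cfg)))
#' @export
corr_matrix <- function(scores, by_food = FALSE, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (by_food) {
    parts <- split(as_tibble(scores), scores$food)
    return(bind_rows(lapply(names(parts), function(f) {
      tibble(food = f, corr_matrix(parts[[f]], FALSE, adjust))
    })))
  }
  m <- get_descriptor_matrix(scores)
  n <- nrow(m)
  if (n < 3L) abort("need at least 3 observations")
  cols <- colnames(m)
  vars <- apply(m, 2L, stats::var)
  if (any(vars == 0)) {
    warn(paste0("zero-variance column(s): ",
                paste(cols[vars == 0], collapse = ", "),
                "; correlations reported as NA"))
  }
  grid <- expand.grid(var1 = cols, var2 = cols,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rp <- purrr::pmap(grid, function(var1, var2) {
    x <- m[, var1]; y <- m[, var2]
    if (vars[var1] == 0 || vars[var2] == 0) {
      return(c(NA_real_, NA_real_))
    }
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r <- max(-1, min(1, r))
    p <- if (abs(r) == 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tt), df = n - 2)
    }
    c(r, p)
  })
  out <- tibble(
    var1 = grid$var1, var2 = grid$var2,
    r = purrr::map_dbl(rp, 1L), p = purrr::map_dbl(rp, 2L)
  )
  if (adjust == "holm") {
    off <- out$var1 < out$var2  # each unordered pair once
    adj <- stats::p.adjust(out$p[off], method = "holm")
    key <- ifelse(out$var1 < out$var2,
                  paste(out$var1, out$var2), paste(out$var2, out$var1))
    lut <- setNames(adj, key[off])
    out$p <- ifelse(out$var1 == out$var2, out$p, lut[key])
  }
  out
}

#' Poisson regression of final choice on the other descriptors
#'
#' Log-link Poisson GLM with the FC score as response and FA, RJ, delay
#' score and AG as predictors, fitted by iteratively reweighted least
#' squares (IRLS) from a zero start until the deviance changes by less
#' than `tol`. Wald z and two-sided p-values per coefficient; deviance
#' residuals are exposed for the usual residual-distribution check of
#' model fit.
#'
#' @param scores A score table ([score_trials()]), or any data frame
#'   holding the response and predictor columns.
#' @param response Response column (default `"fc"`); must be nonnegative
#'   integers.
#' @param predictors Predictor columns (default FA, RJ, delay, AG).
#' @param tol Deviance-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `poisson_glm_fit` with `coefficients`,
#'   `se`, `z`, `p`, `vcov`, `deviance`, `null_deviance`, `loglik`,
#'   `fitted`, `residuals` (deviance scale), `iterations`, `converged`.
#'   Supports [tidy()], [glance()], `residuals()`.
#' @examples
#' cfg <- sim_config(n_trials = 40, seed = 8)
#' fit <- fit_poisson_glm(score_trials(simulate_trials(cfg)))
#' tidy(fit)
#' @export
fit_poisson_glm <- function(scores, response = "fc",
                            predictors = c("fa", "rj", "delay_score", "ag"),
                            tol = 1e-10, max_iter = 100L) {
  df <- as.data.frame(scores)
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  y <- df[[response]]
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y))) {
    abort("response must be nonnegative integers for a Poisson model")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  if (qr(X)$rank < ncol(X)) {
    abort("rank-deficient design: predictors are linearly dependent")
  }

  dev_fun <- function(y, mu) {
    r <- mu - y
    lg <- y > 0
    r[lg] <- y[lg] * log(y[lg] / mu[lg]) - (y[lg] - mu[lg])
    2 * sum(r)
  }

  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  dev <- dev_fun(y, mu)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu
    zz <- eta + (y - mu) / mu
    fit <- lm.wfit(X, zz, w)
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    dev_new <- dev_fun(y, mu)
    if (abs(dev_new - dev) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  info <- crossprod(X, mu * X)
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  z <- beta / se
  dres <- sign(y - mu) * sqrt(pmax(0, 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                                             (y - mu))))
  mu0 <- mean(y)
  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      se = setNames(se, colnames(X)),
      z = setNames(z, colnames(X)),
      p = setNames(2 * pnorm(-abs(z)), colnames(X)),
      vcov = vcov,
      deviance = dev,
      null_deviance = dev_fun(y, rep(mu0, length(y))),
      loglik = sum(stats::dpois(y, mu, log = TRUE)),
      fitted = mu,
      residuals = dres,
      n = length(y),
      iterations = iter,
      converged = converged
    ),
    class = "poisson_glm_fit"
  )
}

#' @export
print.poisson_glm_fit <- function(x, ...) {
  cat("Poisson GLM (log link), n =", x$n,
      "; deviance =", format(x$deviance, digits = 6), "\n")
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.poisson_glm_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p)
  )
}

#' @exportS3Method generics::glance
glance.poisson_glm_fit <- function(x, ...) {
  tibble(
    deviance = x$deviance, null.deviance = x$null_deviance,
    logLik = x$loglik, nobs = x$n,
    iterations = x$iterations, converged = x$converged
  )
}

#' @export
residuals.poisson_glm_fit <- function(object, ...) object$residuals

#' Principal component analysis of the descriptor scores
#'
#' Eigendecomposition of the correlation (default) or covariance matrix
#' of the five descriptors. Components are ordered by descending
#' eigenvalue; the sign of each loading vector is fixed so its
#' largest-magnitude entry is positive. The descriptors sit on
#' heterogeneous ordinal scales, which is why the correlation matrix is
#' the default; covariance mode is retained for unstandardised analyses.
#'
#' @param scores A score table ([score_trials()]).
#' @param mode `"correlation"` or `"covariance"`.
#' @param cols Columns to analyse (default the five descriptors).
#' @return An object of class `descriptor_pca` with `eigenvalues`,
#'   `proportion`, `cumulative`, `loadings` (descriptor x component),
#'   `scores` (observation x component), `mode`, and the analysed
#'   `matrix`. Supports [tidy()], [glance()] and [ggplot2::autoplot()]
#'   (biplot).
#' @examples
#' cfg <- sim_config(n_trials = 40, seed = 6)
#' pca <- pca_descriptors(score_trials(simulate_trials(cfg)))
#' tidy(pca)
#' @export
pca_descriptors <- function(scores, mode = c("correlation", "covariance"),
                            cols = descriptor_cols()) {
  mode <- match.arg(mode)
  m <- get_descriptor_matrix(scores, cols)
  if (nrow(m) < 2L) abort("need at least 2 observations")
  vars <- apply(m, 2L, stats::var)
  if (mode == "correlation" && any(vars == 0)) {
    abort(paste0("zero-variance column(s) in correlation mode: ",
                 paste(colnames(m)[vars == 0], collapse = ", ")))
  }
  S <- if (mode == "correlation") stats::cor(m) else stats::cov(m)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(m), paste0("PC", seq_len(ncol(vecs))))
  ctr <- scale(m, center = TRUE,
               scale = if (mode == "correlation") apply(m, 2L, stats::sd)
                       else FALSE)
  structure(
    list(
      eigenvalues = vals,
      proportion = vals / sum(vals),
      cumulative = cumsum(vals / sum(vals)),
      loadings = vecs,
      scores = ctr %*% vecs,
      matrix = S,
      mode = mode
    ),
    class = "descriptor_pca"
  )
}

#' @export
print.descriptor_pca <- function(x, ...) {
  cat("PCA of descriptors (", x$mode, " matrix)\n", sep = "")
  tab <- rbind(`Proportion of Variance` = x$proportion,
               `Cumulative proportion` = x$cumulative)
  colnames(tab) <- colnames(x$loadings)
  print(round(tab, 3))
  cat("Loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.descriptor_pca <- function(x, ...) {
  tibble(
    component = colnames(x$loadings),
    eigenvalue = x$eigenvalues,
    proportion = x$proportion,
    cumulative = x$cumulative
  )
}

#' @exportS3Method generics::glance
glance.descriptor_pca <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_components = length(x$eigenvalues),
    pc1_proportion = x$proportion[1L]
  )
}

#' Pearson chi-square test of independence for a contingency table
#'
#' The classic Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the row/column margins, `df = (r - 1)(c - 1)` and the
#' upper chi-square tail; no continuity correction is applied.
#'
#' @param table A numeric matrix (or table) of counts, at least 2x2.
#' @return A one-row tibble `statistic, df, p.value`.
#' @examples
#' chi_square_contingency(rbind(c(10, 0), c(0, 10)))
#' @export
chi_square_contingency <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0) || anyNA(O)) abort("counts must be nonnegative")
  if (nrow(O) < 2L || ncol(O) < 2L) {
    abort("contingency table must be at least 2x2")
  }
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) abort("zero row/column margin")
  E <- outer(rs, cs) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  tibble(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Pearson chi-square goodness-of-fit test
#'
#' Compares observed counts to expected proportions: the expected count
#' of class k is `proportion_k * sum(observed)`; `df = k - 1`.
#'
#' @param observed Nonnegative counts.
#' @param expected Expected proportions, summing to 1 (uniform by
#'   default).
#' @return A one-row tibble `statistic, df, p.value`.
#' @examples
#' chi_square_gof(c(20, 0), c(0.5, 0.5))
#' @export
chi_square_gof <- function(observed,
                           expected = rep(1 / length(observed),
                                          length(observed))) {
  if (length(observed) != length(expected)) {
    abort("observed and expected must have the same length")
  }
  if (any(observed < 0)) abort("observed counts must be nonnegative")
  if (abs(sum(expected) - 1) > 1e-8) {
    abort("expected proportions must sum to 1")
  }
  E <- expected * sum(observed)
  if (any(E <= 0)) abort("all expected counts must be positive")
  stat <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  tibble(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}
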