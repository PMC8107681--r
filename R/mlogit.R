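#' Build a choice dataset from a score table
#'
#' Expands a score table into the long one-row-per-trial-per-alternative
#' form used by the multinomial logit models. The outcome flags the food
#' that carries the top ordinal score of the requested stage: FA = 5 for
#' the `"attempt"` set (which food was reached for first) or FC = 5 for
#' the `"choice"` set (which food was eaten first). Trials in which no
#' food was attempted (or eaten, for the choice set) carry no outcome and
#' are dropped; the number dropped is recorded in the `n_excluded`
#' attribute. Alternatives are enumerated in the fixed tray order with
#' equal availability in every trial.
#'
#' @param scores A score table from [score_trials()].
#' @param stage `"attempt"` or `"choice"`.
#' @param foods Food vocabulary (fixed alternative order).
#' @return A tibble with columns `trial_id, food, choice` (0/1, exactly
#'   one 1 per trial) and the descriptor columns carried through;
#'   attributes `stage`, `foods`, `n_excluded`.
#' @examples
#' cfg <- sim_config(n_trials = 10, seed = 2)
#' scores <- score_trials(simulate_trials(cfg))
#' cd <- build_choice_data(scores, "attempt")
#' attr(cd, "n_excluded")
#' @export
build_choice_data <- function(scores, stage = c("attempt", "choice"),
                              foods = food_names()) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(scores))
  col <- if (stage == "attempt") "fa" else "fc"
  top <- length(foods) + 1L
  scores <- as_tibble(scores)
  if (!all(c("trial_id", "food", col) %in% names(scores))) {
    abort(sprintf("scores must have columns trial_id, food, %s", col))
  }
  scores$food <- match_foods(scores$food, foods)

  by_trial <- split(scores, scores$trial_id)
  keep <- list()
  n_excluded <- 0L
  for (tr in by_trial) {
    s <- tr[[col]]
    hits <- sum(s == top)
    if (hits > 1L) {
      abort(sprintf(
        "malformed scores: two foods share the top %s score in trial %s",
        toupper(col), tr$trial_id[[1L]]
      ))
    }
    if (hits == 0L) {
      if (max(s) > 1L) {
        abort(sprintf(
          "malformed scores: no top %s score but scores > 1 in trial %s",
          toupper(col), tr$trial_id[[1L]]
        ))
      }
      n_excluded <- n_excluded + 1L  # nothing attempted/eaten
      next
    }
    tr <- tr[match(foods, tr$food), , drop = FALSE]
    tr$choice <- as.integer(tr[[col]] == top)
    keep[[length(keep) + 1L]] <- tr
  }
  out <- bind_rows(keep)
  if (nrow(out) == 0L) {
    out <- tibble(trial_id = character(), food = character(),
                  choice = integer())
  }
  attr(out, "stage") <- stage
  attr(out, "foods") <- foods
  attr(out, "n_excluded") <- n_excluded
  out
}

# Design matrix of the conditional logit: ASC dummies for the
# non-reference alternatives plus optional alternative-varying covariates.
mnl_design <- function(data, reference, covariates, foods) {
  non_ref <- setdiff(foods, reference)
  X <- sapply(non_ref, function(f) as.numeric(data$food == f))
  X <- matrix(X, nrow = nrow(data), dimnames = list(NULL, non_ref))
  if (length(covariates) > 0L) {
    miss <- setdiff(covariates, names(data))
    if (length(miss) > 0L) {
      abort(paste0("covariate column(s) not in data: ",
                   paste(miss, collapse = ", ")))
    }
    X <- cbind(X, as.matrix(data[, covariates, drop = FALSE]))
  }
  X
}

#' Log-likelihood of the conditional multinomial logit
#'
#' Evaluates the conditional-logit log-likelihood
#' `sum_i log( exp(v_iy) / sum_j exp(v_ij) )` where the systematic
#' utility `v_ij` of alternative j in trial i is its
#' alternative-specific constant (the reference alternative fixed at 0)
#' plus any covariate terms. Shift-invariant in the raw utilities; finite
#' for finite `beta`.
#'
#' @param beta Coefficient vector: one contrast per non-reference
#'   alternative (in tray order) followed by one coefficient per
#'   covariate.
#' @param data A choice dataset from [build_choice_data()].
#' @param reference Reference food whose utility is fixed at 0.
#' @param covariates Character vector of alternative-varying covariate
#'   columns (e.g. `c("rj", "ag")`); empty for the ASC-only model.
#' @return The log-likelihood (scalar).
#' @export
mlogit_loglik <- function(beta, data, reference = "bread",
                          covariates = character()) {
  foods <- attr(data, "foods") %||% food_names()
  X <- mnl_design(data, reference, covariates, foods)
  if (length(beta) != ncol(X)) {
    abort(sprintf("beta must have length %d, got %d", ncol(X), length(beta)))
  }
  eta <- drop(X %*% beta)
  J <- length(foods)
  E <- matrix(eta, nrow = J)  # one column per trial (complete choice sets)
  m <- apply(E, 2L, max)
  lse <- m + log(colSums(exp(sweep(E, 2L, m))))
  sum(eta[data$choice == 1L]) - sum(lse)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the multinomial logit preference model by Newton-Raphson
#'
#' Maximum-likelihood estimation of the alternative-specific-constant
#' (ASC) conditional logit, optionally with alternative-varying
#' covariates. Newton-Raphson iterations on the analytic gradient and
#' Hessian start from `beta = 0` (equal 0.25 alternative shares) with
#' step-halving whenever a full step fails to increase the likelihood;
#' convergence is declared when the gradient max-norm or the
#' log-likelihood change drops below `tol`. The coefficient covariance is
#' the inverse of the negative Hessian at the optimum; z and two-sided
#' normal p-values are Wald statistics.
#'
#' If some alternative is never chosen its ASC diverges to `-Inf`
#' (complete separation); the fit warns and flags `separation = TRUE`.
#'
#' @inheritParams mlogit_loglik
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `mnl_fit` with elements `coefficients`,
#'   `vcov`, `se`, `z`, `p`, `loglik`, `loglik_null`, `n_trials`,
#'   `n_excluded`, `counts`, `reference`, `stage`, `foods`,
#'   `covariates`, `converged`, `separation`, `iterations`. Supports
#'   [tidy()], [glance()], `print()` and feeds [loco_report()],
#'   [rank_preferences()].
#' @examples
#' cfg <- sim_config(n_trials = 40, seed = 5)
#' scores <- score_trials(simulate_trials(cfg))
#' fit <- fit_mlogit(build_choice_data(scores, "attempt"))
#' tidy(fit)
#' @export
fit_mlogit <- function(data, reference = "bread", covariates = character(),
                       tol = 1e-8, max_iter = 100L) {
  foods <- attr(data, "foods") %||% food_names()
  stage <- attr(data, "stage") %||% NA_character_
  if (!reference %in% foods) {
    abort(sprintf("reference %s is not among the alternatives", reference))
  }
  n_rows <- nrow(data)
  if (n_rows == 0L) abort("empty choice dataset")
  J <- length(foods)
  n <- n_rows / J
  if (n != floor(n)) abort("choice dataset rows are not a multiple of #foods")
  trial_index <- rep(seq_len(n), each = J)

  counts <- tapply(data$choice, factor(data$food, levels = foods), sum)
  counts[is.na(counts)] <- 0
  separation <- any(counts == 0)
  if (separation) {
    warn(paste0(
      "separation: alternative(s) never chosen (",
      paste(foods[counts == 0], collapse = ", "),
      "); their contrasts diverge"
    ))
  }

  X <- mnl_design(data, reference, covariates, foods)
  y <- data$choice
  beta <- rep(0, ncol(X))
  ll <- mlogit_loglik(beta, data, reference, covariates)
  converged <- FALSE
  iter <- 0L
  H <- NULL

  prob_vec <- function(beta) {
    eta <- drop(X %*% beta)
    E <- matrix(eta, nrow = J)
    P <- sweep(exp(sweep(E, 2L, apply(E, 2L, max))), 2L,
               colSums(exp(sweep(E, 2L, apply(E, 2L, max)))), "/")
    as.vector(P)
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    p <- prob_vec(beta)
    grad <- drop(crossprod(X, y - p))
    A <- crossprod(X, p * X)
    S <- rowsum(p * X, trial_index)
    info <- A - crossprod(S)  # negative Hessian (Fisher information)
    H <- info
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(delta)) break  # singular information (separation)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- mlogit_loglik(cand, data, reference, covariates)
      if (ll_new >= ll || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta + step * delta
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  vcov <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      vcov = vcov,
      se = setNames(se, colnames(X)),
      z = setNames(z, colnames(X)),
      p = setNames(2 * pnorm(-abs(z)), colnames(X)),
      loglik = ll,
      loglik_null = n * log(1 / J),
      n_trials = as.integer(n),
      n_excluded = attr(data, "n_excluded") %||% 0L,
      counts = counts,
      reference = reference,
      stage = stage,
      foods = foods,
      covariates = covariates,
      converged = converged && !separation,
      separation = separation,
      iterations = iter
    ),
    class = "mnl_fit"
  )
}

#' Fitted utilities of every alternative (reference at 0)
#' @param fit An `mnl_fit`.
#' @return Named numeric vector over the foods.
#' @export
utilities <- function(fit) {
  stopifnot(inherits(fit, "mnl_fit"))
  u <- setNames(rep(0, length(fit$foods)), fit$foods)
  asc <- intersect(names(fit$coefficients), fit$foods)
  u[asc] <- fit$coefficients[asc]
  u
}

#' Fitted per-trial choice probabilities
#' @param fit An `mnl_fit`.
#' @return For the ASC-only model a named probability vector over the
#'   foods (equal across trials and equal to the empirical shares at the
#'   MLE).
#' @export
choice_shares <- function(fit) {
  stopifnot(inherits(fit, "mnl_fit"))
  u <- utilities(fit)
  exp(u) / sum(exp(u))
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("Conditional multinomial logit (", x$stage, " set), reference: ",
      x$reference, "\n", sep = "")
  cat("n =", x$n_trials, "trials (", x$n_excluded, "excluded );",
      "logLik =", format(x$loglik, digits = 6), "\n")
  print(as.data.frame(tidy(x)), digits = 4)
  if (!x$converged) cat("** fit did not converge cleanly **\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mnl_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p)
  )
}

#' @exportS3Method generics::glance
glance.mnl_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    logLik_null = x$loglik_null,
    nobs = x$n_trials,
    n_excluded = x$n_excluded,
    df = length(x$coefficients),
    iterations = x$iterations,
    converged = x$converged
  )
}
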