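#' Leave-one-component-out (LOCO) contrast tables with odds ratios
#'
#' Re-expresses one fitted multinomial logit as the four published-style
#' sub-tables in which each food in turn serves as the reference
#' alternative: for every reference r and alternative j the entry is the
#' utility contrast `u_j - u_r`, its delta-method standard error from the
#' fitted covariance, Wald z and two-sided p, and the odds ratio
#' `exp(u_j - u_r)`. Because all sub-tables come from the same fit, the
#' antisymmetry `est(j | r) = -est(r | j)` and the transitivity
#' `est(k | i) = est(k | j) + est(j | i)` hold exactly.
#'
#' @param fit A converged [fit_mlogit()] object.
#' @return A tibble with columns `stage, reference, alternative,
#'   estimate, std.error, statistic, p.value, odds_ratio`, three rows per
#'   reference food.
#' @examples
#' cfg <- sim_config(n_trials = 60, seed = 9)
#' scores <- score_trials(simulate_trials(cfg))
#' fit <- fit_mlogit(build_choice_data(scores, "attempt"))
#' loco_report(fit)
#' @export
loco_report <- function(fit) {
  stopifnot(inherits(fit, "mnl_fit"))
  if (!fit$converged) {
    abort(paste0(
      "refusing to build a LOCO table from a non-converged fit (",
      if (fit$separation) "separation detected" else
        sprintf("stopped after %d iterations", fit$iterations),
      ")"
    ))
  }
  foods <- fit$foods
  coefs <- fit$coefficients
  V <- fit$vcov
  rows <- list()
  for (r in foods) {
    for (j in setdiff(foods, r)) {
      cvec <- setNames(rep(0, length(coefs)), names(coefs))
      if (j %in% names(cvec)) cvec[j] <- 1
      if (r %in% names(cvec)) cvec[r] <- -1
      est <- sum(cvec * coefs)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      rows[[length(rows) + 1L]] <- tibble(
        stage = fit$stage, reference = r, alternative = j,
        estimate = est, std.error = se,
        statistic = est / se, p.value = 2 * pnorm(-abs(est / se)),
        odds_ratio = exp(est)
      )
    }
  }
  bind_rows(rows)
}

#' Build a LOCO table directly from published contrasts
#'
#' Re-references a single block of printed utility contrasts (estimates
#' relative to one reference food) into the full set of sub-tables, with
#' odds ratios. Useful for checking the internal consistency of
#' published contrast tables when the covariance matrix is not
#' available; standard errors are reported as `NA`.
#'
#' @param contrasts Named numeric vector of contrasts `u_j - u_ref` for
#'   the non-reference foods.
#' @param reference The reference food of `contrasts`.
#' @param stage Label carried into the `stage` column.
#' @return A tibble shaped like [loco_report()]'s output.
#' @examples
#' loco_from_contrasts(
#'   c(brinjal = 0.075, cauliflower = -0.080, peanuts = -0.293),
#'   reference = "bread"
#' )
#' @export
loco_from_contrasts <- function(contrasts, reference, stage = "attempt") {
  foods <- c(reference, names(contrasts))
  u <- c(setNames(0, reference), contrasts)
  rows <- list()
  for (r in foods) {
    for (j in setdiff(foods, r)) {
      est <- u[[j]] - u[[r]]
      rows[[length(rows) + 1L]] <- tibble(
        stage = stage, reference = r, alternative = j,
        estimate = est, std.error = NA_real_,
        statistic = NA_real_, p.value = NA_real_,
        odds_ratio = exp(est)
      )
    }
  }
  bind_rows(rows)
}

#' Odds ratios of utility contrasts
#'
#' The elementwise exponential of log-odds contrasts: an odds ratio above
#' 1 means the alternative is preferred over the reference.
#'
#' @param estimates A numeric vector of contrasts, or a data frame with
#'   an `estimate` column (e.g. a LOCO table), in which case an
#'   `odds_ratio` column is (re)computed.
#' @return A numeric vector, or the data frame with `odds_ratio` set.
#' @examples
#' odds_ratios(c(0.368, 0, -0.293))
#' @export
odds_ratios <- function(estimates) {
  if (is.data.frame(estimates)) {
    if (!"estimate" %in% names(estimates)) {
      abort("data frame input must have an 'estimate' column")
    }
    estimates$odds_ratio <- exp(estimates$estimate)
    return(as_tibble(estimates))
  }
  exp(estimates)
}

#' Rank food preferences from fitted utilities
#'
#' Orders the foods by descending fitted utility contrast (the reference
#' alternative sits at 0). Exact ties are broken alphabetically and
#' flagged in the `tied` column.
#'
#' @param fit A converged [fit_mlogit()] object, or a named numeric
#'   vector of utilities.
#' @return A tibble with columns `rank, food, utility, tied`, ordered by
#'   preference.
#' @examples
#' rank_preferences(c(bread = 0, brinjal = 0.075,
#'                    cauliflower = -0.080, peanuts = -0.293))
#' @export
rank_preferences <- function(fit) {
  u <- if (inherits(fit, "mnl_fit")) {
    if (!fit$converged) abort("refusing to rank a non-converged fit")
    utilities(fit)
  } else {
    stopifnot(is.numeric(fit), !is.null(names(fit)))
    fit
  }
  ord <- order(-u, names(u))  # alphabetical tie-break
  u <- u[ord]
  dup <- duplicated(u) | duplicated(u, fromLast = TRUE)
  tibble(
    rank = seq_along(u),
    food = names(u),
    utility = unname(u),
    tied = unname(dup)
  )
}

#' Min-max normalisation of LOCO estimates for plotting
#'
#' Rescales each reference block of a LOCO table to `[0, 1]` via
#' `(x - min) / (max - min)` so all bar heights are nonnegative with the
#' block maximum at 1 (the usual presentation of estimate bar charts). A
#' constant (or single-entry) block is mapped to 0.5 with a warning.
#'
#' @param loco A LOCO table ([loco_report()]).
#' @return The table with an added `normalized` column.
#' @examples
#' loco <- loco_from_contrasts(
#'   c(brinjal = 0.075, cauliflower = -0.080, peanuts = -0.293), "bread"
#' )
#' normalize_estimates(loco)
#' @export
normalize_estimates <- function(loco) {
  stopifnot(is.data.frame(loco), "estimate" %in% names(loco))
  if (!all(is.finite(loco$estimate))) abort("estimates must be finite")
  grp <- paste(loco$stage %||% "", loco$reference)
  out <- loco
  out$normalized <- NA_real_
  for (g in unique(grp)) {
    i <- grp == g
    x <- loco$estimate[i]
    rng <- range(x)
    if (diff(rng) == 0) {
      warn(sprintf(
        "constant estimate block (reference %s): normalized values set to 0.5",
        unique(loco$reference[i])
      ))
      out$normalized[i] <- 0.5
    } else {
      out$normalized[i] <- (x - rng[1]) / diff(rng)
    }
  }
  as_tibble(out)
}
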