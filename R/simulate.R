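#' Simulate choice trials with known latent utilities
#'
#' `simulate_trial()` draws one trial from the random-utility generative
#' model described in [sim_config()] using the current RNG state;
#' `simulate_trials()` seeds a single stream from `config$seed` and draws
#' `config$n_trials` independent trials, so the same config yields an
#' identical event log.
#'
#' A trial unfolds as: (1) the four foods are ranked by attempt utility
#' plus independent standard Gumbel noise; the session closes after each
#' rank with probability `1 - p_continue`, leaving later foods
#' unattempted; (2) among attempted foods an eating order is drawn the
#' same way from the choice utilities (Plackett-Luce), again truncated by
#' `p_continue`, leaving some foods approached-but-never-eaten; (3) each
#' attempted food accrues a geometric number of REJECT events
#' (success parameter `1 - p_reject`); (4) eaten foods get a CHOICE event
#' delayed exponentially (mean `delay_scale` seconds, rounded to whole
#' seconds) after their first ATTEMPT, with choice timestamps clamped to
#' respect the drawn eating order; (5) with probability `p_aggression`
#' one AGGRESSION event attaches to the first-chosen food; (6) each eaten
#' food spawns a SHARE event with probability
#' `p_share * sharing_weights / mean(sharing_weights)`, with initiator and
#' recipient life stages drawn from `stage_mix`.
#'
#' @param config A [sim_config()].
#' @param trial_id Identifier for the simulated trial.
#' @return A tibble in event-log form (columns
#'   `trial_id, zone, time_s, event, food, actor_stage, recipient_stage,
#'   share_fraction`), one row per timestamped event, sorted by time with
#'   ties preserving generation order.
#' @examples
#' cfg <- sim_config(n_trials = 3, seed = 7)
#' logs <- simulate_trials(cfg)
#' head(logs)
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    logs <- lapply(seq_len(config$n_trials), function(i) {
      simulate_trial(config, trial_id = sprintf("T%04d", i))
    })
  })
  bind_rows(logs)
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(config, trial_id = "T0001") {
  stopifnot(inherits(config, "sim_config"))
  foods <- config$foods
  nf <- length(foods)
  zone <- if (length(config$zones) == 1L) {
    config$zones
  } else {
    sample(config$zones, 1L)
  }

  rgumbel <- function(n) -log(-log(runif(n)))

  # (1) attempt order by Gumbel-perturbed attempt utilities
  att_order <- order(config$utilities_attempt + rgumbel(nf), decreasing = TRUE)
  k <- 1L
  while (k < nf && runif(1) < config$p_continue) k <- k + 1L
  attempted <- foods[att_order[seq_len(k)]]
  t_att <- setNames(cumsum(pmax(1, round(rexp(k, 1 / config$attempt_gap_s)))),
                    attempted)

  # (2) eating order among attempted foods (Plackett-Luce), truncated
  eat_rank <- order(config$utilities_choice[attempted] + rgumbel(k),
                    decreasing = TRUE)
  m <- 0L
  while (m < k && runif(1) < config$p_continue) m <- m + 1L
  eaten <- attempted[eat_rank][seq_len(m)]

  # (4) choice times: independent exponential delays clamped to the order
  t_choice <- numeric(0)
  if (m > 0L) {
    t_choice <- setNames(numeric(m), eaten)
    prev <- -Inf
    for (f in eaten) {
      tc <- t_att[[f]] + round(rexp(1, 1 / config$delay_scale))
      tc <- max(tc, prev)
      t_choice[[f]] <- tc
      prev <- tc
    }
  }
  t_end <- max(c(t_att, t_choice)) + 10

  e_time <- numeric(0)
  e_kind <- e_food <- e_actor <- e_recip <- character(0)
  e_frac <- numeric(0)
  add <- function(time_s, event, food = NA_character_,
                  actor = NA_character_, recipient = NA_character_,
                  fraction = NA_real_) {
    e_time[length(e_time) + 1L] <<- as.numeric(time_s)
    e_kind[length(e_kind) + 1L] <<- event
    e_food[length(e_food) + 1L] <<- food
    e_actor[length(e_actor) + 1L] <<- actor
    e_recip[length(e_recip) + 1L] <<- recipient
    e_frac[length(e_frac) + 1L] <<- fraction
  }
  for (f in attempted) add(t_att[[f]], "ATTEMPT", f)

  # (3) rejection events between first attempt and consumption/session end;
  # an attempted food that is never eaten ends with a final rejection
  for (f in attempted) {
    g <- rgeom(1, 1 - config$p_reject[[f]])
    if (!(f %in% eaten)) g <- max(g, 1L)
    if (g > 0) {
      hi <- if (f %in% eaten) t_choice[[f]] else t_end
      times <- sort(sample(seq(t_att[[f]], max(t_att[[f]], hi)), g,
                           replace = TRUE))
      for (tt in times) add(tt, "REJECT", f)
    }
  }
  for (f in eaten) add(t_choice[[f]], "CHOICE", f)

  # (5) aggression over the first-chosen food
  if (m > 0L && runif(1) < config$p_aggression) {
    add(t_choice[[eaten[1L]]], "AGGRESSION", eaten[1L])
  }

  # (6) sharing of eaten foods, weighted toward high sharing_weights
  if (m > 0L) {
    w <- config$sharing_weights
    p_sh <- pmin(config$p_share * w / mean(w), 1)  # keeps food names
    stages <- names(config$stage_mix)
    for (f in eaten) {
      if (runif(1) < p_sh[[f]]) {
        add(
          t_choice[[f]] + pmax(1, round(rexp(1, 1 / 5))), "SHARE", f,
          actor = sample(stages, 1L, prob = config$stage_mix),
          recipient = sample(stages, 1L, prob = config$stage_mix),
          fraction = round(runif(1, 0.05, 0.95), 2)
        )
      }
    }
  }

  ord <- order(e_time)  # stable: ties keep generation order
  tibble(
    trial_id = trial_id, zone = zone,
    time_s = e_time[ord], event = e_kind[ord], food = e_food[ord],
    actor_stage = e_actor[ord], recipient_stage = e_recip[ord],
    share_fraction = e_frac[ord]
  )
}

#' Simulate a location-level food census
#'
#' Generates counts of feeding records per location split into processed
#' and unprocessed categories: each location contributes
#' `Binomial(n_records, processed_fraction)` processed records, the
#' remainder unprocessed. Emulates census tables contrasting a heavily
#' provisioned site (~83% processed diet) with sites relying on plant
#' food.
#'
#' @param profiles A data frame with columns `location`,
#'   `processed_fraction` (in `[0, 1]`) and `n_records`.
#' @param seed Integer seed.
#' @return A tibble with columns `location`, `category`, `count` (two
#'   rows per location).
#' @examples
#' simulate_food_census(
#'   data.frame(
#'     location = c("Dakshineswar", "Nalpur", "Nangi"),
#'     processed_fraction = c(0.83, 0.16, 0.18),
#'     n_records = 500
#'   ),
#'   seed = 1
#' )
#' @export
simulate_food_census <- function(profiles, seed = 1L) {
  stopifnot(is.data.frame(profiles))
  req <- c("location", "processed_fraction", "n_records")
  if (!all(req %in% names(profiles))) {
    abort("profiles must have columns location, processed_fraction, n_records")
  }
  if (any(profiles$processed_fraction < 0 | profiles$processed_fraction > 1)) {
    abort("processed_fraction must lie in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    processed <- rbinom(
      nrow(profiles), profiles$n_records, profiles$processed_fraction
    )
  })
  tibble(
    location = rep(profiles$location, each = 2L),
    category = rep(c("processed", "unprocessed"), nrow(profiles)),
    count = as.integer(rbind(processed, profiles$n_records - processed))
  )
}
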