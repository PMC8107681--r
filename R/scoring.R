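#' Score a choice trial into the five per-food ordinal descriptors
#'
#' Converts a timestamped trial event log into the ordinal descriptors
#' used throughout the analysis: first attempt (FA), first choice (FC),
#' rejection (RJ), aggression (AG) and delay.
#'
#' For a tray of k foods (k = 4 by default) the top FA/FC score is k + 1:
#' * **FA** — foods ranked by the time of their first ATTEMPT; the first
#'   scores 5, the second 4, ..., never-attempted foods score 1.
#' * **FC** — foods ranked by the time of their CHOICE (consumption)
#'   event the same way; uneaten foods score 1.
#' * **RJ** — the number of REJECT events between a food's first attempt
#'   and its consumption (or session end), capped at 8; a food rejected
#'   but never eaten scores the cap value 8; never rejected scores 0.
#' * **AG** — 1 if the food attracted at least one AGGRESSION event,
#'   else 0.
#' * **delay** — `delay_s` is the latency (s) between first attempt and
#'   consumption for eaten foods. Zero latency scores 0; positive
#'   latencies are ranked within the trial, the largest scoring 4 and
#'   lower ranks counting down; foods approached but never eaten score
#'   5; unattempted foods score 0 with `delay_s` absent.
#'
#' Ties in event time preserve log order (field logs have 1-second
#' resolution).
#'
#' @param trial An event-log tibble for a single trial (see
#'   [simulate_trials()] for the columns).
#' @param foods Character vector of the food vocabulary; defaults to the
#'   four tray items.
#' @param trial_id Trial identifier; defaults to the one found in
#'   `trial` (required explicitly for an empty log).
#' @return `score_trial()` returns a tibble with one row per food and
#'   columns `trial_id, zone, food, fa, fc, rj, ag, delay_score,
#'   delay_s`. The single-descriptor helpers return named vectors (or,
#'   for [score_delay()], a two-column tibble) keyed by food.
#' @examples
#' cfg <- sim_config(n_trials = 1, seed = 3)
#' score_trial(simulate_trial(cfg))
#' @export
score_trial <- function(trial, foods = food_names(), trial_id = NULL) {
  trial <- validate_event_log(trial, foods)
  if (is.null(trial_id)) {
    ids <- unique(trial$trial_id)
    if (length(ids) > 1L) abort("score_trial expects a single trial")
    trial_id <- if (length(ids) == 1L) ids else NA_character_
  }
  core <- score_trial_core(trial, foods)
  tibble(trial_id = trial_id, zone = core$zone, food = foods,
         fa = core$fa, fc = core$fc, rj = core$rj, ag = core$ag,
         delay_score = core$delay_score, delay_s = core$delay_s)
}

# All five scorers at once, returning plain vectors (hot path).
score_trial_core <- function(trial, foods) {
  zone <- if (nrow(trial) > 0L) trial$zone[[1L]] else NA_character_
  dl <- score_delay_core(trial, foods)
  list(
    zone = zone,
    fa = unname(score_attempts(trial, foods)[foods]),
    fc = unname(score_choices(trial, foods)[foods]),
    rj = unname(score_rejections(trial, foods)[foods]),
    ag = unname(score_aggression(trial, foods)[foods]),
    delay_score = dl$delay_score,
    delay_s = dl$delay_s
  )
}

# first index of the first ATTEMPT / CHOICE per food, in stable time order
first_event_rows <- function(trial, kind) {
  idx <- which(trial$event == kind)
  idx[!duplicated(trial$food[idx])]
}

#' @rdname score_trial
#' @export
score_attempts <- function(trial, foods = food_names()) {
  trial <- validate_event_log(trial, foods)
  top <- length(foods) + 1L
  fa <- setNames(rep(1L, length(foods)), foods)
  att <- trial$food[first_event_rows(trial, "ATTEMPT")]
  if (length(att) > 0L) fa[att] <- top - seq_along(att) + 1L
  fa
}

#' @rdname score_trial
#' @export
score_choices <- function(trial, foods = food_names()) {
  trial <- validate_event_log(trial, foods)
  top <- length(foods) + 1L
  fc <- setNames(rep(1L, length(foods)), foods)
  ch_rows <- which(trial$event == "CHOICE")
  if (anyDuplicated(trial$food[ch_rows])) {
    abort("malformed log: more than one CHOICE event for a food")
  }
  att_rows <- which(trial$event == "ATTEMPT")
  for (i in ch_rows) {
    if (!any(att_rows < i & trial$food[att_rows] == trial$food[i])) {
      abort(sprintf(
        "malformed log: CHOICE for %s without a prior ATTEMPT", trial$food[i]
      ))
    }
  }
  ch <- trial$food[ch_rows]
  if (length(ch) > 0L) fc[ch] <- top - seq_along(ch) + 1L
  fc
}

#' @rdname score_trial
#' @export
score_rejections <- function(trial, foods = food_names()) {
  trial <- validate_event_log(trial, foods)
  rj <- setNames(rep(0L, length(foods)), foods)
  att_rows <- first_event_rows(trial, "ATTEMPT")
  ch_rows <- first_event_rows(trial, "CHOICE")
  for (j in seq_along(att_rows)) {
    f <- trial$food[att_rows[j]]
    t0 <- trial$time_s[att_rows[j]]
    cr <- ch_rows[trial$food[ch_rows] == f]
    t1 <- if (length(cr) == 1L) trial$time_s[cr] else Inf
    n_rej <- sum(trial$event == "REJECT" & trial$food == f &
                   trial$time_s >= t0 & trial$time_s <= t1)
    rj[f] <- if (is.infinite(t1) && n_rej > 0L) {
      8L  # rejected at attempt, never consumed: cap value
    } else {
      min(n_rej, 8L)
    }
  }
  rj
}

#' @rdname score_trial
#' @export
score_aggression <- function(trial, foods = food_names()) {
  trial <- validate_event_log(trial, foods)
  ag <- setNames(rep(0L, length(foods)), foods)
  hit <- unique(trial$food[trial$event == "AGGRESSION"])
  ag[hit[!is.na(hit)]] <- 1L
  ag
}

#' @rdname score_trial
#' @export
score_delay <- function(trial, foods = food_names()) {
  trial <- validate_event_log(trial, foods)
  dl <- score_delay_core(trial, foods)
  tibble(food = foods, delay_score = dl$delay_score, delay_s = dl$delay_s)
}

score_delay_core <- function(trial, foods) {
  att_rows <- first_event_rows(trial, "ATTEMPT")
  ch_rows <- first_event_rows(trial, "CHOICE")
  att_foods <- trial$food[att_rows]
  ch_foods <- trial$food[ch_rows]
  delay_s <- setNames(rep(NA_real_, length(foods)), foods)
  score <- setNames(rep(0L, length(foods)), foods)
  score[setdiff(att_foods, ch_foods)] <- 5L  # approached, never eaten
  for (j in seq_along(ch_rows)) {
    f <- ch_foods[j]
    delay_s[f] <- trial$time_s[ch_rows[j]] -
      trial$time_s[att_rows[att_foods == f]]
  }
  pos <- names(delay_s)[!is.na(delay_s) & delay_s > 0]
  if (length(pos) > 0L) {
    # largest delay anchored at 4, lower ranks count down; ties keep
    # eating order (stable)
    pos <- pos[order(match(pos, ch_foods))]
    ranked <- pos[order(-delay_s[pos])]
    score[ranked] <- 4L - seq_along(ranked) + 1L
  }
  list(delay_score = unname(score[foods]), delay_s = unname(delay_s[foods]))
}

#' Score a set of trials into a score table
#'
#' Applies the five descriptor scorers ([score_trial()]) to every trial
#' of an event log, yielding the 4-foods-per-trial score table that feeds
#' the preference models and supporting statistics.
#'
#' @param events An event-log tibble covering one or more trials, or a
#'   list of single-trial tibbles.
#' @param foods Food vocabulary (defaults to the four tray items).
#' @return A tibble with `length(foods)` rows per trial (columns as in
#'   [score_trial()]).
#' @examples
#' cfg <- sim_config(n_trials = 4, seed = 11)
#' score_trials(simulate_trials(cfg))
#' @export
score_trials <- function(events, foods = food_names()) {
  if (is.data.frame(events)) {
    events <- validate_event_log(events, foods)
    parts <- lapply(split(as.data.frame(events), events$trial_id),
                    function(p) {
                      attr(p, "fc_validated") <- TRUE  # split keeps order
                      p
                    })
    cores <- lapply(parts, score_trial_core, foods = foods)
    nf <- length(foods)
    return(tibble(
      trial_id = rep(names(parts), each = nf),
      zone = rep(vapply(cores, `[[`, "", "zone"), each = nf),
      food = rep(foods, length(parts)),
      fa = unlist(lapply(cores, `[[`, "fa"), use.names = FALSE),
      fc = unlist(lapply(cores, `[[`, "fc"), use.names = FALSE),
      rj = unlist(lapply(cores, `[[`, "rj"), use.names = FALSE),
      ag = unlist(lapply(cores, `[[`, "ag"), use.names = FALSE),
      delay_score = unlist(lapply(cores, `[[`, "delay_score"),
                           use.names = FALSE),
      delay_s = unlist(lapply(cores, `[[`, "delay_s"), use.names = FALSE)
    ))
  }
  ids <- purrr::map(events, function(e) unique(e$trial_id))
  if (anyDuplicated(unlist(ids))) {
    abort("duplicate trial_id across trials")
  }
  bind_rows(lapply(events, score_trial, foods = foods))
}
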