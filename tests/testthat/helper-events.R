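# Build a single-trial event log from terse row specs:
#   trial_log(list(t, event, food), list(t, event, food, actor, recipient, frac))
trial_log <- function(..., trial_id = "T1", zone = "Z1") {
  specs <- list(...)
  get_at <- function(s, i, default) {
    if (length(s) >= i && !is.null(s[[i]])) s[[i]] else default
  }
  tibble::tibble(
    trial_id = rep(trial_id, length(specs)),
    zone = rep(zone, length(specs)),
    time_s = vapply(specs, function(s) as.numeric(s[[1]]), numeric(1)),
    event = vapply(specs, function(s) as.character(s[[2]]), character(1)),
    food = vapply(specs, function(s) as.character(s[[3]]), character(1)),
    actor_stage = vapply(specs, function(s) {
      as.character(get_at(s, 4, NA_character_))
    }, character(1)),
    recipient_stage = vapply(specs, function(s) {
      as.character(get_at(s, 5, NA_character_))
    }, character(1)),
    share_fraction = vapply(specs, function(s) {
      as.numeric(get_at(s, 6, NA_real_))
    }, numeric(1))
  )
}

empty_trial <- function(trial_id = "T1") {
  trial_log(trial_id = trial_id)[0, ]
}

# ASC-only choice dataset with the given per-alternative choice counts.
choice_data_from_counts <- function(counts, foods = food_names()) {
  stopifnot(length(counts) == length(foods))
  chosen <- rep(foods, counts)
  n <- length(chosen)
  out <- tibble::tibble(
    trial_id = rep(sprintf("T%04d", seq_len(n)), each = length(foods)),
    food = rep(foods, n),
    choice = as.integer(rep(chosen, each = length(foods)) ==
                          rep(foods, n))
  )
  attr(out, "stage") <- "attempt"
  attr(out, "foods") <- foods
  attr(out, "n_excluded") <- 0L
  out
}

# First-attempted food of every trial, straight from the event log.
first_attempts <- function(events) {
  att <- events[events$event == "ATTEMPT", ]
  att[!duplicated(att$trial_id), ]$food
}
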