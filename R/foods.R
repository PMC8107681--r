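#' Food and life-stage vocabularies
#'
#' The experimental tray holds four food items: two factory-made
#' ("processed") items, bread and peanuts, and two plant-based
#' ("unprocessed") items, brinjal and cauliflower. Sharing events are
#' recorded between four life stages. Both vocabularies are closed by
#' default; scoring and model code accept an extended food set (the
#' ordinal top score scales as k + 1 for k foods) when `foods` is
#' overridden explicitly.
#'
#' @return `food_items()` returns a tibble with columns `food` and
#'   `category` (in the fixed alternative order bread, brinjal,
#'   cauliflower, peanuts); `food_names()` and `life_stages()` return
#'   character vectors; `event_kinds()` returns the five event codes of
#'   the trial log.
#' @examples
#' food_items()
#' @export
food_items <- function() {
  tibble(
    food = c("bread", "brinjal", "cauliflower", "peanuts"),
    category = c("processed", "unprocessed", "unprocessed", "processed")
  )
}

#' @rdname food_items
#' @export
food_names <- function() food_items()$food

#' @rdname food_items
#' @export
life_stages <- function() c("adult", "subadult", "juvenile", "infant")

#' @rdname food_items
#' @export
event_kinds <- function() c("ATTEMPT", "CHOICE", "REJECT", "AGGRESSION", "SHARE")

# Normalise a food label vector against a vocabulary (case-insensitive).
match_foods <- function(x, foods = food_names(), what = "food") {
  lx <- tolower(trimws(as.character(x)))
  bad <- !is.na(lx) & !(lx %in% foods)
  if (any(bad)) {
    abort(sprintf(
      "unknown %s label(s): %s", what,
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  lx
}

match_stages <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  bad <- !is.na(lx) & !(lx %in% life_stages())
  if (any(bad)) {
    abort(sprintf(
      "unknown life-stage label(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  lx
}

event_log_columns <- function() {
  c(
    "trial_id", "zone", "time_s", "event", "food",
    "actor_stage", "recipient_stage", "share_fraction"
  )
}

# Internal validator for an event-log tibble (one or many trials).
# Sets a marker attribute so downstream scorers skip re-validation.
validate_event_log <- function(events, foods = food_names()) {
  stopifnot(is.data.frame(events))
  if (isTRUE(attr(events, "fc_validated"))) {
    return(events)
  }
  missing_cols <- setdiff(event_log_columns(), names(events))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "event log is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(events) == 0) {
    return(as_tibble(events))
  }
  if (any(is.na(events$time_s)) || any(events$time_s < 0)) {
    abort("event log: time_s must be nonnegative and non-missing")
  }
  if (!all(events$event %in% event_kinds())) {
    abort(sprintf(
      "event log: unknown event kind(s): %s",
      paste(setdiff(unique(events$event), event_kinds()), collapse = ", ")
    ))
  }
  events$food <- match_foods(events$food, foods)
  shares <- events$event == "SHARE"
  if (any(shares)) {
    if (any(is.na(events$actor_stage[shares])) ||
          any(is.na(events$recipient_stage[shares]))) {
      abort("event log: SHARE events must carry actor_stage and recipient_stage")
    }
    events$actor_stage[shares] <- match_stages(events$actor_stage[shares])
    events$recipient_stage[shares] <- match_stages(events$recipient_stage[shares])
  }
  # stable sort within trial: ties in time_s preserve log order
  events$.ord <- seq_len(nrow(events))
  events <- dplyr::arrange(events, .data$trial_id, .data$time_s, .data$.ord)
  events$.ord <- NULL
  events <- as_tibble(events)
  attr(events, "fc_validated") <- TRUE
  events
}
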