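#' Extract sharing events from an event log
#'
#' @param events An event-log tibble.
#' @return A tibble with columns `trial_id, food, initiator_stage,
#'   recipient_stage, share_fraction`, one row per SHARE event.
#' @export
sharing_events <- function(events) {
  events <- validate_event_log(events)
  sh <- events[events$event == "SHARE", , drop = FALSE]
  tibble(
    trial_id = sh$trial_id,
    food = sh$food,
    initiator_stage = sh$actor_stage,
    recipient_stage = sh$recipient_stage,
    share_fraction = sh$share_fraction
  )
}

check_sharing_events <- function(events) {
  if (is.data.frame(events) && "event" %in% names(events)) {
    events <- sharing_events(events)
  }
  stopifnot(is.data.frame(events))
  req <- c("food", "initiator_stage", "recipient_stage")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0L) {
    abort(paste0("sharing events missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  events$food <- match_foods(events$food)
  events$initiator_stage <- match_stages(events$initiator_stage)
  events$recipient_stage <- match_stages(events$recipient_stage)
  as_tibble(events)
}

#' Per-food directed food-sharing networks over life stages
#'
#' Builds one directed weighted network per food present in the sharing
#' events: nodes are the four life stages (always all four, including
#' isolates), an edge initiator -> recipient is weighted by the number
#' of sharing incidents between those stages, and self-loops (e.g.
#' adult -> adult) are counted. Each sharing incident is one link;
#' repeated shares of a food within a trial count separately.
#'
#' @param events A sharing-event tibble ([sharing_events()]) or a full
#'   event log (SHARE rows are extracted).
#' @return An object of class `stage_networks`: a named list (one
#'   element per food) of [igraph::graph] objects, with the edge-count
#'   tibble in attribute `edges`.
#' @examples
#' ev <- tibble::tibble(
#'   trial_id = "T1", food = c("peanuts", "peanuts"),
#'   initiator_stage = c("adult", "adult"),
#'   recipient_stage = c("juvenile", "adult"),
#'   share_fraction = 0.5
#' )
#' nets <- build_networks(ev)
#' degree_summary(nets)
#' @export
build_networks <- function(events) {
  events <- check_sharing_events(events)
  edges <- events %>%
    count(.data$food, .data$initiator_stage, .data$recipient_stage,
          name = "weight") %>%
    rename(initiator = "initiator_stage", recipient = "recipient_stage")
  nets <- lapply(split(edges, edges$food), function(e) {
    igraph::graph_from_data_frame(
      e[, c("initiator", "recipient", "weight")],
      directed = TRUE,
      vertices = life_stages()
    )
  })
  structure(nets, class = "stage_networks", edges = edges)
}

#' @export
print.stage_networks <- function(x, ...) {
  cat("<stage_networks> ", length(x), " food network(s): ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' In/out-degree summary of the sharing networks
#'
#' One row per food x life stage (zeros included for stages absent from
#' the events): the number of sharing incidents initiated (`outdegree`)
#' and received (`indegree`) by that stage. Degrees are weighted by
#' incident counts, so for every food the indegree and outdegree totals
#' both equal the number of sharing events of that food.
#'
#' @param networks A `stage_networks` object ([build_networks()]).
#' @return A tibble `food, stage, indegree, outdegree`.
#' @export
degree_summary <- function(networks) {
  stopifnot(inherits(networks, "stage_networks"))
  bind_rows(lapply(names(networks), function(f) {
    g <- networks[[f]]
    tibble(
      food = f,
      stage = life_stages(),
      indegree = as.numeric(igraph::strength(
        g, vids = life_stages(), mode = "in", loops = TRUE
      )),
      outdegree = as.numeric(igraph::strength(
        g, vids = life_stages(), mode = "out", loops = TRUE
      ))
    )
  }))
}

#' Composition and rate of food sharing
#'
#' Summarises which foods get shared: the per-food share of all sharing
#' incidents, and the overall sharing rate, i.e. the number of distinct
#' shared (trial, food) cases divided by the number of successful
#' (eaten) cases.
#'
#' @param events Sharing events ([sharing_events()]) or a full event
#'   log.
#' @param eaten_cases Number of successful (trial, food) cases; must be
#'   positive and at least the number of distinct shared cases.
#' @return A list with `composition` (tibble `food, n_events,
#'   proportion`), `sharing_rate` (proportion of successful cases
#'   shared), `shared_cases` and `eaten_cases`.
#' @examples
#' ev <- tibble::tibble(
#'   trial_id = c("T1", "T1", "T2"),
#'   food = c("peanuts", "cauliflower", "peanuts"),
#'   initiator_stage = "adult", recipient_stage = "juvenile",
#'   share_fraction = 0.4
#' )
#' sharing_composition(ev, eaten_cases = 10)
#' @export
sharing_composition <- function(events, eaten_cases) {
  events <- check_sharing_events(events)
  if (length(eaten_cases) != 1L || is.na(eaten_cases) || eaten_cases <= 0) {
    abort("eaten_cases must be a positive count")
  }
  shared_cases <- if (nrow(events) == 0L) {
    0L
  } else if ("trial_id" %in% names(events)) {
    nrow(distinct(events, .data$trial_id, .data$food))
  } else {
    nrow(events)
  }
  if (eaten_cases < shared_cases) {
    abort("eaten_cases is smaller than the number of shared cases")
  }
  comp <- events %>%
    count(.data$food, name = "n_events") %>%
    mutate(proportion = .data$n_events / sum(.data$n_events))
  if (nrow(events) == 0L) {
    comp <- tibble(food = character(), n_events = integer(),
                   proportion = numeric())
  }
  list(
    composition = comp,
    sharing_rate = shared_cases / eaten_cases,
    shared_cases = as.integer(shared_cases),
    eaten_cases = as.integer(eaten_cases)
  )
}

#' Export sharing networks
#'
#' `write_network_edges()` writes the edge list as CSV
#' (`food,initiator,recipient,weight`); `write_network_graphml()` writes
#' one GraphML file per food for external network viewers.
#'
#' @param networks A `stage_networks` object.
#' @param path CSV path, or a directory for the GraphML files.
#' @return The written path(s), invisibly.
#' @export
write_network_edges <- function(networks, path) {
  stopifnot(inherits(networks, "stage_networks"))
  readr::write_csv(attr(networks, "edges"), path)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(networks, path) {
  stopifnot(inherits(networks, "stage_networks"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- vapply(names(networks), function(f) {
    p <- file.path(path, paste0("sharing_", f, ".graphml"))
    igraph::write_graph(networks[[f]], p, format = "graphml")
    p
  }, character(1))
  invisible(paths)
}
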