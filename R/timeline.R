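# Treatment-timeline modelling: segmentation of raw patient event logs into
# [action(s), status] cycles, the single-cycle simplification with a
# three-year outcome, and treatment-sequence pattern mining.

ACTION_KIND_PATTERNS <- c(
  chemotherapy = "chemo|biotherapy|investigational|smi",
  radiotherapy = "radiat",
  surgery = "surgery|surgical"
)

RELAPSE_PATTERN <- "relapse|recurrence"

classify_action <- function(procedure) {
  p <- tolower(procedure)
  kind <- rep("other", length(p))
  for (k in names(ACTION_KIND_PATTERNS)) {
    kind[grepl(ACTION_KIND_PATTERNS[[k]], p)] <- k
  }
  kind
}

#' Read a patient event log
#'
#' @param path CSV with columns `day`, `category`, `procedure`; `day` in
#'   days from treatment start, `category` one of `TreatmentStart`,
#'   `Action`, `Status`.
#' @return An event-log tibble.
#' @export
read_event_log <- function(path) {
  log <- readr::read_csv(path, col_types = readr::cols(
    day = readr::col_double(), category = readr::col_character(),
    procedure = readr::col_character()
  ), progress = FALSE)
  log$category <- sub("^Treatment Start$", "TreatmentStart", log$category)
  log
}

#' Segment an event log into treatment cycles
#'
#' A cycle is a maximal run of action events followed by status events,
#' closed by a relapse/recurrence status (which it includes) or by a new
#' action or the end of the log. Within a cycle, a chemotherapy action and
#' a radiation action whose days differ by at most `merge_window_days` are
#' merged into one concurrent action, `radiotherapy (w/ concurrent
#' chemotherapy)`, dated at the earlier of the two.
#'
#' @param log Event-log tibble (`day`, `category`, `procedure`); sorted by
#'   day internally. Must contain the day-0 `TreatmentStart` event.
#' @param merge_window_days Concurrency window in days (default 45).
#' @return A `twin_cycles` list; each element has tibbles `actions`
#'   (`day`, `procedure`, `kind`) and `statuses` (`day`, `procedure`,
#'   `relapse`).
#' @export
#' @examples
#' log <- patient_case_log(1)
#' length(segment_cycles(log))
segment_cycles <- function(log, merge_window_days = 45) {
  log <- dplyr::arrange(tibble::as_tibble(log), .data$day)
  if (any(log$day < 0)) stop_hnc("event days must be >= 0")
  start <- log$category == "TreatmentStart"
  if (sum(start) != 1 || log$day[start] != 0) {
    stop_hnc("event log must contain exactly one TreatmentStart at day 0")
  }
  ev <- log[!start, ]

  cycles <- list()
  cur_actions <- cur_statuses <- list()
  in_statuses <- FALSE
  pending_statuses <- list()  # statuses seen before any action

  close_cycle <- function() {
    if (length(cur_actions)) {
      cycles[[length(cycles) + 1L]] <<- list(
        actions = dplyr::bind_rows(cur_actions),
        statuses = if (length(cur_statuses)) dplyr::bind_rows(cur_statuses) else
          tibble::tibble(day = numeric(0), procedure = character(0), relapse = logical(0))
      )
    }
    cur_actions <<- list(); cur_statuses <<- list(); in_statuses <<- FALSE
  }

  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$category == "Action") {
      if (in_statuses) close_cycle()
      cur_actions[[length(cur_actions) + 1L]] <- tibble::tibble(
        day = e$day, procedure = e$procedure, kind = classify_action(e$procedure)
      )
    } else if (e$category == "Status") {
      rel <- grepl(RELAPSE_PATTERN, tolower(e$procedure))
      srow <- tibble::tibble(day = e$day, procedure = e$procedure, relapse = rel)
      if (!length(cur_actions) && !length(cycles)) {
        warn_hnc("status '%s' (day %g) precedes any action; attached to first cycle",
                 e$procedure, e$day)
        pending_statuses[[length(pending_statuses) + 1L]] <- srow
        next
      }
      in_statuses <- TRUE
      cur_statuses[[length(cur_statuses) + 1L]] <- srow
      if (rel) close_cycle()
    } else {
      stop_hnc("unknown event category '%s'", e$category)
    }
  }
  close_cycle()

  if (length(pending_statuses) && length(cycles)) {
    cycles[[1]]$statuses <- dplyr::arrange(
      dplyr::bind_rows(dplyr::bind_rows(pending_statuses), cycles[[1]]$statuses),
      .data$day)
  }

  cycles <- purrr::map(cycles, merge_concurrent, merge_window_days = merge_window_days)
  structure(cycles, class = "twin_cycles")
}

# Merge a chemotherapy + radiation pair within the concurrency window into
# one concurrent-chemoradiotherapy action.
merge_concurrent <- function(cycle, merge_window_days) {
  a <- cycle$actions
  chemo_i <- which(a$kind == "chemotherapy")
  rad_i <- which(a$kind == "radiotherapy")
  if (length(chemo_i) && length(rad_i)) {
    for (ci in chemo_i) {
      gaps <- abs(a$day[rad_i] - a$day[ci])
      if (any(gaps <= merge_window_days)) {
        ri <- rad_i[which.min(gaps)]
        merged <- tibble::tibble(
          day = min(a$day[ci], a$day[ri]),
          procedure = "radiotherapy (w/ concurrent chemotherapy)",
          kind = "concurrent_chemoradiotherapy"
        )
        a <- dplyr::bind_rows(a[-c(ci, ri), ], merged)
        a <- dplyr::arrange(a, .data$day)
        break
      }
    }
  }
  unrec <- a$kind == "other"
  if (any(unrec)) {
    warn_hnc("unrecognized action label(s): %s",
             paste(unique(a$procedure[unrec]), collapse = ", "))
  }
  cycle$actions <- a
  cycle
}

#' Simplify a cycle list to a single-cycle record with a year-3 outcome
#'
#' Decodes the first cycle's actions into the three first-cycle action
#' variables (surgery -> definitive; standalone chemotherapy -> induction;
#' radiation with/without merged concurrent chemotherapy -> radiotherapy
#' class). `relapse_yr3` is `"True"` iff any relapse event in any cycle
#' occurs at or before `horizon_days`; `"False"` when the log demonstrably
#' extends past the horizon without one; otherwise missing. `status_yr3`
#' takes the status nearest the horizon within a +/-`grace_days` window,
#' falling back to the latest status before the horizon.
#'
#' @param cycles A `twin_cycles` list from [segment_cycles()].
#' @param horizon_days Outcome horizon (default 1095 days = 3 years).
#' @param grace_days Grace window for the year-3 status (default 90).
#' @return A one-row tibble: `definitive`, `induction`, `radio_chemo`,
#'   `status_yr3`, `relapse_yr3`.
#' @export
#' @examples
#' simplify_to_single_cycle(segment_cycles(patient_case_log(2)))
simplify_to_single_cycle <- function(cycles, horizon_days = 1095, grace_days = 90) {
  if (!length(cycles)) stop_hnc("no cycles to simplify")
  first <- cycles[[1]]
  kinds <- first$actions$kind

  definitive <- if (any(kinds == "surgery")) "yes" else "no"
  induction <- if (any(kinds == "chemotherapy")) "yes" else "no"
  radio_chemo <- if (any(kinds == "concurrent_chemoradiotherapy")) {
    "yes_with_concurrent_chemotherapy"
  } else if (any(kinds == "radiotherapy")) "yes" else "no"

  statuses <- dplyr::bind_rows(purrr::map(cycles, "statuses"))
  relapse_days <- statuses$day[statuses$relapse]
  relapse_yr3 <- if (any(relapse_days <= horizon_days)) {
    "True"
  } else if (nrow(statuses) && max(statuses$day) >= horizon_days) {
    "False"
  } else {
    NA_character_
  }

  status_yr3 <- NA_character_
  if (nrow(statuses)) {
    d <- abs(statuses$day - horizon_days)
    in_window <- d <= grace_days
    if (any(in_window)) {
      cand <- which(in_window)
      status_yr3 <- statuses$procedure[cand[which.min(d[cand])]]
    } else {
      before <- which(statuses$day <= horizon_days)
      if (length(before)) status_yr3 <- statuses$procedure[max(before)]
    }
  }

  tibble::tibble(definitive = definitive, induction = induction,
                 radio_chemo = radio_chemo, status_yr3 = status_yr3,
                 relapse_yr3 = relapse_yr3)
}

#' Months elapsed between two event days
#'
#' Converts a day gap to whole months using the mean month length of
#' 30.44 days.
#'
#' @param day_a,day_b Day numbers with `day_b >= day_a`.
#' @return `round((day_b - day_a) / 30.44)` as an integer.
#' @export
#' @examples
#' elapsed_months(28, 517)  # 16 months from first action to relapse
elapsed_months <- function(day_a, day_b) {
  if (any(day_b < day_a)) stop_hnc("day_b must be >= day_a")
  as.integer(round((day_b - day_a) / 30.44))
}

#' Mine first-cycle treatment-sequence patterns
#'
#' Counts each (definitive, induction, radiotherapy) triple among
#' simplified records and renders it in the `"x -> y -> z"` notation of the
#' published pattern table, sorted by descending count.
#'
#' @param records A tibble with columns `definitive`, `induction`,
#'   `radio_chemo` (one row per patient).
#' @return A tibble with columns `pattern`, `definitive`, `induction`,
#'   `radio_chemo`, `count`.
#' @export
mine_sequence_patterns <- function(records) {
  rt_label <- c(no = "n/a", yes = "radiotherapy",
                yes_with_concurrent_chemotherapy = "radiotherapy (w/ concurrent chemotherapy)")
  out <- records |>
    dplyr::count(.data$definitive, .data$induction, .data$radio_chemo,
                 name = "count") |>
    dplyr::mutate(pattern = paste(
      dplyr::if_else(.data$definitive == "yes", "definitive surgery", "n/a"),
      dplyr::if_else(.data$induction == "yes", "induction therapy", "n/a"),
      rt_label[.data$radio_chemo],
      sep = " -> "
    )) |>
    dplyr::arrange(dplyr::desc(.data$count)) |>
    dplyr::relocate("pattern")
  out
}

#' Published case-study event logs
#'
#' The two worked-example patient timelines bundled with the package:
#' patient 1 (short course, concurrent chemoradiotherapy, early relapse)
#' and patient 2 (prolonged multi-modal history with recurrences).
#'
#' @param which 1 or 2.
#' @return An event-log tibble.
#' @export
patient_case_log <- function(which) {
  path <- system.file("extdata", paste0("patient", which, "_events.csv"),
                      package = "hnctwin", mustWork = TRUE)
  read_event_log(path)
}
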