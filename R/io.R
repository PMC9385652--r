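TRAJ_COLS <- c("participant_id", "phase", "trial_index", "goal_id",
               "step_index", "row", "col", "action", "next_row", "next_col",
               "reward", "truncated")

#' Validate a trajectory table
#'
#' Checks the step schema against a task: columns present, rooms in grid,
#' actions legal and consistent with the recorded next room, steps chained
#' within each trial, reward only on goal entry, and the goal room entered
#' only at the final step of non-truncated trials. Errors cite the
#' offending rows.
#'
#' @param data trajectory tibble.
#' @param task a [nav_task()].
#' @return the data, invisibly, on success.
#' @export
validate_trajectories <- function(data, task) {
  miss <- setdiff(TRAJ_COLS, names(data))
  if (length(miss))
    stop("missing trajectory columns: ", paste(miss, collapse = ", "))
  g <- task$grid
  bad_room <- which(data$row < 0 | data$row >= g$n_rows |
                    data$col < 0 | data$col >= g$n_cols |
                    data$next_row < 0 | data$next_row >= g$n_rows |
                    data$next_col < 0 | data$next_col >= g$n_cols)
  if (length(bad_room))
    stop("rooms outside the grid at rows: ",
         paste(head(bad_room, 5), collapse = ", "))
  if (!all(data$phase %in% c("fixed", "random")))
    stop("phase must be 'fixed' or 'random'")
  if (!all(data$action %in% ACTIONS)) stop("unknown action labels")
  if (!all(data$goal_id %in% names(task$goals)))
    stop("goal_id not among the task goals")
  deltas <- t(vapply(data$action, action_delta, integer(2)))
  bad_adj <- which(data$next_row != data$row + deltas[, 1] |
                   data$next_col != data$col + deltas[, 2])
  if (length(bad_adj))
    stop("next room is not the result of the action at rows: ",
         paste(head(bad_adj, 5), collapse = ", "))
  d <- dplyr::arrange(data, .data$participant_id,
                      factor(.data$phase, c("fixed", "random")),
                      .data$trial_index, .data$step_index)
  key <- paste(d$participant_id, d$phase, d$trial_index)
  same <- key == dplyr::lag(key, default = "")
  bad_chain <- which(same & (d$row != dplyr::lag(d$next_row) |
                             d$col != dplyr::lag(d$next_col)))
  if (length(bad_chain))
    stop("steps do not chain within trial at sorted rows: ",
         paste(head(bad_chain, 5), collapse = ", "))
  goal_rooms <- t(vapply(d$goal_id, function(id) task$goals[[id]], integer(2)))
  at_goal <- d$next_row == goal_rooms[, 1] & d$next_col == goal_rooms[, 2]
  last <- !duplicated(key, fromLast = TRUE)
  bad_goal <- which(at_goal & !last)
  if (length(bad_goal))
    stop("goal room entered before the final step at sorted rows: ",
         paste(head(bad_goal, 5), collapse = ", "))
  bad_end <- which(last & !d$truncated & !at_goal)
  if (length(bad_end))
    stop("non-truncated trial does not end at its goal at sorted rows: ",
         paste(head(bad_end, 5), collapse = ", "))
  bad_rew <- which((d$reward > 0) != at_goal)
  if (length(bad_rew))
    stop("reward inconsistent with goal entry at sorted rows: ",
         paste(head(bad_rew, 5), collapse = ", "))
  invisible(data)
}

#' Read trajectories from CSV
#'
#' One row per step in the package schema; validated against `task` when
#' supplied.
#'
#' @param path CSV file path.
#' @param task optional [nav_task()] for validation.
#' @return trajectory tibble.
#' @export
read_trajectories <- function(path, task = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character(),
                         phase = readr::col_character(),
                         goal_id = readr::col_character(),
                         action = readr::col_character(),
                         reward = readr::col_double(),
                         .default = readr::col_integer()))
  d$truncated <- as.logical(d$truncated)
  if (!is.null(task)) validate_trajectories(d, task)
  d
}

#' Write trajectories to CSV
#'
#' Deterministic column order and formatting: two writes of the same data
#' are byte-identical.
#'
#' @param data trajectory tibble.
#' @param path output path.
#' @export
write_trajectories <- function(data, path) {
  d <- data[, TRAJ_COLS]
  d$truncated <- as.integer(d$truncated)
  readr::write_csv(d, path)
  invisible(path)
}

#' Write fit results to CSV
#'
#' Likelihood quantities are written with 12 significant digits.
#'
#' @param fits [fit_mle()] rows.
#' @param path output path.
#' @export
write_fits <- function(fits, path) {
  f <- fits
  for (nm in c("alpha", "theta", "lam", "omega", "nll", "bic"))
    f[[nm]] <- sprintf("%.12g", f[[nm]])
  readr::write_csv(f, path)
  invisible(path)
}

#' Read fit results from CSV
#' @param path CSV written by [write_fits()].
#' @return tibble of fits.
#' @export
read_fits <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    phase = readr::col_character(),
                    model = readr::col_character(),
                    k = readr::col_integer(), n = readr::col_integer(),
                    n_restarts = readr::col_integer(),
                    seed = readr::col_integer(),
                    best_restart = readr::col_integer(),
                    .default = readr::col_double()))
}

#' Write an analysis report as JSON
#'
#' @param report a list of results (tables are written as data frames).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a task configuration as JSON
#' @param task a [nav_task()].
#' @param path output path.
#' @export
write_task <- function(task, path) {
  goals <- lapply(names(task$goals), function(id) {
    list(id = id, row = task$goals[[id]][1], col = task$goals[[id]][2])
  })
  jsonlite::write_json(
    list(grid = task$grid,
         goals = goals,
         fixed_start = list(row = task$fixed_start[1],
                            col = task$fixed_start[2]),
         n_fixed_trials = task$n_fixed_trials,
         n_random_trials = task$n_random_trials,
         reward_magnitude = task$reward_magnitude),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a task configuration from JSON
#' @param path JSON written by [write_task()].
#' @return a [nav_task()].
#' @export
read_task <- function(path) {
  x <- jsonlite::read_json(path)
  goals <- setNames(
    lapply(x$goals, function(g) c(g$row, g$col)),
    vapply(x$goals, function(g) g$id, character(1)))
  nav_task(n_rows = x$grid$n_rows, n_cols = x$grid$n_cols, goals = goals,
           fixed_start = c(x$fixed_start$row, x$fixed_start$col),
           n_fixed_trials = x$n_fixed_trials,
           n_random_trials = x$n_random_trials,
           reward_magnitude = x$reward_magnitude)
}
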