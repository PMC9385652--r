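#' Define the room-grid navigation task
#'
#' Builds the task configuration shared by the simulator, the likelihood
#' replay and the wayfinding metrics: the room grid, the three goal rooms,
#' the fixed start room, and the Fixed/Random phase trial counts. Rooms are
#' addressed as `c(row, col)`, 0-based, with row 0 at the top; "up"
#' decreases the row index. Defaults give the 6 x 6 grid with 9 Fixed and
#' 72 Random trials.
#'
#' @param n_rows,n_cols grid dimensions (rooms); both at least 2.
#' @param goals named list of three distinct goal rooms, each `c(row, col)`.
#' @param fixed_start start room of every Fixed-phase trial; not a goal room.
#' @param n_fixed_trials number of Fixed-phase trials (goal order cycles
#'   through the goals in list order).
#' @param n_random_trials number of Random-phase trials; must be divisible by
#'   the number of goals (each goal appears once per block of three).
#' @param reward_magnitude reward delivered on entering the trial's goal room.
#' @return an object of class `nav_task`.
#' @export
nav_task <- function(n_rows = 6, n_cols = 6,
                     goals = list(G1 = c(1, 4), G2 = c(4, 1), G3 = c(4, 4)),
                     fixed_start = c(0, 0),
                     n_fixed_trials = 9, n_random_trials = 72,
                     reward_magnitude = 1) {
  stopifnot(n_rows >= 2, n_cols >= 2, reward_magnitude >= 0,
            n_fixed_trials >= 0, n_random_trials >= 0)
  if (is.null(names(goals)) || any(!nzchar(names(goals))))
    stop("goals must be a named list")
  grid <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols))
  goals <- lapply(goals, function(g) as.integer(g))
  for (g in goals) assert_in_grid(grid, g)
  assert_in_grid(grid, fixed_start)
  idx <- vapply(goals, function(g) state_index(grid, g), integer(1))
  if (anyDuplicated(idx)) stop("goal rooms must be pairwise distinct")
  if (state_index(grid, fixed_start) %in% idx)
    stop("fixed_start must not be a goal room")
  if (n_random_trials %% length(goals) != 0)
    stop("n_random_trials must be divisible by the number of goals")
  structure(list(grid = grid, goals = goals,
                 fixed_start = as.integer(fixed_start),
                 n_fixed_trials = as.integer(n_fixed_trials),
                 n_random_trials = as.integer(n_random_trials),
                 reward_magnitude = reward_magnitude),
            class = "nav_task")
}

#' @export
print.nav_task <- function(x, ...) {
  cat(sprintf("<nav_task> %d x %d rooms, %d goals, %d fixed + %d random trials\n",
              x$grid$n_rows, x$grid$n_cols, length(x$goals),
              x$n_fixed_trials, x$n_random_trials))
  for (id in names(x$goals))
    cat(sprintf("  %s at (%d,%d)\n", id, x$goals[[id]][1], x$goals[[id]][2]))
  cat(sprintf("  fixed start (%d,%d), reward %g\n",
              x$fixed_start[1], x$fixed_start[2], x$reward_magnitude))
  invisible(x)
}

as_grid <- function(x) if (inherits(x, "nav_task")) x$grid else x

assert_in_grid <- function(grid, room) {
  grid <- as_grid(grid)
  if (length(room) != 2 || any(is.na(room)) ||
      room[1] < 0 || room[1] >= grid$n_rows ||
      room[2] < 0 || room[2] >= grid$n_cols)
    stop(sprintf("room (%s) is outside the %d x %d grid",
                 paste(room, collapse = ","), grid$n_rows, grid$n_cols))
  invisible(room)
}

# 1-based linear state index, s = row * n_cols + col + 1
state_index <- function(grid, room) {
  grid <- as_grid(grid)
  as.integer(room[1]) * grid$n_cols + as.integer(room[2]) + 1L
}

state_room <- function(grid, index) {
  grid <- as_grid(grid)
  i <- as.integer(index) - 1L
  c(i %/% grid$n_cols, i %% grid$n_cols)
}

action_delta <- function(action) {
  switch(action,
         up = c(-1L, 0L), down = c(1L, 0L),
         left = c(0L, -1L), right = c(0L, 1L),
         stop(sprintf("unknown action '%s'", action)))
}

#' Legal moves from a room
#'
#' Directions whose adjacent room lies inside the grid: 2 in a corner, 3 on
#' an edge, 4 in the interior. There are no interior walls.
#'
#' @param grid a `nav_task` or a list with `n_rows`, `n_cols`.
#' @param room `c(row, col)`, 0-based.
#' @return character vector, a subset of `c("up","down","left","right")`.
#' @export
available_actions <- function(grid, room) {
  grid <- as_grid(grid)
  assert_in_grid(grid, room)
  ok <- vapply(ACTIONS, function(a) {
    nxt <- room + action_delta(a)
    nxt[1] >= 0 && nxt[1] < grid$n_rows && nxt[2] >= 0 && nxt[2] < grid$n_cols
  }, logical(1))
  ACTIONS[ok]
}

#' Deterministic room transition
#'
#' @inheritParams available_actions
#' @param action one of `"up"`, `"down"`, `"left"`, `"right"`; must be legal
#'   at `room`.
#' @return the adjacent room `c(row, col)`.
#' @export
step_room <- function(grid, room, action) {
  grid <- as_grid(grid)
  assert_in_grid(grid, room)
  if (!action %in% available_actions(grid, room))
    stop(sprintf("action '%s' is illegal at room (%d,%d)",
                 action, room[1], room[2]))
  room + action_delta(action)
}

#' Shortest path length between rooms
#'
#' Minimal number of room transitions between two rooms. The grid has no
#' interior walls, so the breadth-first-search distance on the room graph
#' reduces to the Manhattan distance.
#'
#' @inheritParams available_actions
#' @param origin,target rooms `c(row, col)`, 0-based.
#' @return nonnegative integer count of room transitions.
#' @export
shortest_path_rooms <- function(grid, origin, target) {
  grid <- as_grid(grid)
  assert_in_grid(grid, origin)
  assert_in_grid(grid, target)
  as.integer(abs(origin[1] - target[1]) + abs(origin[2] - target[2]))
}
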