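#' Parameter bounds for the choice models
#'
#' Learning rate alpha in \[0, 1\], inverse temperature theta in \[1, 15\],
#' trace decay lambda in \[0, 1\], model-based weight omega in \[0, 1\].
#'
#' @return named list of `c(lower, upper)` per parameter.
#' @export
param_bounds <- function() {
  list(alpha = c(0, 1), theta = c(1, 15), lam = c(0, 1), omega = c(0, 1))
}

#' Free parameters of each model
#'
#' TD(0) and TD(1) fit (alpha, theta); TD(lambda) adds lambda; the
#' model-based model fits theta only; the hybrid fits all four.
#'
#' @param model_kind one of `"TD0"`, `"TD1"`, `"TDLAMBDA"`, `"MB"`, `"HYBRID"`.
#' @return character vector of free-parameter names.
#' @export
free_params <- function(model_kind) {
  switch(match.arg(model_kind, MODEL_KINDS),
         TD0 = c("alpha", "theta"),
         TD1 = c("alpha", "theta"),
         TDLAMBDA = c("alpha", "theta", "lam"),
         MB = "theta",
         HYBRID = c("alpha", "theta", "lam", "omega"))
}

#' Number of free parameters (the BIC's k)
#' @inheritParams free_params
#' @export
n_free_params <- function(model_kind) length(free_params(model_kind))

#' Construct a validated parameter set
#'
#' Parameters irrelevant to `model_kind` may be omitted; they are stored as
#' `NA` and ignored by every operation.
#'
#' @inheritParams free_params
#' @param alpha learning rate in \[0, 1\].
#' @param theta softmax inverse temperature in \[1, 15\].
#' @param lam eligibility-trace decay in \[0, 1\].
#' @param omega model-based weight in \[0, 1\].
#' @return a list of class `nav_params`.
#' @export
model_params <- function(model_kind, alpha = NA_real_, theta = NA_real_,
                         lam = NA_real_, omega = NA_real_) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  p <- list(model_kind = model_kind, alpha = alpha, theta = theta,
            lam = lam, omega = omega)
  b <- param_bounds()
  for (nm in free_params(model_kind)) {
    v <- p[[nm]]
    if (is.na(v)) stop(sprintf("%s requires parameter '%s'", model_kind, nm))
    if (v < b[[nm]][1] || v > b[[nm]][2])
      stop(sprintf("'%s' = %g outside [%g, %g]", nm, v, b[[nm]][1], b[[nm]][2]))
  }
  structure(p, class = "nav_params")
}

#' Softmax choice probabilities
#'
#' Probability of each available action given its value, with inverse
#' temperature `theta`. Computed with a max-shift, so the result is invariant
#' to adding a constant to all values.
#'
#' @param q_row named numeric vector of action values (the available actions).
#' @param theta inverse temperature.
#' @return named probability vector summing to 1.
#' @export
softmax_probs <- function(q_row, theta) {
  if (length(q_row) == 0) stop("empty action set: corrupted state")
  z <- theta * q_row
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' One temporal-difference update
#'
#' Applies the SARSA-style update for one observed transition to one goal's
#' model-free value table. The error is
#' `delta = r + Q(s', a') - Q(s, a)`, with the bootstrap term `Q(s', a')`
#' equal to 0 on the terminal (goal-entering) step. `TD0` updates the
#' current pair only; `TDLAMBDA` first decays every trace entry by `lam` and
#' adds 1 to the current pair, then updates all pairs by
#' `alpha * delta * e`; `TD1` holds a replacing trace at 1 for every pair
#' visited this trial (set `td1_accumulating = TRUE` for the literal
#' lambda = 1 accumulating variant).
#'
#' @param params a [model_params()] object.
#' @param q numeric matrix `n_states x 4` of model-free values for the
#'   trial's goal (states in row-major room order, columns up/down/left/right).
#' @param trace numeric matrix like `q`, the trial's eligibility trace.
#' @param grid a `nav_task` or grid list.
#' @param step list with `state`, `action`, `next_state` (rooms / action
#'   name) and `reward`.
#' @param next_action the action actually taken from `next_state`, or
#'   `"TERMINAL"` when `next_state` is the goal.
#' @param td1_accumulating use the accumulating lambda = 1 trace for TD(1).
#' @return list with updated `q` and `trace`.
#' @export
td_update <- function(params, q, trace, grid, step, next_action,
                      td1_accumulating = FALSE) {
  grid <- as_grid(grid)
  stopifnot(inherits(params, "nav_params"))
  s <- state_index(grid, step$state) - 1L
  a <- match(step$action, ACTIONS) - 1L
  s2 <- state_index(grid, step$next_state) - 1L
  terminal <- identical(next_action, "TERMINAL")
  a2 <- if (terminal) -1L else match(next_action, ACTIONS) - 1L
  if (is.na(a) || (!terminal && is.na(a2))) stop("unknown action")
  td_update_cpp(q, trace, MODEL_CODE[[params$model_kind]],
                if (is.na(params$alpha)) 0 else params$alpha,
                if (is.na(params$lam)) 0 else params$lam,
                s, a, step$reward, s2, a2,
                grid$n_rows, grid$n_cols, td1_accumulating)
}

#' Model-based action values from dynamic programming
#'
#' Value-iteration sweep over all rooms, terminating at the goal, repeated
#' until the largest absolute change falls below `tol`. On this
#' deterministic grid the converged value of taking action `a` from `s`
#' (landing in `s'` at room distance `d` from the goal) is
#' `reward * gamma^d`. These values assume a perfect cognitive map: they are
#' identical for all participants and are never updated.
#'
#' @param task a [nav_task()].
#' @param gamma discount factor (default 0.8).
#' @param tol convergence threshold on the sweep (default 1e-4).
#' @return numeric array `n_states x 4 x n_goals` with `NA` for illegal
#'   actions; dimnames give actions and goal ids.
#' @export
mb_values <- function(task, gamma = 0.8, tol = 1e-4) {
  stopifnot(inherits(task, "nav_task"))
  if (tol <= 0) stop("tol must be positive")
  g <- task$grid
  out <- vapply(task$goals, function(goal) {
    mb_values_cpp(g$n_rows, g$n_cols, state_index(g, goal) - 1L,
                  gamma, tol, task$reward_magnitude)
  }, matrix(0, g$n_rows * g$n_cols, 4))
  dimnames(out) <- list(NULL, ACTIONS, names(task$goals))
  out
}

#' Export model-based values as a tidy table
#'
#' @param task a [nav_task()].
#' @param q_mb array from [mb_values()]; recomputed if missing.
#' @return tibble with goal_id, row, col, action, value (legal actions only).
#' @export
mb_values_table <- function(task, q_mb = mb_values(task)) {
  g <- task$grid
  rows <- lapply(names(task$goals), function(gid) {
    m <- q_mb[, , gid]
    idx <- which(!is.na(m), arr.ind = TRUE)
    rooms <- t(vapply(idx[, 1], function(i) state_room(g, i), integer(2)))
    tibble::tibble(goal_id = gid, row = rooms[, 1], col = rooms[, 2],
                   action = ACTIONS[idx[, 2]], value = m[idx])
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$goal_id, .data$row, .data$col)
}

#' Hybrid action values
#'
#' Entrywise mixture `(1 - omega) * Q_MF + omega * Q_MB`. At omega = 0 the
#' hybrid reduces to the model-free learner, at omega = 1 to the model-based
#' values.
#'
#' @param q_mf,q_mb arrays of identical shape (and dimnames, if any).
#' @param omega model-based weight in \[0, 1\].
#' @return array like the inputs.
#' @export
hybrid_q <- function(q_mf, q_mb, omega) {
  stopifnot(omega >= 0, omega <= 1)
  if (!identical(dim(q_mf), dim(q_mb)) ||
      !identical(dimnames(q_mf), dimnames(q_mb)))
    stop("q_mf and q_mb must cover identical (goal, state, action) keys")
  (1 - omega) * q_mf + omega * q_mb
}
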