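# Independent oracles: slow, matrix-based re-implementations used only to
# check the package's C++ core. They share no code with the replay path.

ACTS <- c("up", "down", "left", "right")

# closed-form model-based values: Q(s, a) = reward * gamma^d(next, goal)
oracle_mb <- function(task, gamma = 0.8) {
  g <- task$grid
  nS <- g$n_rows * g$n_cols
  gids <- names(task$goals)
  q <- array(NA_real_, c(nS, 4, length(gids)),
             dimnames = list(NULL, ACTS, gids))
  for (gi in seq_along(gids)) {
    goal <- task$goals[[gids[gi]]]
    for (s in seq_len(nS)) {
      room <- c((s - 1) %/% g$n_cols, (s - 1) %% g$n_cols)
      legal <- available_actions(g, room)
      for (a in seq_along(ACTS)) {
        if (!ACTS[a] %in% legal) next
        nxt <- step_room(g, room, ACTS[a])
        q[s, a, gi] <- task$reward_magnitude *
          gamma^shortest_path_rooms(g, nxt, goal)
      }
    }
  }
  q
}

# one full-matrix TD update (terminal step: s2 = NA)
oracle_update <- function(kind, q, e, alpha, lam, s, a, r, s2, a2) {
  boot <- if (is.na(s2)) 0 else q[s2, a2]
  delta <- r + boot - q[s, a]
  if (kind == "TD0") {
    q[s, a] <- q[s, a] + alpha * delta
  } else if (kind != "MB") {
    if (kind == "TD1") {
      e[s, a] <- 1
    } else {  # TDLAMBDA and the hybrid's model-free component
      e <- lam * e
      e[s, a] <- e[s, a] + 1
    }
    q <- q + alpha * delta * e
  }
  list(q = q, e = e)
}

# plain-R likelihood replay over a trajectory tibble (one participant)
oracle_nll <- function(data, phase, kind, alpha, theta, lam, omega, task,
                       warm_start = TRUE, gamma = 0.8) {
  g <- task$grid
  nS <- g$n_rows * g$n_cols
  gids <- names(task$goals)
  qmb <- oracle_mb(task, gamma)
  q <- array(0, c(nS, 4, length(gids)))
  d <- data[order(factor(data$phase, c("fixed", "random")),
                  data$trial_index, data$step_index), ]
  d <- d[!d$truncated, ]
  if (phase == "fixed") d <- d[d$phase == "fixed", ]
  if (phase == "random" && !warm_start) d <- d[d$phase == "random", ]
  count <- switch(phase, fixed = d$phase == "fixed",
                  random = d$phase == "random", both = rep(TRUE, nrow(d)))
  key <- paste(d$phase, d$trial_index)
  nll <- 0
  for (rows in split(seq_len(nrow(d)), factor(key, levels = unique(key)))) {
    e <- matrix(0, nS, 4)
    gi <- match(d$goal_id[rows[1]], gids)
    sprev <- aprev <- NA
    for (j in seq_along(rows)) {
      i <- rows[j]
      s <- d$row[i] * g$n_cols + d$col[i] + 1
      a <- match(d$action[i], ACTS)
      if (count[i]) {
        legal <- which(!is.na(qmb[s, , gi]))
        qeff <- switch(kind,
                       MB = qmb[s, legal, gi],
                       HYBRID = (1 - omega) * q[s, legal, gi] +
                         omega * qmb[s, legal, gi],
                       q[s, legal, gi])
        pr <- exp(theta * qeff - max(theta * qeff))
        pr <- pr / sum(pr)
        nll <- nll - log(unname(pr[match(a, legal)]))
      }
      if (j > 1) {
        upd <- oracle_update(kind, q[, , gi], e, alpha, lam,
                             sprev, aprev, 0, s, a)
        q[, , gi] <- upd$q
        e <- upd$e
      }
      sprev <- s
      aprev <- a
      if (j == length(rows) && d$reward[i] > 0) {
        upd <- oracle_update(kind, q[, , gi], e, alpha, lam,
                             s, a, d$reward[i], NA, NA)
        q[, , gi] <- upd$q
        e <- upd$e
      }
    }
  }
  nll
}

# uniform random-walk navigator following the two-phase protocol; built
# directly on the grid primitives, independent of the package simulator
random_walk_data <- function(task, pid = "P1", seed = 1, max_steps = 5000) {
  withr::with_seed(seed, {
    gids <- names(task$goals)
    plan <- data.frame(
      phase = rep(c("fixed", "random"),
                  c(task$n_fixed_trials, task$n_random_trials)),
      trial_index = c(seq_len(task$n_fixed_trials),
                      seq_len(task$n_random_trials)),
      goal_id = c(make_goal_order("fixed", task$n_fixed_trials, gids),
                  make_goal_order("random", task$n_random_trials, gids)))
    starts <- rbind(sample_start(task, "fixed", task$n_fixed_trials),
                    sample_start(task, "random", task$n_random_trials))
    out <- list()
    for (t in seq_len(nrow(plan))) {
      room <- starts[t, ]
      goal <- task$goals[[plan$goal_id[t]]]
      for (k in seq_len(max_steps)) {
        acts <- available_actions(task$grid, room)
        a <- sample(acts, 1)
        nxt <- step_room(task$grid, room, a)
        hit <- all(nxt == goal)
        out[[length(out) + 1]] <- data.frame(
          participant_id = pid, phase = plan$phase[t],
          trial_index = plan$trial_index[t], goal_id = plan$goal_id[t],
          step_index = k, row = room[1], col = room[2], action = a,
          next_row = nxt[1], next_col = nxt[2],
          reward = if (hit) task$reward_magnitude else 0,
          truncated = FALSE)
        room <- nxt
        if (hit) break
      }
    }
    tibble::as_tibble(do.call(rbind, out))
  })
}

# a small task for fast tests
tiny_task <- function() {
  nav_task(n_rows = 4, n_cols = 4,
           goals = list(G1 = c(0, 3), G2 = c(3, 0), G3 = c(3, 3)),
           fixed_start = c(0, 0), n_fixed_trials = 3, n_random_trials = 6)
}
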