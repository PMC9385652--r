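test_that("BIC follows k ln n + 2 nll", {
  expect_equal(bic(10, 2, 9), 2 * log(9) + 20)
  expect_equal(bic(100, 1, 72), log(72) + 200)
  expect_equal(bic(7.5, 0, 40), 15)
  expect_error(bic(1, 2, 0), ">= 1")
})

test_that("replay at all-zero values equals the uniform counting oracle", {
  task <- nav_task()
  d <- random_walk_data(task, seed = 7)
  # alpha = 0 keeps every model-free value at its initial 0
  p <- model_params("TD0", alpha = 0, theta = 9)
  g <- task$grid
  n_legal <- mapply(function(r, c) length(available_actions(g, c(r, c))),
                    d$row, d$col)
  for (ph in c("fixed", "random", "both")) {
    counted <- switch(ph, fixed = d$phase == "fixed",
                      random = d$phase == "random", both = rep(TRUE, nrow(d)))
    expect_equal(trajectory_nll(d, ph, p, task),
                 sum(log(n_legal[counted])), tolerance = 1e-10)
  }
})

test_that("likelihood replay matches an independent plain-R replay", {
  task <- tiny_task()
  d <- random_walk_data(task, seed = 31)
  cases <- list(
    list(kind = "TD0", alpha = 0.5, theta = 2, lam = 0, omega = 0),
    list(kind = "TD1", alpha = 0.4, theta = 3, lam = 0, omega = 0),
    list(kind = "TDLAMBDA", alpha = 0.6, theta = 4, lam = 0.7, omega = 0),
    list(kind = "MB", alpha = 0, theta = 5, lam = 0, omega = 0),
    list(kind = "HYBRID", alpha = 0.3, theta = 6, lam = 0.4, omega = 0.55))
  for (cs in cases) {
    p <- model_params(cs$kind, alpha = cs$alpha, theta = cs$theta,
                      lam = cs$lam, omega = cs$omega)
    for (ph in c("fixed", "random", "both")) {
      expect_equal(
        trajectory_nll(d, ph, p, task),
        oracle_nll(d, ph, cs$kind, cs$alpha, cs$theta, cs$lam, cs$omega,
                   task),
        tolerance = 1e-8,
        label = sprintf("%s / %s", cs$kind, ph))
    }
  }
})

test_that("replay is deterministic and warm/cold starts differ", {
  task <- nav_task()
  d <- random_walk_data(task, seed = 13)
  p <- model_params("TDLAMBDA", alpha = 0.5, theta = 4, lam = 0.5)
  n1 <- trajectory_nll(d, "random", p, task)
  n2 <- trajectory_nll(d, "random", p, task)
  expect_identical(n1, n2)
  n_cold <- trajectory_nll(d, "random", p, task, warm_start = FALSE)
  expect_false(isTRUE(all.equal(n1, n_cold)))
  expect_equal(n_cold,
               oracle_nll(d, "random", "TDLAMBDA", 0.5, 4, 0.5, 0, task,
                          warm_start = FALSE), tolerance = 1e-8)
})

test_that("TD(lambda = 0) reproduces TD(0) exactly", {
  task <- tiny_task()
  for (k in 1:10) {
    d <- random_walk_data(task, seed = 200 + k)
    p0 <- model_params("TD0", alpha = 0.47, theta = 3)
    pl <- model_params("TDLAMBDA", alpha = 0.47, theta = 3, lam = 0)
    r0 <- trajectory_nll(d, "both", p0, task, details = TRUE)
    rl <- trajectory_nll(d, "both", pl, task, details = TRUE)
    expect_equal(r0$nll, rl$nll, tolerance = 1e-12)
    expect_equal(r0$q_mf, rl$q_mf, tolerance = 1e-12)
  }
})

test_that("hybrid at omega endpoints equals the pure models", {
  task <- tiny_task()
  d <- random_walk_data(task, seed = 57)
  h0 <- model_params("HYBRID", alpha = 0.4, theta = 5, lam = 0.6, omega = 0)
  td <- model_params("TDLAMBDA", alpha = 0.4, theta = 5, lam = 0.6)
  expect_equal(trajectory_nll(d, "both", h0, task),
               trajectory_nll(d, "both", td, task), tolerance = 1e-12)
  h1 <- model_params("HYBRID", alpha = 0.4, theta = 5, lam = 0.6, omega = 1)
  mb <- model_params("MB", theta = 5)
  expect_equal(trajectory_nll(d, "both", h1, task),
               trajectory_nll(d, "both", mb, task), tolerance = 1e-12)
})

test_that("MLE pushes theta to the bounds for random and greedy data", {
  task <- nav_task()
  # uniform random walker: the most random available policy fits best
  d <- random_walk_data(task, seed = 91)
  f <- fit_mle(d, "random", "MB", task, n_restarts = 5, seed = 2)
  expect_lt(f$theta, 1.3)
  # deterministic shortest-path (greedy on model-based values) navigator
  qmb <- mb_values(task)
  g <- task$grid
  gids <- names(task$goals)
  rows <- list()
  for (t in seq_along(gids)) {
    room <- c(5, 2)
    goal <- task$goals[[gids[t]]]
    k <- 1
    while (!all(room == goal)) {
      s <- room[1] * 6 + room[2] + 1
      a <- which.max(ifelse(is.na(qmb[s, , t]), -Inf, qmb[s, , t]))
      nxt <- step_room(g, room, c("up", "down", "left", "right")[a])
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = "G", phase = "fixed", trial_index = t,
        goal_id = gids[t], step_index = k, row = room[1], col = room[2],
        action = c("up", "down", "left", "right")[a],
        next_row = nxt[1], next_col = nxt[2],
        reward = as.numeric(all(nxt == goal)), truncated = FALSE)
      room <- nxt
      k <- k + 1
    }
  }
  dg <- tibble::as_tibble(do.call(rbind, rows))
  fg <- fit_mle(dg, "fixed", "MB", task, n_restarts = 5, seed = 2)
  expect_equal(fg$theta, 15, tolerance = 1e-6)
})

test_that("fitted TD(0) parameters recover the generating values", {
  task <- nav_task()
  ag <- agent_spec("R1", model_kind = "TD0", alpha = 0.3, theta_fixed = 5,
                   theta_random = 5)
  d <- simulate_agent(ag, task, seed = 202)
  f <- fit_mle(d, "both", "TD0", task, n_restarts = 8, seed = 5)
  expect_lt(abs(f$alpha - 0.3), 0.15)
  expect_lt(abs(f$theta - 5), 2)
  expect_equal(f$bic, f$k * log(f$n) + 2 * f$nll, tolerance = 1e-9)
  expect_equal(f$n, 81)
})

test_that("fit is invariant to row shuffling within step-sorted trials", {
  task <- tiny_task()
  d <- random_walk_data(task, seed = 44)
  f1 <- fit_mle(d, "both", "TD0", task, n_restarts = 3, seed = 9)
  set.seed(1)
  f2 <- fit_mle(d[sample(nrow(d)), ], "both", "TD0", task, n_restarts = 3,
                seed = 9)
  expect_equal(f1, f2)
})

test_that("model comparison penalises parameters and reports winners", {
  mk <- function(pid, model, nll, k, n) {
    tibble::tibble(participant_id = pid, phase = "fixed", model = model,
                   alpha = NA, theta = NA, lam = NA, omega = NA, nll = nll,
                   k = k, n = n, bic = bic(nll, k, n), n_restarts = 1,
                   seed = 1, best_restart = 1)
  }
  fits <- dplyr::bind_rows(
    mk("p1", "TDLAMBDA", 10, 3, 9), mk("p1", "TD0", 10, 2, 9),
    mk("p2", "TDLAMBDA", 10, 3, 9), mk("p2", "TD0", 10, 2, 9))
  cmp <- compare_models(fits, "fixed")
  # identical NLL: the smaller model wins by exactly ln 9
  expect_equal(unname(cmp$pairwise["TDLAMBDA", "TD0"]), log(9))
  expect_true(all(cmp$winners$model == "TD0"))
  expect_equal(cmp$summary$n_wins[cmp$summary$model == "TD0"], 2)
  # equal BIC and equal k: lexicographic tie-break
  tie <- dplyr::bind_rows(mk("p1", "TD1", 10, 2, 9), mk("p1", "TD0", 10, 2, 9))
  expect_equal(compare_models(tie, "fixed")$winners$model, "TD0")
  # a missing cell is an error naming the gap
  expect_error(compare_models(fits[-2, ], "fixed"), "p1")
  expect_error(compare_models(mk("p1", "TD0", 5, 2, 9), "random"), "no fits")
})
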