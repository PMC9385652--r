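test_that("goal orders follow the phase protocols", {
  gids <- c("G1", "G2", "G3")
  expect_equal(make_goal_order("fixed", 9, gids),
               rep(c("G1", "G2", "G3"), 3))
  ord <- make_goal_order("random", 72, gids, seed = 5)
  blocks <- matrix(ord, nrow = 3)
  for (b in seq_len(ncol(blocks)))
    expect_setequal(blocks[, b], gids)
  expect_identical(ord, make_goal_order("random", 72, gids, seed = 5))
  expect_error(make_goal_order("random", 70, gids), "divisible")
})

test_that("start rooms respect the phase rules", {
  task <- nav_task()
  s <- sample_start(task, "fixed", n = 5)
  expect_true(all(s[, 1] == 0 & s[, 2] == 0))
  draws <- sample_start(task, "random", n = 10000, seed = 8)
  goal_keys <- vapply(task$goals, paste, collapse = ",", character(1))
  keys <- paste(draws[, 1], draws[, 2], sep = ",")
  expect_false(any(keys %in% goal_keys))
  # frequencies within 3 sd of uniform over the 33 non-goal rooms
  tab <- table(keys)
  expect_equal(length(tab), 33)
  expected <- 10000 / 33
  sd3 <- 3 * sqrt(10000 * (1 / 33) * (32 / 33))
  expect_true(all(abs(tab - expected) <= sd3))
})

test_that("simulated trials are well-formed and deterministic", {
  task <- nav_task()
  ag <- agent_spec("S1", theta_fixed = 6, theta_random = 4)
  d <- simulate_agent(ag, task, seed = 77)
  expect_silent(validate_trajectories(d, task))
  expect_identical(d, simulate_agent(ag, task, seed = 77))
  expect_equal(length(unique(d$trial_index[d$phase == "fixed"])), 9)
  expect_equal(length(unique(d$trial_index[d$phase == "random"])), 72)
  # fixed-phase goal order is shared across agents
  d2 <- simulate_agent(agent_spec("S2", alpha = 0.2), task, seed = 991)
  ord1 <- d$goal_id[d$phase == "fixed"][!duplicated(
    d$trial_index[d$phase == "fixed"])]
  ord2 <- d2$goal_id[d2$phase == "fixed"][!duplicated(
    d2$trial_index[d2$phase == "fixed"])]
  expect_equal(ord1, ord2)
  expect_equal(ord1, rep(c("G1", "G2", "G3"), 3))
  expect_error(simulate_agent(ag, task, seed = NULL), "seed")
})

test_that("a fully model-based exploitative agent navigates near-optimally", {
  task <- nav_task()
  eds <- sapply(1:5, function(k) {
    ag <- agent_spec(paste0("O", k), model_kind = "MB", theta_fixed = 15,
                     theta_random = 15, omega_fixed = 1, omega_random = 1)
    d <- simulate_agent(ag, task, seed = 300 + k)
    e <- ed_table(d, task)
    mean(e$ed[e$phase == "random"])
  })
  # near-optimal but not perfect: far from the goal the value differences
  # shrink as gamma^d, so even theta = 15 leaves a little residual wander
  expect_lt(mean(eds), 0.15)
})

test_that("mean excessive distance decreases with theta for map-guided agents", {
  task <- nav_task()
  mean_ed <- sapply(c(1, 5, 15), function(th) {
    eds <- sapply(1:100, function(k) {
      ag <- agent_spec("T", model_kind = "MB", theta_fixed = th,
                       theta_random = th, omega_fixed = 1, omega_random = 1)
      d <- simulate_agent(ag, task, seed = 1000 * th + k)
      e <- ed_table(d, task)
      mean(e$ed[e$phase == "random"])
    })
    mean(eds)
  })
  expect_true(all(diff(mean_ed) < 0))
})

test_that("first-trial choices of a naive random agent are uniform", {
  task <- nav_task()
  # theta = 1 with all-zero values: first step from the corner start is a
  # fair coin between the two legal actions
  firsts <- sapply(1:400, function(k) {
    ag <- agent_spec("U", model_kind = "TD0", alpha = 0.5, theta_fixed = 1,
                     theta_random = 1)
    d <- simulate_agent(ag, task, seed = 5000 + k)
    d$action[1]
  })
  counts <- table(factor(firsts, c("down", "right")))
  expect_gt(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value, 0.001)
})

test_that("cohort sampling hits the target omega-theta correlation", {
  spec <- cohort_spec(n_agents = 200, rho_fixed = 0.25, rho_random = -0.35)
  b <- param_bounds()
  params <- withr::with_seed(1, {
    # sample parameters only (no trajectories) via the exported pieces
    simulate_cohort(cohort_spec(n_agents = 200,
                                task = tiny_task(),
                                rho_fixed = 0.25, rho_random = -0.35,
                                max_steps = 200),
                    seed = 10)$params
  })
  expect_equal(nrow(params), 200)
  for (nm in c("alpha", "lam")) {
    expect_true(all(params[[nm]] >= 0 & params[[nm]] <= 1))
  }
  expect_true(all(params$theta_fixed >= 1 & params$theta_fixed <= 15))
  expect_true(all(params$omega_random >= 0 & params$omega_random <= 1))
  sf <- cor(params$omega_fixed, params$theta_fixed, method = "spearman")
  sr <- cor(params$omega_random, params$theta_random, method = "spearman")
  expect_lt(abs(sf - 0.25), 0.12)
  expect_lt(abs(sr + 0.35), 0.12)
  # zero target: empirical correlation small
  p0 <- simulate_cohort(cohort_spec(n_agents = 200, task = tiny_task(),
                                    rho_fixed = 0, rho_random = 0,
                                    max_steps = 200), seed = 11)$params
  expect_lt(abs(cor(p0$omega_fixed, p0$theta_fixed, method = "spearman")),
            0.15)
  # determinism of the whole cohort
  c1 <- simulate_cohort(cohort_spec(n_agents = 5, task = tiny_task(),
                                    max_steps = 200), seed = 3)
  c2 <- simulate_cohort(cohort_spec(n_agents = 5, task = tiny_task(),
                                    max_steps = 200), seed = 3)
  expect_identical(c1, c2)
  expect_error(cohort_spec(rho_fixed = 1), "\\(-1, 1\\)")
})

test_that("a strongly planted omega-theta correlation survives refitting", {
  # the correlation computed from fitted parameters is attenuated by
  # estimation noise, but for a strong planted value its sign must survive
  task <- nav_task()
  qmb <- mb_values(task)
  coh <- simulate_cohort(cohort_spec(n_agents = 100, rho_random = -0.5),
                         seed = 88, q_mb = qmb)
  fits <- fit_cohort(coh$trajectories, task, models = "HYBRID",
                     phases = "random", n_restarts = 5, seed = 89,
                     q_mb = qmb)
  expect_lt(cor(fits$omega, fits$theta), 0)
})

test_that("the generating parameters are near a likelihood optimum", {
  task <- nav_task()
  cs <- cohort_spec(n_agents = 50, max_steps = 2000)
  coh <- simulate_cohort(cs, seed = 42)
  qmb <- mb_values(task)
  diffs <- sapply(seq_len(nrow(coh$params)), function(i) {
    p <- coh$params[i, ]
    d <- coh$trajectories[coh$trajectories$participant_id == p$agent_id, ]
    at <- function(alpha, theta, lam, omega) {
      trajectory_nll(d, "random",
                     model_params("HYBRID", alpha = alpha, theta = theta,
                                  lam = lam, omega = omega),
                     task, q_mb = qmb)
    }
    truth <- at(p$alpha, p$theta_random, p$lam, p$omega_random)
    bnd <- param_bounds()
    cl <- function(x, b) min(max(x, b[1]), b[2])
    pert <- c(
      at(cl(p$alpha + 0.2, bnd$alpha), p$theta_random, p$lam, p$omega_random),
      at(cl(p$alpha - 0.2, bnd$alpha), p$theta_random, p$lam, p$omega_random),
      at(p$alpha, p$theta_random, p$lam, cl(p$omega_random + 0.2, bnd$omega)),
      at(p$alpha, p$theta_random, p$lam, cl(p$omega_random - 0.2, bnd$omega)))
    mean(pert) - truth
  })
  expect_gt(mean(diffs), 0)
})
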