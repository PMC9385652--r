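#' Goal order for a phase
#'
#' Fixed phase: the goals cycle in their task order for every participant.
#' Random phase: within each consecutive block of three trials the goals are
#' an independent seeded permutation, so each goal is found exactly once per
#' block but in an unpredictable order.
#'
#' @param phase `"fixed"` or `"random"`.
#' @param n_trials number of trials; must be divisible by the number of
#'   goals in the random phase.
#' @param goals character vector of goal ids.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return character vector of goal ids, length `n_trials`.
#' @export
make_goal_order <- function(phase, n_trials, goals, seed = NULL) {
  phase <- match.arg(phase, c("fixed", "random"))
  draw <- function() {
    if (phase == "fixed") {
      rep_len(goals, n_trials)
    } else {
      if (n_trials %% length(goals) != 0)
        stop("random-phase n_trials must be divisible by the number of goals")
      as.vector(vapply(seq_len(n_trials %/% length(goals)),
                       function(i) sample(goals), character(length(goals))))
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Start rooms for a phase
#'
#' Fixed phase: always the task's fixed start. Random phase: uniform over
#' the non-goal rooms.
#'
#' @param task a [nav_task()].
#' @inheritParams make_goal_order
#' @param n number of draws.
#' @return integer matrix `n x 2` of rooms (row, col).
#' @export
sample_start <- function(task, phase, n = 1, seed = NULL) {
  phase <- match.arg(phase, c("fixed", "random"))
  g <- task$grid
  draw <- function() {
    if (phase == "fixed") {
      matrix(rep(task$fixed_start, each = n), n, 2)
    } else {
      goal_idx <- vapply(task$goals, function(x) state_index(g, x), integer(1))
      pool <- setdiff(seq_len(g$n_rows * g$n_cols), goal_idx)
      idx <- pool[sample.int(length(pool), n, replace = TRUE)]
      t(vapply(idx, function(i) state_room(g, i), integer(2)))
    }
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(out) <- c("row", "col")
  out
}

#' Specify a generative agent
#'
#' One softmax RL navigator. `theta` and `omega` may differ between phases
#' (strategy and choice consistency shift at the phase boundary); `alpha`
#' and `lam` are shared.
#'
#' @param agent_id identifier used as `participant_id` in the output.
#' @param model_kind generative model (default `"HYBRID"`).
#' @param alpha,lam learning rate and trace decay.
#' @param theta_fixed,theta_random inverse temperature per phase.
#' @param omega_fixed,omega_random model-based weight per phase.
#' @param max_steps cap on steps per trial; trials hitting it are flagged
#'   truncated (humans always found the goal; a near-random agent may not).
#' @return list of class `nav_agent`.
#' @export
agent_spec <- function(agent_id, model_kind = "HYBRID", alpha = 0.35,
                       theta_fixed = 8, theta_random = 5, lam = 0.5,
                       omega_fixed = 0.35, omega_random = 0.6,
                       max_steps = 2000) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  b <- param_bounds()
  chk <- function(nm, v) {
    if (v < b[[nm]][1] || v > b[[nm]][2])
      stop(sprintf("'%s' = %g outside [%g, %g]", nm, v, b[[nm]][1], b[[nm]][2]))
  }
  chk("alpha", alpha); chk("lam", lam)
  chk("theta", theta_fixed); chk("theta", theta_random)
  chk("omega", omega_fixed); chk("omega", omega_random)
  structure(list(agent_id = agent_id, model_kind = model_kind, alpha = alpha,
                 theta_fixed = theta_fixed, theta_random = theta_random,
                 lam = lam, omega_fixed = omega_fixed,
                 omega_random = omega_random,
                 max_steps = as.integer(max_steps)),
            class = "nav_agent")
}

#' Simulate one agent on the task
#'
#' Runs the Fixed then the Random protocol: goal orders and start rooms are
#' drawn first under `seed`, then the agent navigates each trial by softmax
#' choice over its effective values, learning online through exactly the
#' same update code the likelihood replay uses. Values carry across trials
#' and phases; traces reset each trial; a trial ends when the goal room is
#' entered or at `max_steps` (flagged truncated).
#'
#' @param agent an [agent_spec()].
#' @param task a [nav_task()].
#' @param seed integer seed; the run is a pure function of (agent, task, seed).
#' @param q_mb precomputed [mb_values()] (recomputed if missing).
#' @param td1_accumulating TD(1) trace variant, see [td_update()].
#' @return trajectory tibble in the package step schema.
#' @export
simulate_agent <- function(agent, task, seed, q_mb = NULL,
                           td1_accumulating = FALSE) {
  stopifnot(inherits(agent, "nav_agent"), inherits(task, "nav_task"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  g <- task$grid
  if (agent$max_steps < (g$n_rows - 1) + (g$n_cols - 1))
    stop("max_steps is below the longest shortest path on the grid")
  if (is.null(q_mb)) q_mb <- mb_values(task)
  gids <- names(task$goals)
  goal_states <- vapply(task$goals, function(x) state_index(g, x) - 1L,
                        integer(1))
  withr::with_seed(as.integer(seed), {
    goal_order <- c(make_goal_order("fixed", task$n_fixed_trials, gids),
                    make_goal_order("random", task$n_random_trials, gids))
    starts <- rbind(sample_start(task, "fixed", task$n_fixed_trials),
                    sample_start(task, "random", task$n_random_trials))
    phase <- rep(c(0L, 1L), c(task$n_fixed_trials, task$n_random_trials))
    raw <- simulate_agent_cpp(
      g$n_rows, g$n_cols, unname(goal_states),
      match(goal_order, gids) - 1L,
      as.integer(starts[, 1] * g$n_cols + starts[, 2]), phase,
      MODEL_CODE[[agent$model_kind]], agent$alpha,
      c(agent$theta_fixed, agent$theta_random), agent$lam,
      c(agent$omega_fixed, agent$omega_random),
      as.numeric(q_mb_for_core(q_mb)), task$reward_magnitude,
      agent$max_steps, td1_accumulating)
    t_all <- raw$trial + 1L
    phase_of_row <- phase[t_all]
    tibble::tibble(
      participant_id = as.character(agent$agent_id),
      phase = c("fixed", "random")[phase_of_row + 1L],
      trial_index = ifelse(phase_of_row == 0L, t_all,
                           t_all - task$n_fixed_trials),
      goal_id = goal_order[t_all],
      step_index = raw$step + 1L,
      row = raw$state %/% g$n_cols, col = raw$state %% g$n_cols,
      action = ACTIONS[raw$action + 1L],
      next_row = raw$next_state %/% g$n_cols,
      next_col = raw$next_state %% g$n_cols,
      reward = raw$reward,
      truncated = raw$truncated[t_all] == 1L)
  })
}

#' Simulate a table of agents
#'
#' @param params tibble with one row per agent: `agent_id`, `model_kind`,
#'   `alpha`, `theta_fixed`, `theta_random`, `lam`, `omega_fixed`,
#'   `omega_random` (missing parameter columns fall back to the
#'   [agent_spec()] defaults).
#' @param task a [nav_task()].
#' @param seed master seed; per-agent seeds are drawn from it.
#' @param max_steps per-trial step cap.
#' @inheritParams simulate_agent
#' @return list with `trajectories` (all agents row-bound) and `params`
#'   (the input plus each agent's simulation seed).
#' @export
simulate_agents <- function(params, task, seed, max_steps = 2000,
                            q_mb = NULL, td1_accumulating = FALSE) {
  if (is.null(q_mb)) q_mb <- mb_values(task)
  n <- nrow(params)
  agent_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(2147483646L, n))
  defaults <- agent_spec("x")
  get_col <- function(nm) {
    if (nm %in% names(params)) params[[nm]] else rep(defaults[[nm]], n)
  }
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    ag <- agent_spec(params$agent_id[i],
                     model_kind = as.character(get_col("model_kind")[i]),
                     alpha = get_col("alpha")[i],
                     theta_fixed = get_col("theta_fixed")[i],
                     theta_random = get_col("theta_random")[i],
                     lam = get_col("lam")[i],
                     omega_fixed = get_col("omega_fixed")[i],
                     omega_random = get_col("omega_random")[i],
                     max_steps = max_steps)
    trajs[[i]] <- simulate_agent(ag, task, agent_seeds[i], q_mb = q_mb,
                                 td1_accumulating = td1_accumulating)
  }
  out_params <- params
  out_params$seed <- agent_seeds
  list(trajectories = dplyr::bind_rows(trajs), params = out_params)
}

#' Specify a synthetic cohort
#'
#' Marginal parameter distributions plus a target Spearman correlation
#' between omega and theta within each phase, induced by a Gaussian copula.
#' Each marginal is `list(dist = "uniform", lo =, hi =)` or
#' `list(dist = "tnorm", mean =, sd =)` (normal truncated to the parameter
#' bounds). Defaults emulate the qualitative regime of the human study:
#' omega stochastically larger and theta stochastically smaller in the
#' Random phase, omega-theta correlation positive in Fixed and negative in
#' Random.
#'
#' @param n_agents cohort size (default 114, the study's sample size).
#' @param task a [nav_task()].
#' @param alpha,lam marginals of the shared parameters.
#' @param theta_fixed,theta_random,omega_fixed,omega_random per-phase
#'   marginals.
#' @param rho_fixed,rho_random target Spearman correlation between omega and
#'   theta in each phase, in (-1, 1).
#' @param model_kind generative model for every agent.
#' @param max_steps per-trial step cap.
#' @return list of class `nav_cohort_spec`.
#' @export
cohort_spec <- function(n_agents = 114, task = nav_task(),
                        alpha = list(dist = "tnorm", mean = 0.35, sd = 0.15),
                        lam = list(dist = "tnorm", mean = 0.5, sd = 0.25),
                        theta_fixed = list(dist = "tnorm", mean = 9, sd = 2),
                        theta_random = list(dist = "tnorm", mean = 7.5, sd = 1.2),
                        omega_fixed = list(dist = "tnorm", mean = 0.35, sd = 0.25),
                        omega_random = list(dist = "tnorm", mean = 0.55, sd = 0.3),
                        rho_fixed = 0.25, rho_random = -0.35,
                        model_kind = "HYBRID", max_steps = 2000) {
  stopifnot(n_agents >= 2)
  if (abs(rho_fixed) >= 1 || abs(rho_random) >= 1)
    stop("target correlations must lie in (-1, 1)")
  structure(list(n_agents = as.integer(n_agents), task = task,
                 marginals = list(alpha = alpha, lam = lam,
                                  theta_fixed = theta_fixed,
                                  theta_random = theta_random,
                                  omega_fixed = omega_fixed,
                                  omega_random = omega_random),
                 rho_fixed = rho_fixed, rho_random = rho_random,
                 model_kind = match.arg(model_kind, MODEL_KINDS),
                 max_steps = as.integer(max_steps)),
            class = "nav_cohort_spec")
}

# quantile of a marginal spec given uniforms in (0,1)
marginal_quantile <- function(u, spec, bounds) {
  if (spec$dist == "uniform") {
    lo <- if (!is.null(spec$lo)) spec$lo else bounds[1]
    hi <- if (!is.null(spec$hi)) spec$hi else bounds[2]
    lo + u * (hi - lo)
  } else if (spec$dist == "tnorm") {
    plo <- pnorm(bounds[1], spec$mean, spec$sd)
    phi <- pnorm(bounds[2], spec$mean, spec$sd)
    qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
  } else stop("unknown marginal dist '", spec$dist, "'")
}

# draw (omega, theta) with target Spearman rho via a Gaussian copula
copula_pair <- function(n, rho_s, omega_spec, theta_spec, b) {
  rho_l <- 2 * sin(pi * rho_s / 6)  # latent normal corr for Spearman target
  if (abs(rho_l) > 1) stop("infeasible correlation for a Gaussian copula")
  z1 <- rnorm(n)
  z2 <- rho_l * z1 + sqrt(1 - rho_l^2) * rnorm(n)
  list(omega = marginal_quantile(pnorm(z1), omega_spec, b$omega),
       theta = marginal_quantile(pnorm(z2), theta_spec, b$theta))
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Samples per-agent parameters from the cohort marginals — with the target
#' omega-theta Spearman correlation per phase induced by a Gaussian copula —
#' then simulates every agent on the Fixed/Random protocol.
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed; parameters, per-agent seeds and all trajectories
#'   are a pure function of (spec, seed).
#' @inheritParams simulate_agent
#' @return list with `trajectories` and the true-parameter table `params`.
#' @export
simulate_cohort <- function(spec, seed, q_mb = NULL,
                            td1_accumulating = FALSE) {
  stopifnot(inherits(spec, "nav_cohort_spec"))
  b <- param_bounds()
  n <- spec$n_agents
  params <- withr::with_seed(as.integer(seed), {
    fx <- copula_pair(n, spec$rho_fixed, spec$marginals$omega_fixed,
                      spec$marginals$theta_fixed, b)
    rd <- copula_pair(n, spec$rho_random, spec$marginals$omega_random,
                      spec$marginals$theta_random, b)
    tibble::tibble(
      agent_id = sprintf("A%03d", seq_len(n)),
      model_kind = spec$model_kind,
      alpha = marginal_quantile(runif(n), spec$marginals$alpha, b$alpha),
      theta_fixed = fx$theta, theta_random = rd$theta,
      lam = marginal_quantile(runif(n), spec$marginals$lam, b$lam),
      omega_fixed = fx$omega, omega_random = rd$omega)
  })
  sim <- simulate_agents(params, spec$task,
                         seed = (as.integer(seed) + 1L) %% 2147483647L,
                         max_steps = spec$max_steps, q_mb = q_mb,
                         td1_accumulating = td1_accumulating)
  list(trajectories = sim$trajectories, params = sim$params)
}
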