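#' Bayesian Information Criterion
#'
#' `k * ln(n) + 2 * nll` (natural logarithm). By package convention `n` is
#' the number of trials in the fitted phase.
#'
#' @param nll negative log-likelihood at the maximum-likelihood estimate.
#' @param k number of free parameters.
#' @param n sample-size term (trials, or choices if configured).
#' @export
bic <- function(nll, k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0)) stop("k must be >= 0")
  k * log(n) + 2 * nll
}

# Flatten one participant's trajectories into the replay vectors consumed by
# the C++ core. Fixed-phase steps precede Random-phase steps; for
# phase = "random" with warm_start the Fixed steps are replayed uncounted.
prep_replay <- function(data, phase, task, warm_start = TRUE,
                        include_truncated = FALSE) {
  phase <- match.arg(phase, c("both", "fixed", "random"))
  if (length(unique(data$participant_id)) != 1)
    stop("data must contain exactly one participant")
  d <- dplyr::arrange(data,
                      factor(.data$phase, c("fixed", "random")),
                      .data$trial_index, .data$step_index)
  if (!include_truncated) d <- d[!d$truncated, , drop = FALSE]
  if (phase == "fixed") d <- d[d$phase == "fixed", , drop = FALSE]
  if (phase == "random" && !warm_start)
    d <- d[d$phase == "random", , drop = FALSE]
  if (nrow(d) == 0) stop("no usable trials in the requested phase")
  grid <- task$grid
  count <- switch(phase,
                  fixed = d$phase == "fixed",
                  random = d$phase == "random",
                  both = rep(TRUE, nrow(d)))
  key <- paste(d$phase, d$trial_index)
  new_trial <- !duplicated(key)
  last_of_trial <- !duplicated(key, fromLast = TRUE)
  goal <- match(d$goal_id, names(task$goals)) - 1L
  if (anyNA(goal)) stop("goal_id not present in task goals")
  list(state = as.integer(d$row * grid$n_cols + d$col),
       action = match(d$action, ACTIONS) - 1L,
       rew = as.numeric(d$reward),
       goal = goal,
       new_trial = new_trial,
       terminal = last_of_trial & d$reward > 0,
       count = count,
       reset_q = rep(FALSE, nrow(d)),
       n_trials = length(unique(key[count])),
       n_choices = sum(count))
}

replay_with_params <- function(prep, params_vec, model_kind, task, q_mb,
                               td1_accumulating = FALSE) {
  g <- task$grid
  replay_nll_cpp(prep$state, prep$action, prep$rew, prep$goal,
                 prep$new_trial, prep$terminal, prep$count, prep$reset_q,
                 MODEL_CODE[[model_kind]],
                 params_vec[["alpha"]], params_vec[["theta"]],
                 params_vec[["lam"]], params_vec[["omega"]],
                 as.numeric(q_mb_for_core(q_mb)), g$n_rows, g$n_cols,
                 length(task$goals), td1_accumulating)
}

# the C++ core wants a dense numeric block with 0 at illegal actions
q_mb_for_core <- function(q_mb) {
  q_mb[is.na(q_mb)] <- 0
  q_mb
}

full_param_vec <- function(params) {
  c(alpha = if (is.na(params$alpha)) 0 else params$alpha,
    theta = if (is.na(params$theta)) 1 else params$theta,
    lam = if (is.na(params$lam)) 0 else params$lam,
    omega = if (is.na(params$omega)) 0 else params$omega)
}

#' Negative log-likelihood of observed room choices
#'
#' Deterministic replay of one participant's trajectories under a model.
#' Model-free values start at 0 at the beginning of the experiment and are
#' carried across trials and phases; eligibility traces reset at each trial
#' start. At every step the softmax probability of the observed action is
#' computed from the model's effective values (model-free, model-based, or
#' the hybrid mixture) over the available actions, `-log p` is accumulated,
#' and then the learning update for the previous step is applied — the same
#' choose-then-update order the generative agent uses.
#'
#' `phase = "fixed"` scores Fixed-phase choices only; `phase = "random"`
#' first replays the Fixed phase without scoring (warm start) and then
#' scores the Random phase, unless `warm_start = FALSE`, which starts the
#' Random phase from all-zero values; `phase = "both"` scores everything.
#'
#' @param data trajectory tibble (one participant) in the package's step
#'   schema; see [read_trajectories()].
#' @param phase `"both"`, `"fixed"` or `"random"`.
#' @param params a [model_params()] object.
#' @param task the [nav_task()] the data were collected on.
#' @param q_mb precomputed [mb_values()]; recomputed if missing.
#' @param warm_start replay the Fixed phase (unscored) before scoring the
#'   Random phase.
#' @param include_truncated score the partial choice sequences of truncated
#'   trials (excluded by default).
#' @param td1_accumulating TD(1) trace variant, see [td_update()].
#' @param details return a list with the final model-free values and choice
#'   count alongside the NLL.
#' @return the NLL (nonnegative scalar), or a list if `details = TRUE`.
#' @export
trajectory_nll <- function(data, phase, params, task, q_mb = NULL,
                           warm_start = TRUE, include_truncated = FALSE,
                           td1_accumulating = FALSE, details = FALSE) {
  stopifnot(inherits(params, "nav_params"), inherits(task, "nav_task"))
  if (is.null(q_mb)) q_mb <- mb_values(task)
  prep <- prep_replay(data, phase, task, warm_start, include_truncated)
  res <- replay_with_params(prep, full_param_vec(params), params$model_kind,
                            task, q_mb, td1_accumulating)
  if (!details) return(res$nll)
  g <- task$grid
  # the core's layout is [goal][state][action] with action fastest
  q <- aperm(array(res$q, dim = c(4, g$n_rows * g$n_cols,
                                  length(task$goals))), c(2, 1, 3))
  dimnames(q) <- list(NULL, ACTIONS, names(task$goals))
  list(nll = res$nll, n_choices = res$n_choices, n_trials = prep$n_trials,
       q_mf = q)
}

#' Bounded maximum-likelihood fit of one model to one participant
#'
#' Minimises the choice NLL with L-BFGS-B inside the parameter box
#' ([param_bounds()]), restarting from `n_restarts` seeded uniform-random
#' points; the best restart wins, and the reported NLL is never above the
#' NLL at any restart's starting point.
#'
#' @inheritParams trajectory_nll
#' @param model_kind one of the five model names.
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer seed for the starting points.
#' @param bic_n `"trials"` (default) counts trials in the fitted phase for
#'   the BIC's n; `"choices"` counts individual room choices.
#' @return one-row tibble: participant_id, phase, model, alpha, theta, lam,
#'   omega, nll, k, n, bic, n_restarts, seed, best_restart.
#' @export
fit_mle <- function(data, phase, model_kind, task, n_restarts = 10, seed = 1L,
                    q_mb = NULL, warm_start = TRUE, include_truncated = FALSE,
                    bic_n = c("trials", "choices"), td1_accumulating = FALSE) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  bic_n <- match.arg(bic_n)
  if (is.null(q_mb)) q_mb <- mb_values(task)
  prep <- prep_replay(data, phase, task, warm_start, include_truncated)
  free <- free_params(model_kind)
  b <- param_bounds()
  lower <- vapply(free, function(nm) b[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) b[[nm]][2], numeric(1))
  base <- c(alpha = 0, theta = 1, lam = 0, omega = 0)
  obj <- function(x) {
    v <- base
    v[free] <- x
    nll <- replay_with_params(prep, v, model_kind, task, q_mb,
                              td1_accumulating)$nll
    # extreme corners (alpha, lam near 1) can blow the model-free values up
    # to overflow; report a finite, terrible fit so the search moves on
    if (!is.finite(nll)) 1e10 else nll
  }
  starts <- withr::with_seed(seed, {
    matrix(runif(n_restarts * length(free), rep(lower, each = n_restarts),
                 rep(upper, each = n_restarts)),
           nrow = n_restarts, dimnames = list(NULL, free))
  })
  best <- NULL
  failures <- character(0)
  for (i in seq_len(n_restarts)) {
    x0 <- starts[i, ]
    f0 <- obj(x0)
    fit <- tryCatch(
      optim(x0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) {
      failures <- c(failures, sprintf("restart %d: optimiser error", i))
      cand <- list(par = x0, value = f0)
    } else if (fit$value <= f0) {
      cand <- fit
    } else {
      cand <- list(par = x0, value = f0)  # never report worse than the start
    }
    if (is.null(best) || cand$value < best$value) {
      best <- cand
      best$restart <- i
    }
  }
  if (length(failures) == n_restarts)
    stop(paste(c("all restarts failed:", failures), collapse = "\n"))
  est <- c(alpha = NA_real_, theta = NA_real_, lam = NA_real_,
           omega = NA_real_)
  est[free] <- best$par
  k <- length(free)
  n <- if (bic_n == "trials") prep$n_trials else prep$n_choices
  tibble::tibble(participant_id = data$participant_id[1], phase = phase,
                 model = model_kind, alpha = est[["alpha"]],
                 theta = est[["theta"]], lam = est[["lam"]],
                 omega = est[["omega"]], nll = best$value, k = k, n = n,
                 bic = bic(best$value, k, n), n_restarts = n_restarts,
                 seed = as.integer(seed), best_restart = best$restart)
}

#' Fit several models to every participant
#'
#' Convenience loop over participants x models x phases; each cell gets its
#' own deterministic seed derived from `seed`.
#'
#' @inheritParams fit_mle
#' @param data trajectory tibble, any number of participants.
#' @param models model names to fit.
#' @param phases phases to fit (each fit separately).
#' @return tibble of [fit_mle()] rows.
#' @export
fit_cohort <- function(data, task, models = MODEL_KINDS,
                       phases = c("fixed", "random"), n_restarts = 10,
                       seed = 1L, q_mb = NULL, warm_start = TRUE,
                       include_truncated = FALSE,
                       bic_n = c("trials", "choices"),
                       td1_accumulating = FALSE, verbose = FALSE) {
  bic_n <- match.arg(bic_n)
  if (is.null(q_mb)) q_mb <- mb_values(task)
  ids <- unique(data$participant_id)
  out <- vector("list", length(ids) * length(models) * length(phases))
  j <- 0L
  for (i in seq_along(ids)) {
    d <- data[data$participant_id == ids[i], , drop = FALSE]
    for (m in seq_along(models)) {
      for (p in seq_along(phases)) {
        j <- j + 1L
        sub_seed <- (as.integer(seed) + 7919L * i + 101L * m + p) %% 2147483647L
        out[[j]] <- fit_mle(d, phases[p], models[m], task,
                            n_restarts = n_restarts, seed = sub_seed,
                            q_mb = q_mb, warm_start = warm_start,
                            include_truncated = include_truncated,
                            bic_n = bic_n,
                            td1_accumulating = td1_accumulating)
      }
    }
    if (verbose) message(sprintf("fitted participant %s (%d/%d)",
                                 ids[i], i, length(ids)))
  }
  dplyr::bind_rows(out)
}

#' Per-phase BIC model comparison
#'
#' Summarises fits for one phase: mean and sd BIC per model, each
#' participant's winning model (minimum BIC, ties broken toward fewer
#' parameters, then lexicographic model name), winner counts, and the mean
#' pairwise BIC differences.
#'
#' @param fits tibble of [fit_mle()] rows covering every participant x model
#'   cell for `phase`.
#' @param phase which phase to compare.
#' @return list with `summary` (model, mean_bic, sd_bic, n_wins), `winners`
#'   (participant_id, model), and `pairwise` (mean BIC difference matrix,
#'   row model minus column model).
#' @export
compare_models <- function(fits, phase) {
  f <- fits[fits$phase == phase, , drop = FALSE]
  if (nrow(f) == 0) stop("no fits for phase '", phase, "'")
  models <- sort(unique(f$model))
  ids <- unique(f$participant_id)
  cells <- table(f$participant_id, f$model)
  if (any(cells != 1)) {
    gaps <- which(cells != 1, arr.ind = TRUE)
    stop("missing or duplicated participant x model cells: ",
         paste(sprintf("%s/%s", rownames(cells)[gaps[, 1]],
                       colnames(cells)[gaps[, 2]]), collapse = ", "))
  }
  winners <- dplyr::summarise(
    dplyr::group_by(f, .data$participant_id),
    model = {
      o <- order(.data$bic, .data$k, .data$model)
      .data$model[o[1]]
    }, .groups = "drop")
  summary <- dplyr::summarise(
    dplyr::group_by(f, .data$model),
    mean_bic = mean(.data$bic), sd_bic = sd(.data$bic), .groups = "drop")
  summary$n_wins <- vapply(summary$model,
                           function(m) sum(winners$model == m),
                           numeric(1), USE.NAMES = FALSE)
  wide <- matrix(NA_real_, length(ids), length(models),
                 dimnames = list(ids, models))
  wide[cbind(match(f$participant_id, ids), match(f$model, models))] <- f$bic
  pairwise <- outer(seq_along(models), seq_along(models),
                    Vectorize(function(i, j) mean(wide[, i] - wide[, j])))
  dimnames(pairwise) <- list(models, models)
  list(summary = summary, winners = winners, pairwise = pairwise,
       bic_wide = wide)
}
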