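#' Excessive distance
#'
#' `(actual - optimal) / optimal`, both measured in traversed rooms. 0 is
#' perfect wayfinding; 1 means the path was 100% longer than optimal.
#'
#' @param actual traversed room transitions (steps).
#' @param optimal shortest-path room transitions; must be at least 1.
#' @return excessive distance (dimensionless, nonnegative for
#'   goal-terminated paths).
#' @export
excessive_distance <- function(actual, optimal) {
  if (any(optimal < 1)) stop("optimal distance must be >= 1 (start != goal)")
  (actual - optimal) / optimal
}

#' Per-trial excessive distance table
#'
#' @param data trajectory tibble (any number of participants).
#' @param task the [nav_task()] the data were collected on.
#' @param truncated how to treat truncated trials: `"drop"` (default) or
#'   `"na"` (keep with `ed = NA`).
#' @return tibble: participant_id, phase, trial_index, goal_id, actual,
#'   optimal, ed.
#' @export
ed_table <- function(data, task, truncated = c("drop", "na")) {
  truncated <- match.arg(truncated)
  g <- task$grid
  d <- dplyr::summarise(
    dplyr::group_by(data, .data$participant_id, .data$phase,
                    .data$trial_index, .data$goal_id),
    actual = dplyr::n(),
    start_row = .data$row[which.min(.data$step_index)],
    start_col = .data$col[which.min(.data$step_index)],
    truncated = any(.data$truncated), .groups = "drop")
  d$optimal <- mapply(function(r, c, gid) {
    shortest_path_rooms(g, c(r, c), task$goals[[gid]])
  }, d$start_row, d$start_col, d$goal_id)
  if (any(d$optimal < 1)) stop("trial starting in its goal room")
  d$ed <- excessive_distance(d$actual, d$optimal)
  d$ed[d$truncated] <- NA_real_
  if (truncated == "drop") d <- d[!d$truncated, , drop = FALSE]
  d[, c("participant_id", "phase", "trial_index", "goal_id", "actual",
        "optimal", "ed", "truncated")]
}

#' Paired t test with Cohen's d
#'
#' Cohen's d for the paired design is `mean(x - y) / sd(x - y)`. Identical
#' vectors return t = 0, d = 0; constant non-zero differences (zero
#' variance) are an error.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list: t, df, p, cohens_d, mean_diff.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(x) - 1, p = 1, cohens_d = 0,
                  mean_diff = 0))
    stop("zero variance of non-zero differences")
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / sd(d), mean_diff = mean(d))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a complete participants x conditions
#' table. Reports the classical eta squared
#' `SS_cond / (SS_cond + SS_subj + SS_error)` alongside partial eta squared
#' `SS_cond / (SS_cond + SS_error)`.
#'
#' @param values numeric matrix or data frame, participants in rows,
#'   conditions in columns; no missing cells.
#' @return list: F, df1, df2, p, eta_sq, partial_eta_sq.
#' @export
rm_anova_oneway <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells in the participants x conditions table")
  N <- nrow(values); k <- ncol(values)
  stopifnot(N >= 3, k >= 2)
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(N), times = k)),
    cond = factor(rep(seq_len(k), each = N)))
  fit <- aov(y ~ cond + Error(subject), data = long)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  between <- s[["Error: subject"]][[1]]
  ss_cond <- within["cond", "Sum Sq"]
  ss_err <- within["Residuals", "Sum Sq"]
  ss_subj <- between["Residuals", "Sum Sq"]
  df1 <- k - 1; df2 <- (k - 1) * (N - 1)
  if (ss_cond < .Machine$double.eps * sum(values^2 + 1))
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, eta_sq = 0,
                partial_eta_sq = 0))
  Fv <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fv, df1 = df1, df2 = df2, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       eta_sq = ss_cond / (ss_cond + ss_subj + ss_err),
       partial_eta_sq = ss_cond / (ss_cond + ss_err))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors, length >= 4, non-constant.
#' @return list: r, p, n.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

fisher_z <- function(r) atanh(r)

# Pearson-Filon covariance term between r12 and r34 (same sample, no shared
# variable)
pf_cov_num <- function(r12, r34, r13, r14, r23, r24) {
  0.5 * r12 * r34 * (r13^2 + r14^2 + r23^2 + r24^2) +
    r13 * r24 + r14 * r23 -
    (r12 * r13 * r14 + r12 * r23 * r24 + r34 * r13 * r23 + r34 * r14 * r24)
}

#' Compare two dependent, non-overlapping correlations
#'
#' Tests `r12 == r34` where variables 1-2 and 3-4 are measured on the same
#' sample but share no variable (e.g. the omega-theta correlation in the
#' Fixed vs. the Random phase). The default `"fisher"` variant applies the
#' Pearson-Filon covariance with Fisher-z stabilisation; `"pearson1898"`
#' gives the classical statistic on the raw correlations.
#'
#' @param r12,r34 the two correlations under comparison.
#' @param r13,r14,r23,r24 the four cross-correlations among the variables.
#' @param n sample size (>= 10).
#' @param variant `"fisher"` (default) or `"pearson1898"`.
#' @return list: z, p (two-sided), variant.
#' @export
compare_dependent_correlations <- function(r12, r34, r13, r14, r23, r24, n,
                                           variant = c("fisher", "pearson1898")) {
  variant <- match.arg(variant)
  rs <- c(r12, r34, r13, r14, r23, r24)
  stopifnot(all(abs(rs) < 1), n >= 10)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- r12; R[3, 4] <- R[4, 3] <- r34
  R[1, 3] <- R[3, 1] <- r13; R[1, 4] <- R[4, 1] <- r14
  R[2, 3] <- R[3, 2] <- r23; R[2, 4] <- R[4, 2] <- r24
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation matrix is not positive semidefinite")
  num <- pf_cov_num(r12, r34, r13, r14, r23, r24)
  if (variant == "fisher") {
    cov_z <- num / ((1 - r12^2) * (1 - r34^2))
    z <- (fisher_z(r12) - fisher_z(r34)) * sqrt((n - 3) / (2 - 2 * cov_z))
  } else {
    z <- (r12 - r34) * sqrt(n) /
      sqrt((1 - r12^2)^2 + (1 - r34^2)^2 - 2 * num)
  }
  list(z = z, p = 2 * pnorm(-abs(z)), variant = variant)
}

#' Smallest detectable correlation (sensitivity power analysis)
#'
#' Inverse Fisher-z of `(z_{1-alpha/2} + z_power) / sqrt(n - 3)`, the
#' smallest population correlation a two-sided test at level `alpha`
#' detects with the given power at sample size `n`.
#'
#' @param n sample size (>= 4).
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @return the minimum detectable r.
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.8) {
  if (n < 4) stop("n must be >= 4")
  tanh((qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n - 3))
}

#' Parameter- and model-recovery report
#'
#' Joins a ground-truth parameter table with fitted results and summarises
#' how well the pipeline identifies them: per-parameter Pearson correlation,
#' bias (mean fitted minus true) and RMSE, plus — when fits for several
#' candidate models are supplied — the confusion matrix of generating model
#' versus BIC-selected model.
#'
#' @param true_params tibble with `agent_id` and true parameter columns
#'   (e.g. `alpha`, `theta_fixed`, `omega_random`, or plain `theta`/`omega`).
#' @param fits [fit_mle()] rows; parameter recovery uses the rows whose
#'   `model` equals `param_model` (default the generating kind if unique,
#'   else `"HYBRID"`).
#' @param phase which fitted phase to evaluate against the truth; its
#'   per-phase true columns (`*_fixed`/`*_random`) are matched by suffix,
#'   with un-suffixed columns used for `"both"`.
#' @param param_model model whose fitted parameters are compared to truth.
#' @return list of class `nav_recovery`: `params` (tibble parameter, r,
#'   bias, rmse, n) and `confusion` (generating x selected counts, or NULL).
#' @export
recovery_report <- function(true_params, fits, phase = "both",
                            param_model = NULL) {
  if (is.null(param_model)) {
    param_model <- if ("model_kind" %in% names(true_params) &&
                       length(unique(true_params$model_kind)) == 1)
      unique(true_params$model_kind) else "HYBRID"
  }
  pf <- fits[fits$phase == phase & fits$model == param_model, , drop = FALSE]
  param_tbl <- NULL
  if (nrow(pf) > 0) {
    if (!all(pf$participant_id %in% true_params$agent_id))
      stop("fitted participants missing from the true-parameter table")
    m <- match(pf$participant_id, true_params$agent_id)
    suffix <- switch(phase, fixed = "_fixed", random = "_random", "")
    rows <- lapply(free_params(param_model), function(nm) {
      true_col <- if (paste0(nm, suffix) %in% names(true_params))
        paste0(nm, suffix) else if (nm %in% names(true_params)) nm else NA
      if (is.na(true_col)) return(NULL)
      tru <- true_params[[true_col]][m]
      est <- pf[[nm]]
      tibble::tibble(parameter = nm,
                     r = if (sd(tru) > 0 && sd(est) > 0) cor(tru, est) else NA_real_,
                     bias = mean(est - tru),
                     rmse = sqrt(mean((est - tru)^2)),
                     n = length(est))
    })
    param_tbl <- dplyr::bind_rows(rows)
  }
  confusion <- NULL
  if ("model_kind" %in% names(true_params) &&
      length(unique(fits$model[fits$phase == phase])) > 1) {
    cmp <- compare_models(fits, phase)
    gen <- true_params$model_kind[match(cmp$winners$participant_id,
                                        true_params$agent_id)]
    confusion <- table(generating = gen, selected = cmp$winners$model)
  }
  structure(list(params = param_tbl, confusion = confusion,
                 phase = phase, param_model = param_model),
            class = "nav_recovery")
}

#' @export
print.nav_recovery <- function(x, ...) {
  cat(sprintf("<nav_recovery> phase = %s, parameter model = %s\n",
              x$phase, x$param_model))
  if (!is.null(x$params)) print(x$params)
  if (!is.null(x$confusion)) {
    cat("model recovery (generating x selected):\n")
    print(x$confusion)
  }
  invisible(x)
}
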