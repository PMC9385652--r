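#!/usr/bin/env Rscript
# Step 5 — parameter and model recovery.
#
# Validates the fitting pipeline on ground truth it controls: (i) parameter
# recovery — 50 hybrid agents with phase-invariant parameters, refit with
# the hybrid model over the whole experiment; (ii) model recovery — 30
# TD(0)-generated and 30 model-based-generated agents at theta = 8, all
# five models fit and the BIC winner tallied against the generator. Writes
# results/recovery.json.

suppressPackageStartupMessages(library(navrl))

seed <- 20260921L
task <- nav_task()
qmb <- mb_values(task)

# parameter recovery
params <- withr::with_seed(seed, {
  p <- tibble::tibble(
    agent_id = sprintf("R%02d", 1:50), model_kind = "HYBRID",
    alpha = runif(50, 0.1, 0.6), theta_fixed = runif(50, 3, 10),
    lam = runif(50), omega_fixed = runif(50))
  p$theta_random <- p$theta_fixed
  p$omega_random <- p$omega_fixed
  p$theta <- p$theta_fixed
  p$omega <- p$omega_fixed
  p
})
sim <- simulate_agents(params, task, seed = seed + 1L, q_mb = qmb)
fits_p <- fit_cohort(sim$trajectories, task, models = "HYBRID",
                     phases = "both", n_restarts = 10, seed = seed + 2L,
                     q_mb = qmb)
rec_p <- recovery_report(params, fits_p, phase = "both")
cat("parameter recovery (hybrid, 50 agents x 81 trials):\n")
print(rec_p)

# model recovery
confusions <- list()
for (kind in c("TD0", "MB")) {
  p <- withr::with_seed(seed + match(kind, c("TD0", "MB")), tibble::tibble(
    agent_id = sprintf("%s%02d", kind, 1:30), model_kind = kind,
    alpha = runif(30, 0.2, 0.8), theta_fixed = 8, theta_random = 8,
    lam = runif(30), omega_fixed = 0.5, omega_random = 0.5))
  simk <- simulate_agents(p, task, seed = seed + 5L, q_mb = qmb)
  fitsk <- fit_cohort(simk$trajectories, task, phases = "both",
                      n_restarts = 10, seed = seed + 6L, q_mb = qmb)
  reck <- recovery_report(p, fitsk, phase = "both", param_model = kind)
  cat(sprintf("\nmodel recovery, %s-generated cohort:\n", kind))
  print(reck$confusion)
  confusions[[kind]] <- as.data.frame(reck$confusion)
}

write_report(list(parameter_recovery = as.data.frame(rec_p$params),
                  model_recovery = confusions), "results/recovery.json")
cat("\nwrote results/recovery.json\n")
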