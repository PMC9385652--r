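#!/usr/bin/env Rscript
# Step 3 — BIC model comparison, phase by phase.
#
# Mirrors the study's two comparisons on the synthetic cohort: (i) the three
# model-free TD variants against each other, via one-way repeated-measures
# ANOVA on BIC followed by paired t tests; (ii) model-free vs model-based vs
# hybrid. Writes results/model_comparison.json.

suppressPackageStartupMessages(library(navrl))

fits <- read_fits("results/fits.csv")
report <- list()

for (ph in c("fixed", "random")) {
  cmp <- compare_models(fits, ph)
  cat(sprintf("\n== %s phase ==\n", ph))
  print(as.data.frame(cmp$summary), digits = 5)

  td <- cmp$bic_wide[, c("TD0", "TD1", "TDLAMBDA")]
  a_td <- rm_anova_oneway(td)
  cat(sprintf("TD family RM-ANOVA: F(%d,%d) = %.2f, p = %.3g, eta^2 = %.2f\n",
              a_td$df1, a_td$df2, a_td$F, a_td$p, a_td$eta_sq))
  t_l1 <- paired_t(td[, "TDLAMBDA"], td[, "TD1"])
  t_l0 <- paired_t(td[, "TDLAMBDA"], td[, "TD0"])
  cat(sprintf("  TD(lambda) vs TD(1): t(%d) = %.2f, p = %.3g, d = %.2f\n",
              t_l1$df, t_l1$t, t_l1$p, t_l1$cohens_d))
  cat(sprintf("  TD(lambda) vs TD(0): t(%d) = %.2f, p = %.3g, d = %.2f\n",
              t_l0$df, t_l0$t, t_l0$p, t_l0$cohens_d))

  three <- cmp$bic_wide[, c("TDLAMBDA", "MB", "HYBRID")]
  a3 <- rm_anova_oneway(three)
  t_hm <- paired_t(three[, "HYBRID"], three[, "TDLAMBDA"])
  t_hb <- paired_t(three[, "HYBRID"], three[, "MB"])
  cat(sprintf("MF/MB/hybrid RM-ANOVA: F(%d,%d) = %.2f, p = %.3g, eta^2 = %.2f\n",
              a3$df1, a3$df2, a3$F, a3$p, a3$eta_sq))
  cat(sprintf("  hybrid vs model-free: t(%d) = %.2f, p = %.3g, d = %.2f\n",
              t_hm$df, t_hm$t, t_hm$p, t_hm$cohens_d))
  cat(sprintf("  hybrid vs model-based: t(%d) = %.2f, p = %.3g, d = %.2f\n",
              t_hb$df, t_hb$t, t_hb$p, t_hb$cohens_d))

  report[[ph]] <- list(
    summary = as.data.frame(cmp$summary),
    winners = table(cmp$winners$model),
    td_anova = a_td[c("F", "df1", "df2", "p", "eta_sq")],
    hybrid_vs_mf = t_hm[c("t", "df", "p", "cohens_d")],
    hybrid_vs_mb = t_hb[c("t", "df", "p", "cohens_d")])
}

write_report(report, "results/model_comparison.json")
cat("\nwrote results/model_comparison.json\n")
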