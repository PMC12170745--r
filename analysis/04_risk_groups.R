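#!/usr/bin/env Rscript

# Step 4: risk-group stratification.
#
# Dichotomizes the cohort by the combined full model's risk scores at the
# log-rank-optimal threshold (minimum group size 33% of the cohort) and
# draws Kaplan-Meier curves overall and per tumor subtype.

suppressPackageStartupMessages(library(radsurv))

cohort <- load_cohort("results/cohort")
ft <- read.csv("results/features.csv", stringsAsFactors = FALSE)
res <- run_study(cohort, feature_table = ft, B = 200, tau = 5, seed = 1)

st <- res$stratification
cat(sprintf("Risk threshold: %.3f  (chi-square %.1f, p = %.3g)\n",
            st$threshold, st$chisq, st$p_value))
cat(sprintf("High risk: %d patients, low risk: %d patients\n",
            st$n_high, st$n_low))
for (sub in names(st$by_subtype)) {
  bs <- st$by_subtype[[sub]]
  if (!is.null(bs$chisq))
    cat(sprintf("  %s: chi-square %.1f, p = %.3g\n", sub, bs$chisq,
                bs$p_value))
}

pdf("results/km_risk_groups.pdf", width = 9, height = 4)
par(mfrow = c(1, 3))
plot_km <- function(sel, main) {
  tm <- cohort$outcomes$time_years[sel]
  ev <- cohort$outcomes$event[sel]
  gr <- droplevels(res$group[sel])
  plot(NULL, xlim = c(0, max(tm)), ylim = c(0, 1), xlab = "Years",
       ylab = "Survival", main = main)
  cols <- c(low = "forestgreen", high = "firebrick")
  for (g in levels(gr)) {
    cv <- km_curves(tm, ev, gr)[[g]]
    lines(stepfun(cv$times, c(1, cv$surv)), col = cols[[g]], do.points = FALSE)
  }
  legend("bottomleft", legend = levels(gr), col = cols[levels(gr)], lty = 1,
         bty = "n")
}
plot_km(rep(TRUE, nrow(cohort$clinical)), "Entire cohort")
plot_km(cohort$clinical$subtype == "astrocytoma", "Astrocytoma")
plot_km(cohort$clinical$subtype == "oligodendroglioma", "Oligodendroglioma")
dev.off()
cat("Kaplan-Meier figure written to results/km_risk_groups.pdf\n")
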