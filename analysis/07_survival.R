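#!/usr/bin/env Rscript
# Stage 7 -- signature-quartile survival stratification. Within each ERG
# stratum, samples are split into signature-score quartiles and the top
# versus bottom quartile compared by log-rank test; Kaplan-Meier curves for
# the extreme quartiles are written alongside.

suppressMessages(library(motifdev))
datadir <- "results/data"

cohort <- read_cohort(file.path(datadir, "cohort.csv"))
out <- survival_by_quartile(cohort, by_erg_status = TRUE)
write.table(out, "results/survival_logrank.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top vs bottom signature quartile, log-rank within ERG strata:")
for (i in seq_len(nrow(out)))
  message(sprintf("  ERG %-8s n = %3d  chi-square = %6.2f  p = %.3g",
                  out$stratum[i], out$n[i], out$statistic[i], out$p[i]))

curves <- lapply(split(cohort, cohort$erg_status), function(d) {
  lab <- suppressMessages(quartile_stratify(d$score))
  rbind(
    cbind(quartile = "top", erg = d$erg_status[1],
          km_estimate(d$time[lab == "top"], d$event[lab == "top"])),
    cbind(quartile = "bottom", erg = d$erg_status[1],
          km_estimate(d$time[lab == "bottom"], d$event[lab == "bottom"])))
})
write.table(do.call(rbind, curves), "results/km_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Kaplan-Meier curves written to results/km_curves.tsv")
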