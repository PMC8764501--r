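#!/usr/bin/env Rscript
# Stage 3: combine the sex-level prevalence with the (censored) site- and
# sex-specific relative risks into total and level-wise population
# attributable fractions.

suppressMessages(library(alcoburden))

prev <- read.csv("results/tables/prevalence_by_sex.csv")
rr <- censor_nonsignificant(default_rr_table())
paf <- paf_table(prev, rr, cancer_sites())
write.csv(paf, "results/tables/paf.csv", row.names = FALSE)

cat("population attributable fractions (total, %):\n")
for (i in seq_len(nrow(paf))) {
  cat(sprintf("  %-13s %s  %5.1f%%  (light %4.1f / moderate %4.1f / heavy %4.1f)\n",
              paf$site[i], paf$sex[i], 100 * paf$paf_total[i],
              100 * paf$paf_light[i], 100 * paf$paf_moderate[i],
              100 * paf$paf_heavy[i]))
}
cat("PAF table written to results/tables/paf.csv\n")
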