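#!/usr/bin/env Rscript
# Stage 4: clean and group the registry, apply the PAFs, and assemble
# total and attributable deaths, YLLs, YLDs and DALYs, with the
# publication-style report tables.

suppressMessages(library(alcoburden))

registry <- read.csv("results/data/registry.csv")
life_table <- read.csv("results/data/life_table.csv")
yld_inputs <- read.csv("results/data/yld_inputs.csv")
paf <- read.csv("results/tables/paf.csv")
sites <- cancer_sites()

grouped <- filter_and_group(registry, sites)
ex <- grouped$exclusions
cat(sprintf(
  "registry: %d records; %d grouped to target sites, %d missing sex/age (%.2f%%), %d non-target, %d malformed\n",
  ex$n_input, ex$n_grouped, ex$n_missing, 100 * ex$n_missing / ex$n_input,
  ex$n_ignored, ex$n_malformed))

burden <- assemble_burden(grouped$deaths, life_table, yld_inputs, paf)
write.csv(burden, "results/tables/burden.csv", row.names = FALSE)
write.csv(render_burden_table(burden, "deaths", sites),
          "results/tables/report_deaths.csv", row.names = FALSE)
write.csv(render_burden_table(burden, "dalys", sites),
          "results/tables/report_dalys.csv", row.names = FALSE)
write.csv(level_share_summary(burden, "deaths"),
          "results/tables/level_shares_deaths.csv", row.names = FALSE)
write.csv(level_share_summary(burden, "dalys"),
          "results/tables/level_shares_dalys.csv", row.names = FALSE)

sh <- level_share_summary(burden, "deaths")
cat(sprintf("attributable deaths: %.0f of %.0f site deaths (%.1f%%)\n",
            sum(burden$deaths_attrib), sum(burden$deaths_total),
            100 * sum(burden$deaths_attrib) / sum(burden$deaths_total)))
cat(sprintf("attributable DALYs: %.0f (YLL %.0f + YLD %.0f)\n",
            sum(burden$daly_attrib), sum(burden$yll_attrib),
            sum(burden$yld_attrib)))
cat(sprintf("moderate drinkers carry %.0f%% of attributable deaths\n",
            100 * sh$share[sh$sex == "all" & sh$level == "moderate"]))
cat("burden tables written to results/tables\n")
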