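#!/usr/bin/env Rscript

# Step 1: simulate the raw care-zone data of the shared practices.
#
# Eight general practices of ~5,750 enrolled patients each over the
# 2017-2019 window, with the recording imperfections that make the two
# downstream ETL rule-sets diverge: occasionally missing social security
# numbers, quarterly capitation gaps, pharmacy re-records of GP
# prescriptions within 8 days, and episodes of care recorded for only a
# fraction of coded contacts.

library(ehretl)

seed <- 20190101L
cfg <- generator_config()
cat("Simulating raw EHR extract (seed", seed, ")...\n")
print(cfg)

extract <- generate_extract(cfg, seed = seed)
print(extract)

write_extract(extract, "results/raw_extract")
cat("\nWrote results/raw_extract/ (6 CSV tables + meta.json)\n")
cat(sprintf(
  "Found: %s patients across %d practices; %s prescription records of which %.1f%% pharmacy-sourced.\n",
  format(nrow(extract$patients), big.mark = ","), cfg$n_practices,
  format(nrow(extract$prescriptions), big.mark = ","),
  100 * mean(extract$prescriptions$source == "pharmacy")
))
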