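#!/usr/bin/env Rscript

# Step 2: process the raw extract through the two ETL rule-sets.
#
# The minimal-processing rule-set keeps all claims codes, GP prescriptions
# only and recorded episodes, and derives registration quarters from the
# enrollment date under a postal-code pseudonym. The extensive rule-set
# filters claims to a study-relevant selection, keeps pharmacy feedback but
# deduplicates within 8 days, rebuilds episodes with the episode-of-care
# construct, and derives quarters from capitation fees under a social
# security number pseudonym.

library(ehretl)

extract <- read_extract("results/raw_extract")

for (cfg in list(ahon_style(), nivel_style())) {
  cat("\n--- rule-set:", cfg$name, "---\n")
  print(cfg)
  ds <- run_pipeline(extract, cfg)
  print(ds)
  write_processed_dataset(ds, file.path("results", cfg$name))
  cat(sprintf(
    "Found: %s patients retained (%.1f%% of raw), %.0f patient-years.\n",
    format(nrow(ds$patients), big.mark = ","),
    100 * nrow(ds$patients) / nrow(extract$patients),
    patient_years_total(ds)
  ))
}
cat("\nWrote results/ahon_style/ and results/nivel_style/\n")
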