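#!/usr/bin/env Rscript
# Derive the analysis phenotypes from the raw records: carcass protein and
# phosphorus from the DXA calibrations, baseline-corrected efficiencies,
# ADG / ADFI / FCR, weight-adjusted residual slaughter age, and drip /
# cooking loss for the carcass subset. Round-trips the generator exactly,
# which is the point: the derivation code, not the generator, defines the
# phenotypes used downstream.

library(effigen)

records <- read.delim("results/data/records.tsv", stringsAsFactors = FALSE)
meat <- read.delim("results/data/meat_quality.tsv", stringsAsFactors = FALSE)

res <- run_derive(records, meat = meat, out_dir = "results/derived")
cat(sprintf("derived %d phenotype rows; %d QC flags\n",
            nrow(res$phenotypes), nrow(res$qc)))
print(head(res$phenotypes[, c("animal_id", "pe", "phe", "adg", "adfi", "fcr")]))
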