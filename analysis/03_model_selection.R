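#!/usr/bin/env Rscript
# All-subsets AIC screening of the fixed-effect structure per trait,
# respecting marginality, before the animal-model fits. The union of the
# top-model terms per trait is echoed for the genetics stage.

library(effigen)

pheno <- read.delim("results/derived/derived_phenotypes.tsv",
                    stringsAsFactors = FALSE)
pheno$year_of_change <- factor(pheno$year_of_change)
pheno$sex <- factor(pheno$sex)
pheno$treatment <- factor(pheno$treatment)

full_terms <- c("sex", "treatment", "year_of_change", "slaughter_bw",
                "temperature", "ragelw", "treatment:ragelw",
                "slaughter_bw:sex", "treatment:sex",
                "year_of_change:ragelw")

dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)
for (tr in c("pe", "phe", "adg", "fcr", "adfi")) {
  res <- dredge_aic(pheno, tr, full_terms)
  write.table(res$table, sprintf("results/selection/dredge_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d candidates, top model: %s (%d within delta AIC < 2)\n",
              tr, nrow(res$table),
              if (length(res$top_terms)) paste(res$top_terms, collapse = " + ")
              else "(intercept)",
              length(res$top_set)))
}
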