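#!/usr/bin/env Rscript
## Regenerates inst/extdata/adducts.csv from the compositional adduct
## definitions in the package (run from the repository root).
library(metanno)
reg <- adduct_registry()
reg$provenance <- paste0(
    "computed: (", ifelse(nzchar(reg$formula_add), reg$formula_add, "-"),
    " - ", ifelse(nzchar(reg$formula_sub), reg$formula_sub, "-"),
    " - ", reg$charge, "*m_e) / ", abs(reg$charge))
write.csv(reg[, c("name", "mass_multi", "mass_add", "charge", "polarity",
                  "provenance")],
          "inst/extdata/adducts.csv", row.names = FALSE, quote = TRUE)
cat("wrote", nrow(reg), "adducts\n")
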