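#!/usr/bin/env Rscript
## Derivation of the packaged isotopic-substitution table
## (isotopologue_substitutions()) from isotope-abundance arithmetic, and
## regeneration of inst/extdata/substitutions.csv.
##
## For a substitution replacing k atoms of element E by its heavy isotope,
## the expected intensity ratio isotopologue/monoisotopic of a molecule
## with n_E atoms of E is choose(n_E, k) * (p / (1 - p))^k with p the
## heavy-isotope abundance. Element counts are bracketed by chemically
## plausible element densities (atoms per Da of molecular mass):
##   carbon:   mass/45 .. mass/12  (heteroatom-rich .. pure carbon)
##   optional elements (H, N, O, S, Cl): 0 .. mass/atomic-mass
## Margins of 0.5x (lower) and 1.5x (upper) absorb abundance variation
## and intensity measurement error. For 2x13C the true upper ratio is
## quadratic in mass; the stored linear upper bound is the chord of that
## quadratic over the supported range [0, 1500] Da, which dominates the
## convex curve on the whole interval.
library(metanno)
tab <- isotopologue_substitutions()

## recompute the 13C upper slope from first principles as a check
p <- 0.0107; r <- p / (1 - p)
stopifnot(all.equal(tab$a_hi[tab$name == "13C"], 1.5 * r / 12))
stopifnot(all.equal(tab$a_hi[tab$name == "2x13C"],
                    1.5 * choose(1500 / 12, 2) * r^2 / 1500))

## mass differences are isotope-mass differences (NIST):
##   13C - 12C, 2 * (13C - 12C), 2H - 1H, 15N - 14N, 18O - 16O,
##   34S - 32S, 37Cl - 35Cl
print(tab)
write.csv(tab, "inst/extdata/substitutions.csv", row.names = FALSE)
cat("wrote", nrow(tab), "substitutions\n")
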