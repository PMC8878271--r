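---
title: "Annotating metabolomics features with metanno: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating metabolomics features with metanno: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanno)
```

# Scope

Untargeted LC-MS metabolomics produces *features* — m/z and retention-time
pairs with intensities — whose chemical identity is unknown. `metanno`
implements the computational building blocks used to annotate them:
formula and mass arithmetic, adduct-based mass-to-m/z conversion,
tolerance-based value matching, spectra similarity scoring, isotopologue
grouping, retention-index and CE-mobility normalization, a portable
SQLite reference-database format, and high-level MS¹/MS² matching that
returns scored many-to-many results. This vignette explains the models
behind each component, the tunable parameters, and the design decisions
that were genuinely open.

# Masses and formulas

Monoisotopic masses are sums of the masses of each element's most
abundant isotope (`element_masses()`, NIST values, 60 elements).
Formulas use a deliberately strict grammar — element symbols with
optional positive counts, e.g. `C8H10N4O2`. Parentheses, hydrates
(`·H2O`), isotope markers (`[13C]`) and charges are rejected with an
explicit parse error rather than silently misread; supporting them would
require a grammar with nesting and was left out of scope. Hill notation
(C, then H, then other elements alphabetically; alphabetical without C)
is the canonical output order. All masses are carried at full double
precision.

```{r}
calculate_mass(c("C27H42O3", "C26H28O11"))
```

# Adducts

Electrospray ionization attaches or removes charged species, mapping a
neutral mass $M$ to an ion at

$$ m/z = \frac{n \, M + \sum m_\text{gained} - \sum m_\text{lost} - z\,m_e}{|z|} $$

with multimer count $n$, signed charge $z$ and the electron mass $m_e$
(0.00054858 Da) accounting for the charge state — necessary for sub-ppm
accuracy. The registry ships 58 adducts (33 positive, 25 negative)
covering protonation/deprotonation, alkali and ammonium attachment,
halide and organic-acid anions, solvent clusters, water losses, 2M/3M
multimers and up to triply charged states. Each entry is stored
*compositionally* (gained and lost formulas), so the numeric transform is
always consistent with the element table; the derived constants are also
exported as `inst/extdata/adducts.csv` (regenerated by
`scripts/make_adducts_csv.R`). User-supplied definitions — a data.frame
with `name`, `mass_multi`, `mass_add` — participate identically.

# Tolerance matching and peak joins

All matching accepts an absolute (`tolerance`, Da) plus a relative
(`ppm`) error; query $x$ matches target $t$ when
$|x - t| \le \text{tolerance} + x \cdot \text{ppm} \cdot 10^{-6}$.
The window is computed on the *query* side, which keeps windows monotone
in $x$ but makes matching asymmetric: `closest(x, table)` need not mirror
`closest(table, x)`.

`closest()` by default enforces a one-to-one mapping
(`duplicates = "closest"`): all in-window candidate pairs are ranked by
ascending absolute difference (ties: lower target index, then lower
query index) and assigned greedily. This fully deterministic rule is
also what the test suite's brute-force oracle implements independently.

`join_peaks()` computes matched peak pairs once via `closest()` and then
reports rows according to SQL-style join semantics: `outer` (all peaks
of both spectra; the default used for scoring), `inner`, `left`,
`right`. `join_peaks_gnps()` implements the hybrid ("modified cosine")
strategy: a pair also qualifies when its m/z difference matches the
precursor m/z difference of the two spectra. Candidates are *kept with
duplicates* (a peak may match both directly and shifted) and conflict
resolution is deferred to the score, mirroring the two-stage design of
spectral-library hybrid search.

# Similarity scores

Scores operate on joined peak rows with weights
$w = mz^{\,m}\,I^{\,n}$; gaps weigh 0. Defaults are $m = 0$, $n = 0.5$
(square-root intensity stabilizes the dominance of base peaks), matching
common library-search practice; both are overridable per call.

* `ndotproduct`: $\left(\sum w_q w_t\right)^2 / \left(\sum w_q^2 \sum w_t^2\right)$ — the squared cosine; symmetric.
* `neuclidean`: $\left(1 + \sum (w_q - w_t)^2 / \sum w_t^2\right)^{-1}$.
* `navdist`: $\left(1 + \sum |w_q - w_t| / \sum w_t\right)^{-1}$.
* `nspectraangle`: $1 - 2\arccos(\cos\theta)/\pi$.

The normalization side of the two distance-based scores is not uniquely
fixed in the literature restatements we based this on; here both
normalize over the **target** (reference/library) weights, treating the
reference as ground truth, and are documented and tested as asymmetric.
A numerical subtlety: the spectral-angle cosine is computed with a
single square root of the norm product so that identical inputs give
$\cos\theta = 1$ exactly — `acos` would amplify a one-ulp defect to
$\sim 10^{-8}$ in the score. Empty-versus-empty joins return 0 with a
warning, never `NaN`.

`gnps_score()` normalizes every candidate contribution by the full peak
norms of both spectra and selects the conflict-free subset (each peak
used once) with maximal total contribution: exact branch-and-bound up to
32 candidate pairs, greedy by descending contribution beyond (realistic
joins rarely exceed a handful of conflicts; the tests assert exact and
greedy agree on the fixtures).

`compare_spectra()` composes any join with any score into a full
pairwise matrix and accepts user-supplied functions satisfying the same
contracts.

# Isotopologue grouping

MS¹ peaks of the same compound appear as isotopologue series with
characteristic mass offsets and bounded intensity ratios. Without
knowing the formula, a peak at $mz_0$ with intensity $I_0$ is compatible
with an isotopologue at $mz_0 + \Delta m_s$ when its intensity ratio
$I/I_0$ lies in a mass-dependent interval. The packaged substitution
table (13C, 2×13C, 2H, 15N, 18O, 34S, 37Cl) derives those intervals from
isotope-abundance arithmetic — for one heavy atom of element $E$ the
expected ratio is $n_E\,p_E/(1-p_E)$ with the element count bracketed by
plausible element densities (carbon: $M/45 \le n_C \le M/12$), with
0.5×/1.5× safety margins; optional elements get a lower bound of 0, and
the quadratic 2×13C upper bound is replaced by its chord over the
supported 0–1500 Da range (which dominates the convex curve). The
derivation is reproducible via `scripts/derive_substitutions.R`. These
bounds are a documented heuristic; bounds fitted to a large reference
database would be tighter in edge cases.

The grouping loop scans peaks in ascending m/z; each yet-unassigned peak
seeds a candidate group and collects later unassigned peaks compatible
in m/z (via `closest`) and ratio. Two choices resolve ambiguities in
loop-based grouping: an assigned peak can neither seed nor join a second
group (preventing chained mis-grouping), and multi-substitutions are
matched against the *seed*, not iteratively against the previous
isotopologue. Single-member groups are dropped.

# Retention index and effective mobility

`index_rtime()` converts retention times to retention indices by
piecewise-linear interpolation through a calibration series
(`rtime`/`rindex` data.frame); values outside the calibrated range are
linearly extrapolated from the terminal segment and flagged (callers can
filter on the flag) rather than returned missing. Any user function
`f(rt, calibration)` can replace the default.

`convert_mtime()` normalizes CE-MS migration times to effective
mobilities (units $10^{-9}\,\mathrm{m^2 V^{-1} s^{-1}}$, input times in
minutes, seconds internally). With one marker the capillary length and
field are used, $\mu(t) = \mu_M + \frac{L}{E}(1/t' - 1/t'_M)$, assuming
detection at the capillary end (the CE-MS configuration). With two
markers — one of which must be the neutral EOF marker, $\mu = 0$ — the
geometry cancels. The voltage-ramp correction is $t' = t - t_\text{ramp}/2$:
during a linear ramp the average field is half the final field, so the
ion effectively loses half the ramp time; the exact convention used by
reference instruments is not published, so this choice is isolated in
one place and documented.

# Reference databases

`create_compdb()` writes a self-describing SQLite file (schema v1:
`metadata`, `ms_compound`, `synonym`, `msms_spectrum`,
`msms_spectrum_peak`) with mandatory provenance (source, version, date,
schema version) so a database can be pinned in an analysis. Peaks are
stored as rows of 8-byte reals — queryable, portable, and bit-exact on
round trip; blob storage would be faster at library scale but opaque.
`insert_ions()` extends a database with measured ions (IonDb layout,
schema version `1-ion`) without touching existing tables.
Formula/exact-mass inconsistencies on import *warn* rather than error,
because public resources do contain them. The schema is normative for
this package only.

# MS¹ and MS² annotation

`match_mz()` reports **all** in-window (query, target, adduct)
combinations, not just the closest — annotation is a screening step and
the one-to-many structure is real; nearest-only is one
`filter_matches(top_rank = TRUE)` away. Scores per match are the signed
$\Delta m/z$ (query − target), the ppm error, and for Rt parameters the
signed $\Delta t$. `match_spectra()` gates candidate pairs on precursor
m/z by default (`require_precursor = TRUE`, using the peak-matching
tolerance unless a separate precursor tolerance is given — one knob by
default, two when needed) and keeps pairs with similarity strictly
greater than the threshold (default 0.7). Forward/reverse matching adds
the reverse score (computed on a right join, i.e. against the reference
peak list only) and the presence ratio (matched query peaks / all query
peaks).

Every result is a `Matched` object bundling query, target, match table
*and the parameter object*, so re-running the stored parameters on the
stored inputs reproduces the match table exactly (tested). All indices
in the API are 1-based, the native R convention. `matched_data()`
flattens with left-join semantics: queries without matches keep one row.

# Synthetic data

`simulate_reference()` generates compounds from a C/H/N/O/P/S formula
grammar (5–30 carbons, H/C ratio 1–2.1, masses accepted within 100–600
Da by default), one MS² spectrum per compound (10 uniform-random
fragment m/z below the precursor, exponential intensities — a simple
heavy-tailed model of fragment abundances), and the adduct-converted ion
grid. Decoy compounds are generated the same way under separate ids.
`perturb_spectra()` emulates re-measurement: Gaussian m/z noise with the
ppm parameter read as a 3-sigma mass-accuracy bound (how vendors quote
accuracy), multiplicative intensity noise, and peak dropout as
*detection-limit censoring* — the number of lost peaks is binomial, but
the *weakest* peaks vanish, because that is how peaks disappear between
replicate measurements; uniform dropout would remove base peaks, which
is unphysical and makes recovery of a spectrum essentially a coin flip
on which peak was lost. Both generators require an explicit seed and
restore the caller's RNG state.

What the generator does *not* emulate: correlated noise, in-source
fragmentation, chimeric spectra, electronic noise peaks, isotope
envelopes in MS², retention-time drift. Passing the planted-truth tests
therefore demonstrates algorithmic correctness of the matching chain,
not expected performance on real libraries.

# Test problem sizes

The property suites run 500 random spectrum pairs for join set-algebra,
brute-force join equivalence at up to 12 peaks per side, 50 compounds
plus 50 decoys for MS² planted-truth recovery, 30 compounds × 4 adducts
for MS¹ recovery, and a 9-compound isotope-pattern fixture; these sizes
keep the full suite under half a minute while exercising every code
path several hundred times.

# Known limitations

* The formula grammar is flat: no parentheses, hydrates, isotopes or
  charges.
* Isotopologue ratio bounds are abundance heuristics, not fitted to a
  reference database.
* The adduct registry's membership reflects commonly published ESI
  lists; in-source fragments and exotic clusters are absent (custom
  definitions fill the gap).
* `neuclidean`/`navdist` target-side normalization is one of the
  plausible conventions; scores are comparable within this package but
  not necessarily bit-identical to other implementations.
* Spectra I/O covers MGF and NIST MSP; vendor raw formats and
  mzML/mzXML are out of scope.
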