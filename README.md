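# metanno

Modular building blocks for annotating features from untargeted LC-MS
and CE-MS metabolomics experiments.

Untargeted metabolomics preprocessing yields *features* — m/z and
retention-time pairs — whose chemical identity must be established by
matching against reference knowledge: compound masses (MS¹), reference
fragment spectra (MS²), retention indices and, for capillary
electrophoresis, effective mobilities. `metanno` provides that tool
chain as small, composable functions on plain R data structures, for
metabolomics bioinformaticians who want to build or script annotation
workflows rather than run a monolithic pipeline.

## What is inside

* **Formulas and masses** — `count_elements()`, `paste_elements()`
  (Hill notation), `add_elements()`/`subtract_elements()`,
  `calculate_mass()` over a packaged NIST monoisotopic element table.
* **Adducts** — a 58-entry electrospray adduct registry
  (`adduct_registry()`) defining the affine map
  `mz = mass_multi * M + mass_add` (electron-mass corrected);
  `mass2mz()` / `mz2mass()`, vectorized over masses and adducts.
* **Matching core** — `closest()` with combined absolute (`tolerance`)
  and relative (`ppm`) windows and deterministic one-to-one assignment;
  `join_peaks()` (outer/inner/left/right SQL semantics) and
  `join_peaks_gnps()` (precursor-shift aware hybrid matching).
* **Similarity** — normalized dot product, normalized Euclidean and
  absolute-value distances, normalized spectral angle
  (`ndotproduct()`, `neuclidean()`, `navdist()`, `nspectraangle()`),
  a GNPS-style modified cosine (`gnps_score()`), and all-pairs
  `compare_spectra()`. The scores use weights `w = mz^m * intensity^n`,
  defaults `m = 0`, `n = 0.5`. For matched weight vectors the
  normalized dot product is

  `ndotproduct = (Σ w_q w_t)^2 / (Σ w_q^2 · Σ w_t^2)`

* **Isotopologues** — `isotopologues()` groups MS¹ peaks compatible
  with isotopic substitutions (13C, 2×13C, 2H, 15N, 18O, 34S, 37Cl) by
  mass offset and mass-dependent intensity-ratio bounds, without
  knowing the formula.
* **Retention and migration** — `index_rtime()` (linear retention-time
  indexing against a calibration series) and `convert_mtime()`
  (CE migration time to effective mobility via EOF markers).
* **Reference databases** — `create_compdb()` / `compdb()` /
  `import_msp_library()` / `insert_ions()`: portable, versioned SQLite
  compound/spectra/ion databases with a query surface
  (`query_compounds()`, `query_spectra()`, `query_ions()`).
* **Annotation** — `match_mz()` (MS¹, parameter objects `MzParam`,
  `MzRtParam`, `Mass2MzParam`, `Mass2MzRtParam`) and `match_spectra()`
  (MS², `CompareSpectraParam`, `MatchForwardReverseParam`) returning a
  `Matched` result that keeps query, target, scored many-to-many match
  table and the parameters; `matched_data()` and `filter_matches()`
  handle the bookkeeping.
* **Spectra I/O and fixtures** — MGF and NIST MSP readers/writers with
  bit-exact round trips; seeded synthetic reference generators
  (`simulate_reference()`, `perturb_spectra()`); a thin command-line
  tool (`exec/metanno`) over the same functions.

## Worked example

Annotate three simulated features against a simulated compound table,
then match re-measured MS² spectra against their reference library:

```r
library(metanno)

calculate_mass(c("C27H42O3", "C26H28O11"))
#>  C27H42O3 C26H28O11
#>  414.3134  516.1632

ref <- simulate_reference(6, seed = 42, adducts = c("[M+H]+", "[M+Na]+"))
fts <- data.frame(mz = ref$ions$mz[c(1, 4, 9)] * (1 + 1e-6))  # 1 ppm off
res <- match_mz(fts, ref$compounds, Mass2MzParam(c("[M+H]+", "[M+Na]+"), ppm = 5))
res
#> Matched
#>   3 queries, 3 with at least one match, 3 match rows
matched_data(res)[, c("mz", "adduct", "ppm_error", "compound_id", "formula")]
#>         mz  adduct ppm_error compound_id    formula
#> 1 487.2494  [M+H]+  0.999999     SIM0001 C21H43O8PS
#> 2 456.1218 [M+Na]+  0.999999     SIM0002  C22H25O7S
#> 3 305.0094  [M+H]+  0.999999     SIM0005  C7H13O9PS

qry <- perturb_spectra(ref$spectra, seed = 43, mz_jitter_ppm = 10, dropout = 0.1)
match_spectra(qry, ref$spectra, CompareSpectraParam())$matches
#>   query_idx target_idx     score
#> 1         1          1 0.9964728
#> 2         2          2 0.9803472
#> 3         3          3 0.9886959
#> 4         4          4 0.9909181
#> 5         5          5 1.0000000
#> 6         6          6 1.0000000
```

Each feature is matched to the compound and adduct that generated it
with the expected 1 ppm error; each perturbed MS² spectrum matches its
own reference spectrum with a normalized dot product above the 0.7
default threshold (scores below 1 reflect the injected m/z jitter and
dropped low-intensity peaks).

## Documentation

See `vignettes/annotation-methods.Rmd` for the models, parameter
conventions, numerical choices and known limitations, and the roxygen
help pages of the individual functions.
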