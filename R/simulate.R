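#' Simulate a synthetic reference set
#'
#' Generates a deterministic, fully synthetic reference set for testing
#' and demonstration: compounds with random (but chemically shaped)
#' molecular formulas drawn from a C/H/N/O/P/S grammar whose exact mass is
#' computed from the formula; one MS2 spectrum per compound with
#' pseudo-random fragment peaks below the precursor m/z; and the ion grid
#' obtained by applying the configured adducts to every compound mass.
#' Optional decoy compounds (independent random formulas and fragment
#' peaks, ids prefixed `DEC`) allow false-positive checks. All randomness
#' flows through the mandatory `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param n_compounds Number of (non-decoy) compounds (> 0).
#' @param seed Integer seed (mandatory; no silent nondeterminism).
#' @param mass_range Numeric length-2: accepted neutral mass range (Da).
#' @param adducts Adduct names used for the ion grid and the spectrum
#'   precursors.
#' @param n_peaks Fragment peaks per spectrum.
#' @param n_decoys Number of additional decoy compounds.
#' @return `list` with elements `compounds` (data.frame `compound_id`,
#'   `name`, `formula`, `exactmass`, `decoy`), `spectra`
#'   ([SpectraCollection()], one MS2 spectrum per compound, metadata
#'   `compound_id`), and `ions` (data.frame `ion_id`, `compound_id`,
#'   `adduct`, `mz`).
#' @examples
#' ref <- simulate_reference(5, seed = 42)
#' ref$compounds
#' @export
simulate_reference <- function(n_compounds, seed,
                               mass_range = c(100, 600),
                               adducts = "[M+H]+", n_peaks = 10L,
                               n_decoys = 0L) {
    if (n_compounds < 1L)
        stop("'n_compounds' must be >= 1")
    if (missing(seed))
        stop("'seed' is mandatory")
    withr::local_preserve_seed()
    set.seed(seed)
    n_total <- n_compounds + n_decoys
    formulas <- character(n_total)
    masses <- numeric(n_total)
    for (i in seq_len(n_total)) {
        for (try in 1:1000) {
            f <- .random_formula()
            m <- unname(calculate_mass(f))
            if (m >= mass_range[1L] && m <= mass_range[2L]) break
        }
        if (m < mass_range[1L] || m > mass_range[2L])
            stop("could not sample a formula within the mass range")
        formulas[i] <- f; masses[i] <- m
    }
    decoy <- c(rep(FALSE, n_compounds), rep(TRUE, n_decoys))
    compounds <- data.frame(
        compound_id = ifelse(decoy,
                             sprintf("DEC%04d", seq_len(n_total)),
                             sprintf("SIM%04d", seq_len(n_total))),
        name = ifelse(decoy, sprintf("decoy %d", seq_len(n_total)),
                      sprintf("simulated compound %d", seq_len(n_total))),
        formula = formulas, exactmass = masses, decoy = decoy)
    spectra <- SpectraCollection(lapply(seq_len(n_total), function(i) {
        adduct <- sample(adducts, 1L)
        pmz <- unname(mass2mz(masses[i], adduct))
        mz <- sort(stats::runif(n_peaks, 50, max(51, pmz - 1)))
        int <- stats::rexp(n_peaks) * 1000
        Spectrum(mz, int, ms_level = 2L, precursor_mz = pmz,
                 polarity = "positive",
                 meta = list(compound_id = compounds$compound_id[i],
                             name = compounds$name[i],
                             adduct = adduct, charge = "1"))
    }), metadata = list(source = "simulate_reference", format = "memory"))
    grid <- mass2mz(masses, adducts)
    if (is.null(dim(grid)))
        grid <- matrix(grid, ncol = 1L, dimnames = list(NULL, adducts))
    ions <- do.call(rbind, lapply(seq_along(adducts), function(a)
        data.frame(compound_id = compounds$compound_id,
                   adduct = colnames(grid)[a], mz = grid[, a])))
    ions <- ions[order(ions$compound_id, ions$adduct), , drop = FALSE]
    ions <- data.frame(ion_id = sprintf("ION%04d", seq_len(nrow(ions))),
                       ions, row.names = NULL)
    list(compounds = compounds, spectra = spectra, ions = ions)
}

## amphiphilic small-molecule formula grammar; H drawn relative to C to
## stay near chemically plausible H/C ratios
.random_formula <- function() {
    nc <- sample(5:30, 1L)
    nh <- max(1L, round(nc * stats::runif(1, 1.0, 2.1)))
    cnt <- c(C = nc, H = nh, N = sample(0:4, 1L), O = sample(0:10, 1L),
             P = sample(0:1, 1L), S = sample(0:1, 1L))
    paste_elements(cnt)
}

#' Perturb spectra with mass jitter, intensity jitter and peak dropout
#'
#' Emulates re-measurement of reference spectra on an instrument with
#' limited mass accuracy: m/z values (peaks and precursor) receive
#' Gaussian relative noise with `mz_jitter_ppm` interpreted as a 3-sigma
#' mass-accuracy bound (sd = ppm / 3), and intensities multiplicative
#' Gaussian noise with sd `intensity_jitter` (truncated at 10% of the
#' original). Peak dropout emulates detection-limit censoring: the number
#' of lost peaks is drawn as Binomial(n, `dropout`) and the weakest peaks
#' are removed (peaks disappear between replicate measurements because
#' they fall below the noise threshold, not uniformly at random); at
#' least one peak is always retained. The source spectrum's
#' `compound_id`/`name` metadata survive and the provenance is recorded
#' in the `source_spectrum` metadata entry.
#'
#' @param x A [SpectraCollection()].
#' @param seed Integer seed (mandatory).
#' @param mz_jitter_ppm Mass accuracy bound in ppm (3 sigma).
#' @param intensity_jitter Relative intensity noise (fraction, sd).
#' @param dropout Per-peak dropout probability in `[0, 1]`.
#' @return A [SpectraCollection()] of the same length.
#' @export
perturb_spectra <- function(x, seed, mz_jitter_ppm = 0,
                            intensity_jitter = 0, dropout = 0) {
    if (missing(seed))
        stop("'seed' is mandatory")
    if (dropout < 0 || dropout > 1)
        stop("'dropout' must be in [0, 1]")
    withr::local_preserve_seed()
    set.seed(seed)
    sdrel <- mz_jitter_ppm / 3 * 1e-6
    SpectraCollection(lapply(seq_len(length(x)), function(i) {
        s <- x[[i]]
        np <- length(s$mz)
        k <- min(stats::rbinom(1, np, dropout), np - 1L)
        keep <- rep(TRUE, np)
        if (k > 0)
            keep[order(s$intensity)[seq_len(k)]] <- FALSE
        mz <- s$mz[keep]
        int <- s$intensity[keep]
        mz <- mz * (1 + stats::rnorm(length(mz), sd = sdrel))
        int <- int * pmax(0.1, 1 + stats::rnorm(length(int),
                                                sd = intensity_jitter))
        pmz <- s$precursor_mz
        if (!is.na(pmz))
            pmz <- pmz * (1 + stats::rnorm(1, sd = sdrel))
        meta <- s$meta
        meta$source_spectrum <-
            if (!is.null(s$meta$compound_id)) s$meta$compound_id
            else as.character(i)
        Spectrum(mz, int, ms_level = s$ms_level, precursor_mz = pmz,
                 rtime = s$rtime, polarity = s$polarity, meta = meta)
    }), metadata = c(x$metadata, list(perturbed = "true")))
}

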