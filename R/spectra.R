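#' Mass spectra containers
#'
#' A `Spectrum` is a lightweight container for one mass spectrum: a peak
#' list (m/z, intensity), the MS level, optional precursor m/z and
#' retention time, polarity, and free-form character metadata. A
#' `SpectraCollection` is an ordered list of spectra plus collection-level
#' metadata (e.g. source file and format).
#'
#' Peaks are stored sorted by m/z; constructors and readers sort unsorted
#' input and record this in the metadata (`"was_unsorted"`) rather than
#' erroring, because real spectral libraries are frequently unsorted.
#'
#' @param mz,intensity `numeric` peak values of equal length; `intensity`
#'   must be non-negative.
#' @param ms_level `integer(1)`, MS level (>= 1).
#' @param precursor_mz `numeric(1)` precursor m/z or `NA`.
#' @param rtime `numeric(1)` retention time in seconds or `NA`.
#' @param polarity `"positive"`, `"negative"` or `"unknown"`.
#' @param meta Named `list` of character metadata (id, compound name,
#'   adduct, ...).
#' @return `Spectrum()` returns a `Spectrum` object.
#' @examples
#' s <- Spectrum(c(138.0662, 110.0713), c(999, 250), ms_level = 2,
#'               precursor_mz = 195.0877)
#' peaks_mz(s)
#' @export
Spectrum <- function(mz = numeric(), intensity = numeric(), ms_level = 1L,
                     precursor_mz = NA_real_, rtime = NA_real_,
                     polarity = c("unknown", "positive", "negative"),
                     meta = list()) {
    polarity <- match.arg(polarity)
    if (length(mz) != length(intensity))
        stop("'mz' and 'intensity' must have equal length")
    if (anyNA(mz))
        stop("'mz' must not contain missing values")
    if (is.unsorted(mz)) {
        o <- order(mz)
        mz <- mz[o]; intensity <- intensity[o]
        meta$was_unsorted <- "true"
    }
    structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                   ms_level = as.integer(ms_level),
                   precursor_mz = as.numeric(precursor_mz),
                   rtime = as.numeric(rtime), polarity = polarity,
                   meta = meta),
              class = "Spectrum")
}

#' @rdname Spectrum
#' @param x A `Spectrum`.
#' @export
peaks_mz <- function(x) x$mz

#' @rdname Spectrum
#' @export
peaks_intensity <- function(x) x$intensity

#' @rdname Spectrum
#' @export
precursor_mz <- function(x) x$precursor_mz

#' @export
print.Spectrum <- function(x, ...) {
    cat(sprintf("Spectrum (MS%d): %d peaks", x$ms_level, length(x$mz)))
    if (!is.na(x$precursor_mz))
        cat(sprintf(", precursor m/z %.4f", x$precursor_mz))
    if (!is.na(x$rtime))
        cat(sprintf(", rt %.1f s", x$rtime))
    cat("\n")
    invisible(x)
}

#' Validate a spectrum
#'
#' Checks the `Spectrum` invariants and reports violations as a character
#' vector (empty when the spectrum is valid); it never raises.
#'
#' @param x A `Spectrum`.
#' @return `character` of human-readable violations.
#' @examples
#' validate_spectrum(Spectrum(c(100, 200), c(1, 2)))
#' @export
validate_spectrum <- function(x) {
    v <- character()
    if (length(x$mz) != length(x$intensity))
        v <- c(v, "m/z and intensity lengths differ")
    if (anyNA(x$mz))
        v <- c(v, "m/z contains missing values")
    else if (length(x$mz) > 1) {
        bad <- which(diff(x$mz) < 0)
        if (length(bad))
            v <- c(v, sprintf("m/z not ascending at index %d", bad[1L] + 1L))
    }
    if (any(x$intensity < 0, na.rm = TRUE))
        v <- c(v, "negative intensity")
    if (!is.na(x$ms_level) && x$ms_level < 1L)
        v <- c(v, "ms_level < 1")
    v
}

#' @rdname Spectrum
#' @param spectra `list` of `Spectrum` objects.
#' @param metadata Named `list` of collection-level metadata.
#' @export
SpectraCollection <- function(spectra = list(), metadata = list()) {
    if (!all(vapply(spectra, inherits, logical(1), "Spectrum")))
        stop("all elements must be Spectrum objects")
    structure(list(spectra = spectra, metadata = metadata),
              class = "SpectraCollection")
}

#' @export
length.SpectraCollection <- function(x) length(x$spectra)

#' @export
`[.SpectraCollection` <- function(x, i) {
    SpectraCollection(x$spectra[i], x$metadata)
}

#' @export
`[[.SpectraCollection` <- function(x, i) x$spectra[[i]]

#' @export
print.SpectraCollection <- function(x, ...) {
    cat(sprintf("SpectraCollection with %d spectra\n", length(x)))
    invisible(x)
}

## Apply over spectra keeping collection structure out of user code.
spectra_apply <- function(x, f, ...) lapply(x$spectra, f, ...)
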