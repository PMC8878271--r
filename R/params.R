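#' Annotation parameter objects
#'
#' Parameter objects select and configure the algorithm used by
#' [match_mz()] and [match_spectra()] and are stored verbatim inside the
#' returned [Matched] result, documenting exactly what settings an
#' annotation is based on.
#'
#' * `MzParam()`: direct m/z matching between query and target m/z values.
#' * `MzRtParam()`: as `MzParam()` plus a retention time gate.
#' * `Mass2MzParam()`: target *masses* are first converted to m/z for each
#'   configured adduct, then matched.
#' * `Mass2MzRtParam()`: as `Mass2MzParam()` plus a retention time gate.
#' * `CompareSpectraParam()`: MS2 spectra matching; candidate pairs
#'   (optionally gated on precursor m/z) are scored with
#'   `sim_fun(map_fun(query, target))` and kept when the score exceeds
#'   `threshold`.
#' * `MatchForwardReverseParam()`: as `CompareSpectraParam()`, but for
#'   every kept match a reverse score (computed on a right join, i.e.
#'   against the full reference peak list) and the presence ratio
#'   (matched query peaks / all query peaks) are reported in addition.
#'
#' @param tolerance,ppm Acceptance window, see [closest()].
#' @param rt_tolerance Maximum absolute retention time difference
#'   (seconds).
#' @param adducts Adduct names or definition data.frame, see [mass2mz()].
#' @param map_fun Peak mapping function for MS2 matching.
#' @param sim_fun Similarity function for MS2 matching.
#' @param m,n Peak weighting exponents, see [ndotproduct()].
#' @param threshold Minimum similarity; matches require score strictly
#'   greater than `threshold`.
#' @param require_precursor If `TRUE` only spectrum pairs whose precursor
#'   m/z match within the precursor tolerance are compared.
#' @param precursor_tolerance,precursor_ppm Precursor acceptance window;
#'   default to `tolerance`/`ppm`.
#' @return A parameter object (a list with class as above).
#' @name annotation-params
NULL

.new_param <- function(class, ...) {
    x <- list(...)
    if (!is.null(x$tolerance) && (x$tolerance < 0 || x$ppm < 0))
        stop("'tolerance' and 'ppm' must be >= 0")
    structure(x, class = c(class, "AnnotationParam"))
}

#' @rdname annotation-params
#' @export
MzParam <- function(tolerance = 0, ppm = 5) {
    .new_param("MzParam", tolerance = tolerance, ppm = ppm)
}

#' @rdname annotation-params
#' @export
MzRtParam <- function(tolerance = 0, ppm = 5, rt_tolerance = 30) {
    if (rt_tolerance < 0) stop("'rt_tolerance' must be >= 0")
    .new_param("MzRtParam", tolerance = tolerance, ppm = ppm,
               rt_tolerance = rt_tolerance)
}

#' @rdname annotation-params
#' @export
Mass2MzParam <- function(adducts = "[M+H]+", tolerance = 0, ppm = 5) {
    if (!length(adducts)) stop("at least one adduct is required")
    .resolve_adducts(adducts)
    .new_param("Mass2MzParam", adducts = adducts, tolerance = tolerance,
               ppm = ppm)
}

#' @rdname annotation-params
#' @export
Mass2MzRtParam <- function(adducts = "[M+H]+", tolerance = 0, ppm = 5,
                           rt_tolerance = 30) {
    if (!length(adducts)) stop("at least one adduct is required")
    if (rt_tolerance < 0) stop("'rt_tolerance' must be >= 0")
    .resolve_adducts(adducts)
    .new_param("Mass2MzRtParam", adducts = adducts, tolerance = tolerance,
               ppm = ppm, rt_tolerance = rt_tolerance)
}

#' @rdname annotation-params
#' @export
CompareSpectraParam <- function(tolerance = 0, ppm = 20,
                                map_fun = join_peaks,
                                sim_fun = ndotproduct,
                                m = 0, n = 0.5, threshold = 0.7,
                                require_precursor = TRUE,
                                precursor_tolerance = tolerance,
                                precursor_ppm = ppm) {
    if (threshold < 0 || threshold > 1)
        stop("'threshold' must be in [0, 1]")
    .new_param("CompareSpectraParam", tolerance = tolerance, ppm = ppm,
               map_fun = map_fun, sim_fun = sim_fun, m = m, n = n,
               threshold = threshold,
               require_precursor = require_precursor,
               precursor_tolerance = precursor_tolerance,
               precursor_ppm = precursor_ppm)
}

#' @rdname annotation-params
#' @export
MatchForwardReverseParam <- function(tolerance = 0, ppm = 20,
                                     map_fun = join_peaks,
                                     sim_fun = ndotproduct,
                                     m = 0, n = 0.5, threshold = 0.7,
                                     require_precursor = TRUE,
                                     precursor_tolerance = tolerance,
                                     precursor_ppm = ppm) {
    p <- CompareSpectraParam(tolerance, ppm, map_fun, sim_fun, m, n,
                             threshold, require_precursor,
                             precursor_tolerance, precursor_ppm)
    class(p) <- c("MatchForwardReverseParam", class(p))
    p
}
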