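#' Isotopic substitution definitions
#'
#' An isotopic substitution is described by its name, the m/z difference
#' `md` it induces relative to the monoisotopic peak, and a mass-dependent
#' interval of plausible intensity ratios (isotopologue / monoisotopic),
#' parameterized as two lines `lo = a_lo * mass + b_lo` (floored at 0) and
#' `hi = a_hi * mass + b_hi` valid on `[mass_min, mass_max]`.
#'
#' The packaged table covers the substitutions most frequently seen in
#' small-molecule MS1 data (13C, 2x13C, 2H, 15N, 18O, 34S, 37Cl). Mass
#' differences come from the isotope masses; the ratio bounds follow from
#' isotope-abundance arithmetic: for one heavy atom of element E the
#' expected ratio is `n_E * p_E / (1 - p_E)` with `p_E` the heavy-isotope
#' abundance, and the element count `n_E` is bracketed by chemically
#' plausible element densities (e.g. for carbon, `mass/45 <= n_C <=
#' mass/12`, i.e. from heteroatom-rich up to pure-carbon backbones), with
#' a 0.5x/1.5x safety margin on the lower/upper line. For substitutions of
#' optional elements (N, S, Cl, O, H) the lower bound is 0; for the
#' two-heavy-atom substitution 2x13C the upper line is the chord of the
#' quadratic ratio over the supported mass range, which dominates the
#' (convex) true ratio. The derivation is reproduced in
#' `scripts/derive_substitutions.R`.
#'
#' @param path Optional CSV file with columns `name`, `md`, `a_lo`,
#'   `b_lo`, `a_hi`, `b_hi`, `mass_min`, `mass_max` replacing the packaged
#'   table.
#' @return `data.frame` of substitution definitions.
#' @examples
#' isotopologue_substitutions()
#' @export
isotopologue_substitutions <- function(path = NULL) {
    if (is.null(path))
        return(.PACKAGED_SUBSTITUTIONS)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "md", "a_lo", "b_lo", "a_hi", "b_hi",
              "mass_min", "mass_max")
    if (!all(need %in% names(tab)))
        stop("substitution table needs columns ",
             paste(need, collapse = ", "))
    .validate_substitutions(tab)
    tab
}

.validate_substitutions <- function(tab) {
    if (any(tab$md <= 0))
        stop("substitution mass differences must be > 0")
    for (i in seq_len(nrow(tab))) {
        ## lo (floored at 0) must not exceed hi anywhere in the mass range
        ms <- c(tab$mass_min[i], tab$mass_max[i])
        lo <- pmax(0, tab$a_lo[i] * ms + tab$b_lo[i])
        hi <- tab$a_hi[i] * ms + tab$b_hi[i]
        if (any(lo > hi))
            stop("substitution '", tab$name[i],
                 "': lower ratio bound exceeds upper bound within ",
                 "[mass_min, mass_max]")
    }
    invisible(tab)
}

.PACKAGED_SUBSTITUTIONS <- local({
    p13C <- 0.0107; r13C <- p13C / (1 - p13C)
    sub <- function(name, md, a_lo, a_hi)
        data.frame(name = name, md = md, a_lo = a_lo, b_lo = 0,
                   a_hi = a_hi, b_hi = 0, mass_min = 0, mass_max = 1500)
    rbind(
        ## carbon backbone: n_C in [mass/45, mass/12], margins 0.5x / 1.5x
        sub("13C",   1.0033548378, 0.5 * r13C / 45, 1.5 * r13C / 12),
        ## two 13C: ratio ~ choose(n_C, 2) * r^2; chord over [0, 1500]
        sub("2x13C", 2.0067096756, 0,
            1.5 * choose(1500 / 12, 2) * r13C^2 / 1500),
        ## optional elements: lower bound 0, upper from max element density
        sub("2H",    1.0062767281, 0, 1.5 * (0.000115 / 0.999885) / 4),
        sub("15N",   0.9970348693, 0, 1.5 * (0.00364 / 0.99636) / 14),
        sub("18O",   2.0042449924, 0, 1.5 * (0.00205 / 0.99757) / 16),
        sub("34S",   1.9957958776, 0, 1.5 * (0.0425 / 0.9499) / 32),
        sub("37Cl",  1.9970499000, 0, 1.5 * (0.2424 / 0.7576) / 35)
    )
})

#' Group MS1 peaks into potential isotopologue groups
#'
#' Scans the peaks of an MS1 spectrum in order of increasing m/z. Each
#' peak not yet assigned to a group is assumed to be the monoisotopic peak
#' of some compound and seeds a candidate group; for every isotopic
#' substitution, later unassigned peaks are searched (via [closest()]) for
#' an m/z of `seed + md` within the tolerance and an intensity ratio to
#' the seed inside the substitution's mass-dependent bounds evaluated at
#' the seed m/z. Compatible peaks join the seed's group; an assigned peak
#' can neither seed a new group nor join a second one. Groups that attract
#' no isotopologue peak are dropped.
#'
#' @param mz,intensity `numeric` peak values, `mz` sorted ascending and
#'   `intensity` positive.
#' @param substitutions `data.frame` from [isotopologue_substitutions()].
#' @param tolerance,ppm Match tolerance for the m/z offsets (ppm relative
#'   to the expected isotopologue m/z).
#' @return `list` of integer vectors; each element is one isotopologue
#'   group, ordered by m/z with the assumed monoisotopic peak first.
#' @examples
#' isotopologues(c(100, 101.00335), c(1e5, 1.1e4), ppm = 20)
#' @export
isotopologues <- function(mz, intensity,
                          substitutions = isotopologue_substitutions(),
                          tolerance = 0, ppm = 20) {
    .check_sorted(mz, "'mz'")
    if (length(mz) != length(intensity))
        stop("'mz' and 'intensity' must have equal length")
    if (any(intensity <= 0))
        stop("intensities must be > 0")
    .validate_substitutions(substitutions)
    n <- length(mz)
    assigned <- logical(n)
    groups <- list()
    for (i in seq_len(n)) {
        if (assigned[i]) next
        members <- integer()
        for (s in seq_len(nrow(substitutions))) {
            if (mz[i] < substitutions$mass_min[s] ||
                mz[i] > substitutions$mass_max[s]) next
            expect <- mz[i] + substitutions$md[s]
            free <- which(!assigned & seq_len(n) > i &
                          !(seq_len(n) %in% members))
            if (!length(free)) next
            hit <- closest(expect, mz[free], tolerance = tolerance,
                           ppm = ppm, duplicates = "closest")
            if (is.na(hit)) next
            j <- free[hit]
            ratio <- intensity[j] / intensity[i]
            lo <- max(0, substitutions$a_lo[s] * mz[i] +
                         substitutions$b_lo[s])
            hi <- substitutions$a_hi[s] * mz[i] + substitutions$b_hi[s]
            if (ratio >= lo && ratio <= hi)
                members <- c(members, j)
        }
        if (length(members)) {
            grp <- c(i, sort(members))
            assigned[grp] <- TRUE
            groups[[length(groups) + 1L]] <- grp
        }
    }
    groups
}
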