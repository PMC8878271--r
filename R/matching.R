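#' ppm/tolerance matching of sorted numeric values
#'
#' Matching of m/z (or any numeric) values accepts differences expressed as
#' an absolute error (`tolerance`, Da) plus a relative error (`ppm`); query
#' value `x` matches table value `t` when
#' `|x - t| <= tolerance + x * ppm * 1e-6`. The window is computed on the
#' query side, so matching is intentionally asymmetric.
#'
#' @name matching
NULL

.mz_window <- function(x, tolerance, ppm) tolerance + x * ppm * 1e-6

.check_sorted <- function(x, what) {
    if (anyNA(x) || any(!is.finite(x)))
        stop(what, " must be finite and free of missing values")
    if (is.unsorted(x))
        stop(what, " must be sorted ascending")
}

## All in-window (query, table) candidate pairs, ordered for deterministic
## one-to-one assignment: ascending |delta|, then table index, then query
## index. Optionally a precursor-difference shift is applied to the table
## values (GNPS-style matching).
.candidate_pairs <- function(x, table, tolerance, ppm, shift = 0) {
    res <- vector("list", length(x))
    for (i in seq_along(x)) {
        win <- .mz_window(x[i], tolerance, ppm)
        j <- which(abs(x[i] - table - shift) <= win)
        if (length(j))
            res[[i]] <- data.frame(qidx = i, tidx = j,
                                   delta = abs(x[i] - table[j] - shift))
    }
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(qidx = integer(), tidx = integer(),
                          delta = numeric())
    out[order(out$delta, out$tidx, out$qidx), , drop = FALSE]
}

## Greedy one-to-one assignment over candidates sorted by ascending
## |delta| (ties: lower table index, then lower query index).
.assign_one_to_one <- function(cand, nx, ntab) {
    map <- rep(NA_integer_, nx)
    tab_used <- logical(ntab)
    for (k in seq_len(nrow(cand))) {
        qi <- cand$qidx[k]; ti <- cand$tidx[k]
        if (is.na(map[qi]) && !tab_used[ti]) {
            map[qi] <- ti
            tab_used[ti] <- TRUE
        }
    }
    map
}

#' Match query values to the closest in-window table values
#'
#' Each `x` is matched to the in-window `table` entry with the smallest
#' absolute difference (ties resolved toward the lower table index). With
#' `duplicates = "closest"` (default) the mapping is additionally one-to-one:
#' when several queries compete for one table value, assignments are made in
#' order of increasing absolute difference and losing queries fall back to
#' their next-best in-window candidate, or to no match.
#'
#' @param x `numeric`, sorted ascending: query values.
#' @param table `numeric`, sorted ascending: reference values.
#' @param tolerance Absolute acceptable difference (same unit as `x`).
#' @param ppm Relative acceptable difference in parts per million of `x`.
#' @param duplicates `"closest"` (one-to-one) or `"keep"` (independent
#'   per-query matching, a table value may be hit repeatedly).
#' @return `integer` of length `length(x)` with the matched table index or
#'   `NA` for no match.
#' @examples
#' closest(c(100.0005, 200), c(100, 150), ppm = 10)
#' @export
closest <- function(x, table, tolerance = 0, ppm = 0,
                    duplicates = c("closest", "keep")) {
    duplicates <- match.arg(duplicates)
    .check_sorted(x, "'x'")
    .check_sorted(table, "'table'")
    if (tolerance < 0 || ppm < 0)
        stop("'tolerance' and 'ppm' must be >= 0")
    cand <- .candidate_pairs(x, table, tolerance, ppm)
    if (duplicates == "keep") {
        map <- rep(NA_integer_, length(x))
        ## candidates are sorted best-first; first hit per query wins
        for (k in seq_len(nrow(cand)))
            if (is.na(map[cand$qidx[k]])) map[cand$qidx[k]] <- cand$tidx[k]
        map
    } else {
        .assign_one_to_one(cand, length(x), length(table))
    }
}

#' Join the peaks of two spectra
#'
#' Peaks of a query and a target spectrum are mapped one-to-one by m/z
#' using [closest()] (`duplicates = "closest"`); the join `type` only
#' controls which unmatched peaks are reported, the matched pairs are
#' identical across all four types (SQL join semantics): `"outer"` reports
#' all peaks of both spectra, `"inner"` only matched pairs, `"left"` all
#' query peaks, `"right"` all target peaks.
#'
#' @param x,y [Spectrum()] objects (query and target).
#' @param tolerance,ppm Match tolerance, see [closest()].
#' @param type One of `"outer"`, `"inner"`, `"left"`, `"right"`.
#' @return `data.frame` with one row per reported peak pair/gap, columns
#'   `qidx`, `tidx` (integer index into the respective spectrum, `NA` for a
#'   gap), `mz_q`, `intensity_q`, `mz_t`, `intensity_t`, ordered by
#'   ascending m/z of whichever side is present. Attribute `"type"` records
#'   the join type.
#' @examples
#' q <- Spectrum(c(100, 200, 300), c(10, 20, 30))
#' t <- Spectrum(c(100.0005, 250), c(10, 5))
#' join_peaks(q, t, ppm = 10, type = "outer")
#' @export
join_peaks <- function(x, y, tolerance = 0, ppm = 20,
                       type = c("outer", "inner", "left", "right")) {
    type <- match.arg(type)
    map <- closest(peaks_mz(x), peaks_mz(y), tolerance, ppm,
                   duplicates = "closest")
    qidx <- seq_along(peaks_mz(x))
    matched_q <- qidx[!is.na(map)]
    matched_t <- map[!is.na(map)]
    rows <- data.frame(qidx = matched_q, tidx = matched_t)
    if (type %in% c("outer", "left")) {
        gq <- setdiff(qidx, matched_q)
        if (length(gq))
            rows <- rbind(rows, data.frame(qidx = gq, tidx = NA_integer_))
    }
    if (type %in% c("outer", "right")) {
        gt <- setdiff(seq_along(peaks_mz(y)), matched_t)
        if (length(gt))
            rows <- rbind(rows, data.frame(qidx = NA_integer_, tidx = gt))
    }
    .finish_join(rows, x, y, type)
}

.finish_join <- function(rows, x, y, type) {
    rows$mz_q <- peaks_mz(x)[rows$qidx]
    rows$intensity_q <- peaks_intensity(x)[rows$qidx]
    rows$mz_t <- peaks_mz(y)[rows$tidx]
    rows$intensity_t <- peaks_intensity(y)[rows$tidx]
    ord_mz <- ifelse(is.na(rows$mz_q), rows$mz_t, rows$mz_q)
    rows <- rows[order(ord_mz, rows$mz_t, na.last = FALSE), , drop = FALSE]
    rownames(rows) <- NULL
    attr(rows, "type") <- type
    rows
}

#' Join peaks allowing precursor-difference shifted matches
#'
#' GNPS-style ("hybrid search") peak mapping: a query/target peak pair is a
#' candidate when the two m/z match directly within the tolerance, or when
#' their difference matches the difference of the two precursor m/z values.
#' A peak may take part in both a direct and a shifted candidate pair; all
#' candidates are kept (conflict resolution happens in [gnps_score()]) and
#' unmatched peaks of both sides are reported as gaps (outer semantics).
#'
#' @inheritParams join_peaks
#' @return `data.frame` as for [join_peaks()] with an extra character
#'   column `match_type` (`"direct"`, `"shifted"`, or `NA` for gaps).
#' @export
join_peaks_gnps <- function(x, y, tolerance = 0, ppm = 20) {
    if (is.na(precursor_mz(x)) || is.na(precursor_mz(y)))
        stop("both spectra must have a precursor m/z for GNPS-style ",
             "peak matching")
    shift <- precursor_mz(x) - precursor_mz(y)
    direct <- .candidate_pairs(peaks_mz(x), peaks_mz(y), tolerance, ppm)
    direct$match_type <- rep("direct", nrow(direct))
    shifted <- .candidate_pairs(peaks_mz(x), peaks_mz(y), tolerance, ppm,
                                shift = shift)
    shifted$match_type <- rep("shifted", nrow(shifted))
    ## a zero shift duplicates every direct pair; collapse those to direct
    dup <- paste(shifted$qidx, shifted$tidx) %in%
        paste(direct$qidx, direct$tidx)
    cand <- rbind(direct, shifted[!dup, , drop = FALSE])
    rows <- data.frame(qidx = cand$qidx, tidx = cand$tidx,
                       match_type = cand$match_type)
    gq <- setdiff(seq_along(peaks_mz(x)), cand$qidx)
    gt <- setdiff(seq_along(peaks_mz(y)), cand$tidx)
    if (length(gq))
        rows <- rbind(rows, data.frame(qidx = gq, tidx = NA_integer_,
                                       match_type = NA_character_))
    if (length(gt))
        rows <- rbind(rows, data.frame(qidx = NA_integer_, tidx = gt,
                                       match_type = NA_character_))
    .finish_join(rows, x, y, "gnps")
}
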