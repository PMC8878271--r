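## shared fixtures and independent oracles for the test suite

## random spectrum with peaks in a narrow m/z band (to provoke join
## collisions); caller controls the RNG state
random_spectrum <- function(n, mz_min = 100, mz_max = 110,
                            precursor = NA_real_) {
    Spectrum(sort(runif(n, mz_min, mz_max)), rexp(n) * 100,
             ms_level = 2L, precursor_mz = precursor)
}

## Brute-force peak-matching oracle: enumerate all in-window pairs
## (window on the query side), then build a one-to-one assignment by
## ascending absolute difference, ties towards the lower target then
## query index. Returns matched (qidx, tidx) pairs.
oracle_match_pairs <- function(qmz, tmz, tolerance = 0, ppm = 0) {
    pairs <- expand.grid(qidx = seq_along(qmz), tidx = seq_along(tmz))
    delta <- abs(qmz[pairs$qidx] - tmz[pairs$tidx])
    win <- tolerance + qmz[pairs$qidx] * ppm * 1e-6
    pairs <- pairs[delta <= win, , drop = FALSE]
    delta <- delta[seq_len(nrow(pairs))] # recompute below after subset
    delta <- abs(qmz[pairs$qidx] - tmz[pairs$tidx])
    pairs <- pairs[order(delta, pairs$tidx, pairs$qidx), , drop = FALSE]
    used_q <- logical(length(qmz)); used_t <- logical(length(tmz))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        if (!used_q[pairs$qidx[k]] && !used_t[pairs$tidx[k]]) {
            keep[k] <- TRUE
            used_q[pairs$qidx[k]] <- TRUE
            used_t[pairs$tidx[k]] <- TRUE
        }
    }
    out <- pairs[keep, , drop = FALSE]
    out[order(out$qidx), , drop = FALSE]
}

## vector-space oracle for the normalized dot product: project both
## spectra on the union m/z grid of a join and compute the squared cosine
oracle_ndotproduct <- function(joined, m = 0, n = 1) {
    wq <- ifelse(is.na(joined$intensity_q), 0,
                 joined$mz_q^m * joined$intensity_q^n)
    wt <- ifelse(is.na(joined$intensity_t), 0,
                 joined$mz_t^m * joined$intensity_t^n)
    (sum(wq * wt) / sqrt(sum(wq^2) * sum(wt^2)))^2
}

## extract matched index pairs from a join result
join_pairs <- function(joined) {
    p <- joined[!is.na(joined$qidx) & !is.na(joined$tidx),
                c("qidx", "tidx")]
    p[order(p$qidx), , drop = FALSE]
}

## formulas of spaced-out common metabolites used by isotopologue tests:
## all pairwise neutral-mass differences exceed 5 Da
iso_fixture_formulas <- function() {
    c(glycine = "C2H5NO2", methionine = "C5H11NO2S",
      glucose = "C6H12O6", caffeine = "C8H10N4O2",
      tryptophan = "C11H12N2O2", palmitate = "C16H32O2",
      sucrose = "C12H22O11", cholesterol = "C27H46O",
      atp = "C10H16N5O13P3")
}

## plant exact binomial 13C (and, for >= 8 carbons, 2x13C) isotopologue
## peaks for the fixture compounds, as singly protonated ions; returns
## peak table plus ground-truth compound and role per peak
planted_isotopologue_peaks <- function() {
    fl <- iso_fixture_formulas()
    masses <- unname(calculate_mass(fl))
    ncarb <- vapply(count_elements(fl), function(x) unname(x["C"]),
                    numeric(1))
    r <- 0.0107 / (1 - 0.0107)
    md1 <- 1.0033548378
    rows <- list()
    for (i in seq_along(fl)) {
        mz0 <- masses[i] + 1.00727646688
        i0 <- 1e5 * (0.5 + 1.5 * (i / length(fl)))
        rows[[length(rows) + 1L]] <- data.frame(
            compound = names(fl)[i], role = "mono", mz = mz0,
            intensity = i0)
        rows[[length(rows) + 1L]] <- data.frame(
            compound = names(fl)[i], role = "13C", mz = mz0 + md1,
            intensity = i0 * ncarb[i] * r)
        if (ncarb[i] >= 8)
            rows[[length(rows) + 1L]] <- data.frame(
                compound = names(fl)[i], role = "2x13C",
                mz = mz0 + 2 * md1,
                intensity = i0 * choose(ncarb[i], 2) * r^2)
    }
    peaks <- do.call(rbind, rows)
    peaks[order(peaks$mz), , drop = FALSE]
}
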