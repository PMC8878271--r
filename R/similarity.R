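#' Normalized spectra similarity scores
#'
#' All scores operate on the output of a peak-join ([join_peaks()] or
#' [join_peaks_gnps()]): each row contributes a query weight and a target
#' weight `w = mz^m * intensity^n` (gaps contribute weight 0). The default
#' weighting `m = 0`, `n = 0.5` (square-root intensity, no m/z weighting)
#' follows common spectral-library search practice.
#'
#' * `ndotproduct()`: normalized dot product (squared cosine),
#'   `(sum(wq * wt))^2 / (sum(wq^2) * sum(wt^2))`, symmetric, in `[0, 1]`.
#' * `neuclidean()`: normalized Euclidean similarity,
#'   `1 / (1 + sum((wq - wt)^2) / sum(wt^2))`; normalization is over the
#'   target (reference) weights, so it is asymmetric under query/target
#'   swap.
#' * `navdist()`: normalized absolute-value distance similarity,
#'   `1 / (1 + sum(|wq - wt|) / sum(wt))`, also target-normalized and
#'   asymmetric.
#' * `nspectraangle()`: normalized spectral angle,
#'   `1 - 2 * acos(cos_sim) / pi`, in `[0, 1]`.
#'
#' Joins in which either side carries no signal give a score of 0 with a
#' warning instead of `NaN`.
#'
#' @param joined `data.frame` from [join_peaks()] (columns `mz_q`,
#'   `intensity_q`, `mz_t`, `intensity_t`).
#' @param m Exponent on m/z in the peak weight.
#' @param n Exponent on intensity in the peak weight.
#' @return `numeric(1)` score.
#' @examples
#' q <- Spectrum(c(100, 200), c(1, 1))
#' t <- Spectrum(c(100, 300), c(1, 1))
#' ndotproduct(join_peaks(q, t), m = 0, n = 1)
#' @export
ndotproduct <- function(joined, m = 0, n = 0.5) {
    w <- .join_weights(joined, m, n)
    sq <- sum(w$q^2); st <- sum(w$t^2)
    if (sq == 0 || st == 0) {
        warning("one side has zero total weight; returning 0")
        return(0)
    }
    sum(w$q * w$t)^2 / (sq * st)
}

#' @rdname ndotproduct
#' @export
neuclidean <- function(joined, m = 0, n = 0.5) {
    w <- .join_weights(joined, m, n)
    st <- sum(w$t^2)
    if (st == 0) {
        warning("target side has zero total weight; returning 0")
        return(0)
    }
    1 / (1 + sum((w$q - w$t)^2) / st)
}

#' @rdname ndotproduct
#' @export
navdist <- function(joined, m = 0, n = 0.5) {
    w <- .join_weights(joined, m, n)
    st <- sum(w$t)
    if (st == 0) {
        warning("target side has zero total weight; returning 0")
        return(0)
    }
    1 / (1 + sum(abs(w$q - w$t)) / st)
}

#' @rdname ndotproduct
#' @export
nspectraangle <- function(joined, m = 0, n = 0.5) {
    w <- .join_weights(joined, m, n)
    sq <- sum(w$q^2); st <- sum(w$t^2)
    if (sq == 0 || st == 0) {
        warning("one side has zero total weight; returning 0")
        return(0)
    }
    ## single sqrt keeps identical inputs at cos = 1 exactly (acos would
    ## otherwise amplify a 1-ulp defect to ~1e-8 in the angle)
    cosv <- min(1, max(-1, sum(w$q * w$t) / sqrt(sq * st)))
    1 - 2 * acos(cosv) / pi
}

.join_weights <- function(joined, m, n) {
    wq <- ifelse(is.na(joined$intensity_q), 0,
                 joined$mz_q^m * joined$intensity_q^n)
    wt <- ifelse(is.na(joined$intensity_t), 0,
                 joined$mz_t^m * joined$intensity_t^n)
    list(q = wq[!is.na(wq) | !is.na(wt)], t = wt[!is.na(wq) | !is.na(wt)])
}

#' GNPS-style modified cosine on a shift-aware peak join
#'
#' Scores the output of [join_peaks_gnps()]. Every candidate pair (direct
#' or precursor-shifted) contributes
#' `wq * wt / (||wq|| * ||wt||)` where the norms run over all peaks of the
#' respective spectrum; because a peak can occur in several candidate
#' pairs, a conflict-free subset (each query and each target peak used at
#' most once) maximizing the summed contribution is selected and its sum
#' returned. The maximum-weight matching is computed exactly by
#' branch-and-bound for up to 32 candidate pairs and greedily (descending
#' contribution) above that.
#'
#' @param joined `data.frame` from [join_peaks_gnps()].
#' @inheritParams ndotproduct
#' @return `numeric(1)` score in `[0, 1]`.
#' @export
gnps_score <- function(joined, m = 0, n = 0.5) {
    ## norms over all peaks of each side (each peak counted once)
    qp <- unique(joined[!is.na(joined$qidx), c("qidx", "mz_q",
                                               "intensity_q")])
    tp <- unique(joined[!is.na(joined$tidx), c("tidx", "mz_t",
                                               "intensity_t")])
    nq <- sqrt(sum((qp$mz_q^m * qp$intensity_q^n)^2))
    nt <- sqrt(sum((tp$mz_t^m * tp$intensity_t^n)^2))
    if (nq == 0 || nt == 0) {
        warning("one side has zero total weight; returning 0")
        return(0)
    }
    cand <- joined[!is.na(joined$qidx) & !is.na(joined$tidx), , drop = FALSE]
    if (!nrow(cand))
        return(0)
    contrib <- (cand$mz_q^m * cand$intensity_q^n) *
        (cand$mz_t^m * cand$intensity_t^n) / (nq * nt)
    .max_weight_matching(cand$qidx, cand$tidx, contrib)
}

## Maximum-weight one-to-one selection among candidate pairs. Exact
## branch-and-bound for small candidate sets, greedy beyond.
.max_weight_matching <- function(qidx, tidx, w, exact_limit = 32L) {
    o <- order(-w)
    qidx <- qidx[o]; tidx <- tidx[o]; w <- w[o]
    k <- length(w)
    greedy <- function() {
        total <- 0
        uq <- integer(); ut <- integer()
        for (i in seq_len(k)) {
            if (!(qidx[i] %in% uq) && !(tidx[i] %in% ut)) {
                total <- total + w[i]
                uq <- c(uq, qidx[i]); ut <- c(ut, tidx[i])
            }
        }
        total
    }
    if (k > exact_limit)
        return(greedy())
    best <- greedy()
    suffix <- rev(cumsum(rev(w)))
    recurse <- function(i, used_q, used_t, acc) {
        if (i > k) {
            if (acc > best) best <<- acc
            return()
        }
        if (acc + suffix[i] <= best)
            return()
        if (!(qidx[i] %in% used_q) && !(tidx[i] %in% used_t))
            recurse(i + 1L, c(used_q, qidx[i]), c(used_t, tidx[i]),
                    acc + w[i])
        recurse(i + 1L, used_q, used_t, acc)
    }
    recurse(1L, integer(), integer(), 0)
    best
}

#' All-pairs spectra similarity matrix
#'
#' Computes the full pairwise similarity between two spectra collections
#' as a two-step procedure: peaks of each spectrum pair are mapped with
#' `map_fun` and the mapped peaks scored with `sim_fun`. Both functions
#' can be user-supplied as long as they honour the join/score contracts.
#'
#' @param x,y [SpectraCollection()] objects.
#' @param map_fun Peak mapping function (default [join_peaks()]).
#' @param sim_fun Similarity function (default [ndotproduct()]).
#' @param tolerance,ppm Peak match tolerance passed to `map_fun`.
#' @param m,n Weighting exponents passed to `sim_fun`.
#' @param ... Further arguments passed to `map_fun`.
#' @return `numeric` matrix of dimension `length(x)` by `length(y)`.
#' @examples
#' a <- SpectraCollection(list(Spectrum(c(100, 150), c(5, 10))))
#' compare_spectra(a, a)
#' @export
compare_spectra <- function(x, y, map_fun = join_peaks,
                            sim_fun = ndotproduct, tolerance = 0, ppm = 20,
                            m = 0, n = 0.5, ...) {
    res <- matrix(NA_real_, nrow = length(x), ncol = length(y))
    for (i in seq_len(length(x))) {
        for (j in seq_len(length(y))) {
            s <- sim_fun(map_fun(x[[i]], y[[j]], tolerance = tolerance,
                                 ppm = ppm, ...), m = m, n = n)
            if (!is.numeric(s) || length(s) != 1L)
                stop("similarity function '",
                     deparse(substitute(sim_fun)),
                     "' must return a single numeric value")
            res[i, j] <- s
        }
    }
    res
}
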