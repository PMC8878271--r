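#' MS2 annotation: match query spectra against reference spectra
#'
#' Compares experimental MS2 spectra against a reference library. With
#' `require_precursor = TRUE` (default) only spectrum pairs whose
#' precursor m/z agree within the precursor tolerance are scored; query
#' spectra lacking a precursor are then skipped (their number is recorded
#' in the processing log). Each candidate pair is scored with
#' `sim_fun(map_fun(query, target))` and kept when the score is strictly
#' greater than the threshold. All query spectra remain represented in
#' the result, matched or not.
#'
#' With a [MatchForwardReverseParam()] two additional quantities are
#' reported per kept match: `reverse_score`, the same similarity computed
#' on a right join (all reference peaks plus only the matching query
#' peaks), and `presence_ratio`, the fraction of query peaks with a
#' matching reference peak.
#'
#' @param query A [SpectraCollection()] of experimental MS2 spectra.
#' @param target A [SpectraCollection()] or a `CompDb` with reference
#'   spectra.
#' @param params A [CompareSpectraParam()] or
#'   [MatchForwardReverseParam()].
#' @return A [Matched] object with subclass `MatchedSpectra`; match
#'   columns are `query_idx`, `target_idx`, `score` and, for
#'   forward/reverse matching, `reverse_score` and `presence_ratio`.
#' @examples
#' sp <- SpectraCollection(list(
#'     Spectrum(c(100, 150, 200), c(10, 50, 100), precursor_mz = 220)))
#' match_spectra(sp, sp, CompareSpectraParam())$matches
#' @export
match_spectra <- function(query, target, params = CompareSpectraParam()) {
    if (!inherits(params, "CompareSpectraParam"))
        stop("'params' must be a CompareSpectraParam or ",
             "MatchForwardReverseParam object")
    if (!inherits(query, "SpectraCollection"))
        stop("'query' must be a SpectraCollection")
    target_in <- target
    if (inherits(target, "CompDb")) {
        target <- query_spectra(target)
        if (!length(target))
            stop("the CompDb target contains no spectra")
    }
    if (!inherits(target, "SpectraCollection"))
        stop("'target' must be a SpectraCollection or CompDb")
    fwd_rev <- inherits(params, "MatchForwardReverseParam")
    qpmz <- vapply(query$spectra, precursor_mz, numeric(1))
    tpmz <- vapply(target$spectra, precursor_mz, numeric(1))
    skipped <- 0L
    rows <- list()
    for (i in seq_len(length(query))) {
        if (params$require_precursor) {
            if (is.na(qpmz[i])) {
                skipped <- skipped + 1L
                next
            }
            win <- .mz_window(qpmz[i], params$precursor_tolerance,
                              params$precursor_ppm)
            cand <- which(!is.na(tpmz) & abs(qpmz[i] - tpmz) <= win)
        } else {
            cand <- seq_len(length(target))
        }
        for (j in cand) {
            joined <- params$map_fun(query[[i]], target[[j]],
                                     tolerance = params$tolerance,
                                     ppm = params$ppm)
            score <- params$sim_fun(joined, m = params$m, n = params$n)
            if (score > params$threshold) {
                row <- data.frame(query_idx = i, target_idx = j,
                                  score = score)
                if (fwd_rev) {
                    rj <- join_peaks(query[[i]], target[[j]],
                                     tolerance = params$tolerance,
                                     ppm = params$ppm, type = "right")
                    row$reverse_score <- params$sim_fun(rj, m = params$m,
                                                        n = params$n)
                    n_matched <- sum(!is.na(joined$qidx) &
                                     !is.na(joined$tidx))
                    nq <- length(peaks_mz(query[[i]]))
                    row$presence_ratio <- if (nq) n_matched / nq else 0
                }
                rows[[length(rows) + 1L]] <- row
            }
        }
    }
    mm <- if (length(rows)) do.call(rbind, rows)
          else {
              base <- data.frame(query_idx = integer(),
                                 target_idx = integer(),
                                 score = numeric())
              if (fwd_rev) {
                  base$reverse_score <- numeric()
                  base$presence_ratio <- numeric()
              }
              base
          }
    log <- c(paste0("match_spectra(", class(params)[1L], ")"),
             if (skipped)
                 paste0(skipped, " query spectra without precursor ",
                        "skipped"))
    out <- Matched(query, target_in, mm, params, log = log)
    class(out) <- c("MatchedSpectra", class(out))
    out
}
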