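#' Scored many-to-many annotation results
#'
#' A `Matched` object bundles the query object, the target object, a
#' match table of scored query-target relations (a query can have zero,
#' one or many matches) and the parameter object that produced it, so the
#' full provenance of an annotation travels with its result. MS2 results
#' carry the subclass `MatchedSpectra`.
#'
#' @param query Query object (data.frame or [SpectraCollection()]).
#' @param target Target object (data.frame, [SpectraCollection()] or
#'   `CompDb`).
#' @param matches `data.frame` with integer columns `query_idx`,
#'   `target_idx` (1-based) and score columns.
#' @param params The parameter object used.
#' @param log Character vector of processing steps.
#' @return A `Matched` object.
#' @seealso [match_mz()], [match_spectra()], [matched_data()],
#'   [filter_matches()]
#' @export
Matched <- function(query, target, matches, params, log = character()) {
    stopifnot(is.data.frame(matches),
              all(c("query_idx", "target_idx") %in% names(matches)))
    structure(list(query = query, target = target, matches = matches,
                   params = params, log = log),
              class = "Matched")
}

.n_query <- function(x) {
    if (inherits(x, "SpectraCollection")) length(x) else nrow(x)
}

#' @export
print.Matched <- function(x, ...) {
    cat(sprintf("%s\n  %d queries, %d with at least one match, %d match rows\n",
                class(x)[1L], .n_query(x$query),
                length(unique(x$matches$query_idx)), nrow(x$matches)))
    invisible(x)
}

#' Flatten a Matched result to one row per query-match pair
#'
#' Left-join semantics: every query appears at least once; queries without
#' any match get a single row with `NA` target fields. Query columns come
#' first in their original order; target columns whose names collide with
#' query columns are prefixed with `target_`.
#'
#' @param x A [Matched] object.
#' @return `data.frame`.
#' @export
matched_data <- function(x) {
    qdf <- .as_feature_frame(x$query, "query")
    tdf <- .as_feature_frame(x$target, "target")
    mm <- x$matches
    all_q <- seq_len(nrow(qdf))
    unmatched <- setdiff(all_q, mm$query_idx)
    if (length(unmatched)) {
        pad <- mm[rep(NA_integer_, length(unmatched)), , drop = FALSE]
        pad$query_idx <- unmatched
        mm <- rbind(mm, pad)
    }
    mm <- mm[order(mm$query_idx), , drop = FALSE]
    clash <- intersect(names(tdf), names(qdf))
    names(tdf)[names(tdf) %in% clash] <- paste0("target_", clash)
    out <- cbind(qdf[mm$query_idx, , drop = FALSE],
                 mm[, setdiff(names(mm), c("query_idx", "target_idx")),
                    drop = FALSE],
                 tdf[mm$target_idx, , drop = FALSE])
    out$query_idx <- mm$query_idx
    out$target_idx <- mm$target_idx
    rownames(out) <- NULL
    out
}

## uniform tabular view of query/target objects for matched_data()
.as_feature_frame <- function(x, side) {
    if (is.data.frame(x))
        return(x)
    if (inherits(x, "CompDb"))
        return(query_compounds(x))
    if (inherits(x, "SpectraCollection")) {
        return(data.frame(
            spectrum = seq_len(length(x)),
            precursor_mz = vapply(x$spectra, precursor_mz, numeric(1)),
            rtime = vapply(x$spectra, function(s) s$rtime, numeric(1)),
            id = vapply(x$spectra, function(s)
                if (!is.null(s$meta$id)) s$meta$id
                else if (!is.null(s$meta$name)) s$meta$name
                else NA_character_, character(1))))
    }
    stop("cannot flatten ", side, " of class ", class(x)[1L])
}

#' Filter or subset a Matched result
#'
#' Strategies (applied in this order when combined):
#' `query_subset` keeps only the given query indices and re-indexes the
#' queries; `score_threshold` keeps match rows whose `score` column value
#' is strictly greater than the cut; `top_rank` keeps per query only the
#' best match (largest `score`, or smallest `|ppm_error|` when
#' `rank_by = "ppm_error"`). The applied filter is appended to the
#' result's processing log.
#'
#' @param x A [Matched] object.
#' @param query_subset Integer indices of queries to keep.
#' @param score_threshold Numeric cut on the score column (strict `>`).
#' @param top_rank If `TRUE` keep only the best match per query.
#' @param rank_by `"score"` or `"ppm_error"`.
#' @return A new [Matched] object.
#' @export
filter_matches <- function(x, query_subset = NULL, score_threshold = NULL,
                           top_rank = FALSE,
                           rank_by = c("score", "ppm_error")) {
    rank_by <- match.arg(rank_by)
    mm <- x$matches
    query <- x$query
    log <- x$log
    if (!is.null(query_subset)) {
        nq <- .n_query(x$query)
        if (any(query_subset < 1L | query_subset > nq))
            stop("'query_subset' indices out of range (1..", nq, ")")
        query <- if (inherits(query, "SpectraCollection"))
            query[query_subset]
        else query[query_subset, , drop = FALSE]
        mm <- mm[mm$query_idx %in% query_subset, , drop = FALSE]
        mm$query_idx <- match(mm$query_idx, query_subset)
        log <- c(log, paste0("query_subset(",
                             paste(query_subset, collapse = ","), ")"))
    }
    if (!is.null(score_threshold)) {
        if (!"score" %in% names(mm))
            stop("matches have no 'score' column")
        mm <- mm[mm$score > score_threshold, , drop = FALSE]
        log <- c(log, paste0("score_threshold(", score_threshold, ")"))
    }
    if (isTRUE(top_rank)) {
        key <- if (rank_by == "ppm_error") abs(mm$ppm_error) else -mm$score
        keep <- unlist(lapply(split(seq_len(nrow(mm)), mm$query_idx),
                              function(i) i[which.min(key[i])]))
        mm <- mm[sort(keep), , drop = FALSE]
        log <- c(log, paste0("top_rank(", rank_by, ")"))
    }
    rownames(mm) <- NULL
    out <- Matched(query, x$target, mm, x$params, log)
    class(out) <- class(x)
    out
}
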