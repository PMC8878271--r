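#' MS1 annotation: match feature m/z values against reference values
#'
#' Matches the m/z (and optionally retention time) of query features
#' against target reference values. With [Mass2MzParam()] /
#' [Mass2MzRtParam()] the target table provides neutral exact masses which
#' are converted to an m/z grid over the configured adducts before
#' matching; with [MzParam()] / [MzRtParam()] target m/z values are
#' matched directly. Annotation is a screening step, so *all* in-window
#' (query, target, adduct) combinations are reported, not only the
#' closest; use [filter_matches()] for nearest-only results. Queries
#' without matches remain part of the result.
#'
#' @param query `data.frame` with a numeric m/z column (default name
#'   `"mz"`) and, for Rt parameters, a retention time column (default
#'   `"rt"`, seconds).
#' @param target `data.frame` with an `exactmass` (Mass2Mz parameters) or
#'   `mz` (Mz parameters) column, or a `CompDb` (Mass2Mz parameters; its
#'   compound table is used). Rt parameters need an `rt` column (for a
#'   CompDb, retention times are taken from its ion table if present).
#' @param params A parameter object, see [annotation-params].
#' @param mz_col,rt_col Query column names.
#' @param target_mz_col,target_rt_col Target column names (`mz`/
#'   `exactmass` resolved by parameter type when left `NULL`).
#' @return A [Matched] object; its match table has columns `query_idx`,
#'   `target_idx`, `adduct` (`NA` for direct m/z matching), `delta_mz`
#'   (signed, query - target, Da), `ppm_error`, `score` (`|delta_mz|`)
#'   and, for Rt parameters, `delta_rt` (signed, seconds).
#' @examples
#' fts <- data.frame(mz = mass2mz(calculate_mass("C8H10N4O2"), "[M+H]+"))
#' cmp <- data.frame(name = "caffeine",
#'                   exactmass = calculate_mass("C8H10N4O2"))
#' match_mz(fts, cmp, Mass2MzParam("[M+H]+", ppm = 5))$matches
#' @export
match_mz <- function(query, target, params, mz_col = "mz", rt_col = "rt",
                     target_mz_col = NULL, target_rt_col = NULL) {
    if (!inherits(params, "AnnotationParam"))
        stop("'params' must be an annotation parameter object")
    if (!is.data.frame(query))
        stop("'query' must be a data.frame")
    if (!mz_col %in% names(query))
        stop("query lacks m/z column '", mz_col, "'; available: ",
             paste(names(query), collapse = ", "))
    use_rt <- inherits(params, c("MzRtParam", "Mass2MzRtParam"))
    mass_based <- inherits(params, c("Mass2MzParam", "Mass2MzRtParam"))
    target_in <- target
    if (inherits(target, "CompDb")) {
        cmp <- query_compounds(target)
        if (use_rt) {
            ions <- query_ions(target)
            cmp$rt <- ions$rtime[match(cmp$compound_id, ions$compound_id)]
        }
        target <- cmp
    }
    if (!is.data.frame(target))
        stop("'target' must be a data.frame or CompDb")
    if (is.null(target_mz_col))
        target_mz_col <- if (mass_based) "exactmass" else "mz"
    if (!target_mz_col %in% names(target))
        stop("target lacks column '", target_mz_col, "'; available: ",
             paste(names(target), collapse = ", "))
    if (is.null(target_rt_col))
        target_rt_col <- "rt"
    if (use_rt && !rt_col %in% names(query))
        stop("query lacks retention time column '", rt_col, "'")
    if (use_rt && !target_rt_col %in% names(target))
        stop("target lacks retention time column '", target_rt_col, "'")

    qmz <- query[[mz_col]]
    if (mass_based) {
        defs <- .resolve_adducts(params$adducts)
        grids <- lapply(seq_len(nrow(defs)), function(a)
            target[[target_mz_col]] * defs$mass_multi[a] +
                defs$mass_add[a])
        adduct_names <- defs$name
    } else {
        grids <- list(target[[target_mz_col]])
        adduct_names <- NA_character_
    }
    rows <- list()
    for (a in seq_along(grids)) {
        tmz <- grids[[a]]
        for (i in seq_along(qmz)) {
            win <- .mz_window(qmz[i], params$tolerance, params$ppm)
            j <- which(!is.na(tmz) & abs(qmz[i] - tmz) <= win)
            if (!length(j)) next
            rows[[length(rows) + 1L]] <- data.frame(
                query_idx = i, target_idx = j,
                adduct = adduct_names[a],
                delta_mz = qmz[i] - tmz[j],
                ppm_error = (qmz[i] - tmz[j]) / qmz[i] * 1e6)
        }
    }
    mm <- if (length(rows)) do.call(rbind, rows)
          else data.frame(query_idx = integer(), target_idx = integer(),
                          adduct = character(), delta_mz = numeric(),
                          ppm_error = numeric())
    if (use_rt && nrow(mm)) {
        drt <- query[[rt_col]][mm$query_idx] -
            target[[target_rt_col]][mm$target_idx]
        mm$delta_rt <- drt
        mm <- mm[!is.na(drt) & abs(drt) <= params$rt_tolerance, ,
                 drop = FALSE]
    } else if (use_rt) {
        mm$delta_rt <- numeric()
    }
    mm$score <- abs(mm$delta_mz)
    mm <- mm[order(mm$query_idx, mm$target_idx), , drop = FALSE]
    rownames(mm) <- NULL
    Matched(query, target_in, mm, params,
            log = paste0("match_mz(", class(params)[1L], ")"))
}
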