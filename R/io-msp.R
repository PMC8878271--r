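#' Read and write NIST MSP spectral library files
#'
#' MSP records start at a `Name:` line (case-insensitive) followed by
#' further `Key: value` headers; a `Num Peaks:` line announces the peak
#' list, which may be space- or tab-separated with multiple m/z-intensity
#' pairs per line. Header keys are matched case-insensitively:
#' `PrecursorMZ` becomes the precursor m/z, `RetentionTime` the retention
#' time (seconds), `Ion_mode` / `Polarity` the polarity; all keys are kept
#' lower-cased in the metadata. The declared and actual peak counts must
#' agree. Writing uses 17 significant digits so peak values round-trip
#' bit-exactly.
#'
#' @param path Path of the MSP file.
#' @return `read_msp()` returns a [SpectraCollection()].
#' @export
read_msp <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- sub("\r$", "", readLines(path, warn = FALSE))
    starts <- grep("^[Nn][Aa][Mm][Ee]:", trimws(lines))
    if (!length(starts) && any(nzchar(trimws(lines))))
        stop("no 'Name:' record found in ", path)
    ends <- c(starts[-1L] - 1L, length(lines))
    spectra <- lapply(seq_along(starts), function(k)
        .parse_msp_record(lines[starts[k]:ends[k]], starts[k]))
    SpectraCollection(spectra, metadata = list(source = path,
                                               format = "msp"))
}

.parse_msp_record <- function(lines, offset) {
    meta <- list()
    n_declared <- NA_integer_
    peak_from <- NA_integer_
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        key <- tolower(sub(":.*", "", ln))
        if (grepl("^num +peaks$", key)) {
            n_declared <- as.integer(trimws(sub("^[^:]*:", "", ln)))
            peak_from <- i + 1L
            break
        }
        if (!grepl(":", ln, fixed = TRUE))
            stop("record at line ", offset, ": header line without ':': '",
                 ln, "'")
        meta[[gsub(" ", "_", key)]] <- trimws(sub("^[^:]*:", "", ln))
    }
    mz <- numeric(); int <- numeric()
    if (!is.na(peak_from) && peak_from <= length(lines)) {
        for (ln in trimws(lines[peak_from:length(lines)])) {
            if (!nzchar(ln)) next
            tok <- strsplit(ln, "[ \t;]+")[[1L]]
            vals <- suppressWarnings(as.numeric(tok))
            if (anyNA(vals) || length(vals) %% 2L != 0L)
                stop("record '", meta$name, "': malformed peak line '",
                     ln, "'")
            idx <- seq(1L, length(vals), by = 2L)
            mz <- c(mz, vals[idx]); int <- c(int, vals[idx + 1L])
        }
    }
    if (is.na(n_declared))
        stop("record '", meta$name, "' (line ", offset,
             "): missing 'Num Peaks:' header")
    if (length(mz) != n_declared)
        stop("record '", meta$name, "': declared ", n_declared,
             " peaks but found ", length(mz))
    precursor <- NA_real_
    for (k in c("precursormz", "precursor_m/z", "precursor_mz")) {
        if (!is.null(meta[[k]])) {
            precursor <- as.numeric(meta[[k]])
            meta[[k]] <- NULL
            break
        }
    }
    rtime <- NA_real_
    if (!is.null(meta$retentiontime)) {
        rtime <- as.numeric(meta$retentiontime)
        meta$retentiontime <- NULL
    }
    polarity <- "unknown"
    pol <- tolower(c(meta$ion_mode, meta$ionmode, meta$polarity)[1L])
    if (length(pol) && !is.na(pol)) {
        if (pol %in% c("p", "positive", "+")) polarity <- "positive"
        if (pol %in% c("n", "negative", "-")) polarity <- "negative"
    }
    Spectrum(mz, int, ms_level = 2L, precursor_mz = precursor,
             rtime = rtime, polarity = polarity, meta = meta)
}

#' @rdname read_msp
#' @param x A [SpectraCollection()].
#' @export
write_msp <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (s in x$spectra) {
        m <- s$meta
        name <- if (!is.null(m$name)) m$name else "unknown"
        writeLines(paste0("Name: ", name), con)
        for (key in setdiff(names(m), "name"))
            writeLines(paste0(.msp_key(key), ": ", m[[key]]), con)
        if (!is.na(s$precursor_mz))
            writeLines(sprintf("PrecursorMZ: %.17g", s$precursor_mz), con)
        if (!is.na(s$rtime))
            writeLines(sprintf("RetentionTime: %.17g", s$rtime), con)
        if (s$polarity != "unknown" && is.null(m$ion_mode) &&
            is.null(m$ionmode) && is.null(m$polarity))
            writeLines(paste0("Ion_mode: ",
                              toupper(substr(s$polarity, 1, 1))), con)
        writeLines(sprintf("Num Peaks: %d", length(s$mz)), con)
        writeLines(sprintf("%.17g %.17g", s$mz, s$intensity), con)
        writeLines("", con)
    }
    invisible(path)
}

## restore conventional capitalization of common MSP keys
.msp_key <- function(key) {
    fixed <- c(name = "Name", formula = "Formula", inchikey = "InChIKey",
               exactmass = "ExactMass", comment = "Comment",
               adduct = "Adduct", compound_id = "Compound_id")
    if (!is.na(fixed[key])) unname(fixed[key]) else key
}
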