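#' Read and write Mascot Generic Format (MGF) files
#'
#' MGF stores one MS2 spectrum per `BEGIN IONS`/`END IONS` block with
#' `KEY=VALUE` headers followed by `mz intensity` peak lines. On reading,
#' the first token of `PEPMASS` becomes the precursor m/z (any further
#' tokens, typically the precursor intensity, are kept in the metadata),
#' `RTINSECONDS` becomes the retention time in seconds, and the sign of
#' `CHARGE` sets the polarity; `TITLE` and unrecognized keys are stored
#' verbatim in the metadata (keys lower-cased). Writing formats peaks with
#' 17 significant digits so that a read-write-read cycle reproduces them
#' bit-exactly.
#'
#' @param path Path of the MGF file.
#' @return `read_mgf()` returns a [SpectraCollection()].
#' @examples
#' f <- tempfile(fileext = ".mgf")
#' write_mgf(SpectraCollection(list(
#'     Spectrum(c(100, 200), c(1, 2), ms_level = 2, precursor_mz = 300))), f)
#' length(read_mgf(f))
#' @export
read_mgf <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- sub("\r$", "", readLines(path, warn = FALSE))
    spectra <- list()
    in_block <- FALSE
    header <- list(); mz <- numeric(); int <- numeric(); block_start <- NA
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        if (ln == "BEGIN IONS") {
            if (in_block)
                stop("line ", i, ": BEGIN IONS inside an open block")
            in_block <- TRUE
            header <- list(); mz <- numeric(); int <- numeric()
            block_start <- i
        } else if (ln == "END IONS") {
            if (!in_block)
                stop("line ", i, ": END IONS without BEGIN IONS")
            spectra[[length(spectra) + 1L]] <- .mgf_spectrum(header, mz, int)
            in_block <- FALSE
        } else if (in_block) {
            if (grepl("=", ln, fixed = TRUE)) {
                key <- toupper(sub("=.*", "", ln))
                header[[key]] <- sub("^[^=]*=", "", ln)
            } else {
                tok <- strsplit(ln, "[ \t]+")[[1L]]
                vals <- suppressWarnings(as.numeric(tok[1:2]))
                if (length(tok) < 2L || anyNA(vals))
                    stop("line ", i, ": malformed peak line '", ln, "'")
                mz <- c(mz, vals[1L]); int <- c(int, vals[2L])
            }
        }
        ## content outside blocks (comments) is ignored
    }
    if (in_block)
        stop("unterminated BEGIN IONS block starting at line ", block_start)
    SpectraCollection(spectra, metadata = list(source = path,
                                               format = "mgf"))
}

.parse_charge <- function(x) {
    x <- trimws(x)
    sign <- if (grepl("-", x, fixed = TRUE)) -1L else 1L
    num <- suppressWarnings(as.integer(gsub("[^0-9]", "", x)))
    if (is.na(num) || num == 0L) NA_integer_ else sign * num
}

.mgf_spectrum <- function(header, mz, int) {
    meta <- list()
    precursor <- NA_real_; rtime <- NA_real_; polarity <- "unknown"
    for (key in names(header)) {
        val <- header[[key]]
        if (key == "PEPMASS") {
            tok <- strsplit(trimws(val), "[ \t]+")[[1L]]
            precursor <- as.numeric(tok[1L])
            if (length(tok) > 1L)
                meta$pepmass_intensity <- tok[2L]
        } else if (key == "RTINSECONDS") {
            rtime <- as.numeric(val)
        } else if (key == "CHARGE") {
            chg <- .parse_charge(val)
            if (!is.na(chg)) {
                polarity <- if (chg < 0) "negative" else "positive"
                meta$charge <- as.character(chg)
            }
        } else {
            meta[[tolower(key)]] <- val
        }
    }
    Spectrum(mz, int, ms_level = 2L, precursor_mz = precursor,
             rtime = rtime, polarity = polarity, meta = meta)
}

#' @rdname read_mgf
#' @param x A [SpectraCollection()].
#' @export
write_mgf <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (s in x$spectra) {
        writeLines("BEGIN IONS", con)
        m <- s$meta
        if (!is.null(m$title))
            writeLines(paste0("TITLE=", m$title), con)
        if (!is.na(s$precursor_mz)) {
            pm <- sprintf("PEPMASS=%.17g", s$precursor_mz)
            if (!is.null(m$pepmass_intensity))
                pm <- paste(pm, m$pepmass_intensity)
            writeLines(pm, con)
        }
        if (!is.na(s$rtime))
            writeLines(sprintf("RTINSECONDS=%.17g", s$rtime), con)
        if (!is.null(m$charge)) {
            chg <- as.integer(m$charge)
            writeLines(sprintf("CHARGE=%d%s", abs(chg),
                               if (chg < 0) "-" else "+"), con)
        } else if (s$polarity != "unknown") {
            writeLines(sprintf("CHARGE=1%s",
                               if (s$polarity == "negative") "-" else "+"),
                       con)
        }
        skip <- c("title", "pepmass_intensity", "charge")
        for (key in setdiff(names(m), skip))
            writeLines(paste0(toupper(key), "=", m[[key]]), con)
        writeLines(sprintf("%.17g %.17g", s$mz, s$intensity), con)
        writeLines(c("END IONS", ""), con)
    }
    invisible(path)
}
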