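#' Portable SQLite compound reference databases (CompDb / IonDb)
#'
#' A CompDb is a self-describing SQLite file bundling compound annotations
#' (id, name, formula, exact mass, structure identifiers, synonyms),
#' optional reference MS2 spectra, and provenance metadata (source name,
#' source version, creation date, schema version), making reference
#' resources portable and versionable. Adding measured ions (adduct, m/z,
#' retention time per compound) extends the database to the IonDb layout
#' used for in-house libraries; the compound and spectrum tables are left
#' untouched by that extension.
#'
#' Schema v1 tables: `metadata(key, value)`,
#' `ms_compound(compound_id, name, formula, exactmass, inchi, inchikey,
#' smiles)`, `synonym(compound_id, synonym)`,
#' `msms_spectrum(spectrum_id, compound_id, ms_level, precursor_mz,
#' rtime, polarity, meta_json)`,
#' `msms_spectrum_peak(spectrum_id, mz, intensity)` and, after
#' [insert_ions()], `ms_ion(ion_id, compound_id, adduct, mz, rtime)`.
#' Peaks are stored as rows of 8-byte reals, so peak values survive a
#' round trip bit-exactly.
#'
#' @name compdb
NULL

.COMPDB_SCHEMA_VERSION <- "1"
.COMPOUND_COLS <- c("compound_id", "name", "formula", "exactmass",
                    "inchi", "inchikey", "smiles")

.compdb_connect <- function(x) {
    DBI::dbConnect(RSQLite::SQLite(), x$path)
}

#' Open an existing CompDb
#'
#' @param path Path of the SQLite file.
#' @return A `CompDb` handle.
#' @export
compdb <- function(path) {
    if (!file.exists(path))
        stop("database file not found: ", path)
    db <- structure(list(path = path), class = "CompDb")
    con <- .compdb_connect(db)
    on.exit(DBI::dbDisconnect(con))
    if (!all(c("metadata", "ms_compound") %in% DBI::dbListTables(con)))
        stop("not a CompDb database: ", path)
    db
}

#' @export
print.CompDb <- function(x, ...) {
    md <- compdb_metadata(x)
    con <- .compdb_connect(x)
    on.exit(DBI::dbDisconnect(con))
    nc <- DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM ms_compound")$n
    ns <- if ("msms_spectrum" %in% DBI::dbListTables(con))
        DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM msms_spectrum")$n
    else 0L
    cat(sprintf("CompDb: %s v%s (%s)\n  %d compounds, %d spectra\n",
                md[["source"]], md[["source_version"]], md[["date"]],
                nc, ns))
    invisible(x)
}

#' Create a CompDb database
#'
#' @param compounds `data.frame` with column `compound_id` (unique) and
#'   any of `name`, `formula`, `exactmass`, `inchi`, `inchikey`, `smiles`,
#'   `synonyms` (list column or `;`-separated strings).
#' @param metadata Named list/vector with the required entries `source`,
#'   `source_version`, `date` and optional further provenance.
#' @param path Path of the SQLite file to create.
#' @param spectra Optional [SpectraCollection()]; each spectrum must carry
#'   a `compound_id` in its metadata referring to `compounds`.
#' @return A `CompDb` handle.
#' @examples
#' db <- create_compdb(
#'     data.frame(compound_id = "C1", name = "caffeine",
#'                formula = "C8H10N4O2",
#'                exactmass = calculate_mass("C8H10N4O2")),
#'     metadata = list(source = "inhouse", source_version = "1",
#'                     date = "2026-01-01"),
#'     path = tempfile(fileext = ".sqlite"))
#' query_compounds(db)
#' @export
create_compdb <- function(compounds, metadata, path, spectra = NULL) {
    for (key in c("source", "source_version", "date"))
        if (is.null(metadata[[key]]) || !nzchar(metadata[[key]]))
            stop("metadata entry '", key, "' is required and must be ",
                 "non-empty")
    if (!"compound_id" %in% names(compounds))
        stop("'compounds' must have a 'compound_id' column")
    if (anyDuplicated(compounds$compound_id))
        stop("duplicated compound_id: ",
             compounds$compound_id[duplicated(compounds$compound_id)][1L])
    if (file.exists(path))
        stop("file already exists: ", path)
    .check_mass_consistency(compounds)
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    ok <- FALSE
    on.exit({
        DBI::dbDisconnect(con)
        if (!ok) unlink(path)    # no partial databases on failure
    })
    md <- c(as.list(metadata),
            list(schema_version = .COMPDB_SCHEMA_VERSION))
    DBI::dbWriteTable(con, "metadata",
                      data.frame(key = names(md),
                                 value = as.character(unlist(md))))
    cmp <- compounds
    for (col in setdiff(.COMPOUND_COLS, names(cmp)))
        cmp[[col]] <- if (col == "exactmass") NA_real_ else NA_character_
    DBI::dbWriteTable(con, "ms_compound", cmp[, .COMPOUND_COLS])
    syn <- .expand_synonyms(compounds)
    DBI::dbWriteTable(con, "synonym", syn)
    if (!is.null(spectra))
        .write_spectra_tables(con, spectra, compounds$compound_id)
    ok <- TRUE
    DBI::dbDisconnect(con)
    on.exit(NULL)
    compdb(path)
}

.check_mass_consistency <- function(compounds) {
    if (!all(c("formula", "exactmass") %in% names(compounds)))
        return(invisible())
    ok <- !is.na(compounds$formula) & nzchar(compounds$formula) &
        !is.na(compounds$exactmass)
    if (!any(ok)) return(invisible())
    calc <- calculate_mass(compounds$formula[ok])
    off <- abs(calc - compounds$exactmass[ok]) > 0.005
    if (any(off))
        warning("exactmass deviates > 0.005 Da from the formula mass for ",
                "compound(s) ",
                paste(compounds$compound_id[ok][off], collapse = ", "))
}

.expand_synonyms <- function(compounds) {
    if (!"synonyms" %in% names(compounds))
        return(data.frame(compound_id = character(),
                          synonym = character()))
    syn <- compounds$synonyms
    if (!is.list(syn))
        syn <- strsplit(ifelse(is.na(syn), "", syn), ";", fixed = TRUE)
    do.call(rbind, c(list(data.frame(compound_id = character(),
                                     synonym = character())),
                     lapply(seq_along(syn), function(i) {
        s <- trimws(syn[[i]])
        s <- s[nzchar(s)]
        if (!length(s)) return(NULL)
        data.frame(compound_id = compounds$compound_id[i], synonym = s)
    })))
}

.write_spectra_tables <- function(con, spectra, known_ids) {
    heads <- lapply(seq_len(length(spectra)), function(i) {
        s <- spectra[[i]]
        cid <- s$meta$compound_id
        if (is.null(cid))
            stop("spectrum ", i, " lacks a 'compound_id' metadata entry")
        if (!cid %in% known_ids)
            stop("spectrum ", i, " references unknown compound_id '",
                 cid, "'")
        meta <- s$meta[setdiff(names(s$meta), "compound_id")]
        data.frame(spectrum_id = i, compound_id = cid,
                   ms_level = s$ms_level, precursor_mz = s$precursor_mz,
                   rtime = s$rtime, polarity = s$polarity,
                   meta_json = .meta_to_json(meta))
    })
    DBI::dbWriteTable(con, "msms_spectrum", do.call(rbind, heads),
                      append = TRUE)
    peaks <- lapply(seq_len(length(spectra)), function(i)
        data.frame(spectrum_id = i, mz = spectra[[i]]$mz,
                   intensity = spectra[[i]]$intensity))
    DBI::dbWriteTable(con, "msms_spectrum_peak", do.call(rbind, peaks),
                      append = TRUE)
}

## minimal flat string map <-> JSON (values are always strings)
.meta_to_json <- function(meta) {
    if (!length(meta)) return("{}")
    esc <- function(x) gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x))
    paste0("{", paste0("\"", esc(names(meta)), "\":\"",
                       esc(as.character(unlist(meta))), "\"",
                       collapse = ","), "}")
}

.meta_from_json <- function(x) {
    if (is.na(x) || x == "{}") return(list())
    body <- sub("^\\{", "", sub("\\}$", "", x))
    parts <- strsplit(body, "\",\"", fixed = TRUE)[[1L]]
    parts <- gsub("^\"|\"$", "", parts)
    kv <- strsplit(parts, "\":\"", fixed = TRUE)
    un <- function(v) gsub("\\\\\"", "\"", gsub("\\\\\\\\", "\\\\", v))
    stats::setNames(lapply(kv, function(p) un(p[2L])),
                    vapply(kv, function(p) un(p[1L]), character(1)))
}

#' CompDb provenance metadata
#'
#' @param db A `CompDb` handle.
#' @return Named character vector of metadata entries.
#' @export
compdb_metadata <- function(db) {
    con <- .compdb_connect(db)
    on.exit(DBI::dbDisconnect(con))
    md <- DBI::dbReadTable(con, "metadata")
    stats::setNames(md$value, md$key)
}

#' Query compounds from a CompDb
#'
#' Filters are combined with AND; with no filter all compounds are
#' returned. The mass window filter applies the ppm/tolerance acceptance
#' rule of [closest()] on the stored `exactmass` with `mass` as the query
#' value.
#'
#' @param db A `CompDb` handle.
#' @param name_contains Substring filter on the compound name (and
#'   synonyms), case-insensitive.
#' @param mass,tolerance,ppm Mass window filter: keep compounds with
#'   `|mass - exactmass| <= tolerance + mass * ppm * 1e-6`.
#' @param inchikey Exact InChIKey filter.
#' @return `data.frame` of compound records.
#' @export
query_compounds <- function(db, name_contains = NULL, mass = NULL,
                            tolerance = 0, ppm = 0, inchikey = NULL) {
    con <- .compdb_connect(db)
    on.exit(DBI::dbDisconnect(con))
    res <- DBI::dbReadTable(con, "ms_compound")
    if (!is.null(name_contains)) {
        syn <- DBI::dbReadTable(con, "synonym")
        hit_syn <- syn$compound_id[grepl(name_contains, syn$synonym,
                                         ignore.case = TRUE)]
        keep <- grepl(name_contains, res$name, ignore.case = TRUE) |
            res$compound_id %in% hit_syn
        res <- res[keep, , drop = FALSE]
    }
    if (!is.null(mass)) {
        win <- .mz_window(mass, tolerance, ppm)
        res <- res[!is.na(res$exactmass) &
                   abs(res$exactmass - mass) <= win, , drop = FALSE]
    }
    if (!is.null(inchikey))
        res <- res[!is.na(res$inchikey) & res$inchikey == inchikey, ,
                   drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Query reference spectra from a CompDb
#'
#' @param db A `CompDb` handle.
#' @param compound_id Optional compound id filter.
#' @param precursor_mz,tolerance,ppm Optional precursor m/z window filter
#'   (acceptance rule as in [closest()], query side `precursor_mz`).
#' @return A [SpectraCollection()]; each spectrum carries `compound_id`
#'   and `spectrum_id` in its metadata.
#' @export
query_spectra <- function(db, compound_id = NULL, precursor_mz = NULL,
                          tolerance = 0, ppm = 0) {
    con <- .compdb_connect(db)
    on.exit(DBI::dbDisconnect(con))
    if (!"msms_spectrum" %in% DBI::dbListTables(con))
        return(SpectraCollection(metadata = list(source = db$path)))
    heads <- DBI::dbReadTable(con, "msms_spectrum")
    if (!is.null(compound_id))
        heads <- heads[heads$compound_id %in% compound_id, , drop = FALSE]
    if (!is.null(precursor_mz)) {
        win <- .mz_window(precursor_mz, tolerance, ppm)
        heads <- heads[!is.na(heads$precursor_mz) &
                       abs(heads$precursor_mz - precursor_mz) <= win, ,
                       drop = FALSE]
    }
    peaks <- DBI::dbReadTable(con, "msms_spectrum_peak")
    spectra <- lapply(seq_len(nrow(heads)), function(k) {
        h <- heads[k, ]
        pk <- peaks[peaks$spectrum_id == h$spectrum_id, , drop = FALSE]
        meta <- .meta_from_json(h$meta_json)
        meta$compound_id <- h$compound_id
        meta$spectrum_id <- as.character(h$spectrum_id)
        Spectrum(pk$mz, pk$intensity, ms_level = h$ms_level,
                 precursor_mz = h$precursor_mz, rtime = h$rtime,
                 polarity = h$polarity, meta = meta)
    })
    SpectraCollection(spectra, metadata = list(source = db$path))
}

#' Add measured ions to a CompDb (IonDb extension)
#'
#' Creates the `ms_ion` table on first use and bumps the schema version to
#' `"1-ion"`; compound and spectrum tables are untouched.
#'
#' @param db A `CompDb` handle.
#' @param ions `data.frame` with columns `ion_id`, `compound_id`,
#'   `adduct`, `mz` and optional `rtime` (seconds).
#' @return The `CompDb` handle, invisibly.
#' @export
insert_ions <- function(db, ions) {
    need <- c("ion_id", "compound_id", "adduct", "mz")
    if (!all(need %in% names(ions)))
        stop("'ions' must have columns ", paste(need, collapse = ", "))
    if (!"rtime" %in% names(ions))
        ions$rtime <- NA_real_
    known <- query_compounds(db)$compound_id
    bad <- !ions$compound_id %in% known
    if (any(bad))
        stop("ion(s) ", paste(ions$ion_id[bad], collapse = ", "),
             " reference unknown compound_id")
    reg <- .adduct_registry_cache()
    ions$adduct_known <- ions$adduct %in% reg$name
    con <- .compdb_connect(db)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbWriteTable(con, "ms_ion",
                      ions[, c(need, "rtime", "adduct_known")],
                      append = TRUE)
    DBI::dbExecute(con,
        "UPDATE metadata SET value = '1-ion' WHERE key = 'schema_version'")
    invisible(db)
}

#' @rdname insert_ions
#' @export
query_ions <- function(db) {
    con <- .compdb_connect(db)
    on.exit(DBI::dbDisconnect(con))
    if (!"ms_ion" %in% DBI::dbListTables(con))
        return(data.frame(ion_id = character(), compound_id = character(),
                          adduct = character(), mz = numeric(),
                          rtime = numeric(), adduct_known = logical()))
    DBI::dbReadTable(con, "ms_ion")
}

#' Import an MSP spectral library into a new CompDb
#'
#' Reads an MSP file and creates one compound per distinct InChIKey (or,
#' lacking one, compound name) with its spectra attached; `Formula` and
#' `ExactMass` headers populate the compound record when present. Records
#' without InChIKey and name get a generated compound id and are flagged
#' in the compound name.
#'
#' @param path Path of the MSP file.
#' @param metadata Database provenance, see [create_compdb()].
#' @param db_path Path of the SQLite file to create.
#' @return A `CompDb` handle.
#' @export
import_msp_library <- function(path, metadata, db_path) {
    sp <- read_msp(path)
    has <- function(v) !is.null(v) && nzchar(trimws(v))
    keys <- vapply(seq_len(length(sp)), function(i) {
        m <- sp[[i]]$meta
        if (has(m$inchikey)) paste0("ik:", m$inchikey)
        else if (has(m$name)) paste0("nm:", m$name)
        else paste0("anon:", i)
    }, character(1))
    uk <- unique(keys)
    ids <- stats::setNames(sprintf("CMP%04d", seq_along(uk)), uk)
    compounds <- do.call(rbind, lapply(uk, function(k) {
        i <- which(keys == k)[1L]
        m <- sp[[i]]$meta
        data.frame(
            compound_id = unname(ids[k]),
            name = if (has(m$name)) m$name else
                paste0("unidentified record ", i),
            formula = if (has(m$formula))
                standardize_formula(m$formula) else NA_character_,
            exactmass = if (has(m$exactmass))
                as.numeric(m$exactmass) else NA_real_,
            inchi = if (has(m$inchi)) m$inchi else NA_character_,
            inchikey = if (has(m$inchikey)) m$inchikey else
                NA_character_,
            smiles = if (has(m$smiles)) m$smiles else NA_character_)
    }))
    spectra <- SpectraCollection(lapply(seq_len(length(sp)), function(i) {
        s <- sp[[i]]
        s$meta$compound_id <- unname(ids[keys[i]])
        s
    }))
    create_compdb(compounds, metadata, db_path, spectra = spectra)
}
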