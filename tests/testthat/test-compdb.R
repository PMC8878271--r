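make_compounds <- function() {
    data.frame(
        compound_id = c("C1", "C2", "C3"),
        name = c("caffeine", "glucose", "methionine"),
        formula = c("C8H10N4O2", "C6H12O6", "C5H11NO2S"),
        exactmass = unname(calculate_mass(c("C8H10N4O2", "C6H12O6",
                                            "C5H11NO2S"))),
        inchikey = c("RYYVLZVUVIJVGH-UHFFFAOYSA-N",
                     "WQZGKKKJIJFFOK-GASJEMHNSA-N",
                     "FFEARJCKVFRZRR-BYPYZUCNSA-N"),
        synonyms = c("1,3,7-trimethylxanthine;theine", "dextrose", ""))
}

make_ref_spectra <- function() {
    SpectraCollection(list(
        Spectrum(c(110.0713, 138.0662), c(250, 999), ms_level = 2L,
                 precursor_mz = 195.0877, polarity = "positive",
                 meta = list(compound_id = "C1", name = "caffeine")),
        Spectrum(c(69.034, 127.039), c(10, 20), ms_level = 2L,
                 precursor_mz = 181.0707, polarity = "positive",
                 meta = list(compound_id = "C2", name = "glucose"))))
}

local_compdb <- function(env = parent.frame()) {
    path <- withr::local_tempfile(fileext = ".sqlite", .local_envir = env)
    create_compdb(make_compounds(),
                  metadata = list(source = "testdb", source_version = "0.1",
                                  date = "2026-09-28"),
                  path = path, spectra = make_ref_spectra())
}

test_that("create_compdb stores and round-trips all record types", {
    db <- local_compdb()
    cmp <- query_compounds(db)
    expect_equal(nrow(cmp), 3L)
    expect_equal(cmp$compound_id, c("C1", "C2", "C3"))
    expect_equal(cmp$formula, make_compounds()$formula)
    expect_equal(cmp$exactmass, make_compounds()$exactmass)
    sp <- query_spectra(db)
    expect_length(sp, 2L)
    ## peaks survive bit-exactly
    expect_identical(peaks_mz(sp[[1]]), c(110.0713, 138.0662))
    expect_identical(sp[[1]]$meta$compound_id, "C1")
    ## self-describing provenance
    md <- compdb_metadata(db)
    expect_equal(unname(md[c("source", "source_version", "date",
                             "schema_version")]),
                 c("testdb", "0.1", "2026-09-28", "1"))
    ## a fresh handle on the same file sees identical content
    db2 <- compdb(db$path)
    expect_equal(query_compounds(db2), cmp)
    expect_equal(query_spectra(db2)$spectra, sp$spectra)
})

test_that("create_compdb validates inputs", {
    path <- withr::local_tempfile(fileext = ".sqlite")
    expect_error(create_compdb(make_compounds(),
                               metadata = list(source = "x",
                                               source_version = ""),
                               path = path), "source_version")
    cmp <- make_compounds()
    cmp$compound_id[2] <- "C1"
    expect_error(create_compdb(cmp, list(source = "x",
                                         source_version = "1",
                                         date = "d"), path),
                 "duplicated compound_id")
    sp <- SpectraCollection(list(Spectrum(100, 1,
                                          meta = list(compound_id = "NO"))))
    expect_error(create_compdb(make_compounds(),
                               list(source = "x", source_version = "1",
                                    date = "d"), path, spectra = sp),
                 "unknown compound_id")
    cmp2 <- make_compounds()
    cmp2$exactmass[1] <- cmp2$exactmass[1] + 0.1
    expect_warning(create_compdb(cmp2, list(source = "x",
                                            source_version = "1",
                                            date = "d"), path),
                   "deviates")
})

test_that("compound queries compose filters with AND semantics", {
    db <- local_compdb()
    caf_mass <- calculate_mass("C8H10N4O2")
    expect_equal(query_compounds(db, mass = caf_mass,
                                 tolerance = 0.005)$name, "caffeine")
    ## zero-width window slightly off mass matches nothing
    expect_equal(nrow(query_compounds(db, mass = caf_mass + 1e-4)), 0L)
    ## ppm window
    expect_equal(query_compounds(db, mass = caf_mass * (1 + 3e-6),
                                 ppm = 5)$name, "caffeine")
    ## name substring also searches synonyms
    expect_equal(query_compounds(db, name_contains = "theine")$name,
                 "caffeine")
    expect_equal(query_compounds(db,
                                 inchikey = "WQZGKKKJIJFFOK-GASJEMHNSA-N"
                                 )$name, "glucose")
    expect_equal(nrow(query_compounds(db, name_contains = "glu",
                                      mass = caf_mass,
                                      tolerance = 0.01)), 0L)
    sp <- query_spectra(db, precursor_mz = 195.0877, tolerance = 0.01)
    expect_length(sp, 1L)
    expect_length(query_spectra(db, compound_id = "C3"), 0L)
})

test_that("insert_ions extends a CompDb to the IonDb layout", {
    db <- local_compdb()
    ions <- data.frame(ion_id = c("I1", "I2"),
                       compound_id = c("C1", "C1"),
                       adduct = c("[M+H]+", "[M+Na]+"),
                       mz = unname(mass2mz(calculate_mass("C8H10N4O2"),
                                           c("[M+H]+", "[M+Na]+")))[1, ],
                       rtime = c(120, 121))
    insert_ions(db, ions)
    got <- query_ions(db)
    expect_equal(got$ion_id, c("I1", "I2"))
    expect_true(all(got$adduct_known))
    expect_equal(compdb_metadata(db)[["schema_version"]], "1-ion")
    ## compounds and spectra untouched
    expect_equal(nrow(query_compounds(db)), 3L)
    expect_length(query_spectra(db), 2L)
    bad <- data.frame(ion_id = "I9", compound_id = "ZZ",
                      adduct = "[M+H]+", mz = 1)
    expect_error(insert_ions(db, bad), "I9")
})

test_that("import_msp_library groups records by InChIKey or name", {
    f <- withr::local_tempfile(fileext = ".msp")
    writeLines(c(
        "Name: alpha", "InChIKey: AAA", "Formula: C6H12O6",
        "Num Peaks: 1", "100 1", "",
        "Name: alpha prime", "InChIKey: AAA",
        "Num Peaks: 1", "101 1", "",
        "Name: beta", "Formula: H2O",
        "Num Peaks: 2", "50 1 60 2", "",
        "Name: ", "Num Peaks: 1", "70 1", "",
        "Name: gamma", "Num Peaks: 1", "80 1"), f)
    db <- import_msp_library(f, list(source = "msp", source_version = "1",
                                     date = "2026-09-28"),
                             withr::local_tempfile(fileext = ".sqlite"))
    cmp <- query_compounds(db)
    ## 5 records -> 4 compounds (two share an InChIKey)
    expect_equal(nrow(cmp), 4L)
    expect_length(query_spectra(db), 5L)
    shared <- cmp$compound_id[!is.na(cmp$inchikey) & cmp$inchikey == "AAA"]
    expect_length(query_spectra(db, compound_id = shared), 2L)
    ## headerless record got a generated, flagged compound
    expect_true(any(grepl("unidentified", cmp$name)))
    expect_equal(cmp$formula[cmp$inchikey %in% "AAA"], "C6H12O6")
})
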