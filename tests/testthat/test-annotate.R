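test_that("match_mz finds adduct-converted mass matches", {
    fts <- data.frame(mz = 415.3207)
    cmp <- data.frame(name = "5a-cholestan-3-one-ish",
                      exactmass = 414.3134)
    res <- match_mz(fts, cmp, Mass2MzParam("[M+H]+", ppm = 5))
    expect_s3_class(res, "Matched")
    expect_equal(nrow(res$matches), 1L)
    expect_equal(res$matches$adduct, "[M+H]+")
    expect_lt(abs(res$matches$ppm_error), 0.2)
    ## parameters travel with the result
    expect_s3_class(res$params, "Mass2MzParam")
    ## zero-window matching hits only exact grid values
    exact <- data.frame(mz = unname(mass2mz(414.3134, "[M+H]+")))
    expect_equal(nrow(match_mz(exact, cmp,
                               Mass2MzParam("[M+H]+", 0, 0))$matches), 1L)
    expect_equal(nrow(match_mz(fts, cmp,
                               Mass2MzParam("[M+H]+", 0, 0))$matches), 0L)
})

test_that("retention time gates m/z hits with Rt parameter objects", {
    fts <- data.frame(mz = 415.3207, rt = 100)
    cmp <- data.frame(exactmass = 414.3134, rt = 160)
    res <- match_mz(fts, cmp, Mass2MzRtParam("[M+H]+", ppm = 5,
                                             rt_tolerance = 30))
    expect_equal(nrow(res$matches), 0L)
    cmp$rt <- 110
    res <- match_mz(fts, cmp, Mass2MzRtParam("[M+H]+", ppm = 5,
                                             rt_tolerance = 30))
    expect_equal(nrow(res$matches), 1L)
    expect_equal(res$matches$delta_rt, -10)
})

test_that("match_mz reports all in-window matches (one-to-many)", {
    fts <- data.frame(mz = 200.0)
    tgt <- data.frame(mz = c(199.9995, 200.0005))
    res <- match_mz(fts, tgt, MzParam(tolerance = 0.01))
    expect_equal(nrow(res$matches), 2L)
    expect_equal(res$matches$target_idx, c(1L, 2L))
    ## signed delta: query minus target
    expect_equal(res$matches$delta_mz, c(0.0005, -0.0005))
    expect_error(match_mz(data.frame(x = 1), tgt, MzParam()),
                 "available")
    expect_error(match_mz(fts, data.frame(foo = 1), MzParam()), "'mz'")
})

test_that("matched_data flattens with left-join semantics", {
    fts <- data.frame(mz = c(100, 200, 300))
    tgt <- data.frame(mz = c(200.0001, 200.0002), name = c("a", "b"))
    res <- match_mz(fts, tgt, MzParam(tolerance = 0.001))
    flat <- matched_data(res)
    ## query 2 has two matches, queries 1 and 3 none: 4 rows
    expect_equal(nrow(flat), 4L)
    expect_equal(flat$query_idx, c(1L, 2L, 2L, 3L))
    expect_true(all(is.na(flat$name[c(1, 4)])))
    ## colliding column names get the target_ prefix
    expect_true(all(c("mz", "target_mz") %in% names(flat)))
    ## no matches at all: one row per query
    none <- match_mz(fts, tgt, MzParam(0, 0))
    expect_equal(nrow(matched_data(none)), 3L)
})

test_that("filter_matches subsets, thresholds and ranks", {
    fts <- data.frame(mz = c(100, 200))
    tgt <- data.frame(mz = c(200.0001, 200.0004))
    res <- match_mz(fts, tgt, MzParam(tolerance = 0.001))
    expect_equal(nrow(res$matches), 2L)
    top <- filter_matches(res, top_rank = TRUE, rank_by = "ppm_error")
    expect_equal(nrow(top$matches), 1L)
    expect_equal(top$matches$target_idx, 1L)
    ## strict threshold on the score column removes everything at 1.0 cut
    sp <- SpectraCollection(list(Spectrum(c(100, 150), c(1, 2),
                                          precursor_mz = 200)))
    ms <- match_spectra(sp, sp, CompareSpectraParam())
    expect_equal(nrow(filter_matches(ms, score_threshold = 1.0)$matches),
                 0L)
    ## filtering twice equals filtering with the conjunction
    both <- filter_matches(filter_matches(res, query_subset = 2L),
                           top_rank = TRUE, rank_by = "ppm_error")
    conj <- filter_matches(res, query_subset = 2L, top_rank = TRUE,
                           rank_by = "ppm_error")
    expect_equal(both$matches, conj$matches)
    expect_equal(both$log, conj$log)
    ## query_subset re-indexes
    sub <- filter_matches(res, query_subset = 2L)
    expect_equal(sub$matches$query_idx, c(1L, 1L))
    expect_error(filter_matches(res, query_subset = 9L), "out of range")
})

test_that("match_mz pulls masses and retention times from a CompDb", {
    path <- withr::local_tempfile(fileext = ".sqlite")
    cmp <- data.frame(compound_id = c("C1", "C2"),
                      name = c("one", "two"),
                      formula = c("C6H12O6", "C8H10N4O2"),
                      exactmass = unname(calculate_mass(
                          c("C6H12O6", "C8H10N4O2"))))
    db <- create_compdb(cmp, list(source = "t", source_version = "1",
                                  date = "d"), path)
    fts <- data.frame(mz = unname(mass2mz(cmp$exactmass[2], "[M+H]+")))
    res <- match_mz(fts, db, Mass2MzParam("[M+H]+", ppm = 5))
    expect_equal(res$matches$target_idx, 2L)
    flat <- matched_data(res)
    expect_equal(flat$name[1], "two")
})

test_that("match_spectra recovers self matches and gates on precursor", {
    withr::with_seed(41, sp <- SpectraCollection(lapply(1:4, function(i)
        random_spectrum(6, mz_min = 100 + 10 * i, mz_max = 108 + 10 * i,
                        precursor = 150 + 50 * i))))
    res <- match_spectra(sp, sp, CompareSpectraParam())
    expect_s3_class(res, "MatchedSpectra")
    expect_equal(res$matches$query_idx, 1:4)
    expect_equal(res$matches$target_idx, 1:4)
    expect_equal(res$matches$score, rep(1, 4), tolerance = 1e-12)
    ## precursors 50 Da apart: no candidates regardless of peaks
    a <- SpectraCollection(list(Spectrum(c(100, 110), c(1, 1),
                                         precursor_mz = 200)))
    b <- SpectraCollection(list(Spectrum(c(100, 110), c(1, 1),
                                         precursor_mz = 250)))
    expect_equal(nrow(match_spectra(a, b,
                                    CompareSpectraParam())$matches), 0L)
    ## without the gate the identical peak lists match
    expect_equal(nrow(match_spectra(
        a, b, CompareSpectraParam(require_precursor = FALSE))$matches), 1L)
    ## query without precursor is skipped and logged
    c0 <- SpectraCollection(list(Spectrum(c(100, 110), c(1, 1))))
    res0 <- match_spectra(c0, b, CompareSpectraParam())
    expect_equal(nrow(res0$matches), 0L)
    expect_true(any(grepl("without precursor", res0$log)))
})

test_that("forward/reverse matching adds reverse score and presence", {
    s <- Spectrum(c(100, 150, 200), c(10, 20, 30), precursor_mz = 210)
    col <- SpectraCollection(list(s))
    res <- match_spectra(col, col, MatchForwardReverseParam())
    expect_equal(res$matches$score, 1, tolerance = 1e-12)
    expect_equal(res$matches$reverse_score, 1, tolerance = 1e-12)
    expect_equal(res$matches$presence_ratio, 1)
    ## query with extra noise peaks: reverse (target-side) score exceeds
    ## the forward score
    q <- SpectraCollection(list(Spectrum(c(100, 120, 150, 170, 200),
                                         c(10, 5, 20, 5, 30),
                                         precursor_mz = 210)))
    res2 <- match_spectra(q, col,
                          MatchForwardReverseParam(threshold = 0.5))
    expect_equal(nrow(res2$matches), 1L)
    expect_gt(res2$matches$reverse_score, res2$matches$score)
    expect_equal(res2$matches$presence_ratio, 3 / 5)
    ## disjoint spectra produce no match rows
    d <- SpectraCollection(list(Spectrum(c(300, 310), c(1, 1),
                                         precursor_mz = 210)))
    expect_equal(nrow(match_spectra(d, col,
                                    MatchForwardReverseParam())$matches),
                 0L)
})

test_that("stored params re-run on stored inputs reproduce the matches", {
    withr::with_seed(59, {
        ref <- simulate_reference(8, seed = 59, n_peaks = 8)
        qry <- perturb_spectra(ref$spectra, seed = 60, mz_jitter_ppm = 5,
                               intensity_jitter = 0.05, dropout = 0.1)
    })
    res <- match_spectra(qry, ref$spectra, CompareSpectraParam())
    rerun <- match_spectra(res$query, res$target, res$params)
    expect_equal(rerun$matches, res$matches)
    fts <- data.frame(mz = ref$ions$mz)
    res2 <- match_mz(fts, ref$compounds, Mass2MzParam("[M+H]+", ppm = 5))
    rerun2 <- match_mz(res2$query, res2$target, res2$params)
    expect_equal(rerun2$matches, res2$matches)
})

test_that("match_spectra accepts a CompDb target and rejects empty ones", {
    path <- withr::local_tempfile(fileext = ".sqlite")
    cmp <- data.frame(compound_id = "C1", name = "x")
    sp <- SpectraCollection(list(Spectrum(c(100, 150), c(5, 10),
                                          precursor_mz = 180,
                                          meta = list(compound_id = "C1"))))
    db <- create_compdb(cmp, list(source = "t", source_version = "1",
                                  date = "d"), path, spectra = sp)
    res <- match_spectra(sp, db, CompareSpectraParam())
    expect_equal(nrow(res$matches), 1L)
    path2 <- withr::local_tempfile(fileext = ".sqlite")
    db2 <- create_compdb(cmp, list(source = "t", source_version = "1",
                                   date = "d"), path2)
    expect_error(match_spectra(sp, db2, CompareSpectraParam()),
                 "no spectra")
})
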