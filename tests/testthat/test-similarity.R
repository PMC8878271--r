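sim_funs <- list(ndotproduct = ndotproduct, neuclidean = neuclidean,
                 navdist = navdist, nspectraangle = nspectraangle)

test_that("all similarity scores are 1 on identical and bounded in [0,1]", {
    withr::with_seed(5, {
        for (i in 1:20) {
            s <- random_spectrum(sample(2:10, 1))
            j <- join_peaks(s, s)
            for (fn in sim_funs)
                expect_equal(fn(j), 1.0, tolerance = 1e-12)
            t <- random_spectrum(sample(2:10, 1))
            jt <- join_peaks(s, t, tolerance = 0.05)
            for (fn in sim_funs) {
                v <- fn(jt)
                expect_true(v >= 0 && v <= 1)
            }
        }
    })
})

test_that("scores reproduce hand-computed reference values", {
    q <- Spectrum(c(100, 200), c(1, 1))
    t <- Spectrum(c(100, 300), c(1, 1))
    ## one shared of two peaks each: (1*1)^2 / (2*2)
    expect_equal(ndotproduct(join_peaks(q, t), m = 0, n = 1), 0.25)
    ## disjoint spectra: cosine-type scores are zero
    d <- Spectrum(c(150, 400), c(1, 1))
    expect_equal(ndotproduct(join_peaks(q, d), m = 0, n = 1), 0)
    expect_equal(nspectraangle(join_peaks(q, d), m = 0, n = 1), 0)
    ## empty query vs one target peak: both distances give 1/(1+1)
    e <- Spectrum(numeric(), numeric())
    t1 <- Spectrum(100, 1)
    expect_equal(neuclidean(join_peaks(e, t1), m = 0, n = 1), 0.5)
    expect_equal(navdist(join_peaks(e, t1), m = 0, n = 1), 0.5)
    ## wq = (1,1), wt = (1,0): angle pi/4 -> score 0.5
    expect_equal(nspectraangle(join_peaks(q, Spectrum(100, 1)),
                               m = 0, n = 1), 0.5)
})

test_that("target-normalized distances are asymmetric, cosines symmetric", {
    q <- Spectrum(c(100, 200, 300), c(10, 40, 5))
    t <- Spectrum(c(100, 200), c(20, 10))
    jf <- join_peaks(q, t)
    jr <- join_peaks(t, q)
    expect_equal(ndotproduct(jf), ndotproduct(jr), tolerance = 1e-12)
    expect_equal(nspectraangle(jf), nspectraangle(jr), tolerance = 1e-12)
    expect_true(abs(neuclidean(jf) - neuclidean(jr)) > 1e-6)
    expect_true(abs(navdist(jf) - navdist(jr)) > 1e-6)
})

test_that("navdist decreases monotonically under growing perturbation", {
    t <- Spectrum(c(100, 200), c(10, 10))
    scores <- vapply(c(0, 2, 5, 9), function(d)
        navdist(join_peaks(Spectrum(c(100, 200), c(10, 10 - d)), t),
                m = 0, n = 1), numeric(1))
    expect_true(all(diff(scores) < 0))
})

test_that("ndotproduct equals the vector-space cosine-squared oracle", {
    withr::with_seed(9, {
        for (i in 1:25) {
            q <- random_spectrum(sample(2:10, 1))
            t <- random_spectrum(sample(2:10, 1))
            j <- join_peaks(q, t, tolerance = 0.1)
            expect_equal(ndotproduct(j, m = 0, n = 1),
                         oracle_ndotproduct(j, m = 0, n = 1),
                         tolerance = 1e-12)
        }
    })
    ## frozen cross-check against an independent implementation
    ## (matchms CosineGreedy, mz_power 0, intensity_power 1): its cosine
    ## on this pair is 0.6316621429426098; ndotproduct is the square
    q <- Spectrum(c(100, 150, 200, 250), c(10, 40, 20, 30),
                  precursor_mz = 260)
    t <- Spectrum(c(100.0005, 150.001, 220.0, 250.002), c(12, 35, 50, 28),
                  precursor_mz = 260)
    expect_equal(ndotproduct(join_peaks(q, t, tolerance = 0.01), m = 0,
                             n = 1),
                 0.6316621429426098^2, tolerance = 1e-9)
})

test_that("empty joins score zero with a warning", {
    e <- Spectrum(numeric(), numeric())
    j <- join_peaks(e, e)
    for (fn in sim_funs)
        expect_warning(expect_equal(fn(j), 0), "zero total weight")
})

test_that("gnps_score resolves duplicate candidates to a one-to-one set", {
    ## identical spectra with equal precursors: perfect score
    s <- Spectrum(c(100, 150, 200), c(10, 30, 20), precursor_mz = 210)
    expect_equal(gnps_score(join_peaks_gnps(s, s)), 1.0,
                 tolerance = 1e-12)
    ## single shifted pair: its normalized contribution is the score
    q <- Spectrum(c(150), 10, precursor_mz = 214.0157)
    t <- Spectrum(c(135.9843), 20, precursor_mz = 200)
    expect_equal(gnps_score(join_peaks_gnps(q, t, tolerance = 0.01),
                            m = 0, n = 1), 1.0, tolerance = 1e-12)
    ## duplicate direct+shifted candidates for one peak: counted once;
    ## brute-force over all conflict-free subsets of the 2-candidate case
    q2 <- Spectrum(c(100, 110), c(3, 4), precursor_mz = 210)
    t2 <- Spectrum(c(100), 5, precursor_mz = 200)
    j2 <- join_peaks_gnps(q2, t2, tolerance = 0.01)
    ## candidates: direct (100,100) w=3*5, shifted (110,100) w=4*5; only
    ## one can use the target peak, best subset keeps 4*5
    norm <- sqrt(3^2 + 4^2) * sqrt(5^2)
    expect_equal(gnps_score(j2, m = 0, n = 1), 20 / norm,
                 tolerance = 1e-12)
})

test_that("gnps_score with shifts never falls below the direct cosine", {
    withr::with_seed(31, {
        for (i in 1:20) {
            q <- random_spectrum(sample(3:10, 1), precursor = 300)
            t <- random_spectrum(sample(3:10, 1), precursor = 290)
            direct <- sqrt(ndotproduct(join_peaks(q, t, tolerance = 0.05)))
            hybrid <- gnps_score(join_peaks_gnps(q, t, tolerance = 0.05))
            expect_true(hybrid >= direct - 1e-12)
        }
    })
})

test_that("exact and greedy gnps conflict resolution agree on fixtures", {
    withr::with_seed(77, {
        for (i in 1:10) {
            q <- random_spectrum(8, precursor = 300)
            t <- random_spectrum(8, precursor = 295)
            j <- join_peaks_gnps(q, t, tolerance = 0.05)
            cand <- j[!is.na(j$qidx) & !is.na(j$tidx), ]
            w <- (cand$intensity_q^0.5) * (cand$intensity_t^0.5)
            exact <- metanno:::.max_weight_matching(cand$qidx, cand$tidx,
                                                    w, exact_limit = 64L)
            greedy <- metanno:::.max_weight_matching(cand$qidx, cand$tidx,
                                                     w, exact_limit = 0L)
            expect_equal(exact, greedy, tolerance = 1e-9)
        }
    })
})

test_that("compare_spectra returns the full pairwise score matrix", {
    withr::with_seed(13, {
        a <- SpectraCollection(lapply(1:2, function(i) random_spectrum(5)))
        b <- SpectraCollection(lapply(1:3, function(i) random_spectrum(5)))
    })
    m <- compare_spectra(a, b, tolerance = 0.05)
    expect_equal(dim(m), c(2L, 3L))
    ## nested-loop oracle
    for (i in 1:2)
        for (j in 1:3)
            expect_equal(m[i, j],
                         ndotproduct(join_peaks(a[[i]], b[[j]],
                                                tolerance = 0.05)))
    expect_equal(diag(compare_spectra(a, a, tolerance = 0.05)), c(1, 1),
                 tolerance = 1e-12)
    expect_error(compare_spectra(a, b, sim_fun = function(...) "x"),
                 "single numeric")
})
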