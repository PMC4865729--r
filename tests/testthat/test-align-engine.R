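test_that("self-alignment score equals the matrix diagonal sum", {
    m <- substitutionMatrix()
    r <- smithWaterman("PELICAN", "PELICAN", m)
    letters7 <- strsplit("PELICAN", "", fixed = TRUE)[[1L]]
    expect_identical(r$score, sum(m[cbind(letters7, letters7)]))
    expect_identical(r$score, bruteLocalScore("PELICAN", "PELICAN", m))
    expect_identical(r$pairs[, "query"], 1:7)
    expect_identical(r$pairs[, "subject"], 1:7)
})

test_that("alignment floors at zero when no residue pair scores positively", {
    m <- substitutionMatrix()
    r <- smithWaterman("AAAA", "CCCC", m)
    expect_identical(r$score, 0L)
    expect_identical(nrow(r$pairs), 0L)
    expect_identical(r$qstart, 0L)
    expect_error(smithWaterman("", "ACD", m), "non-empty")
})

test_that("pad characters never raise the score", {
    m <- substitutionMatrix()
    r <- smithWaterman("MKSAPK", "XXMKS", m)
    expect_identical(r$score, smithWaterman("MKSAPK", "MKS", m)$score)
    expect_identical(r$score, bruteLocalScore("MKSAPK", "XXMKS", m))
    # fully padded flanks are trimmed out of the local alignment
    r2 <- smithWaterman("XXXMKSXXX", "XXXMKSXXX", m)
    expect_identical(r2$score, smithWaterman("MKS", "MKS", m)$score)
})

test_that("engine matches the brute-force oracle on random short pairs", {
    m <- substitutionMatrix()
    toy <- toyMatrix()
    set.seed(23)
    for (rep in 1:40) {
        a <- randomPeptide(sample(2:8, 1L))
        b <- randomPeptide(sample(2:8, 1L))
        go <- sample(c(5L, 11L), 1L)
        ge <- sample(1:2, 1L)
        expect_identical(smithWaterman(a, b, m, go, ge)$score,
                         bruteLocalScore(a, b, m, go, ge),
                         info = paste(a, b, go, ge))
        # small-alphabet strings exercise gaps and ties much harder
        a2 <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1L),
                           replace = TRUE), collapse = "")
        b2 <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1L),
                           replace = TRUE), collapse = "")
        expect_identical(smithWaterman(a2, b2, toy, 2L, 1L)$score,
                         bruteLocalScore(a2, b2, toy, 2, 1),
                         info = paste(a2, b2))
    }
})

test_that("alignment score is symmetric in its arguments", {
    m <- substitutionMatrix()
    set.seed(5)
    for (rep in 1:20) {
        a <- randomPeptide(sample(3:30, 1L))
        b <- randomPeptide(sample(3:30, 1L))
        expect_identical(smithWaterman(a, b, m)$score,
                         smithWaterman(b, a, m)$score)
    }
})

test_that("pair maps are strictly increasing and consistent with ranges", {
    m <- substitutionMatrix()
    set.seed(9)
    for (rep in 1:20) {
        r <- smithWaterman(randomPeptide(40), randomPeptide(40), m)
        if (nrow(r$pairs) == 0L) next
        expect_true(all(diff(r$pairs[, "query"]) > 0))
        expect_true(all(diff(r$pairs[, "subject"]) > 0))
        expect_identical(r$qstart, r$pairs[1L, "query"][[1L]])
        expect_identical(r$qend, r$pairs[nrow(r$pairs), "query"][[1L]])
        expect_identical(r$sstart, r$pairs[1L, "subject"][[1L]])
        expect_identical(r$send, r$pairs[nrow(r$pairs), "subject"][[1L]])
    }
})

test_that("karlin lambda solves its defining identity", {
    # +1/-1 over a uniform 4-letter alphabet: exp(lambda) solves
    # x/4 + 3/(4x) = 1, i.e. lambda = log 3 exactly
    toy <- toyMatrix()
    freqs <- stats::setNames(rep(0.25, 4), c("A", "C", "G", "T"))
    lam <- karlinLambda(toy, freqs)
    expect_equal(lam, log(3), tolerance = 1e-9)
    pp <- outer(freqs, freqs)
    s <- toy[names(freqs), names(freqs)]
    expect_equal(sum(pp * exp(lam * s)), 1, tolerance = 1e-9)

    m <- substitutionMatrix("BLOSUM62")
    fr <- robinsonFrequencies()
    lam62 <- karlinLambda(m, fr)
    ppr <- outer(fr, fr)
    s62 <- m[names(fr), names(fr)]
    expect_equal(sum(ppr * exp(lam62 * s62)), 1, tolerance = 1e-9)
    # the ungapped value reported for this matrix/composition in the
    # alignment-statistics literature
    expect_equal(lam62, 0.3176, tolerance = 2e-3)
})

test_that("karlin lambda is undefined without negative expectation", {
    allpos <- toyMatrix(mismatch = 2L)
    freqs <- stats::setNames(rep(0.25, 4), c("A", "C", "G", "T"))
    expect_error(karlinLambda(allpos, freqs), "negative")
    allneg <- toyMatrix(match = -1L)
    expect_error(karlinLambda(allneg, freqs), "positive score")
})

test_that("karlin K reproduces the published ungapped BLOSUM62 value", {
    m <- substitutionMatrix("BLOSUM62")
    fr <- robinsonFrequencies()
    K <- karlinK(m, fr)
    expect_equal(K, 0.134, tolerance = 0.01)
    # series is converged: a shorter truncation already agrees closely
    expect_equal(K, karlinK(m, fr, iterations = 250L), tolerance = 1e-6)
})

test_that("E-values follow the closed form", {
    expect_equal(evalueFromScore(0, 10, 100, 0.3, 0.1), 0.1 * 10 * 100)
    expect_equal(evalueFromScore(30, 10, 200, 0.3, 0.1),
                 2 * evalueFromScore(30, 10, 100, 0.3, 0.1))
    expect_equal(evalueFromScore(35, 10, 100, 0.3, 0.1) /
                 evalueFromScore(30, 10, 100, 0.3, 0.1),
                 exp(-0.3 * 5))
})

test_that("database search honours the reporting contract", {
    set.seed(31)
    target <- randomPeptide(60)
    db <- Biostrings::AAStringSet(c(
        T1 = target, U1 = randomPeptide(60), U2 = randomPeptide(60)))
    hits <- searchHits(c(Q = target), db, SearchParams())
    expect_identical(hits$subject_id[1L], "T1")  # self-hit dominates
    # E-value cutoff below every hit gives a valid empty result
    none <- searchHits(c(Q = target), db,
                       SearchParams(evalueCutoff = 1e-300))
    expect_identical(nrow(none), 0L)
    # ties break lexicographically and truncate at maxTargetSeqs
    db5 <- Biostrings::AAStringSet(stats::setNames(
        rep(target, 5), c("S4", "S2", "S5", "S1", "S3")))
    top3 <- searchHits(c(Q = target), db5,
                       SearchParams(maxTargetSeqs = 3L))
    expect_identical(top3$subject_id, c("S1", "S2", "S3"))
    expect_error(searchHits(c(Q = target), Biostrings::AAStringSet(),
                            SearchParams()), "non-empty")
})

test_that("adding an unrelated decoy preserves scores and inflates E-values", {
    set.seed(37)
    query <- randomPeptide(50)
    db <- Biostrings::AAStringSet(c(A = randomPeptide(50), B = query))
    hits <- searchHits(c(Q = query), db, SearchParams())
    db2 <- c(db, Biostrings::AAStringSet(c(Z = randomPeptide(80))))
    hits2 <- searchHits(c(Q = query), db2, SearchParams())
    common <- intersect(hits$subject_id, hits2$subject_id)
    for (s in common) {
        expect_identical(hits2$raw_score[hits2$subject_id == s],
                         hits$raw_score[hits$subject_id == s])
        expect_gt(hits2$evalue[hits2$subject_id == s],
                  hits$evalue[hits$subject_id == s])
    }
})

test_that("search is deterministic", {
    set.seed(41)
    query <- randomPeptide(40)
    db <- Biostrings::AAStringSet(stats::setNames(
        vapply(1:6, function(i) randomPeptide(40), ""),
        paste0("D", 1:6)))
    h1 <- searchHits(c(Q = query), db, SearchParams())
    h2 <- searchHits(c(Q = query), db, SearchParams())
    expect_identical(h1, h2)
})

test_that("bestHit returns the first sorted hit or NULL", {
    expect_null(bestHit(NULL))
    expect_null(bestHit(data.frame()))
    hits <- data.frame(subject_id = c("B", "A"),
                       evalue = c(1e-30, 1e-5))
    expect_identical(bestHit(hits)$subject_id, "B")
})
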