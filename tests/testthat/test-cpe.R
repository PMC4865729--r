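test_that("stage-1 finds the identical known peptide with its site", {
    prot <- tinyProteome()
    kp <- buildKnownPeptides(prot, tinyAnnotations(), w = 7)
    win <- extractWindow(as.character(prot)[["P1"]], 11, 7)
    hit <- blast1FindHit(c(q = win), kp, SearchParams())
    expect_identical(hit$hit_protein_id, "P1")
    expect_identical(hit$hit_site_position, 11L)
    expect_true(hit$center_aligned)
    expect_lt(hit$peptide_evalue, 1)
})

test_that("strict-center mode rejects flank-shifted matches", {
    known <- Biostrings::AAStringSet(c(K1 = "LLLLLLLSKKKKKKK"))
    ann <- data.frame(protein_id = "K1", position = 8L, residue = "S",
                      ptm_type = "phosphorylation")
    kp <- buildKnownPeptides(known, ann, w = 7)
    # candidate window whose center falls one residue past the known
    # center: the optimal alignment is the off-by-one diagonal
    cand <- c(q = "LLLLLLSKKKKKKKK")
    expect_null(blast1FindHit(cand, kp, SearchParams(),
                              strictCenter = TRUE))
    hit <- blast1FindHit(cand, kp, SearchParams(), strictCenter = FALSE)
    expect_false(hit$center_aligned)
    expect_identical(hit$hit_protein_id, "K1")
})

test_that("stage-1 applies the E-value cutoff to the winning hit", {
    prot <- tinyProteome()
    kp <- buildKnownPeptides(prot, tinyAnnotations(), w = 7)
    win <- extractWindow(as.character(prot)[["P1"]], 11, 7)
    expect_null(blast1FindHit(c(q = win), kp,
                              SearchParams(evalueCutoff = 1e-300)))
})

test_that("reciprocal searches report best and pairwise E-values", {
    set.seed(51)
    h <- randomPeptide(80)
    qdb <- Biostrings::AAStringSet(c(Q = h, D1 = randomPeptide(80)))
    ev <- blast2Reciprocal("H", h, "Q", qdb)
    expect_identical(ev$best_subject, "Q")
    expect_identical(ev$E_best, ev$E_pair)

    # a near-identical paralog outcompetes the diverged query protein
    qchars <- strsplit(h, "")[[1L]]
    qchars[seq(1, 80, by = 4)] <- "G"
    qdb2 <- Biostrings::AAStringSet(
        c(Q = paste(qchars, collapse = ""), PAR = h))
    ev2 <- blast2Reciprocal("H", h, "Q", qdb2)
    expect_identical(ev2$best_subject, "PAR")
    expect_lt(ev2$E_best, ev2$E_pair)

    # no alignment at all between hit protein and query protein
    qdb3 <- Biostrings::AAStringSet(
        c(Q = strrep("P", 40), N1 = strrep("W", 40)))
    ev3 <- blast2Reciprocal("H", strrep("W", 40), "Q", qdb3)
    expect_identical(ev3$E_pair, Inf)

    expect_error(blast2Reciprocal("H", h, "MISSING", qdb),
                 "not contained in the query proteome")
})

test_that("stage-3 mirrors stage-2 with roles swapped", {
    set.seed(53)
    q <- randomPeptide(70)
    kdb <- Biostrings::AAStringSet(c(H = q, D1 = randomPeptide(70)))
    ev <- blast3Reciprocal("Q", q, "H", kdb)
    expect_identical(ev$best_subject, "H")
    expect_identical(ev$E_best, ev$E_pair)
    expect_error(blast3Reciprocal("Q", q, "MISSING", kdb),
                 "not contained in the known proteome")
})

test_that("the CPE verdict requires both reciprocal conditions", {
    expect_true(cpeVerdict(1e-30, 1e-30, 1e-28, 1e-28))
    expect_false(cpeVerdict(1e-30, 1e-5, 1e-28, 1e-28))
    expect_false(cpeVerdict(1e-30, 1e-30, 1e-28, 1e-5))
    expect_false(cpeVerdict(1e-30, Inf, 1e-28, 1e-28))
    expect_false(cpeVerdict(Inf, Inf, Inf, Inf))
    # exact ties count as best
    expect_true(cpeVerdict(1e-10, 1e-10 * (1 + 1e-12), 1e-9, 1e-9))
})

test_that("the plain E-value verdict is a simple threshold", {
    expect_true(evalueVerdict(1e-8, 1e-3))
    expect_false(evalueVerdict(0.5, 1e-3))
    expect_false(evalueVerdict(Inf, 1e-3))
    expect_error(evalueVerdict(1e-8, -1))
})

test_that("identical local context with non-homologous parents is caught", {
    # the trap the reciprocity benchmark exists for: the candidate's
    # peptide matches an annotated window exactly, but the query protein's
    # closest known protein is an unannotated paralog, so the E-value
    # benchmark says yes while the CPE benchmark says no
    sc <- syntheticScenario("paralog_trap", seed = 7)
    model <- buildModel(sc$known, sc$annotations, sc$query, w = sc$w)
    pred <- as.data.frame(predictSites(model, emitAll = TRUE))
    trapped <- pred[pred$evalue_verdict & !pred$cpe_verdict &
                    pred$query_protein_id %in%
                        sub("^A", "Q", sc$trapIds), ]
    expect_gt(nrow(trapped), 0L)
    # the failing direction is the query protein preferring its paralog
    expect_true(all(trapped$E_q_best < trapped$E_q_h |
                    startsWith(trapped$best_subject_q, "PAR")))
    # and every CPE-positive row is also E-value-positive
    expect_true(all(!pred$cpe_verdict | pred$evalue_verdict))
})

test_that("swapping the roles of two identical proteomes keeps verdicts", {
    set.seed(59)
    prots <- Biostrings::AAStringSet(stats::setNames(
        vapply(1:4, function(i) randomPeptide(60), ""), paste0("P", 1:4)))
    ev2 <- blast2Reciprocal("P1", as.character(prots)[["P1"]], "P1", prots)
    ev3 <- blast3Reciprocal("P1", as.character(prots)[["P1"]], "P1", prots)
    expect_identical(ev2, ev3[names(ev2)])
    expect_true(cpeVerdict(ev2$E_best, ev2$E_pair, ev3$E_best, ev3$E_pair))
})
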