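test_that("the generator is fully reproducible from its seed", {
    cfg <- synthConfig(seed = 9, nProteins = 6L,
                       lengthRange = c(60L, 90L))
    a <- makeKnownProteome(cfg)
    b <- makeKnownProteome(cfg)
    expect_identical(as.character(a$proteome), as.character(b$proteome))
    expect_identical(as.data.frame(a$annotations),
                     as.data.frame(b$annotations))
    expect_error(makeKnownProteome(synthConfig(seed = 1, nProteins = 0L)),
                 "nProteins")
    expect_error(synthConfig(seed = 1, residueSet = character(0)),
                 "residueSet")
})

test_that("planted sites satisfy the annotation invariants", {
    cfg <- synthConfig(seed = 21, nProteins = 10L,
                       lengthRange = c(50L, 200L),
                       sitesPerProtein = c(1L, 5L))
    kn <- makeKnownProteome(cfg)
    ann <- as.data.frame(kn$annotations)
    seqs <- as.character(kn$proteome)
    expect_true(all(ann$residue %in% cfg@residueSet))
    expect_true(all(vapply(seq_len(nrow(ann)), function(i)
        substr(seqs[[ann$protein_id[i]]], ann$position[i],
               ann$position[i]) == ann$residue[i], NA)))
    # validation accepts the generated annotations wholesale
    validated <- validateAnnotations(ann, kn$proteome)
    expect_equal(nrow(validated), nrow(ann))
})

test_that("zero divergence reproduces the known proteome verbatim", {
    cfg <- synthConfig(seed = 25, nProteins = 5L,
                       lengthRange = c(60L, 80L), divergence = 0)
    kn <- makeKnownProteome(cfg)
    qu <- deriveQueryProteome(kn$proteome, kn$annotations, cfg)
    expect_identical(as.character(qu$proteome),
                     as.character(kn$proteome))
})

test_that("the realised mutation rate tracks the divergence setting", {
    div <- 0.05
    cfg <- synthConfig(seed = 29, nProteins = 10L,
                       lengthRange = c(200L, 300L), divergence = div)
    kn <- makeKnownProteome(cfg)
    qu <- deriveQueryProteome(kn$proteome, kn$annotations, cfg)
    kc <- strsplit(paste(as.character(kn$proteome), collapse = ""), "")[[1]]
    qc <- strsplit(paste(as.character(qu$proteome), collapse = ""), "")[[1]]
    nMut <- sum(kc != qc)
    n <- length(kc)
    # within 4 binomial standard deviations of the expectation
    expect_lt(abs(nMut - n * div), 4 * sqrt(n * div * (1 - div)))
    # planted site residues are never mutated
    ann <- as.data.frame(kn$annotations)
    qs <- as.character(qu$proteome)
    expect_true(all(vapply(seq_len(nrow(ann)), function(i)
        substr(qs[[ann$protein_id[i]]], ann$position[i],
               ann$position[i]) == ann$residue[i], NA)))
})

test_that("mutation sets are nested across divergence levels", {
    cfgs <- lapply(c(0.05, 0.1, 0.2), function(d)
        synthConfig(seed = 33, nProteins = 5L,
                    lengthRange = c(150L, 200L), divergence = d))
    kn <- makeKnownProteome(cfgs[[1L]])
    qus <- lapply(cfgs, function(cfg)
        deriveQueryProteome(kn$proteome, kn$annotations, cfg))
    kc <- strsplit(as.character(kn$proteome), "")
    for (lvl in 1:2) {
        lo <- strsplit(as.character(qus[[lvl]]$proteome), "")
        hi <- strsplit(as.character(qus[[lvl + 1L]]$proteome), "")
        for (p in seq_along(kc)) {
            mutLo <- which(lo[[p]] != kc[[p]])
            mutHi <- which(hi[[p]] != kc[[p]])
            expect_true(all(mutLo %in% mutHi))
            # the substituted letter is the same at every shared position
            expect_identical(lo[[p]][mutLo], hi[[p]][mutLo])
        }
    }
})

test_that("decoys are appended without ground-truth sites", {
    cfg <- synthConfig(seed = 35, nProteins = 4L,
                       lengthRange = c(60L, 80L), nDecoys = 3L)
    kn <- makeKnownProteome(cfg)
    qu <- deriveQueryProteome(kn$proteome, kn$annotations, cfg)
    expect_equal(length(qu$proteome), 4L + 3L)
    expect_false(any(qu$truth$protein_id %in%
                     grep("^DEC", names(qu$proteome), value = TRUE)))
})

test_that("scenario fixture bundles are byte-stable on disk", {
    d1 <- file.path(tempdir(), "scn1")
    d2 <- file.path(tempdir(), "scn2")
    syntheticScenario("holdout", seed = 37, dir = d1)
    syntheticScenario("holdout", seed = 37, dir = d2)
    for (f in c("known.fasta", "annotations.tsv", "query.fasta",
                "truth.tsv")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
    }
    expect_error(syntheticScenario("nope", seed = 1))
})
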