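test_that("FASTA parsing normalises sequences and keeps file order", {
    f <- writeTempFasta(c(">P1 first protein", "mksapk*",
                          ">P2", "ACDEF", ">P3", "MKBUZJO"))
    prot <- readProteome(f)
    expect_identical(names(prot), c("P1", "P2", "P3"))
    expect_identical(as.character(prot[["P1"]]), "MKSAPK")
    expect_identical(as.character(prot[["P2"]]), "ACDEF")
    # rare/ambiguity letters map to X
    expect_identical(as.character(prot[["P3"]]), "MKXXXXX")
    expect_identical(S4Vectors::mcols(prot)$description[1L],
                     "first protein")
})

test_that("FASTA parsing rejects duplicate ids and empty files", {
    dup <- writeTempFasta(c(">P1", "MKSA", ">P1", "ACDE"))
    expect_error(readProteome(dup), "duplicate.*P1")
    empty <- writeTempFasta(character(0))
    expect_error(readProteome(empty), "no sequences")
    expect_error(readProteome(tempfile()), "no such file")
})

test_that("FASTA round trip is the identity and wraps at 60 columns", {
    prot <- Biostrings::AAStringSet(c(
        A1 = paste(rep("ACDEFGHIKL", 13), collapse = ""),  # 130 residues
        B2 = "MKSAPK"))
    f <- tempfile(fileext = ".fasta")
    writeProteome(prot, f)
    lines <- readLines(f)
    seqA <- lines[(which(lines == ">A1") + 1L):(which(lines == ">B2") - 1L)]
    expect_identical(nchar(seqA), c(60L, 60L, 10L))
    back <- readProteome(f)
    expect_identical(as.character(back), as.character(prot))
    expect_error(writeProteome(Biostrings::AAStringSet(), f), "empty")
})

test_that("FASTA round trip holds for generated record sets", {
    set.seed(7)
    for (rep in 1:5) {
        n <- sample(1:6, 1L)
        prot <- Biostrings::AAStringSet(stats::setNames(
            vapply(seq_len(n), function(i)
                randomPeptide(sample(1:200, 1L)), ""),
            paste0("PR", seq_len(n))))
        f <- tempfile(fileext = ".fasta")
        writeProteome(prot, f)
        expect_identical(as.character(readProteome(f)),
                         as.character(prot))
    }
})

test_that("annotation validation accepts matching rows and rejects the rest", {
    prot <- tinyProteome()
    tab <- rbind(tinyAnnotations(),
                 data.frame(protein_id = c("P1", "P9", "P2"),
                            position = c(3L, 3L, 99L),
                            residue = c("T", "S", "S"),
                            ptm_type = "phosphorylation"))
    f <- writeTempTsv(tab)
    ann <- readSiteAnnotations(f, prot)
    expect_equal(nrow(ann), 3L)
    # every accepted row satisfies residue == sequence[position]
    seqs <- as.character(prot)
    expect_true(all(vapply(seq_len(nrow(ann)), function(i)
        substr(seqs[[ann$protein_id[i]]], ann$position[i],
               ann$position[i]) == ann$residue[i], NA)))
    rej <- validationReport(ann)
    expect_equal(nrow(rej), 3L)
    expect_true(any(grepl("residue mismatch", rej$reason)))
    expect_true(any(grepl("unknown protein", rej$reason)))
    expect_true(any(grepl("out of range", rej$reason)))
})

test_that("annotation validation errors when nothing survives", {
    prot <- tinyProteome()
    bad <- data.frame(protein_id = "P9", position = 1L, residue = "S",
                      ptm_type = "phosphorylation")
    expect_error(validateAnnotations(bad, prot), "no annotation rows")
})

test_that("the compact per-protein annotation dialect is accepted", {
    prot <- tinyProteome()
    f <- tempfile(fileext = ".tsv")
    writeLines(c("P1\t3:S:phosphorylation,11:T:phosphorylation",
                 "P3\t6:S:phosphorylation"), f)
    ann <- readSiteAnnotations(f, prot)
    expect_equal(nrow(ann), 3L)
    expect_identical(sort(unique(ann$protein_id)), c("P1", "P3"))
    expect_setequal(ann$position[ann$protein_id == "P1"], c(3L, 11L))
})

test_that("residues outside the PTM candidate set are rejected", {
    prot <- Biostrings::AAStringSet(c(P1 = "MKAAPK"))
    tab <- data.frame(protein_id = c("P1", "P1"),
                      position = c(3L, 2L), residue = c("A", "K"),
                      ptm_type = c("phosphorylation", "acetylation"))
    ann <- validateAnnotations(tab, prot)
    expect_equal(nrow(ann), 1L)   # the alanine cannot be phosphorylated
    expect_identical(ann$residue, "K")
    expect_match(validationReport(ann)$reason, "candidate set")
})
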