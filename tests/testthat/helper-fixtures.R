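# Small in-code fixtures shared across test files.

tinyProteome <- function() {
    Biostrings::AAStringSet(c(
        P1 = "MKSAPKLLRSTYEEAH",
        P2 = "ACDEFGHIKLMNPQRS",
        P3 = "WYVATSSKNDEQGILM"))
}

tinyAnnotations <- function() {
    data.frame(
        protein_id = c("P1", "P1", "P3"),
        position = c(3L, 11L, 6L),
        residue = c("S", "T", "S"),
        ptm_type = "phosphorylation",
        stringsAsFactors = FALSE)
}

writeTempFasta <- function(lines) {
    f <- tempfile(fileext = ".fasta")
    writeLines(lines, f)
    f
}

writeTempTsv <- function(df) {
    f <- tempfile(fileext = ".tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}
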