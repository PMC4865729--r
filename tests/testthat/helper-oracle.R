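# Independent brute-force oracle for optimal local alignment under affine
# gaps: enumerate every pair of equal-length subsequences of the two
# strings; the alignment score is the sum of substitution scores of the
# matched columns minus gapOpen + L*gapExtend for every internal run of L
# skipped residues. Alignments with interleaved gap runs between the same
# matched columns cost at least one extra gap opening and can never beat
# this enumeration, so its maximum (floored at 0) is the Smith-Waterman
# optimum. Exponential, usable only for strings of length <= ~9.
bruteLocalScore <- function(a, b, mat, gapOpen = 11, gapExtend = 1) {
    A <- strsplit(a, "", fixed = TRUE)[[1L]]
    B <- strsplit(b, "", fixed = TRUE)[[1L]]
    na <- length(A)
    nb <- length(B)
    gapcost <- function(L) sum(ifelse(L > 0, gapOpen + L * gapExtend, 0))
    best <- 0
    for (k in seq_len(min(na, nb))) {
        ia <- utils::combn(na, k)
        ib <- utils::combn(nb, k)
        gpB <- apply(ib, 2L, function(j) gapcost(diff(j) - 1L))
        Bletters <- matrix(B[ib], nrow = k)
        for (p in seq_len(ncol(ia))) {
            i <- ia[, p]
            gpA <- gapcost(diff(i) - 1L)
            M <- mat[A[i], , drop = FALSE]
            matchScores <- colSums(matrix(
                M[cbind(rep(seq_len(k), ncol(ib)),
                        match(as.vector(Bletters), colnames(mat)))],
                nrow = k))
            cand <- max(matchScores - gpB) - gpA
            if (cand > best) best <- cand
        }
    }
    as.integer(round(best))
}

# Random amino-acid string over the 20 standard residues.
randomPeptide <- function(len) {
    paste(sample(aminoAcids(), len, replace = TRUE), collapse = "")
}

# Toy +1/-1 substitution matrix over a small uniform alphabet (plus a
# neutral-negative X so the engine accepts padded windows).
toyMatrix <- function(alphabet = c("A", "C", "G", "T"),
                      match = 1L, mismatch = -1L) {
    n <- length(alphabet)
    m <- matrix(mismatch, n + 1L, n + 1L,
                dimnames = list(c(alphabet, "X"), c(alphabet, "X")))
    diag(m)[seq_len(n)] <- match
    m["X", ] <- -1L
    m[, "X"] <- -1L
    storage.mode(m) <- "integer"
    m
}
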