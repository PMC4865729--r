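#' Amino-acid alphabets and background frequencies
#'
#' `aminoAcids()` returns the 20 standard residues; `robinsonFrequencies()`
#' the Robinson-Robinson background composition conventionally used for
#' protein-search statistics; `uniformFrequencies()` a flat composition.
#'
#' @return A character vector of residues, or a named numeric vector of
#'   frequencies summing to 1.
#' @examples
#' sum(robinsonFrequencies())
#' @export
aminoAcids <- function() {
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aminoAcids
#' @export
robinsonFrequencies <- function() {
    f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
           Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
           L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
           S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
    f / sum(f)
}

#' @rdname aminoAcids
#' @export
uniformFrequencies <- function() {
    aa <- aminoAcids()
    stats::setNames(rep(1 / length(aa), length(aa)), aa)
}

#' Candidate residues of the built-in PTM types
#'
#' Maps a PTM type label to the residues that can chemically carry it:
#' phosphorylation on Ser/Thr/Tyr, acetylation, ubiquitination and
#' sumoylation on Lys, methylation on Lys/Arg. Unknown (user-defined) labels
#' raise an error unless a residue set is supplied explicitly wherever one is
#' needed.
#'
#' @param ptmType character PTM type label.
#' @return Character vector of single-letter residues.
#' @examples
#' ptmResidues("phosphorylation")
#' @export
ptmResidues <- function(ptmType) {
    sets <- list(phosphorylation = c("S", "T", "Y"),
                 acetylation = "K",
                 ubiquitination = "K",
                 methylation = c("K", "R"),
                 sumoylation = "K")
    if (!ptmType %in% names(sets))
        stop("no built-in residue set for PTM type '", ptmType,
             "'; supply residueSet explicitly", call. = FALSE)
    sets[[ptmType]]
}

#' Retrieve a protein substitution matrix
#'
#' Fetches a scoring matrix shipped with \pkg{Biostrings} (BLOSUM45/50/62/
#' 80/100, PAM30/40/70/120/250) restricted to the 20 standard residues plus
#' 'X'. The 'X' row/column is verified to be non-positive so that window pad
#' characters can never raise an alignment score.
#'
#' @param name matrix name, e.g. \code{"BLOSUM62"}.
#' @return Integer matrix with dimnames over the 21-letter alphabet.
#' @examples
#' substitutionMatrix()["S", "T"]
#' @export
substitutionMatrix <- function(name = "BLOSUM62") {
    env <- new.env()
    ok <- tryCatch({
        utils::data(list = name, package = "Biostrings", envir = env)
        TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = env))
        stop("unknown substitution matrix: ", name, call. = FALSE)
    m <- get(name, envir = env)
    keep <- c(aminoAcids(), "X")
    if (!all(keep %in% rownames(m)))
        stop("matrix ", name, " lacks required residue letters",
             call. = FALSE)
    m <- m[keep, keep, drop = FALSE]
    storage.mode(m) <- "integer"
    if (!isSymmetric(unname(m)))
        stop("substitution matrix must be symmetric", call. = FALSE)
    if (any(m["X", ] > 0L))
        stop("'X' scores must be non-positive", call. = FALSE)
    m
}

#' Karlin-Altschul ungapped statistical parameter lambda
#'
#' Finds the unique positive root lambda of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}, the scale parameter of the
#' extreme-value distribution of ungapped local-alignment scores, by
#' bracketed root finding to a relative tolerance of 1e-9.
#'
#' @param matrix substitution matrix (see [substitutionMatrix()]).
#' @param freqs named background frequencies over the residues to use; only
#'   letters present in \code{names(freqs)} enter the computation.
#' @return Positive numeric lambda.
#' @examples
#' karlinLambda(substitutionMatrix("BLOSUM62"), robinsonFrequencies())
#' @export
karlinLambda <- function(matrix, freqs = robinsonFrequencies()) {
    aa <- names(freqs)
    if (!all(aa %in% rownames(matrix)))
        stop("frequencies name letters missing from the matrix",
             call. = FALSE)
    s <- matrix[aa, aa, drop = FALSE]
    pp <- outer(freqs, freqs)
    if (sum(pp * s) >= 0)
        stop("expected score must be negative for lambda to exist",
             call. = FALSE)
    if (max(s) <= 0)
        stop("at least one positive score is required", call. = FALSE)
    f <- function(l) sum(pp * exp(l * s)) - 1
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

# Discrete distribution of the per-position score under the background
# model: probabilities indexed by score value smin..smax.
.score_distribution <- function(matrix, freqs) {
    aa <- names(freqs)
    s <- matrix[aa, aa, drop = FALSE]
    pp <- outer(freqs, freqs)
    smin <- min(s); smax <- max(s)
    prob <- numeric(smax - smin + 1L)
    for (v in unique(as.vector(s)))
        prob[v - smin + 1L] <- sum(pp[s == v])
    list(prob = prob, smin = smin, smax = smax)
}

#' Karlin-Altschul ungapped parameter K
#'
#' Computes the pre-factor K of the E-value formula
#' \eqn{E = K m n e^{-\lambda S}} with the standard convergent series over
#' k-fold convolutions of the single-position score distribution,
#' \deqn{K = \frac{d\,\lambda\,e^{-2\sigma}}{H\,(1 - e^{-\lambda d})},
#'   \qquad \sigma = \sum_{k \ge 1} \frac{1}{k}\Big[
#'   \mathrm{E}\big(e^{\lambda S_k};\, S_k < 0\big) + P(S_k \ge 0)\Big],}
#' where d is the score lattice span and H the relative entropy. The series
#' is summed until its terms drop below 1e-12 (or \code{iterations} terms,
#' whichever comes first), well beyond the 1e-6 accuracy the E-value scale
#' needs.
#'
#' @inheritParams karlinLambda
#' @param lambda the value from [karlinLambda()]; computed when missing.
#' @param iterations maximum number of convolution terms.
#' @return Positive numeric K.
#' @examples
#' karlinK(substitutionMatrix("BLOSUM62"), robinsonFrequencies())
#' @export
karlinK <- function(matrix, freqs = robinsonFrequencies(),
                    lambda = karlinLambda(matrix, freqs),
                    iterations = 400L) {
    sd <- .score_distribution(matrix, freqs)
    sc <- sd$smin:sd$smax
    present <- sc[sd$prob > 0]
    d <- Reduce(function(a, b) {
        a <- abs(a); b <- abs(b)
        while (b) { t <- a %% b; a <- b; b <- t }
        a
    }, present)
    H <- lambda * sum(sc * sd$prob * exp(lambda * sc))
    cur <- sd$prob; off <- sd$smin
    sigma <- 0
    for (k in seq_len(iterations)) {
        sck <- off + seq_along(cur) - 1L
        neg <- sck < 0
        term <- (sum(cur[neg] * exp(lambda * sck[neg])) +
                 sum(cur[!neg])) / k
        sigma <- sigma + term
        if (term < 1e-12) break
        # convolve with the single-step distribution
        nxt <- numeric(length(cur) + length(sd$prob) - 1L)
        for (i in seq_along(cur))
            nxt[i:(i + length(sd$prob) - 1L)] <-
                nxt[i:(i + length(sd$prob) - 1L)] + cur[i] * sd$prob
        cur <- nxt; off <- off + sd$smin
    }
    d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
}

#' E-value and bit score of a raw local-alignment score
#'
#' `evalueFromScore()` applies the Karlin-Altschul formula
#' \eqn{E = K m n e^{-\lambda S}} for a query of length m against a database
#' of total residue length n; `bitScoreFromScore()` converts a raw score to
#' bits, \eqn{S' = (\lambda S - \ln K)/\ln 2}.
#'
#' @param score raw alignment score(s).
#' @param m query length (residues).
#' @param n summed residue length of the database.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Numeric vector of E-values (resp. bit scores).
#' @examples
#' evalueFromScore(50, 15, 1000, 0.3176, 0.134)
#' @export
evalueFromScore <- function(score, m, n, lambda, K) {
    stopifnot(m >= 1, n >= 1, lambda > 0, K > 0)
    K * m * n * exp(-lambda * score)
}

#' @rdname evalueFromScore
#' @export
bitScoreFromScore <- function(score, lambda, K) {
    (lambda * score - log(K)) / log(2)
}

# Cached per-matrix/per-frequency-model Karlin-Altschul parameters.
.ka_cache <- new.env(parent = emptyenv())

.ka_params <- function(params) {
    key <- paste(params@matrixName, params@frequencies, sep = "/")
    if (is.null(.ka_cache[[key]])) {
        m <- substitutionMatrix(params@matrixName)
        fr <- switch(params@frequencies,
                     robinson = robinsonFrequencies(),
                     uniform = uniformFrequencies())
        lambda <- karlinLambda(m, fr)
        .ka_cache[[key]] <- list(matrix = m, freqs = fr, lambda = lambda,
                                 K = karlinK(m, fr, lambda))
    }
    .ka_cache[[key]]
}
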