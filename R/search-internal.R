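#' Pairwise Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap costs (a gap of length L costs
#' \code{gapOpen + L * gapExtend}) with a deterministic traceback that
#' prefers, at equal score, the diagonal move, then a gap in the subject,
#' then a gap in the query. Scores are floored at zero; when no residue pair
#' scores positively the alignment is empty with score 0.
#'
#' @param a,b sequences (character scalars or \code{AAString}).
#' @param matrix substitution matrix (see [substitutionMatrix()]).
#' @param gapOpen,gapExtend affine gap penalties.
#' @return A list: \code{score} (integer raw score), \code{qstart},
#'   \code{qend}, \code{sstart}, \code{send} (1-based inclusive aligned
#'   spans, 0 when empty), and \code{pairs}, a two-column integer matrix of
#'   aligned (non-gap) residue-pair coordinates, strictly increasing in both
#'   columns.
#' @examples
#' m <- substitutionMatrix()
#' smithWaterman("PELICAN", "PELICAN", m)$score
#' @export
smithWaterman <- function(a, b, matrix = substitutionMatrix(),
                          gapOpen = 11L, gapExtend = 1L) {
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b))
        stop("sequences must be non-empty", call. = FALSE)
    r <- .sw_align(a, b, matrix, rownames(matrix),
                   as.integer(gapOpen), as.integer(gapExtend))
    list(score = r$score, qstart = r$qstart, qend = r$qend,
         sstart = r$sstart, send = r$send,
         pairs = cbind(query = r$qpos, subject = r$spos))
}

#' Search a query sequence against a sequence database
#'
#' Runs one local-alignment database search and reports hits the way a
#' protein-search tool does: each subject's best local alignment is scored,
#' converted to an E-value with \eqn{E = K m n e^{-\lambda S}} where m is
#' the query length and n the summed residue length of the database, hits
#' with E-value above \code{params@evalueCutoff} are dropped, and the rest
#' are sorted by E-value (ascending), raw score (descending) and subject id
#' (lexicographic) and truncated to \code{params@maxTargetSeqs}. The
#' internal and blastp backends honour the identical contract; hits are
#' tagged with the backend that produced them.
#'
#' @param query named character scalar (or \code{AAStringSet} of length 1):
#'   the query sequence; its name is used as the query id.
#' @param database named \code{AAStringSet} (or named character vector).
#' @param params a \linkS4class{SearchParams}.
#' @param short logical; use short-sequence settings (for peptide-window
#'   queries the blastp adapter switches to its short task and disables
#'   composition-based statistics; the internal engine is unaffected).
#' @return data.frame of hits: \code{query_id}, \code{subject_id},
#'   \code{raw_score}, \code{bit_score}, \code{evalue}, \code{qstart},
#'   \code{qend}, \code{sstart}, \code{send}, list columns \code{qpos} /
#'   \code{spos} with the aligned residue-pair coordinates, and
#'   \code{backend}.
#' @export
searchHits <- function(query, database, params = SearchParams(),
                       short = FALSE) {
    if (!length(database))
        stop("database must be non-empty", call. = FALSE)
    if (is.null(names(database)) || any(!nzchar(names(database))))
        stop("database sequences must be named", call. = FALSE)
    qname <- names(query)
    if (is.null(qname) || !nzchar(qname[1L]))
        stop("query must be named", call. = FALSE)
    qseq <- as.character(query)[1L]
    switch(params@backend,
           internal = .search_internal(qname[1L], qseq, database, params),
           blastp = .search_blastp(qname[1L], qseq, database, params,
                                   short = short))
}

.empty_hits <- function() {
    data.frame(query_id = character(), subject_id = character(),
               raw_score = integer(), bit_score = numeric(),
               evalue = numeric(), qstart = integer(), qend = integer(),
               sstart = integer(), send = integer(),
               qpos = I(list()), spos = I(list()),
               backend = character(), stringsAsFactors = FALSE)
}

.sort_hits <- function(hits, params) {
    if (!nrow(hits)) return(hits)
    ord <- order(hits$evalue, -hits$raw_score, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[hits$evalue <= params@evalueCutoff, , drop = FALSE]
    if (nrow(hits) > params@maxTargetSeqs)
        hits <- hits[seq_len(params@maxTargetSeqs), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

.search_internal <- function(qname, qseq, database, params) {
    ka <- .ka_params(params)
    db <- as.character(database)
    res <- .sw_align_batch(qseq, db, ka$matrix, rownames(ka$matrix),
                           params@gapOpen, params@gapExtend)
    keep <- which(res$score > 0L)
    if (!length(keep)) return(.empty_hits())
    m <- nchar(qseq)
    n <- sum(nchar(db))
    score <- res$score[keep]
    hits <- data.frame(
        query_id = qname,
        subject_id = names(database)[keep],
        raw_score = score,
        bit_score = bitScoreFromScore(score, ka$lambda, ka$K),
        evalue = evalueFromScore(score, m, n, ka$lambda, ka$K),
        qstart = res$qstart[keep], qend = res$qend[keep],
        sstart = res$sstart[keep], send = res$send[keep],
        stringsAsFactors = FALSE)
    hits$qpos <- res$qpos[keep]
    hits$spos <- res$spos[keep]
    hits$backend <- "internal"
    .sort_hits(hits, params)
}

#' Best hit of a sorted hit list
#'
#' @param hits a hit data.frame as returned by [searchHits()] (already
#'   sorted by the search contract).
#' @return The first hit row as a one-row data.frame, or \code{NULL} when
#'   there are no hits.
#' @export
bestHit <- function(hits) {
    if (is.null(hits) || !nrow(hits)) return(NULL)
    hits[1L, , drop = FALSE]
}
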