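#' The three-stage search and the cross-promotion E-value
#'
#' Stage 1 searches the candidate peptide window against the known-peptides
#' database to find the best-matching known peptide (the "hit peptide") and
#' its parent protein (the "hit protein"). Stage 2 searches the hit protein
#' against the whole query proteome and records both its best E-value and
#' its E-value against the query protein specifically; stage 3 mirrors this
#' with the query protein against the known proteome. The cross-promotion
#' E-value (CPE) verdict is "yes" only when both directions are reciprocal:
#' the hit protein's best match in the query proteome is the query protein
#' and the query protein's best match in the known proteome is the hit
#' protein (exact E-value ties count as best).
#' @name cpe
#' @keywords internal
NULL

# Relaxed parameters for the reciprocal whole-protein searches and for the
# first-stage peptide search: no effective E-value cutoff (the configured
# cutoff is applied to the winning peptide hit afterwards) and no target
# truncation, so that the E-value of a specific partner protein is always
# observable.
.relaxed_params <- function(params, nTargets) {
    new("SearchParams", matrixName = params@matrixName,
        gapOpen = params@gapOpen, gapExtend = params@gapExtend,
        evalueCutoff = 1e6, maxTargetSeqs = as.integer(nTargets),
        backend = params@backend, frequencies = params@frequencies)
}

# Memoised whole-protein-vs-proteome search; key is direction-specific so
# the two reciprocal stages never collide.
.proteome_search <- function(key, qname, qseq, database, params, cache) {
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    hits <- searchHits(stats::setNames(qseq, qname), database,
                       .relaxed_params(params, length(database)))
    if (!is.null(cache)) cache[[key]] <- hits
    hits
}

#' Stage-1 peptide search: find the best-matching known peptide
#'
#' Searches one candidate peptide window against the known-peptides database
#' and returns the best hit, mapped back to its parent protein and annotated
#' site. Under strict-center mode (the default) the hit is discarded unless
#' the candidate's central residue is aligned onto the known window's
#' central (modified) residue, so a site is never transferred onto the
#' wrong residue of a similar peptide. The configured E-value cutoff is
#' applied to the winning hit.
#'
#' @param candidateWindow named character scalar: the 2w+1 window around the
#'   candidate residue (name = any query-window identifier).
#' @param knownPeptides a \linkS4class{PeptideWindowSet}.
#' @param params a \linkS4class{SearchParams}.
#' @param strictCenter logical, require center-to-center alignment.
#' @param allTies return every qualifying hit tied at the best E-value
#'   (relative tolerance 1e-9) instead of only the first. Several known
#'   peptides can tie exactly — e.g. the same site window stored for two
#'   homologous known proteins — and a transfer is homology-supported when
#'   any tied hit's parent protein passes the reciprocity check, so the
#'   caller may need all of them.
#' @return A data.frame (one row per reported hit; a single row unless
#'   \code{allTies}) with \code{hit_window_id}, \code{hit_protein_id},
#'   \code{hit_site_position}, \code{hit_ptm_type}, \code{peptide_evalue},
#'   \code{raw_score}, \code{center_aligned}; or \code{NULL} when no
#'   acceptable hit exists.
#' @export
blast1FindHit <- function(candidateWindow, knownPeptides,
                          params = SearchParams(), strictCenter = TRUE,
                          allTies = FALSE) {
    if (!length(knownPeptides))
        stop("known-peptides database is empty", call. = FALSE)
    w <- knownPeptides@w
    hits <- searchHits(candidateWindow, windowSequences(knownPeptides),
                       .relaxed_params(params, length(knownPeptides)),
                       short = TRUE)
    if (is.null(hits) || !nrow(hits)) return(NULL)
    if (hits$evalue[1L] > params@evalueCutoff) return(NULL)
    center <- w + 1L
    centered <- vapply(seq_len(nrow(hits)), function(i) {
        at <- which(hits$qpos[[i]] == center)
        length(at) == 1L && hits$spos[[i]][at] == center
    }, NA)
    tied <- which(hits$evalue <= hits$evalue[1L] * (1 + 1e-9))
    if (strictCenter) tied <- tied[centered[tied]]
    if (!length(tied)) return(NULL)
    if (!allTies) tied <- tied[1L]
    sel <- hits[tied, , drop = FALSE]
    parsed <- .parse_window_id(sel$subject_id)
    data.frame(hit_window_id = sel$subject_id,
               hit_protein_id = parsed$protein_id,
               hit_site_position = parsed$position,
               hit_ptm_type = parsed$ptm_type,
               peptide_evalue = sel$evalue,
               raw_score = sel$raw_score,
               center_aligned = centered[tied],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage-2 reciprocal search: hit protein against the query proteome
#'
#' Searches the hit protein against the entire query proteome and extracts
#' the smallest E-value (its best match) and its E-value against the query
#' protein specifically (+Inf when the pair does not align at all).
#'
#' @param hitProteinId accession of the hit protein.
#' @param hitSequence its sequence.
#' @param queryProteinId accession of the query protein; must exist in the
#'   query proteome (hard error otherwise — a query must always be a member
#'   of the query proteome database).
#' @param queryProteome named \code{AAStringSet}.
#' @param params a \linkS4class{SearchParams}.
#' @param cache optional environment memoising whole-proteome searches.
#' @return list: \code{E_best}, \code{E_pair}, \code{best_subject}.
#' @export
blast2Reciprocal <- function(hitProteinId, hitSequence, queryProteinId,
                             queryProteome, params = SearchParams(),
                             cache = NULL) {
    if (!queryProteinId %in% names(queryProteome))
        stop("query protein '", queryProteinId,
             "' is not contained in the query proteome", call. = FALSE)
    hits <- .proteome_search(paste0("h2q\r", hitProteinId), hitProteinId,
                             as.character(hitSequence), queryProteome,
                             params, cache)
    .reciprocal_evidence(hits, queryProteinId)
}

#' Stage-3 reciprocal search: query protein against the known proteome
#'
#' Mirror image of [blast2Reciprocal()]: the query protein is searched
#' against the known proteome; reports its best E-value and its E-value
#' against the hit protein.
#'
#' @param queryProteinId accession of the query protein.
#' @param querySequence its sequence.
#' @param hitProteinId accession of the hit protein in the known proteome.
#' @param knownProteome named \code{AAStringSet}.
#' @inheritParams blast2Reciprocal
#' @return list: \code{E_best}, \code{E_pair}, \code{best_subject}.
#' @export
blast3Reciprocal <- function(queryProteinId, querySequence, hitProteinId,
                             knownProteome, params = SearchParams(),
                             cache = NULL) {
    if (!hitProteinId %in% names(knownProteome))
        stop("hit protein '", hitProteinId,
             "' is not contained in the known proteome", call. = FALSE)
    hits <- .proteome_search(paste0("q2k\r", queryProteinId),
                             queryProteinId, as.character(querySequence),
                             knownProteome, params, cache)
    .reciprocal_evidence(hits, hitProteinId)
}

.reciprocal_evidence <- function(hits, partnerId) {
    if (is.null(hits) || !nrow(hits))
        return(list(E_best = Inf, E_pair = Inf,
                    best_subject = NA_character_))
    pair <- hits$evalue[match(partnerId, hits$subject_id)]
    list(E_best = hits$evalue[1L],
         E_pair = if (is.na(pair)) Inf else pair,
         best_subject = hits$subject_id[1L])
}

#' Cross-promotion E-value verdict
#'
#' Decides whether a candidate site transfer is homology-supported: "yes"
#' (TRUE) only when the reciprocal conditions hold simultaneously — the hit
#' protein's E-value against the query protein equals its best E-value in
#' the query proteome, and the query protein's E-value against the hit
#' protein equals its best E-value in the known proteome. Exact ties count
#' as best; \code{tieTol} is the relative tolerance used for the equality.
#'
#' @param eHitBest,eHitQuery smallest E-value of the hit protein in the
#'   query proteome, and its E-value against the query protein.
#' @param eQueryBest,eQueryHit smallest E-value of the query protein in the
#'   known proteome, and its E-value against the hit protein.
#' @param tieTol relative tolerance for E-value ties (default 1e-9).
#' @return Logical verdict.
#' @examples
#' cpeVerdict(1e-30, 1e-30, 1e-28, 1e-28)  # reciprocal: TRUE
#' cpeVerdict(1e-30, 1e-5, 1e-28, 1e-28)   # one direction fails: FALSE
#' @export
cpeVerdict <- function(eHitBest, eHitQuery, eQueryBest, eQueryHit,
                       tieTol = 1e-9) {
    recip <- function(best, pair)
        is.finite(pair) && pair <= best * (1 + tieTol)
    recip(eHitBest, eHitQuery) && recip(eQueryBest, eQueryHit)
}

#' Plain E-value verdict
#'
#' The conventional homology benchmark the CPE criterion is compared
#' against: accept the transfer whenever the stage-1 peptide E-value is at
#' or below a threshold, with no reciprocity requirement.
#'
#' @param peptideEvalue E-value of the stage-1 peptide hit.
#' @param threshold positive acceptance threshold.
#' @return Logical verdict.
#' @examples
#' evalueVerdict(1e-8, 1e-3)
#' @export
evalueVerdict <- function(peptideEvalue, threshold) {
    stopifnot(threshold > 0)
    is.finite(peptideEvalue) && peptideEvalue <= threshold
}
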