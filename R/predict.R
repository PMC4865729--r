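#' Predict PTM sites for query proteins
#'
#' Runs the whole pipeline for every candidate residue of the requested
#' query proteins: stage-1 peptide search against the known peptides, then
#' the two reciprocal whole-protein searches, then the CPE and plain
#' E-value verdicts. Whole-proteome searches are memoised per protein, so
#' the cost scales with the number of distinct proteins involved rather
#' than with the number of candidate sites.
#'
#' @param model a \linkS4class{PTMModel}.
#' @param queryIds accessions to predict for (default: every protein in the
#'   model's query proteome). Every id must exist in the query proteome; a
#'   missing id is a hard error.
#' @param params a \linkS4class{SearchParams}; its backend must match the
#'   model's.
#' @param mode which verdict selects the emitted rows: \code{"cpe"}
#'   (default), \code{"evalue"}, or \code{"both"} (rows passing either).
#' @param emitAll emit every candidate with a stage-1 hit regardless of
#'   verdict (both verdict columns are always present).
#' @param strictCenter require the candidate residue to align onto the
#'   known window's central residue in stage 1 (default TRUE).
#' @param evalueThreshold threshold of the plain E-value verdict (default:
#'   \code{params@evalueCutoff}).
#' @param verbose print per-protein progress.
#' @return \code{DataFrame} with one row per emitted candidate site, sorted
#'   by query protein then position: candidate coordinates, hit provenance,
#'   the stage-1 peptide E-value, the four reciprocal E-values
#'   (\code{E_h_best}, \code{E_h_q}, \code{E_q_best}, \code{E_q_h}), the
#'   best-match subjects and the two verdicts.
#' @examples
#' sc <- syntheticScenario("self_inclusion", seed = 1)
#' model <- buildModel(sc$known, sc$annotations, sc$query)
#' head(predictSites(model, queryIds = names(sc$query)[1]))
#' @export
predictSites <- function(model, queryIds = NULL, params = SearchParams(),
                         mode = c("cpe", "evalue", "both"),
                         emitAll = FALSE, strictCenter = TRUE,
                         evalueThreshold = params@evalueCutoff,
                         verbose = FALSE) {
    mode <- match.arg(mode)
    if (params@backend != model@backend)
        stop("params backend (", params@backend,
             ") differs from the model backend (", model@backend, ")",
             call. = FALSE)
    qdb <- model@queryProteome
    if (is.null(queryIds)) queryIds <- names(qdb)
    missing <- setdiff(queryIds, names(qdb))
    if (length(missing))
        stop("query id(s) not contained in the query proteome: ",
             paste(missing, collapse = ", "), call. = FALSE)
    kp <- model@knownPeptides
    kdb <- model@knownProteome
    kseq <- as.character(kdb)
    qseq <- as.character(qdb)
    cache <- new.env(parent = emptyenv())
    rows <- list()
    for (qid in queryIds) {
        cand <- enumerateCandidates(qseq[[qid]], model@ptmType,
                                    model@residueSet)
        if (verbose)
            message(qid, ": ", nrow(cand), " candidate residue(s)")
        for (i in seq_len(nrow(cand))) {
            pos <- cand$position[i]
            win <- extractWindow(qseq[[qid]], pos, model@w)
            tiedHits <- blast1FindHit(
                stats::setNames(win, .window_id(qid, pos, model@ptmType)),
                kp, params, strictCenter = strictCenter, allTies = TRUE)
            if (is.null(tiedHits)) next
            # residue-type guard: transfer only onto chemically valid
            # residues of this PTM type
            if (!cand$residue[i] %in% model@residueSet) next
            # evaluate reciprocity for each tied best peptide in turn and
            # keep the first homology-supported one (ties are genuinely
            # equivalent stage-1 evidence, e.g. the same site stored for
            # two homologous known proteins)
            hit <- ev2 <- ev3 <- NULL
            for (k in seq_len(nrow(tiedHits))) {
                h <- tiedHits[k, , drop = FALSE]
                e2 <- blast2Reciprocal(h$hit_protein_id,
                                       kseq[[h$hit_protein_id]], qid, qdb,
                                       params, cache)
                e3 <- blast3Reciprocal(qid, qseq[[qid]], h$hit_protein_id,
                                       kdb, params, cache)
                if (is.null(hit)) { hit <- h; ev2 <- e2; ev3 <- e3 }
                if (cpeVerdict(e2$E_best, e2$E_pair, e3$E_best,
                               e3$E_pair)) {
                    hit <- h; ev2 <- e2; ev3 <- e3
                    break
                }
            }
            rows[[length(rows) + 1L]] <- data.frame(
                query_protein_id = qid,
                position = pos,
                residue = cand$residue[i],
                ptm_type = model@ptmType,
                hit_protein_id = hit$hit_protein_id,
                hit_site_position = hit$hit_site_position,
                peptide_evalue = hit$peptide_evalue,
                E_h_best = ev2$E_best, E_h_q = ev2$E_pair,
                E_q_best = ev3$E_best, E_q_h = ev3$E_pair,
                best_subject_h = ev2$best_subject,
                best_subject_q = ev3$best_subject,
                cpe_verdict = cpeVerdict(ev2$E_best, ev2$E_pair,
                                         ev3$E_best, ev3$E_pair),
                evalue_verdict = evalueVerdict(hit$peptide_evalue,
                                               evalueThreshold),
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(query_protein_id = character(), position = integer(),
                   residue = character(), ptm_type = character(),
                   hit_protein_id = character(),
                   hit_site_position = integer(),
                   peptide_evalue = numeric(), E_h_best = numeric(),
                   E_h_q = numeric(), E_q_best = numeric(),
                   E_q_h = numeric(), best_subject_h = character(),
                   best_subject_q = character(), cpe_verdict = logical(),
                   evalue_verdict = logical(), stringsAsFactors = FALSE)
    if (!emitAll)
        out <- switch(mode,
            cpe = out[out$cpe_verdict, , drop = FALSE],
            evalue = out[out$evalue_verdict, , drop = FALSE],
            both = out[out$cpe_verdict | out$evalue_verdict, ,
                       drop = FALSE])
    out <- out[order(out$query_protein_id, out$position), , drop = FALSE]
    rownames(out) <- NULL
    S4Vectors::DataFrame(out)
}

#' Evaluate predictions against ground truth
#'
#' Counts predicted and true sites as (protein, position, PTM type) triples:
#' precision is the fraction of predicted sites found in the truth, recall
#' the fraction of true sites that were predicted. With zero predictions
#' the precision is undefined (\code{NA}); with zero true sites the recall
#' is undefined.
#'
#' @param predictions output of [predictSites()] (rows are counted once per
#'   unique site).
#' @param truth data.frame or \code{DataFrame} with \code{protein_id},
#'   \code{position} and \code{ptm_type} columns.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluatePredictions <- function(predictions, truth) {
    pred <- as.data.frame(predictions)
    truth <- as.data.frame(truth)
    pkey <- unique(paste(pred$query_protein_id, pred$position,
                         pred$ptm_type, sep = "\r"))
    tkey <- unique(paste(truth$protein_id, truth$position, truth$ptm_type,
                         sep = "\r"))
    nPred <- length(pkey)
    nTruth <- length(tkey)
    nCorrect <- sum(pkey %in% tkey)
    new("EvalReport", nPredicted = nPred, nCorrect = nCorrect,
        nTruth = nTruth,
        precision = if (nPred > 0L) nCorrect / nPred else NA_real_,
        recall = if (nTruth > 0L) nCorrect / nTruth else NA_real_)
}

#' Write predictions to TSV or GFF3
#'
#' The TSV carries every prediction column, one row per prediction plus a
#' header. The GFF3 uses one \code{modified_amino_acid} feature per site
#' with 1-based protein coordinates and the hit provenance, E-values and
#' verdicts in the attribute column.
#'
#' @param predictions output of [predictSites()].
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @return Invisibly, \code{path}.
#' @export
writePredictions <- function(predictions, path,
                             format = c("tsv", "gff3")) {
    format <- match.arg(format)
    pred <- as.data.frame(predictions)
    if (format == "tsv") {
        utils::write.table(pred, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(path))
    }
    fmt_e <- function(x) ifelse(is.finite(x), sprintf("%.6g", x), "inf")
    lines <- "##gff-version 3"
    if (nrow(pred)) {
        attrs <- sprintf(paste0(
            "ID=%s;ptm_type=%s;residue=%s;hit_protein=%s;hit_site=%d;",
            "peptide_evalue=%s;E_h_best=%s;E_h_q=%s;E_q_best=%s;",
            "E_q_h=%s;cpe_verdict=%s;evalue_verdict=%s"),
            paste(pred$query_protein_id, pred$position, pred$ptm_type,
                  sep = "."),
            pred$ptm_type, pred$residue, pred$hit_protein_id,
            pred$hit_site_position, fmt_e(pred$peptide_evalue),
            fmt_e(pred$E_h_best), fmt_e(pred$E_h_q),
            fmt_e(pred$E_q_best), fmt_e(pred$E_q_h),
            ifelse(pred$cpe_verdict, "yes", "no"),
            ifelse(pred$evalue_verdict, "yes", "no"))
        lines <- c(lines, paste(pred$query_protein_id, "PTMTransfer",
                                "modified_amino_acid", pred$position,
                                pred$position, ".", ".", ".", attrs,
                                sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}
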