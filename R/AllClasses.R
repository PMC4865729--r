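#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importClassesFrom Biostrings AAStringSet
#' @useDynLib PTMTransfer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Search parameters for local-alignment database searches
#'
#' Holds the scoring and reporting parameters shared by every search stage of
#' the pipeline: the substitution matrix, affine gap penalties, the E-value
#' threshold for saving hits, the maximum number of aligned sequences to
#' report, and the backend that performs the search.
#'
#' @slot matrixName name of the substitution matrix (any matrix shipped with
#'   \pkg{Biostrings}, e.g. \code{"BLOSUM62"}).
#' @slot gapOpen,gapExtend non-negative integer affine gap penalties; a gap of
#'   length L costs \code{gapOpen + L * gapExtend}.
#' @slot evalueCutoff positive E-value above which hits are discarded.
#' @slot maxTargetSeqs maximum number of subject sequences reported.
#' @slot backend \code{"internal"} (built-in Smith-Waterman engine) or
#'   \code{"blastp"} (external NCBI blastp adapter).
#' @slot frequencies background amino-acid frequency model used for the
#'   Karlin-Altschul statistics of the internal engine: \code{"robinson"}
#'   (Robinson-Robinson) or \code{"uniform"}.
#' @exportClass SearchParams
setClass("SearchParams",
    representation(matrixName = "character", gapOpen = "integer",
                   gapExtend = "integer", evalueCutoff = "numeric",
                   maxTargetSeqs = "integer", backend = "character",
                   frequencies = "character"))

setValidity("SearchParams", function(object) {
    msg <- character()
    if (object@gapOpen < 0L || object@gapExtend < 0L)
        msg <- c(msg, "gap penalties must be non-negative")
    if (object@gapExtend > object@gapOpen)
        msg <- c(msg, "gapExtend must not exceed gapOpen")
    if (!is.finite(object@evalueCutoff) || object@evalueCutoff <= 0)
        msg <- c(msg, "evalueCutoff must be a positive number")
    if (object@maxTargetSeqs < 1L)
        msg <- c(msg, "maxTargetSeqs must be at least 1")
    if (!object@backend %in% c("internal", "blastp"))
        msg <- c(msg, "backend must be 'internal' or 'blastp'")
    if (!object@frequencies %in% c("robinson", "uniform"))
        msg <- c(msg, "frequencies must be 'robinson' or 'uniform'")
    if (length(msg)) msg else TRUE
})

#' Construct search parameters
#'
#' @param matrixName substitution matrix name (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend affine gap penalties (default 11 / 1, the usual
#'   protein-search defaults).
#' @param evalueCutoff E-value threshold for saving hits (default 10, the
#'   conventional protein-search default).
#' @param maxTargetSeqs maximum number of aligned sequences kept (default 500).
#' @param backend \code{"internal"} or \code{"blastp"}.
#' @param frequencies \code{"robinson"} or \code{"uniform"} background model.
#' @return A \linkS4class{SearchParams} object.
#' @examples
#' SearchParams(evalueCutoff = 1e-3)
#' @export
SearchParams <- function(matrixName = "BLOSUM62", gapOpen = 11L,
                         gapExtend = 1L, evalueCutoff = 10,
                         maxTargetSeqs = 500L,
                         backend = c("internal", "blastp"),
                         frequencies = c("robinson", "uniform")) {
    new("SearchParams", matrixName = matrixName,
        gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
        evalueCutoff = as.numeric(evalueCutoff),
        maxTargetSeqs = as.integer(maxTargetSeqs),
        backend = match.arg(backend), frequencies = match.arg(frequencies))
}

setMethod("show", "SearchParams", function(object) {
    cat("SearchParams:", object@matrixName,
        sprintf("gap %d/%d", object@gapOpen, object@gapExtend),
        sprintf("E<=%g", object@evalueCutoff),
        sprintf("max_target_seqs %d", object@maxTargetSeqs),
        paste0("backend=", object@backend), "\n")
})

#' Set of fixed-width peptide windows centered on (candidate) PTM sites
#'
#' Container for 2w+1-residue peptide segments cut out of parent proteins and
#' centered on a modified (or candidate) residue. Windows that would extend
#' past a sequence end are padded with \code{'X'}. Window identifiers encode
#' provenance as \code{"<protein_id>|<position>|<ptm_type>"} so that a hit
#' peptide can always be mapped back to its parent protein.
#'
#' @slot windows \code{AAStringSet} of the window sequences, named by
#'   window id.
#' @slot meta \code{DataFrame} with one row per window: \code{protein_id},
#'   \code{position} (1-based center position in the parent protein),
#'   \code{residue} (central residue) and \code{ptm_type}.
#' @slot w non-negative integer half-width; every window has width 2w+1.
#' @exportClass PeptideWindowSet
setClass("PeptideWindowSet",
    representation(windows = "AAStringSet", meta = "DataFrame",
                   w = "integer"))

setValidity("PeptideWindowSet", function(object) {
    msg <- character()
    if (length(object@w) != 1L || object@w < 0L)
        msg <- c(msg, "w must be a single non-negative integer")
    if (length(object@windows) != nrow(object@meta))
        msg <- c(msg, "windows and meta must have the same length")
    if (length(object@windows) &&
        any(Biostrings::width(object@windows) != 2L * object@w + 1L))
        msg <- c(msg, "every window must have width 2*w + 1")
    if (anyDuplicated(names(object@windows)))
        msg <- c(msg, "window ids must be unique")
    if (length(object@windows)) {
        ctr <- substr(as.character(object@windows), object@w + 1L,
                      object@w + 1L)
        if (!all(ctr == object@meta$residue))
            msg <- c(msg, "central window residue must match meta$residue")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PeptideWindowSet", function(object) {
    cat("PeptideWindowSet with", length(object@windows), "windows of width",
        2L * object@w + 1L, "(w =", object@w, ")\n")
    if (length(object@windows))
        cat("  ptm types:",
            paste(unique(object@meta$ptm_type), collapse = ", "), "\n")
})

#' @describeIn PeptideWindowSet-class number of windows.
#' @param x,object a \code{PeptideWindowSet}.
#' @export
setMethod("length", "PeptideWindowSet", function(x) length(x@windows))

#' Prediction model: the three search databases plus their parameters
#'
#' A model bundles the three databases the pipeline searches: the known
#' proteome (proteins with experimentally verified PTM sites), the known
#' peptides derived from its annotations, and the query proteome that every
#' query protein must belong to. The manifest records input checksums and a
#' unique content-derived model name, so rebuilding from identical inputs
#' yields an identical model.
#'
#' @slot knownProteome,queryProteome named \code{AAStringSet}s.
#' @slot knownPeptides a \linkS4class{PeptideWindowSet}.
#' @slot annotations validated site annotations (\code{DataFrame}).
#' @slot w window half-width used for the known peptides.
#' @slot ptmType PTM type label of this model.
#' @slot residueSet candidate residues for this PTM type.
#' @slot backend search backend identity the model was built for.
#' @slot manifest list: model \code{name}, \code{created}, input
#'   \code{checksums}, counts.
#' @exportClass PTMModel
setClass("PTMModel",
    representation(knownProteome = "AAStringSet",
                   knownPeptides = "PeptideWindowSet",
                   queryProteome = "AAStringSet",
                   annotations = "DataFrame",
                   w = "integer", ptmType = "character",
                   residueSet = "character", backend = "character",
                   manifest = "list"))

setValidity("PTMModel", function(object) {
    msg <- character()
    if (!length(object@knownProteome))
        msg <- c(msg, "known proteome is empty")
    if (!length(object@queryProteome))
        msg <- c(msg, "query proteome is empty")
    if (object@w != object@knownPeptides@w)
        msg <- c(msg, "w differs from the known-peptide window half-width")
    kp <- object@knownPeptides@meta
    if (nrow(kp) && !all(kp$protein_id %in% names(object@knownProteome)))
        msg <- c(msg, "every known-peptide window must resolve to a known-proteome protein")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PTMModel", function(object) {
    cat("PTMModel", sQuote(object@manifest$name), "\n")
    cat("  ptm type:", object@ptmType,
        sprintf("(residues %s)", paste(object@residueSet, collapse = "")),
        "\n")
    cat("  known proteome:", length(object@knownProteome), "proteins;",
        "known peptides:", length(object@knownPeptides),
        sprintf("(w = %d)", object@w), "\n")
    cat("  query proteome:", length(object@queryProteome), "proteins\n")
    cat("  backend:", object@backend, "\n")
})

#' Site-level evaluation report
#'
#' Precision and recall of a prediction set against ground truth, counted at
#' the level of (protein, position, PTM type) triples: precision is the
#' fraction of predicted sites that are true, recall the fraction of true
#' sites that are predicted. With zero predictions the precision is undefined
#' and reported as \code{NA}.
#'
#' @slot nPredicted,nCorrect,nTruth site counts.
#' @slot precision,recall proportions in [0, 1] (\code{NA} when undefined).
#' @exportClass EvalReport
setClass("EvalReport",
    representation(nPredicted = "integer", nCorrect = "integer",
                   nTruth = "integer", precision = "numeric",
                   recall = "numeric"))

setValidity("EvalReport", function(object) {
    msg <- character()
    if (object@nCorrect > min(object@nPredicted, object@nTruth))
        msg <- c(msg, "nCorrect cannot exceed min(nPredicted, nTruth)")
    ok <- function(p) is.na(p) || (p >= 0 && p <= 1)
    if (!ok(object@precision) || !ok(object@recall))
        msg <- c(msg, "precision and recall must lie in [0, 1] or be NA")
    if (length(msg)) msg else TRUE
})

setMethod("show", "EvalReport", function(object) {
    cat(sprintf(
        "EvalReport: %d predicted, %d correct, %d true sites\n",
        object@nPredicted, object@nCorrect, object@nTruth))
    cat(sprintf("  precision = %s, recall = %s\n",
        ifelse(is.na(object@precision), "NA",
               sprintf("%.3f", object@precision)),
        ifelse(is.na(object@recall), "NA", sprintf("%.3f", object@recall))))
})

#' @describeIn EvalReport-class accessor returning precision.
#' @export
precision <- function(object) object@precision

#' @describeIn EvalReport-class accessor returning recall.
#' @export
recall <- function(object) object@recall

#' Configuration for the synthetic proteome generator
#'
#' Describes one synthetic known/query proteome pair: random known proteins
#' with planted PTM sites, query proteins derived from them by point
#' mutation at a controlled per-residue divergence, plus unrelated decoys and
#' an optional paralog trap (near-duplicate known proteins that break
#' reciprocity for planted candidate sites).
#'
#' @slot seed integer seed fixing every random draw.
#' @slot nProteins number of known proteins.
#' @slot lengthRange min/max protein length (residues).
#' @slot sitesPerProtein min/max planted sites per protein.
#' @slot ptmType PTM type label of the planted sites.
#' @slot residueSet residues eligible to carry the PTM.
#' @slot divergence per-residue substitution probability used to derive the
#'   query homologs (0 = identical copies).
#' @slot nDecoys unrelated random proteins appended to each proteome.
#' @slot paralogTrap logical; insert near-duplicate known proteins so that
#'   the peptide match succeeds while whole-protein reciprocity fails.
#' @slot frequencies background composition of random residues
#'   (\code{"uniform"} or \code{"robinson"}).
#' @exportClass SynthConfig
setClass("SynthConfig",
    representation(seed = "integer", nProteins = "integer",
                   lengthRange = "integer", sitesPerProtein = "integer",
                   ptmType = "character", residueSet = "character",
                   divergence = "numeric", nDecoys = "integer",
                   paralogTrap = "logical", frequencies = "character"))

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (object@nProteins < 1L)
        msg <- c(msg, "nProteins must be at least 1")
    if (length(object@lengthRange) != 2L ||
        any(object@lengthRange < 1L) ||
        object@lengthRange[1L] > object@lengthRange[2L])
        msg <- c(msg, "lengthRange must be an increasing pair of positive lengths")
    if (length(object@sitesPerProtein) != 2L ||
        any(object@sitesPerProtein < 0L) ||
        object@sitesPerProtein[1L] > object@sitesPerProtein[2L])
        msg <- c(msg, "sitesPerProtein must be a non-decreasing pair")
    if (object@divergence < 0 || object@divergence >= 1)
        msg <- c(msg, "divergence must lie in [0, 1)")
    if (!length(object@residueSet))
        msg <- c(msg, "residueSet must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Construct a synthetic-data configuration
#'
#' @param seed integer seed.
#' @param nProteins number of known proteins.
#' @param lengthRange length-2 vector, protein length range.
#' @param sitesPerProtein length-2 vector, planted sites per protein.
#' @param ptmType PTM type label.
#' @param residueSet candidate residues (defaults to the residue set of
#'   \code{ptmType}).
#' @param divergence per-residue substitution probability for query homologs.
#' @param nDecoys unrelated decoy proteins per proteome.
#' @param paralogTrap insert reciprocity-breaking paralogs into the known
#'   proteome.
#' @param frequencies background residue composition.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' synthConfig(seed = 1, nProteins = 5)
#' @export
synthConfig <- function(seed = 42L, nProteins = 30L,
                        lengthRange = c(200L, 400L),
                        sitesPerProtein = c(2L, 4L),
                        ptmType = "phosphorylation",
                        residueSet = ptmResidues(ptmType),
                        divergence = 0, nDecoys = 0L, paralogTrap = FALSE,
                        frequencies = c("uniform", "robinson")) {
    new("SynthConfig", seed = as.integer(seed),
        nProteins = as.integer(nProteins),
        lengthRange = as.integer(lengthRange),
        sitesPerProtein = as.integer(rep(sitesPerProtein, length.out = 2L)),
        ptmType = ptmType, residueSet = residueSet,
        divergence = as.numeric(divergence), nDecoys = as.integer(nDecoys),
        paralogTrap = isTRUE(paralogTrap),
        frequencies = match.arg(frequencies))
}

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig: seed", object@seed, "-", object@nProteins, "proteins,",
        "lengths", paste(object@lengthRange, collapse = "-"),
        ", sites/protein", paste(object@sitesPerProtein, collapse = "-"),
        ",", object@ptmType, "\n")
    cat("  divergence", object@divergence, ", decoys", object@nDecoys,
        ", paralog trap:", object@paralogTrap, "\n")
})
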