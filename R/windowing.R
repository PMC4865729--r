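#' Extract the peptide window around a sequence position
#'
#' Cuts the 2w+1-residue segment centered on \code{position} (1-based), with
#' w residues upstream and w downstream. Positions falling before the start
#' or after the end of the sequence are filled with the pad character 'X',
#' so the window always has exactly 2w+1 characters and the central
#' character always equals the protein residue at \code{position}.
#'
#' @param sequence protein sequence (character scalar or \code{AAString}).
#' @param position 1-based center position.
#' @param w non-negative half-width.
#' @return Character scalar of length 2w+1.
#' @examples
#' extractWindow("MKSAPK", 3, 2)  # "MKSAP"
#' extractWindow("MKSAPK", 1, 2)  # "XXMKS"
#' @export
extractWindow <- function(sequence, position, w) {
    sequence <- as.character(sequence)
    n <- nchar(sequence)
    position <- as.integer(position)
    w <- as.integer(w)
    if (is.na(w) || w < 0L)
        stop("w must be a non-negative integer", call. = FALSE)
    if (is.na(position) || position < 1L || position > n)
        stop("position ", position, " out of range 1..", n, call. = FALSE)
    padded <- paste0(strrep("X", w), sequence, strrep("X", w))
    substr(padded, position, position + 2L * w)
}

#' Enumerate candidate PTM sites of a protein
#'
#' Lists every occurrence of a residue from the candidate set, in ascending
#' position order. These are the positions at which a PTM of the given type
#' could chemically occur and hence the query windows of the pipeline.
#'
#' @param sequence protein sequence (character scalar or \code{AAString}).
#' @param ptmType PTM type label.
#' @param residueSet candidate residues (defaults to the built-in set of
#'   \code{ptmType}).
#' @return data.frame with columns \code{position} and \code{residue}
#'   (zero rows when no candidate residue occurs).
#' @examples
#' enumerateCandidates("MKSAPK", "acetylation")  # K at 2 and 6
#' @export
enumerateCandidates <- function(sequence, ptmType,
                                residueSet = ptmResidues(ptmType)) {
    if (!length(residueSet))
        stop("residueSet must be non-empty", call. = FALSE)
    chars <- strsplit(as.character(sequence), "", fixed = TRUE)[[1L]]
    pos <- which(chars %in% residueSet)
    data.frame(position = pos, residue = chars[pos],
               stringsAsFactors = FALSE)
}

.window_id <- function(protein_id, position, ptm_type) {
    paste(protein_id, position, ptm_type, sep = "|")
}

# Inverse of .window_id; splits from the right so that protein accessions
# may themselves contain '|' (UniProt-style headers).
.parse_window_id <- function(window_id) {
    m <- regmatches(window_id,
                    regexec("^(.*)\\|([0-9]+)\\|([^|]+)$", window_id))
    bad <- vapply(m, length, 0L) != 4L
    if (any(bad))
        stop("corrupt window id(s): ",
             paste(window_id[bad], collapse = ", "), call. = FALSE)
    data.frame(protein_id = vapply(m, `[`, "", 2L),
               position = as.integer(vapply(m, `[`, "", 3L)),
               ptm_type = vapply(m, `[`, "", 4L),
               stringsAsFactors = FALSE)
}

#' Build the known-peptides database from validated annotations
#'
#' Extracts one 2w+1 window per annotated site (duplicate annotation rows
#' collapse to a single window) and names it
#' \code{"<protein_id>|<position>|<ptm_type>"}; the result is the peptide
#' database that candidate windows of query proteins are searched against.
#' Windows are ordered by protein id then position.
#'
#' @param proteome named \code{AAStringSet} of the known proteome.
#' @param annotations validated annotations (see [readSiteAnnotations()]).
#' @param w window half-width.
#' @return A \linkS4class{PeptideWindowSet}.
#' @export
buildKnownPeptides <- function(proteome, annotations, w) {
    ann <- as.data.frame(annotations)
    if (!nrow(ann))
        stop("no annotations to build known peptides from", call. = FALSE)
    missing <- setdiff(unique(ann$protein_id), names(proteome))
    if (length(missing))
        stop("annotated protein(s) absent from the proteome: ",
             paste(missing, collapse = ", "), call. = FALSE)
    key <- paste(ann$protein_id, ann$position, ann$ptm_type, sep = "\r")
    ann <- ann[!duplicated(key), , drop = FALSE]
    ann <- ann[order(ann$protein_id, ann$position), , drop = FALSE]
    seqs <- as.character(proteome)
    win <- vapply(seq_len(nrow(ann)), function(i)
        extractWindow(seqs[[ann$protein_id[i]]], ann$position[i], w), "")
    windows <- Biostrings::AAStringSet(win)
    names(windows) <- .window_id(ann$protein_id, ann$position, ann$ptm_type)
    meta <- S4Vectors::DataFrame(protein_id = ann$protein_id,
                                 position = as.integer(ann$position),
                                 residue = ann$residue,
                                 ptm_type = ann$ptm_type)
    new("PeptideWindowSet", windows = windows, meta = meta,
        w = as.integer(w))
}

#' @describeIn buildKnownPeptides window sequences as an \code{AAStringSet}
#'   named by window id (the exact FASTA payload fed to an external search
#'   backend).
#' @param x a \code{PeptideWindowSet}.
#' @export
windowSequences <- function(x) x@windows

#' @describeIn buildKnownPeptides per-window provenance table.
#' @export
windowInfo <- function(x) x@meta

#' @describeIn buildKnownPeptides window half-width w.
#' @export
halfWidth <- function(x) x@w

#' @describeIn buildKnownPeptides write the windows as FASTA with window ids
#'   as headers.
#' @param path output FASTA path.
#' @export
writeKnownPeptides <- function(x, path) {
    Biostrings::writeXStringSet(x@windows, filepath = path, width = 60L)
    invisible(path)
}
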