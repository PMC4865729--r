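#' Read a proteome from a FASTA file
#'
#' Parses protein sequences, normalises them to the 20 standard residues
#' plus 'X' (uppercasing, stripping trailing stop characters '*', and
#' mapping the ambiguity/rare letters B, Z, U, O, J to 'X'), and enforces
#' unique non-empty accessions. The accession is the first whitespace-
#' delimited token of the header; the remainder is kept as the description
#' in \code{mcols()}.
#'
#' @param path FASTA file path.
#' @return A named \code{AAStringSet}, one element per entry in file order,
#'   with a \code{description} metadata column.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "mksapk*", ">P2", "ACDEF"), f)
#' readProteome(f)
#' @export
readProteome <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    set <- Biostrings::readAAStringSet(path)
    if (!length(set))
        stop("FASTA file contains no sequences: ", path, call. = FALSE)
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (any(!nzchar(ids)))
        stop("empty sequence identifier in ", path, call. = FALSE)
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
             call. = FALSE)
    }
    seqs <- toupper(as.character(set))
    seqs <- sub("\\*+$", "", seqs)
    seqs <- chartr("BZUOJ", "XXXXX", seqs)
    if (any(!nzchar(seqs)))
        stop("zero-length sequence for id(s): ",
             paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
    bad <- grepl(paste0("[^", paste(c(aminoAcids(), "X"), collapse = ""), "]"),
                 seqs)
    if (any(bad))
        stop("invalid residue letters in sequence(s): ",
             paste(ids[bad], collapse = ", "), call. = FALSE)
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

#' Write a proteome to FASTA
#'
#' Writes standard 60-column FASTA; a round trip through [readProteome()]
#' recovers the identical records.
#'
#' @param proteome named \code{AAStringSet}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeProteome <- function(proteome, path) {
    if (!length(proteome))
        stop("refusing to write an empty proteome", call. = FALSE)
    desc <- S4Vectors::mcols(proteome)$description
    out <- proteome
    if (!is.null(desc) && any(nzchar(desc)))
        names(out) <- ifelse(nzchar(desc),
                             paste(names(proteome), desc), names(proteome))
    Biostrings::writeXStringSet(out, filepath = path, width = 60L)
    invisible(path)
}

#' Read and validate PTM site annotations
#'
#' Reads site annotations in either of two tab-separated dialects and checks
#' every row against the proteome: the protein must exist, the position must
#' be within range and the stated residue must equal the sequence letter at
#' that position (1-based); when the PTM type is one of the built-in types,
#' the residue must also belong to its candidate set. Failing rows are
#' rejected and reported, not fatal; if no row survives, an error is raised.
#'
#' The canonical dialect has one row per site with header columns
#' \code{protein_id}, \code{position}, \code{residue}, \code{ptm_type} and
#' optionally \code{organism}. The compact dialect has one row per protein,
#' \code{protein_id<TAB>pos:res:type,pos:res:type,...}, and is detected by
#' the absence of the canonical header.
#'
#' @param path TSV file path.
#' @param proteome named \code{AAStringSet} the annotations refer to.
#' @return A \code{DataFrame} of accepted annotations (columns
#'   \code{protein_id}, \code{position}, \code{residue}, \code{ptm_type},
#'   and \code{organism} when present), ordered by protein then position,
#'   with the rejected rows and their reasons in
#'   \code{metadata(x)$rejected}; see [validationReport()].
#' @examples
#' prot <- Biostrings::AAStringSet(c(P1 = "MKSAPK"))
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\tposition\tresidue\tptm_type",
#'              "P1\t3\tS\tphosphorylation"), f)
#' readSiteAnnotations(f, prot)
#' @export
readSiteAnnotations <- function(path, proteome) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    first <- readLines(path, n = 1L)
    canonical <- grepl("protein_id", first, fixed = TRUE) &&
        grepl("position", first, fixed = TRUE)
    if (canonical) {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                                 colClasses = "character")
        need <- c("protein_id", "position", "residue", "ptm_type")
        if (!all(need %in% names(tab)))
            stop("annotation header must contain columns: ",
                 paste(need, collapse = ", "), call. = FALSE)
    } else {
        lines <- readLines(path)
        lines <- lines[nzchar(trimws(lines))]
        rows <- lapply(lines, function(ln) {
            parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
            if (length(parts) != 2L)
                stop("malformed per-protein annotation line: ", ln,
                     call. = FALSE)
            sites <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
            trip <- strsplit(sites, ":", fixed = TRUE)
            bad <- vapply(trip, length, 0L) != 3L
            if (any(bad))
                stop("malformed site triple in line: ", ln, call. = FALSE)
            data.frame(protein_id = parts[1L],
                       position = vapply(trip, `[`, "", 1L),
                       residue = vapply(trip, `[`, "", 2L),
                       ptm_type = vapply(trip, `[`, "", 3L),
                       stringsAsFactors = FALSE)
        })
        tab <- do.call(rbind, rows)
    }
    validateAnnotations(tab, proteome)
}

#' Validate an in-memory annotation table against a proteome
#'
#' @param tab data.frame-like with columns \code{protein_id},
#'   \code{position}, \code{residue}, \code{ptm_type} (and optionally
#'   \code{organism}).
#' @inheritParams readSiteAnnotations
#' @return As [readSiteAnnotations()].
#' @export
validateAnnotations <- function(tab, proteome) {
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    tab$position <- suppressWarnings(as.integer(tab$position))
    tab$residue <- toupper(trimws(tab$residue))
    n <- nrow(tab)
    reason <- character(n)
    lens <- stats::setNames(Biostrings::width(proteome), names(proteome))
    seqs <- as.character(proteome)
    for (i in seq_len(n)) {
        pid <- tab$protein_id[i]
        pos <- tab$position[i]
        if (!pid %in% names(proteome)) {
            reason[i] <- "unknown protein"
        } else if (is.na(pos) || pos < 1L || pos > lens[[pid]]) {
            reason[i] <- "position out of range"
        } else if (substr(seqs[[pid]], pos, pos) != tab$residue[i]) {
            reason[i] <- sprintf("residue mismatch (sequence has %s)",
                                 substr(seqs[[pid]], pos, pos))
        } else {
            set <- tryCatch(ptmResidues(tab$ptm_type[i]),
                            error = function(e) NULL)
            if (!is.null(set) && !tab$residue[i] %in% set)
                reason[i] <- "residue not in the PTM candidate set"
        }
    }
    rejected <- S4Vectors::DataFrame(row = which(nzchar(reason)),
                                     tab[nzchar(reason), , drop = FALSE],
                                     reason = reason[nzchar(reason)])
    keep <- tab[!nzchar(reason), , drop = FALSE]
    # duplicate site rows collapse to one
    key <- paste(keep$protein_id, keep$position, keep$ptm_type, sep = "\r")
    keep <- keep[!duplicated(key), , drop = FALSE]
    if (!nrow(keep))
        stop("no annotation rows survive validation (",
             nrow(rejected), " rejected)", call. = FALSE)
    keep <- keep[order(keep$protein_id, keep$position), , drop = FALSE]
    rownames(keep) <- NULL
    out <- S4Vectors::DataFrame(keep)
    S4Vectors::metadata(out)$rejected <- rejected
    out
}

#' Rejected-row report of an annotation validation
#'
#' @param annotations the return value of [readSiteAnnotations()] or
#'   [validateAnnotations()].
#' @return \code{DataFrame} of rejected input rows with a \code{reason}
#'   column (zero rows when everything validated).
#' @export
validationReport <- function(annotations) {
    rej <- S4Vectors::metadata(annotations)$rejected
    if (is.null(rej)) S4Vectors::DataFrame() else rej
}

#' Write site annotations as canonical one-row-per-site TSV
#'
#' @param annotations annotation \code{DataFrame} or data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSiteAnnotations <- function(annotations, path) {
    utils::write.table(as.data.frame(annotations), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
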