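#' External blastp search backend
#'
#' The blastp backend shells out to the NCBI \code{makeblastdb} and
#' \code{blastp} executables found on the PATH, requesting tabular output
#' with the BTOP (BLAST traceback operations) column so that per-residue
#' alignment pair maps are available for the strict-center check. Databases
#' are materialised once per unique database content and reused.
#' @name blastp-backend
#' @keywords internal
NULL

.blastdb_cache <- new.env(parent = emptyenv())

.require_tool <- function(tool) {
    path <- Sys.which(tool)
    if (!nzchar(path))
        stop("external backend requires '", tool, "' on the PATH",
             call. = FALSE)
    path
}

.blast_db_path <- function(database) {
    fa <- tempfile(fileext = ".fasta")
    writeLines(paste0(">", names(database), "\n",
                      as.character(database)), fa)
    key <- unname(tools::md5sum(fa))
    if (!is.null(.blastdb_cache[[key]])) {
        unlink(fa)
        return(.blastdb_cache[[key]])
    }
    .require_tool("makeblastdb")
    out <- system2("makeblastdb",
                   c("-in", shQuote(fa), "-dbtype", "prot",
                     "-out", shQuote(fa)),
                   stdout = TRUE, stderr = TRUE)
    status <- attr(out, "status")
    if (!is.null(status) && status != 0L)
        stop("makeblastdb failed: ", paste(out, collapse = "\n"),
             call. = FALSE)
    .blastdb_cache[[key]] <- fa
    fa
}

# Expand a BTOP string into aligned residue-pair coordinates starting at
# (qstart, sstart). Numbers are runs of identities; letter pairs are
# aligned mismatches; '-' on either side is a gap consuming the other
# sequence only.
.parse_btop <- function(btop, qstart, sstart) {
    toks <- regmatches(btop, gregexpr("[0-9]+|[A-Z*-]{2}", btop))[[1L]]
    qp <- integer(0); sp <- integer(0)
    qi <- qstart; si <- sstart
    for (t in toks) {
        if (grepl("^[0-9]+$", t)) {
            k <- as.integer(t)
            if (k > 0L) {
                qp <- c(qp, qi:(qi + k - 1L))
                sp <- c(sp, si:(si + k - 1L))
                qi <- qi + k; si <- si + k
            }
        } else {
            qc <- substr(t, 1L, 1L); sc <- substr(t, 2L, 2L)
            if (qc == "-") {
                si <- si + 1L
            } else if (sc == "-") {
                qi <- qi + 1L
            } else {
                qp <- c(qp, qi); sp <- c(sp, si)
                qi <- qi + 1L; si <- si + 1L
            }
        }
    }
    cbind(qp, sp)
}

.search_blastp <- function(qname, qseq, database, params, short = FALSE) {
    blastp <- .require_tool("blastp")
    db <- .blast_db_path(database)
    qf <- tempfile(fileext = ".fasta")
    on.exit(unlink(qf), add = TRUE)
    writeLines(c(">query", qseq), qf)
    args <- c("-query", shQuote(qf), "-db", shQuote(db),
              "-outfmt", shQuote(paste("6 sseqid evalue bitscore score",
                                       "qstart qend sstart send btop")),
              "-evalue", format(params@evalueCutoff, scientific = TRUE),
              "-max_target_seqs", params@maxTargetSeqs,
              "-gapopen", params@gapOpen, "-gapextend", params@gapExtend,
              "-matrix", params@matrixName)
    if (short)
        args <- c(args, "-task", "blastp-short",
                  "-comp_based_stats", "0", "-seg", "no")
    out <- system2(blastp, args, stdout = TRUE, stderr = TRUE)
    status <- attr(out, "status")
    if (!is.null(status) && status != 0L)
        stop("blastp failed: ", paste(out, collapse = "\n"), call. = FALSE)
    out <- out[nzchar(out) & !startsWith(out, "Warning")]
    if (!length(out)) return(.empty_hits())
    f <- strsplit(out, "\t", fixed = TRUE)
    tab <- data.frame(
        query_id = qname,
        subject_id = vapply(f, `[`, "", 1L),
        raw_score = as.integer(round(as.numeric(vapply(f, `[`, "", 4L)))),
        bit_score = as.numeric(vapply(f, `[`, "", 3L)),
        evalue = as.numeric(vapply(f, `[`, "", 2L)),
        qstart = as.integer(vapply(f, `[`, "", 5L)),
        qend = as.integer(vapply(f, `[`, "", 6L)),
        sstart = as.integer(vapply(f, `[`, "", 7L)),
        send = as.integer(vapply(f, `[`, "", 8L)),
        btop = vapply(f, `[`, "", 9L),
        stringsAsFactors = FALSE)
    # keep only the best HSP per subject (smallest E, then largest score)
    tab <- tab[order(tab$evalue, -tab$raw_score), , drop = FALSE]
    tab <- tab[!duplicated(tab$subject_id), , drop = FALSE]
    pairs <- lapply(seq_len(nrow(tab)), function(i)
        .parse_btop(tab$btop[i], tab$qstart[i], tab$sstart[i]))
    tab$qpos <- lapply(pairs, function(p) as.integer(p[, 1L]))
    tab$spos <- lapply(pairs, function(p) as.integer(p[, 2L]))
    tab$btop <- NULL
    tab$backend <- "blastp"
    .sort_hits(tab, params)
}
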