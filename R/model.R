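.as_proteome <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        readProteome(x)
    else if (methods::is(x, "AAStringSet")) x
    else if (is.character(x) && !is.null(names(x)))
        Biostrings::AAStringSet(x)
    else stop("expected a FASTA path or a named AAStringSet", call. = FALSE)
}

.as_annotations <- function(x, proteome) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        readSiteAnnotations(x, proteome)
    else validateAnnotations(x, proteome)
}

# Content checksum of a character vector, via a canonical temporary file.
.content_md5 <- function(lines) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(lines, f)
    unname(tools::md5sum(f))
}

.proteome_md5 <- function(proteome)
    .content_md5(paste0(">", names(proteome), "\n", as.character(proteome)))

.annotations_md5 <- function(ann) {
    ann <- as.data.frame(ann)
    .content_md5(apply(ann, 1L, paste, collapse = "\t"))
}

#' Build a prediction model (the three search databases)
#'
#' Validates the inputs, extracts the known-peptides database from the
#' annotated sites, and bundles known proteome, known peptides and query
#' proteome together with a manifest of input checksums. The model name is
#' derived from the content checksums, so identical inputs always produce
#' the identically named model, and any of the three databases can be
#' replaced simply by rebuilding with different inputs.
#'
#' @param known known proteome: FASTA path or named \code{AAStringSet}.
#' @param annotations PTM site annotations: TSV path, data.frame or
#'   \code{DataFrame} (validated against \code{known}).
#' @param query query proteome: FASTA path or named \code{AAStringSet}.
#' @param w window half-width (window length 2w+1; default 7).
#' @param ptmType PTM type this model predicts; only annotations of this
#'   type are used.
#' @param residueSet candidate residues for \code{ptmType}.
#' @param backend search backend the model will be used with.
#' @return A \linkS4class{PTMModel}.
#' @examples
#' sc <- syntheticScenario("self_inclusion", seed = 1)
#' buildModel(sc$known, sc$annotations, sc$query, w = 7,
#'            ptmType = "phosphorylation")
#' @export
buildModel <- function(known, annotations, query, w = 7L,
                       ptmType = "phosphorylation",
                       residueSet = ptmResidues(ptmType),
                       backend = c("internal", "blastp")) {
    backend <- match.arg(backend)
    knownProteome <- .as_proteome(known)
    queryProteome <- .as_proteome(query)
    ann <- .as_annotations(annotations, knownProteome)
    ann <- ann[ann$ptm_type == ptmType, , drop = FALSE]
    if (!nrow(ann))
        stop("no valid annotations of type '", ptmType, "'", call. = FALSE)
    peptides <- buildKnownPeptides(knownProteome, ann, w)
    checksums <- c(known_proteome = .proteome_md5(knownProteome),
                   known_peptides = .proteome_md5(windowSequences(peptides)),
                   query_proteome = .proteome_md5(queryProteome),
                   annotations = .annotations_md5(ann))
    name <- paste0("ptm-", ptmType, "-w", w, "-",
                   substr(.content_md5(checksums), 1L, 10L))
    manifest <- list(name = name, created = format(Sys.time(), tz = "UTC"),
                     checksums = checksums,
                     n_known = length(knownProteome),
                     n_peptides = length(peptides),
                     n_query = length(queryProteome))
    new("PTMModel", knownProteome = knownProteome,
        knownPeptides = peptides, queryProteome = queryProteome,
        annotations = ann, w = as.integer(w), ptmType = ptmType,
        residueSet = residueSet, backend = backend, manifest = manifest)
}

#' @describeIn buildModel model manifest (name, creation time, checksums,
#'   database sizes).
#' @param model a \code{PTMModel}.
#' @export
modelManifest <- function(model) model@manifest

#' @describeIn buildModel known-proteome database of a model.
#' @export
knownProteome <- function(model) model@knownProteome

#' @describeIn buildModel query-proteome database of a model.
#' @export
queryProteome <- function(model) model@queryProteome

#' @describeIn buildModel known-peptides database of a model.
#' @export
knownPeptides <- function(model) model@knownPeptides

#' @describeIn buildModel save a model to a directory as plain-text files
#'   (three FASTA databases, annotation TSV and a JSON manifest).
#' @param dir output directory.
#' @export
writeModel <- function(model, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeProteome(model@knownProteome, file.path(dir, "known_proteome.fasta"))
    writeKnownPeptides(model@knownPeptides,
                       file.path(dir, "known_peptides.fasta"))
    writeProteome(model@queryProteome, file.path(dir, "query_proteome.fasta"))
    writeSiteAnnotations(model@annotations,
                         file.path(dir, "annotations.tsv"))
    manifest <- model@manifest
    manifest$w <- model@w
    manifest$ptm_type <- model@ptmType
    manifest$residue_set <- model@residueSet
    manifest$backend <- model@backend
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' @describeIn buildModel load a model previously saved with
#'   \code{writeModel()}; the manifest checksums are re-derived and verified
#'   against the stored ones so silent corruption is caught.
#' @export
readModel <- function(dir) {
    mf <- file.path(dir, "manifest.json")
    if (!file.exists(mf))
        stop("not a model directory (no manifest.json): ", dir,
             call. = FALSE)
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    model <- buildModel(file.path(dir, "known_proteome.fasta"),
                        file.path(dir, "annotations.tsv"),
                        file.path(dir, "query_proteome.fasta"),
                        w = manifest$w, ptmType = manifest$ptm_type,
                        residueSet = manifest$residue_set,
                        backend = manifest$backend)
    if (!identical(unname(modelManifest(model)$checksums),
                   unname(unlist(manifest$checksums))))
        stop("model directory content does not match its manifest: ", dir,
             call. = FALSE)
    model
}

#' Build the organism-holdout model pair (M1 and M2)
#'
#' Reconstructs the two evaluation models used for organism hold-out: M1 is
#' built after removing the held-out organism's PTM data (its annotations
#' and its proteins) from the known proteome, M2 from all data including the
#' held-out organism. Annotations must carry an \code{organism} column; a
#' protein is attributed to the held-out organism when any of its
#' annotations carries that tag.
#'
#' @inheritParams buildModel
#' @param organism tag of the held-out (test) organism.
#' @return list with elements \code{M1} and \code{M2}
#'   (\linkS4class{PTMModel}s).
#' @export
buildHoldoutModels <- function(known, annotations, query, organism,
                               w = 7L, ptmType = "phosphorylation",
                               residueSet = ptmResidues(ptmType),
                               backend = c("internal", "blastp")) {
    backend <- match.arg(backend)
    knownProteome <- .as_proteome(known)
    ann <- .as_annotations(annotations, knownProteome)
    if (!"organism" %in% colnames(ann))
        stop("annotations must carry an 'organism' column for hold-out",
             call. = FALSE)
    if (!organism %in% ann$organism)
        stop("held-out organism '", organism,
             "' absent from the annotations", call. = FALSE)
    heldProteins <- unique(ann$protein_id[ann$organism == organism])
    annM1 <- ann[ann$organism != organism, , drop = FALSE]
    if (!nrow(annM1))
        stop("hold-out removes every annotation; M1 cannot be built",
             call. = FALSE)
    knownM1 <- knownProteome[setdiff(names(knownProteome), heldProteins)]
    list(M1 = buildModel(knownM1, annM1, query, w = w, ptmType = ptmType,
                         residueSet = residueSet, backend = backend),
         M2 = buildModel(knownProteome, ann, query, w = w,
                         ptmType = ptmType, residueSet = residueSet,
                         backend = backend))
}
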