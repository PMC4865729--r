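#' Synthetic proteomes with planted sites and controlled homology
#'
#' The generator emulates the transfer setting end to end without any
#' external data: a "known" proteome of random proteins with planted PTM
#' sites, and a query proteome of point-mutated homologs whose ground truth
#' is the transferred site positions. Mutation draws are made per position
#' before the divergence threshold is applied, so the mutant sets at two
#' divergence levels are nested for a fixed seed (the lower level's
#' mutations are a subset of the higher level's); planted site residues are
#' never mutated so the ground truth stays well defined.
#' @name synthetic
#' @keywords internal
NULL

.with_seed <- function(seed, expr) {
    glob <- globalenv()
    had <- exists(".Random.seed", envir = glob, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = glob) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = glob)
        else suppressWarnings(rm(".Random.seed", envir = glob))
    })
    set.seed(seed)
    force(expr)
}

.bg_freqs <- function(config) {
    switch(config@frequencies,
           uniform = uniformFrequencies(),
           robinson = robinsonFrequencies())
}

.random_protein <- function(len, freqs) {
    paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
          collapse = "")
}

# Point-mutate a sequence: per-position uniform draws and replacement
# residues are generated unconditionally (so mutant sets are nested across
# divergence levels), then applied where the draw falls below `divergence`
# and the position is not protected. Replacements are uniform over the 19
# other standard residues.
.mutate_protein <- function(sequence, divergence, protect = integer(0)) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    len <- length(chars)
    u <- stats::runif(len)
    shift <- sample.int(19L, len, replace = TRUE)
    aa <- aminoAcids()
    idx <- match(chars, aa)
    mut <- which(u < divergence & !seq_len(len) %in% protect & !is.na(idx))
    if (length(mut))
        chars[mut] <- aa[(idx[mut] + shift[mut] - 1L) %% 20L + 1L]
    paste(chars, collapse = "")
}

#' Generate a synthetic known proteome with planted PTM sites
#'
#' Draws \code{nProteins} random proteins and plants 1-based PTM sites at
#' random positions, forcing the planted residue to a member of the
#' configured candidate set. Fully reproducible from \code{config@seed}.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param idPrefix accession prefix for the generated proteins.
#' @param organism organism tag written into the annotations.
#' @return list with \code{proteome} (named \code{AAStringSet}) and
#'   \code{annotations} (\code{DataFrame} with \code{protein_id},
#'   \code{position}, \code{residue}, \code{ptm_type}, \code{organism}).
#' @examples
#' makeKnownProteome(synthConfig(seed = 1, nProteins = 3))
#' @export
makeKnownProteome <- function(config, idPrefix = "KP",
                              organism = "synthetic") {
    methods::validObject(config)
    freqs <- .bg_freqs(config)
    .with_seed(config@seed, {
        seqs <- character(config@nProteins)
        ann <- vector("list", config@nProteins)
        ids <- sprintf("%s%04d", idPrefix, seq_len(config@nProteins))
        for (i in seq_len(config@nProteins)) {
            len <- sample(config@lengthRange[1L]:config@lengthRange[2L], 1L)
            chars <- strsplit(.random_protein(len, freqs), "",
                              fixed = TRUE)[[1L]]
            ns <- sample(
                config@sitesPerProtein[1L]:config@sitesPerProtein[2L], 1L)
            pos <- sort(sample.int(len, min(ns, len)))
            res <- sample(config@residueSet, length(pos), replace = TRUE)
            chars[pos] <- res
            seqs[i] <- paste(chars, collapse = "")
            ann[[i]] <- data.frame(protein_id = ids[i], position = pos,
                                   residue = res,
                                   ptm_type = config@ptmType,
                                   organism = organism,
                                   stringsAsFactors = FALSE)
        }
        proteome <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
        list(proteome = proteome,
             annotations = S4Vectors::DataFrame(do.call(rbind, ann)))
    })
}

#' Derive a query proteome of point-mutated homologs
#'
#' Produces one query protein per known protein by substituting each
#' residue independently with probability \code{config@divergence}
#' (planted site residues are never touched), then appends
#' \code{config@nDecoys} unrelated random decoy proteins that carry no true
#' sites. At divergence 0 the query proteome equals the known proteome.
#'
#' @param known named \code{AAStringSet} of known proteins.
#' @param annotations their planted-site annotations.
#' @param config a \linkS4class{SynthConfig} (supplies divergence, decoys,
#'   seed and background composition).
#' @param ids accessions for the derived proteins (default: same as
#'   \code{known}, so self-inclusion scenarios share identifiers).
#' @return list with \code{proteome} (query \code{AAStringSet}) and
#'   \code{truth} (data.frame of transferred true sites:
#'   \code{protein_id}, \code{position}, \code{residue}, \code{ptm_type}).
#' @export
deriveQueryProteome <- function(known, annotations, config,
                                ids = names(known)) {
    ann <- as.data.frame(annotations)
    freqs <- .bg_freqs(config)
    .with_seed(config@seed + 101L, {
        seqs <- character(length(known))
        kseq <- as.character(known)
        for (i in seq_along(known)) {
            protect <- ann$position[ann$protein_id == names(known)[i]]
            seqs[i] <- .mutate_protein(kseq[[i]], config@divergence,
                                       protect)
        }
        names(seqs) <- ids
        truth <- data.frame(
            protein_id = ids[match(ann$protein_id, names(known))],
            position = ann$position, residue = ann$residue,
            ptm_type = ann$ptm_type, stringsAsFactors = FALSE)
        if (config@nDecoys > 0L) {
            dec <- vapply(seq_len(config@nDecoys), function(j)
                .random_protein(
                    sample(config@lengthRange[1L]:config@lengthRange[2L],
                           1L), freqs), "")
            names(dec) <- sprintf("DEC%03d", seq_len(config@nDecoys))
            seqs <- c(seqs, dec)
        }
        list(proteome = Biostrings::AAStringSet(seqs), truth = truth)
    })
}

#' Named end-to-end synthetic scenarios
#'
#' Builds a complete fixture bundle (known proteome, annotations, query
#' proteome, ground truth) for one of four named settings:
#' \describe{
#'   \item{self_inclusion}{the query proteome is the known proteome and all
#'     sites are present verbatim in the model; every true site should be
#'     recovered (recall 1).}
#'   \item{holdout}{two synthetic organisms, the second derived from the
#'     first at the configured divergence; the query organism's own data can
#'     be held out of the model (tag \code{"orgB"}) for M1/M2 evaluation.}
#'   \item{paralog_trap}{the known proteome additionally contains
#'     unannotated near-duplicates of some annotated proteins, and the query
#'     proteins descend from the duplicates: the local peptide match
#'     succeeds while whole-protein reciprocity fails, so the plain E-value
#'     benchmark accepts transfers the CPE benchmark rejects.}
#'   \item{empty}{query proteins contain no candidate residue at all; the
#'     pipeline must return zero predictions.}
#' }
#' Output is byte-stable for a fixed seed; when \code{dir} is given the
#' bundle is also written as \code{known.fasta}, \code{annotations.tsv},
#' \code{query.fasta} and \code{truth.tsv}.
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param divergence query-homolog divergence used by the \code{holdout}
#'   scenario (default 0.1).
#' @param dir optional output directory for the fixture files.
#' @return list: \code{known}, \code{annotations}, \code{query},
#'   \code{truth}, \code{w}, \code{config}, and for \code{holdout} the tag
#'   \code{heldOrganism}.
#' @examples
#' sc <- syntheticScenario("self_inclusion", seed = 1)
#' length(sc$known)
#' @export
syntheticScenario <- function(name = c("self_inclusion", "holdout",
                                       "paralog_trap", "empty"),
                              seed = 42L, divergence = 0.1, dir = NULL) {
    name <- match.arg(name)
    seed <- as.integer(seed)
    out <- switch(name,
        self_inclusion = .scenario_self_inclusion(seed),
        holdout = .scenario_holdout(seed, divergence),
        paralog_trap = .scenario_paralog_trap(seed),
        empty = .scenario_empty(seed))
    out$w <- 7L
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeProteome(out$known, file.path(dir, "known.fasta"))
        writeSiteAnnotations(out$annotations,
                             file.path(dir, "annotations.tsv"))
        writeProteome(out$query, file.path(dir, "query.fasta"))
        writeSiteAnnotations(out$truth, file.path(dir, "truth.tsv"))
    }
    out
}

# Query proteome identical to the known proteome; the model contains every
# test protein and site verbatim.
.scenario_self_inclusion <- function(seed) {
    cfg <- synthConfig(seed = seed, nProteins = 30L,
                       lengthRange = c(200L, 400L),
                       sitesPerProtein = c(2L, 4L), divergence = 0)
    kn <- makeKnownProteome(cfg, organism = "orgA")
    qu <- deriveQueryProteome(kn$proteome, kn$annotations, cfg)
    list(known = kn$proteome, annotations = kn$annotations,
         query = qu$proteome, truth = qu$truth, config = cfg)
}

# Two organisms: orgB proteins are diverged copies of orgA proteins and
# both contribute annotated sites to the known proteome; the query proteome
# is orgB (plus decoys), so holding out orgB forces prediction through
# cross-organism homology.
.scenario_holdout <- function(seed, divergence) {
    cfg <- synthConfig(seed = seed, nProteins = 10L,
                       lengthRange = c(150L, 250L),
                       sitesPerProtein = c(2L, 3L),
                       divergence = divergence, nDecoys = 3L)
    orgA <- makeKnownProteome(cfg, idPrefix = "A", organism = "orgA")
    orgB <- deriveQueryProteome(orgA$proteome, orgA$annotations, cfg,
                                ids = sub("^A", "B", names(orgA$proteome)))
    annB <- orgB$truth
    annB$organism <- "orgB"
    known <- c(orgA$proteome,
               orgB$proteome[!startsWith(names(orgB$proteome), "DEC")])
    annotations <- S4Vectors::DataFrame(
        rbind(as.data.frame(orgA$annotations), annB))
    list(known = known, annotations = annotations, query = orgB$proteome,
         truth = orgB$truth, heldOrganism = "orgB", config = cfg)
}

# Annotated base proteins plus unannotated near-duplicate paralogs in the
# known proteome; trap queries descend from the paralogs with the site
# windows kept intact, so stage 1 matches the annotated peptide exactly
# while the whole-protein best hit is the paralog.
.scenario_paralog_trap <- function(seed) {
    w <- 7L
    nTrap <- 4L
    cfg <- synthConfig(seed = seed, nProteins = 8L,
                       lengthRange = c(150L, 250L),
                       sitesPerProtein = c(1L, 2L), divergence = 0.02,
                       nDecoys = 2L, paralogTrap = TRUE)
    base <- makeKnownProteome(cfg, idPrefix = "A", organism = "orgA")
    ann <- as.data.frame(base$annotations)
    kseq <- as.character(base$proteome)
    .with_seed(seed + 211L, {
        protectOf <- function(pid) {
            pos <- ann$position[ann$protein_id == pid]
            unique(unlist(lapply(pos, function(p)
                max(1L, p - w):(p + w))))
        }
        # unannotated paralogs of the first nTrap proteins, site windows
        # preserved, 8% divergence elsewhere
        trapIds <- names(base$proteome)[seq_len(nTrap)]
        par <- vapply(trapIds, function(pid)
            .mutate_protein(kseq[[pid]], 0.08, protectOf(pid)), "")
        names(par) <- sub("^A", "PAR", trapIds)
        known <- c(base$proteome, Biostrings::AAStringSet(par))
        # queries: trap queries descend from the paralogs, the rest from
        # the annotated bases; 2% divergence, site windows preserved
        qseqs <- character(length(base$proteome))
        for (i in seq_along(base$proteome)) {
            pid <- names(base$proteome)[i]
            src <- if (pid %in% trapIds) par[[sub("^A", "PAR", pid)]]
                   else kseq[[pid]]
            qseqs[i] <- .mutate_protein(src, cfg@divergence,
                                        protectOf(pid))
        }
        names(qseqs) <- sub("^A", "Q", names(base$proteome))
        freqs <- .bg_freqs(cfg)
        dec <- vapply(seq_len(cfg@nDecoys), function(j)
            .random_protein(sample(150:250, 1L), freqs), "")
        names(dec) <- sprintf("DEC%03d", seq_len(cfg@nDecoys))
        query <- Biostrings::AAStringSet(c(qseqs, dec))
        # ground truth: only sites on queries that descend from annotated
        # proteins; trap positions are not true sites
        keep <- !ann$protein_id %in% trapIds
        truth <- data.frame(
            protein_id = sub("^A", "Q", ann$protein_id[keep]),
            position = ann$position[keep], residue = ann$residue[keep],
            ptm_type = ann$ptm_type[keep], stringsAsFactors = FALSE)
        list(known = known, annotations = base$annotations, query = query,
             truth = truth, trapIds = trapIds, config = cfg)
    })
}

# Query proteins over residues that can never carry the modeled PTM.
.scenario_empty <- function(seed) {
    cfg <- synthConfig(seed = seed, nProteins = 5L,
                       lengthRange = c(100L, 150L),
                       sitesPerProtein = c(1L, 2L))
    kn <- makeKnownProteome(cfg, organism = "orgA")
    .with_seed(seed + 307L, {
        letters_ok <- setdiff(aminoAcids(), cfg@residueSet)
        qs <- vapply(1:4, function(i)
            paste(sample(letters_ok, sample(100:150, 1L), replace = TRUE),
                  collapse = ""), "")
        names(qs) <- sprintf("E%03d", 1:4)
        truth <- data.frame(protein_id = character(),
                            position = integer(), residue = character(),
                            ptm_type = character(),
                            stringsAsFactors = FALSE)
        list(known = kn$proteome, annotations = kn$annotations,
             query = Biostrings::AAStringSet(qs), truth = truth,
             config = cfg)
    })
}
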