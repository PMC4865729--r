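---
title: "Homology-based transfer of PTM sites: model, parameters and design"
author: "PTMTransfer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based transfer of PTM sites: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PTMTransfer)
```

## The problem and the model

Experimentally verified post-translational modification (PTM) sites are
heavily concentrated in a handful of model organisms. For most proteomes
the only practical route to a site-level PTM annotation is transfer by
homology: if a query protein carries a peptide that is essentially
indistinguishable from the context of a verified site in a well-annotated
("known") proteome, the corresponding residue of the query protein is a
credible candidate site.

The naive version of this idea — accept the transfer whenever the peptide
match has a good E-value — has a characteristic failure mode. Peptide
windows are short (15 residues here), so an excellent local match says
little about whether the two *parent proteins* are actually homologous.
A conserved linear motif shared by two unrelated proteins, or by an
annotated protein and an unannotated paralog of the query's true ortholog,
produces a perfect window match and a wrong transfer.

PTMTransfer therefore combines the peptide search with a reciprocal
best-hit criterion at the whole-protein level, the *cross-promotion
E-value* (CPE) benchmark. For each candidate residue of a query protein
$q$ the pipeline runs three searches:

1. **Peptide stage.** The $2w+1$ window centered on the candidate residue
   is searched against the database of known peptides (the windows around
   every verified site). The best-matching known peptide is the *hit
   peptide*; its parent protein $h$ is the *hit protein*.
2. **Hit protein vs query proteome.** $h$ is searched against the whole
   query proteome, giving its smallest E-value $E_h^{best}$ and its
   E-value against the query protein specifically, $E_{h \to q}$.
3. **Query protein vs known proteome.** Symmetrically, $q$ is searched
   against the known proteome, giving $E_q^{best}$ and $E_{q \to h}$.

The transfer is accepted ("verdict yes") only when both directions are
reciprocal:
$$E_{h \to q} \le E_h^{best} \quad\text{and}\quad
  E_{q \to h} \le E_q^{best},$$
i.e. the hit protein's best match in the query proteome *is* the query
protein and vice versa, with exact ties counting as best. The plain
E-value benchmark (`evalueVerdict()`) is implemented alongside for
comparison; because a CPE acceptance presupposes a stage-1 hit under the
same cutoff, the CPE-positive set is by construction a subset of the
E-value-positive set — the reciprocity filter only removes predictions,
which is exactly its point.

### E-value statistics

The built-in search engine scores optimal local alignments
(Smith–Waterman, affine gaps: a gap of length $L$ costs
$\mathrm{open} + L \cdot \mathrm{extend}$) and converts raw scores to
E-values with the Karlin–Altschul formula
$$E = K\,m\,n\,e^{-\lambda S},$$
with $m$ the query length and $n$ the summed residue length of the
database. $\lambda$ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ (bracketed root finding,
relative tolerance $10^{-9}$); $K$ is computed by the standard convergent
series over $k$-fold convolutions of the score distribution,
$$K = \frac{d\,\lambda\,e^{-2\sigma}}{H\,(1 - e^{-\lambda d})},\qquad
\sigma = \sum_{k\ge1}\tfrac1k\left[\mathrm{E}\!\left(e^{\lambda S_k};
S_k<0\right) + P(S_k \ge 0)\right],$$
summed until terms drop below $10^{-12}$. For BLOSUM62 with the
Robinson–Robinson background this reproduces the published ungapped
values ($\lambda \approx 0.3176$, $K \approx 0.134$).

Two deliberate simplifications: the *ungapped* $\lambda$ and $K$ are
applied to gapped scores, and no composition adjustment is made. The CPE
criterion compares E-values *within one search*, where they are a
monotone transform of the raw score, so the verdict depends only on score
order; the absolute E-value scale matters solely for the stage-1 cutoff,
where it is conservative and user-adjustable. Estimating gapped
parameters by simulation was judged complexity without benefit here. The
four E-values of one verdict always come from one backend — the internal
engine and the external `blastp` adapter are never mixed within a
candidate.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `w` | 7 | Window half-width; window length $2w+1 = 15$, the dominant convention for PTM-site models. Configurable per model. |
| `matrixName` | BLOSUM62 | Any BLOSUM/PAM matrix shipped with Biostrings, restricted to the 20 standard residues plus `X`. |
| `gapOpen`, `gapExtend` | 11, 1 | The usual protein-search defaults. |
| `evalueCutoff` | 10 | Threshold for *saving* the stage-1 peptide hit (the conventional protein-search default); also the default threshold of the plain E-value verdict. |
| `maxTargetSeqs` | 500 | Reported-hit cap of a database search. The reciprocal stages internally lift cutoff and cap so that a specific partner's E-value is always observable. |
| `strictCenter` | TRUE | Require the candidate residue to be aligned onto the known window's central (modified) residue; prevents transferring a site onto the wrong residue of a similar peptide. |
| tie tolerance | $10^{-9}$ (relative) | Two E-values within this relative distance are a tie, both in "best match" identity and in stage-1 best-hit selection. |

Padding uses `'X'` (the unknown-residue letter), not a dash or blank:
`X` is legal input to every alignment backend, and its matrix scores are
verified non-positive at load time, so padding can never create
similarity. Coordinates are 1-based inclusive everywhere a user sees
them.

### Tie handling in the peptide stage

Exact ties in stage 1 are not an edge case, they are structural. Two
annotated sites less than $w$ residues apart yield two windows that can
match a candidate window with identical score; and whenever the known
proteome contains two homologs annotated at the equivalent position,
their windows can be identical strings. The pipeline therefore treats
every hit tied at the best E-value as equivalent stage-1 evidence: under
strict-center mode, only center-aligned members of the tie qualify, and
the full pipeline accepts the transfer if *any* tied hit's parent passes
the reciprocity check (`blast1FindHit(allTies = TRUE)`). Without this, a
lexicographic tie-break can hand the verdict to the "wrong" twin of an
identical pair and reject a site whose evidence is impeccable — the
self-inclusion property below would fail for sites that happen to have a
tied twin.

Other tie-breaks are fixed for determinism: hits sort by (E-value,
raw score descending, subject id); the traceback prefers diagonal, then
gap-in-subject, then gap-in-query; among equal-scoring cells the smallest
query index, then subject index, wins. Two runs on identical inputs
produce byte-identical output files.

### Degenerate inputs

Empty sequences, empty databases and empty known-peptide sets are hard
errors; a query id absent from the query proteome is a hard error naming
the id (a query must be a member of its proteome — stage 2 searches it).
Zero surviving annotation rows abort a model build, but individually
failing rows (unknown protein, out-of-range position, residue mismatch,
residue outside the PTM's candidate set) are rejected with a per-row
reason report so one bad line cannot kill a proteome-scale build. A
candidate with no stage-1 hit is silently not a prediction; an absent
pairwise alignment in a reciprocal stage is $E = +\infty$, which can only
produce a "no". Zero predictions give an `NA` precision rather than an
error.

## The synthetic generator

Real inputs to this kind of pipeline are proteome snapshots and curated
site tables, which are large, versioned and external. The package instead
ships a generator (`makeKnownProteome()`, `deriveQueryProteome()`,
`syntheticScenario()`) that produces the same *structure* under
controlled conditions: random proteins (uniform background by default;
Robinson–Robinson composition available) with planted sites whose
residues are forced into the PTM's candidate set, and query proteomes
derived by per-residue point substitution at a configurable divergence,
with planted site residues exempt so ground truth stays well defined.
Substitution draws are made per position *before* the divergence
threshold is applied, so mutant sets are nested across divergence levels
for a fixed seed — recall comparisons across a divergence grid compare
the same realisation, not re-randomised proteomes.

Four named scenarios cover the pipeline's behavioural envelope:

- `self_inclusion` — query proteome equals the known proteome (the "M2"
  construction: every test protein and site is in the model verbatim).
  The defaults are 30 proteins of 200–400 residues with 2–4
  phosphorylation sites each and $w = 7$; the package's acceptance run
  uses exactly these conditions and requires recall $= 1$.
- `holdout` — two synthetic organisms, the second derived from the first;
  holding out the second organism's data (`buildHoldoutModels()`) forces
  prediction through cross-organism homology (the "M1" construction).
- `paralog_trap` — the known proteome additionally contains unannotated
  near-duplicates (8% divergence, site windows preserved) of annotated
  proteins, and the trap queries descend from the duplicates: the peptide
  match is perfect but the query's closest known protein is the paralog,
  so reciprocity fails. This is the constructed analogue of the classic
  false transfer between proteins that share a modified motif without
  being each other's orthologs.
- `empty` — query proteins devoid of candidate residues; the pipeline
  must output nothing.

What the generator does *not* emulate: real site motifs (flanks are
random, so there is no kinase-motif structure around planted sites),
indels (homologs differ by substitutions only, so coordinates transfer
unchanged), domain architecture, and realistic proteome-scale database
sizes. Passing tests on these fixtures therefore demonstrate the
*logic* of the pipeline — windowing arithmetic, E-value ordering,
reciprocity, hold-out bookkeeping, determinism — not its sensitivity or
specificity on real proteomes, which depend on evolutionary distance and
annotation completeness in ways synthetic data cannot represent.

## Problem sizes and numerical checks in the test suite

The suite and the acceptance script are sized to run comfortably on one
CPU: the self-inclusion acceptance run (30 proteins, ~1,350 candidate
residues, ~90 known peptides) takes well under a minute because
whole-proteome reciprocal searches are memoised per protein; the
alignment engine is validated against an exhaustive brute-force
enumeration of local alignments on 220 random string pairs of length at
most 8 (where enumeration over all subsequence pairs is feasible and
independent of the dynamic-programming implementation); $\lambda$ is
checked against its defining identity to $10^{-9}$ and against the
closed form $\lambda = \ln 3$ of the $\pm1$ matrix over a uniform
four-letter alphabet; $K$ is checked against the published BLOSUM62
value. The hold-out determinism check runs the full scenario twice and
compares output files byte for byte.

One empirical note, computed by the test suite itself: on the default
synthetic conditions the M1 hold-out recall stays at 1.0 across the
divergence grid $\{0, 0.05, 0.1, 0.2\}$ — a 15-mer window with about
three substitutions still clears the default cutoff — so the
monotone-recall check is satisfied trivially there. Pushing recall below
1 requires harsher divergence or stricter cutoffs than the defaults.

## Known limitations

- Ungapped E-value statistics applied to gapped scores (order-correct
  within a search, approximate on the absolute scale).
- One optimal local alignment per sequence pair (no sub-optimal HSPs);
  the external blastp adapter keeps only each subject's best HSP for the
  same reason.
- Site transfer assumes positional correspondence through the window
  center; insertions between homologs shift true sites and are out of
  scope of both the generator and the coordinate bookkeeping.
- The annotation dialects (one row per site, or the compact one row per
  protein) are this package's own: no community standard exists for
  site tables.
- Reciprocity is evaluated against the single best match (with ties);
  co-orthologs arising from lineage-specific duplication can fail the
  criterion even when the transfer is biologically right — that is the
  deliberate price of specificity.
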