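---
title: "Methods: domain scanning, binding classification and expression profiling of bHLH families"
author: "bhlhsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain scanning, binding classification and expression profiling of bHLH families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhsurvey)
```

## The biological problem

Basic helix-loop-helix (bHLH) proteins are one of the largest transcription
factor families in plants. The family is defined by a single ~60-residue
domain with four structural regions: an N-terminal *basic region* of about
14–17 residues rich in Lys/Arg/His that contacts DNA, two amphipathic
helices that mediate dimerization, and a connecting *loop* that is the most
variable part of the domain in both length and composition. Whether a given
family member can bind DNA at all — and whether it recognizes the E-box
element (5'-CANNTG-3'), additionally the G-box special case (5'-CACGTG-3'),
or neither — is largely determined by a handful of basic-region residues.
Family surveys therefore follow a standard sequence of steps: find the
domain, partition it, classify the basic region, profile conservation,
build a tree against labeled reference domains from model species to name
subfamilies, call orthologs, and relate all of this to tissue expression.
This package implements each step as a separately testable function and a
composed pipeline (`run_survey()`).

## Domain model and glocal scan

`build_profile()` turns a seed alignment of trusted bHLH domains into a
position-weight profile. Column probabilities use additive pseudocounts,

$$p_j(a) = \frac{n_j(a) + c}{N_j + 20c},$$

where $n_j(a)$ counts residue $a$ in column $j$, $N_j$ is the column's
non-gap count and $c$ is the pseudocount (default 1). Using the non-gap
count as the denominator keeps each column a proper distribution when the
seed alignment is gapped. Scores are log-odds in bits against a uniform
background; columns with more than half gaps are dropped (logged), since a
mostly-absent column carries more alignment artifact than signal. The
unknown-residue code X scores 0 bits everywhere — exactly background — so
runs of X neither attract nor repel the profile, and a protein of only X
can never reach a positive score threshold.

`scan_protein()` aligns the *entire* profile to any substring of the
protein ("glocal": global in the profile, local in the protein) by affine
dynamic programming. The hit score is therefore independent of flank
content, which the tests assert directly. Gap scores default to −4 bits to
open and −1 to extend. Cheap gaps matter here because the loop region
varies in length across the family; a profile that cannot absorb a
one-or-two-column indel would mis-register the helix-2 block, and every
downstream residue-numbered statement (His-2, Glu-7, ..., Lys-50) depends
on register. Both parameters sit in `run_config()`. The acceptance
threshold `min_score` (default 15 bits) is deliberately conservative; no
claim is made that it reproduces any particular published acceptance
boundary, and proteins without a hit are kept in a side table rather than
dropped. Ties are resolved toward the earliest protein position, with
match preferred over insertion over deletion, so the traceback is
deterministic. On small instances the DP score is checked against an
exhaustive recursive enumeration of all gapped placements.

**Coordinates.** All coordinates in this package are 1-based and
inclusive — the R and Biostrings convention — and profile columns are
numbered so that the canonical conserved residues fall at their familiar
positions (His-2, Glu-7, Arg-8, Arg-10, Arg-11 in the basic region; Leu-22
in helix 1; Lys-33/Asp-35 in the loop; Lys-50 in helix 2). Using a single
coordinate convention everywhere, instead of a 0-based internal system with
1-based reports, removes a whole class of off-by-one defects at the cost of
diverging from the habits of languages that index from zero.

`default_regions()` partitions the profile into basic 1–14, helix 1 15–29,
loop 30–36 and helix 2 37–end. The exact basic-region span used for
counting basic residues is a modeling decision, not an established fact —
published conserved basic-region sites stop at position 11 while the region
itself is usually described as ~15 residues — so every span is overridable
in `run_config()`, and overlap between override spans is rejected.

## Binding-category classification

`classify_hit()` reconstructs the four-way basic-region classification in
configurable form (`classifier_rule()`):

1. fewer than `min_basic_residues` (default 6) residues from {K, R, H}
   across the basic-region columns → `NON_BINDING`;
2. otherwise, Glu at column 7 and Arg at column 10 are required for E-box
   recognition; His at column 2 and Arg at column 11 additionally for G-box
   recognition: all four → `EG_BOX`, E-box pair only → `E_BOX_ONLY`,
   anything else → `OTHER_BINDING`.

The literature this rule descends from states the criteria narratively
rather than as a table, so the default is our operationalization mapped
onto the profile numbering above; all published-count comparisons in the
tests are made *against* this rule, never assumed. Two boundary decisions
are fixed and logged: a gap at a required column is an unmet requirement
(not a wildcard) — conservative, and consistent with counting proteins that
lack the basic region as non-binding — and `OTHER_BINDING` means
"binding-competent but failing the E-box residue requirements", since the
narrower readings cannot be distinguished from published counts alone.

`conservation_profile()` reports, per profile column, the modal residue,
its count and its fraction of **all** sequences — gaps stay in the
denominator so heavily gapped columns cannot appear conserved.
`conserved_positions()` applies two tiers: *conserved* columns exceed
`conserved_min_fraction` strictly (default 0.4445, which for 225 sequences
is exactly the "more than 100" rule: 101 qualifies, 100 does not), and
*highly conserved* columns reach `high_min_fraction` (default 0.75)
inclusively. "More than" is read as strict and "approximately 75%" as an
inclusive boundary; both choices are visible in the output tier labels.
`mutation_report()` answers the complementary question — which members
deviate from a reference residue at one column (e.g. Leu-22), with gaps
reported as `lost`.

## Phylogeny and subfamily assignment

Distances are uncorrected p-distances over profile-aligned domains
(mismatches over columns where neither sequence is gapped); pairs with
fewer than 20 comparable columns are flagged, and pairs with none are an
error. No substitution-model correction is applied by default because the
tree consumer here is *subfamily assignment*, which needs local
neighborhood structure rather than calibrated depths; a Poisson-style
correction would rescale, not reorder, the short within-subfamily
distances that drive assignment.

`neighbor_joining()` is a from-scratch Saitou–Nei implementation: join the
pair minimizing $Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$,
assign branch lengths by the standard two-point formulas, reduce the
matrix, and finish with a trifurcation. Ties in $Q$ are broken by the
lexicographically smallest pair of labels (an internal node is labeled by
the smallest leaf beneath it), making output independent of input order;
negative branch-length estimates — a normal NJ artifact — are clamped to
zero with a log entry so serialized Newick stays valid. On additive
matrices the generating tree is recovered exactly (topology and lengths),
and on random matrices the topology is checked against an independent NJ
implementation (`ape::nj`) in the test suite; `ape` is never the
implementation path.

`nj_bootstrap()` resamples profile columns with replacement, rebuilds the
tree per replicate, and counts, for each internal edge of the original
tree, the replicates containing the same leaf bipartition (the default
replicate count in `run_config()` is 1000). `assign_subfamilies()` gives
each query the subfamily of its nearest labeled leaf by patristic distance,
breaking ties by majority label then lexicographically. Queries whose
nearest reference lies beyond `assign_ceiling` (default 0.8) are reported
as *unplaced* rather than forced — this is what lets a query set occupy
fewer subfamilies than the label panel offers, mirroring surveys in which
some reference subfamilies simply have no members in the focal species.
Nearest-labeled-leaf was chosen over clade-majority because published
assignments of this kind are made by inspecting the tree rather than by a
stated algorithm; the nearest-leaf rule is the simplest reproducible
surrogate and its failure mode (an outlier grabbing a distant label) is
exactly what the ceiling suppresses.

## Orthologs, redundancy, chromosomes

`align_local()` wraps Smith–Waterman local alignment with BLOSUM62 and gap
open 11 / extend 1 — protein BLAST's defaults, used here because the
original comparisons were BLAST runs without reported parameters. Percent
identity is computed over aligned residue pairs, excluding gap columns, and
`aligned_length` counts those same pairs, so the two quantities share a
denominator. `call_orthologs()` keeps, per query and partner species, the
best-scoring partner iff aligned length exceeds 60 and identity exceeds
80% — both strictly, so a perfect 60-residue domain match fails and a
61-residue one passes (the domain alone is not enough; some flanking
similarity is required). The filter is one-directional best-hit;
reciprocal-best filtering is a straightforward composition of two calls.
Raising either threshold can only remove rows (monotonicity is a tested
invariant).

`cluster_redundant()` reproduces the *semantics* of cd-hit dereplication —
greedy, longest-first, identity over the shorter sequence, threshold 0.95 —
without its word-filter heuristics, which are a speed device, not part of
the definition. `chromosome_distribution()` tallies gene locations over
the 21 hexaploid wheat chromosomes plus a scaffold bucket, reporting
unmapped genes explicitly so counts always conserve the input.

## Expression analysis

`normalize_expression()` applies the two-stage transform: divide each
sample by the mean FPKM of the reference (housekeeping) genes in that
sample — which cancels any per-sample scale distortion, a tested
equivariance — then standardize each gene row to mean 0, sd 1. Constant
rows cannot be standardized; they are set to 0 and flagged rather than
dropped, so downstream clustering sees every gene. Reference genes are
excluded from the output. A zero or non-finite reference mean in any
sample is an error naming the sample, since silently dividing by it would
poison the whole column.

`cluster_subgroups()` uses complete-linkage agglomeration on Euclidean
distance over the standardized rows — the defaults of the heat-map
clustering tools these analyses conventionally use — cut into exactly `k`
subgroups (default 14). `detect_blocks()` operationalizes "obvious
tissue-specific block" numerically: per subgroup, the mean standardized
value per tissue; the dominant tissue is the argmax and the *specificity
margin* is its lead over the runner-up, flagged when the margin reaches
`margin_threshold` (default 0.5 sd units). The published block structure
is a visual judgment on a heat map; the margin makes that judgment
reproducible and tunable rather than hard-coding any particular
block-to-subgroup mapping.

`qpcr_agreement()` computes per-gene Pearson correlation between RNA-seq
and qPCR values across shared samples on the log2(x+1) scale (raw scale
available), with p-values from the t-distribution on $n-2$ degrees of
freedom. The published correlations do not state their scale;
log2(x+1) is the usual choice for FPKM-vs-relative-expression comparisons
and is recorded here as ours.

## The synthetic-data generator

`generate_family()` emulates the structure the sequence stages assume:
each subfamily descends from a distinct random 60-column archetype domain;
members substitute residues at a configurable per-position rate; each
member's basic region (columns 1–14) is then overwritten with a fixed
template for its assigned binding category, so the category truth always
wins over both archetype and mutation; domains are embedded in random
flanks of configurable length. All archetypes carry the canonical
E/G-box basic region, so a profile built from them has a realistic,
strongly conserved basic region, and members deviate from it only at their
own category-determining residues. Binding-category templates carry 7–8
basic residues and the non-binding template none, so single substitutions
cannot cross the six-residue threshold. Categories are apportioned by
largest remainder of `category_mix` — the default mix is the
133/45/28/19-over-225 partition observed in the wheat family — so a
225-member family carries exactly those counts as planted truth. The
generator is a pure function of its seed (tested byte-identical).

`generate_expression()` emulates the expression stage's assumptions: a
log-normal FPKM background (meanlog 1, sdlog 1 — a simple heavy-tailed
stand-in; no distribution is published for these data), block genes
elevated `block_effect`-fold (default 4) in their tissue, reference genes
with tissue-constant means, multiplicative log-normal measurement noise
(`noise_sd`, default 0.5), and a qPCR panel equal to the FPKM values of up
to six first-tissue block genes under extra multiplicative noise.
`qpcr_noise_sd` defaults to 0.75, calibrated by a 1000-replicate pilot
simulation so the mean per-gene RNA-seq/qPCR correlation sits near 0.7
(95% interval of the replicate mean: 0.587–0.773), comparable to published
RNA-seq/qPCR agreement for this family.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: real domains vary in length (the generator's
are fixed at `domain_length`); real subfamilies differ in size and
divergence; real basic regions vary within a category rather than sharing
a template; FPKM noise is not log-normal with a single sd; and real
reference genes drift. The generator establishes that the machinery is
correct under its stated assumptions, not that any particular biological
census is right.

## Numerical choices and degenerate inputs

* Pseudocount 1 (Laplace) for profiles; pseudocount 0 is allowed and gives
  maximum-likelihood columns.
* Gap scores −4/−1 bits (scan); BLAST's 11/1 penalties (local alignment).
* Strict vs inclusive boundaries: conserved count strictly greater;
  highly-conserved fraction inclusive; ortholog length and identity both
  strictly greater.
* DP tie-breaks: earliest protein position, match > insertion > deletion;
  NJ tie-breaks: lexicographic smallest label pair; clustering tie-breaks
  are inherited from `stats::hclust`, with subgroups renumbered by first
  gene appearance so labels are order-stable.
* Degenerate inputs have defined behavior rather than warnings-and-NA:
  empty FASTA, duplicate ids, ragged alignments, zero-overlap sequence
  pairs, zero reference means, k larger than the gene count, and unlabeled
  leaves are all errors naming the offending record; absence of a domain
  hit is a value (`NULL`), not an error.

## Problem sizes

The shipped tests run the generator at 30–225 proteins, trees at 4–120
leaves, bootstrap at 10–50 replicates, and expression at 20–225 genes ×
6–28 samples; `scripts/acceptance.R` uses the study-scale configuration
(225 proteins, 26-subfamily reference panel, 224-gene seven-block
expression study) and completes in well under two minutes on one CPU.
These sizes were chosen as the smallest that still exercise every rule
and boundary; all of them scale up by changing the spec objects.

## Known limitations

* The profile scan is a PSSM, not a profile HMM: no insert-state emission
  model and no E-value calibration. For family-survey purposes the bit
  threshold plays HMMER's role but is not numerically comparable to it.
* Subfamily assignment depends on reference coverage: a query whose true
  subfamily has no labeled representative will either be mis-assigned to
  the nearest covered subfamily or land beyond the ceiling as unplaced.
* The ortholog filter is sequence-only; no synteny or reciprocal-best
  evidence is consulted unless composed explicitly.
* `cluster_redundant()` is quadratic in the number of sequences; it is
  meant for post-prediction dereplication (hundreds of proteins), not for
  raw assembly output.
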