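blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment under affine gaps (BLAST protein defaults:
#' BLOSUM62, gap open 11, extend 1). `aligned_length` counts aligned residue
#' pairs — gap columns are excluded — so `percent_identity` is
#' `100 * identities / aligned_length`. A best local score <= 0 is reported
#' as an empty alignment rather than an error.
#'
#' @param a,b Single-row [protein_set()]s (or lists with `id`, `sequence`).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11, 1; a gap
#'   of length g costs `gap_open + g * gap_extend`).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return An `alignment_result`: `query_id`, `subject_id`, `aligned_length`,
#'   `identities`, `percent_identity`, `score`.
#' @export
align_local <- function(a, b, gap_open = 11, gap_extend = 1,
                        matrix = NULL) {
  matrix <- matrix %||% blosum62()
  if (!nzchar(a$sequence[1L]) || !nzchar(b$sequence[1L]))
    stop_survey("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(a$sequence[1L], b$sequence[1L],
                                      substitutionMatrix = matrix,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(query_id = a$id[1L], subject_id = b$id[1L],
                          aligned_length = 0L, identities = 0L,
                          percent_identity = 0, score = sc),
                     class = "alignment_result"))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- p != "-" & s != "-"
  ident <- sum(p[both] == s[both])
  alen <- sum(both)
  structure(list(query_id = a$id[1L], subject_id = b$id[1L],
                 aligned_length = alen, identities = ident,
                 percent_identity = if (alen) 100 * ident / alen else 0,
                 score = sc),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d aligned, %.1f%% identity, score %.0f\n",
              x$query_id, x$subject_id, x$aligned_length,
              x$percent_identity, x$score))
  invisible(x)
}

#' Call cross-species orthologs under aligned-length and identity filters
#'
#' For each query protein and each partner species, the best-scoring local
#' alignment is retained iff its aligned length is at least `min_length`
#' (strictly more than `min_length - 1` residue pairs) and its percent
#' identity strictly exceeds `min_identity`. With the defaults this is the
#' "aligned length > 60 and identity > 80%" rule: a perfect 60-residue match
#' fails, a 61-residue one passes. Raising either threshold can only remove
#' rows, never add them.
#'
#' @param queries A [protein_set()] of query (e.g. wheat) proteins.
#' @param references A [protein_set()] with a `species` tag per sequence.
#' @param min_length Minimum aligned length (default 61, i.e. > 60).
#' @param min_identity Exclusive percent-identity bound (default 80).
#' @param gap_open,gap_extend,matrix Alignment parameters, as in
#'   [align_local()].
#' @return An `ortholog_table`: data.frame (`query_id`, `partner_species`,
#'   `partner_id`, `percent_identity`, `aligned_length`, `score`) with a
#'   `summary` attribute counting queries with partners in exactly one or
#'   both of the first two partner species.
#' @export
call_orthologs <- function(queries, references, min_length = 61L,
                           min_identity = 80, gap_open = 11, gap_extend = 1,
                           matrix = NULL) {
  stopifnot(inherits(queries, "protein_set"),
            inherits(references, "protein_set"))
  if (!nrow(queries) || !nrow(references))
    stop_survey("queries and references must be non-empty")
  if (anyNA(references$species))
    stop_survey("every reference needs a species tag")
  species <- unique(references$species)
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- queries[qi, ]
    for (sp in species) {
      refs <- references[references$species == sp, ]
      # one vectorized score pass per query x species; the detailed
      # alignment is only extracted for the best-scoring partner
      scores <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep(q$sequence, nrow(refs))),
        Biostrings::AAStringSet(refs$sequence),
        substitutionMatrix = matrix %||% blosum62(),
        gapOpening = gap_open, gapExtension = gap_extend,
        type = "local", scoreOnly = TRUE)
      best <- align_local(q, refs[which.max(scores), ], gap_open = gap_open,
                          gap_extend = gap_extend, matrix = matrix)
      if (best$aligned_length > min_length - 1L &&
          best$percent_identity > min_identity)
        rows[[length(rows) + 1L]] <-
          data.frame(query_id = q$id, partner_species = sp,
                     partner_id = best$subject_id,
                     percent_identity = best$percent_identity,
                     aligned_length = best$aligned_length,
                     score = best$score, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), partner_species = character(),
               partner_id = character(), percent_identity = numeric(),
               aligned_length = integer(), score = numeric())
  summary <- NULL
  if (length(species) >= 1L) {
    sp1 <- species[1L]
    sp2 <- if (length(species) >= 2L) species[2L] else NA_character_
    has1 <- unique(out$query_id[out$partner_species == sp1])
    has2 <- if (is.na(sp2)) character(0) else
      unique(out$query_id[out$partner_species == sp2])
    summary <- c(only_first = length(setdiff(has1, has2)),
                 only_second = length(setdiff(has2, has1)),
                 both = length(intersect(has1, has2)),
                 total = length(union(has1, has2)))
  }
  structure(out, summary = summary,
            class = c("ortholog_table", "data.frame"))
}

global_identity <- function(a_seq, b_seq) {
  pa <- Biostrings::pairwiseAlignment(a_seq, b_seq,
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1,
                                      type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  both <- p != "-" & s != "-"
  sum(p[both] == s[both]) / min(nchar(a_seq), nchar(b_seq))
}

#' Greedy redundancy clustering at a global-identity threshold
#'
#' Dereplication with cd-hit-style greedy semantics: sequences are sorted by
#' decreasing length (ties by id), each sequence joins the first existing
#' representative whose global identity (identities over the shorter
#' sequence's length) reaches `identity_threshold`, otherwise it founds a
#' new cluster. The word-filter heuristics of cd-hit are not reproduced;
#' only its clustering semantics are.
#'
#' @param records A non-empty [protein_set()].
#' @param identity_threshold Identity threshold in `[0, 1]` (default 0.95).
#' @return A list with `representatives` (a [protein_set()]) and `members`
#'   (named character: id -> representative id).
#' @export
cluster_redundant <- function(records, identity_threshold = 0.95) {
  stopifnot(inherits(records, "protein_set"))
  if (!nrow(records)) stop_survey("no sequences to cluster")
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, ]
  rep_idx <- integer(0)
  members <- stats::setNames(character(nrow(records)), records$id)
  for (k in seq_len(nrow(records))) {
    assigned <- FALSE
    for (r in rep_idx) {
      if (global_identity(records$sequence[r], records$sequence[k]) >=
          identity_threshold) {
        members[records$id[k]] <- records$id[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, k)
      members[records$id[k]] <- records$id[k]
    }
  }
  list(representatives = records[rep_idx, ], members = members)
}

#' Per-chromosome counts of a gene list
#'
#' @param loc A location data.frame as from [read_locations()].
#' @param genes Character vector of gene ids to tally.
#' @param universe Chromosome names defining the count vector (default: the
#'   21 hexaploid wheat chromosomes plus `"scaffold"`); locations outside the
#'   universe are counted under `"scaffold"`.
#' @return A list with `counts` (named integer over the universe) and
#'   `unmapped` (ids absent from `loc`); `sum(counts) + length(unmapped)`
#'   always equals `length(genes)`.
#' @export
chromosome_distribution <- function(loc, genes,
                                    universe = wheat_chromosomes()) {
  hit <- genes %in% loc$gene
  counts <- stats::setNames(integer(length(universe)), universe)
  if (any(hit)) {
    chrom <- loc$chrom[match(genes[hit], loc$gene)]
    chrom[!chrom %in% universe] <- "scaffold"
    tab <- table(factor(chrom, levels = universe))
    counts <- stats::setNames(as.integer(tab), universe)
  }
  list(counts = counts, unmapped = genes[!hit])
}

#' The 21 chromosomes of hexaploid wheat, plus a scaffold bucket
#' @return Character vector `1A`..`7D`, `"scaffold"`.
#' @export
wheat_chromosomes <- function() {
  c(paste0(rep(1:7, each = 3), c("A", "B", "D")), "scaffold")
}
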