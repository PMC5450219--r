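#' Uncorrected p-distance between aligned domains
#'
#' `d(i,j)` is the fraction of mismatched residues over columns where neither
#' sequence has a gap. Pairs with fewer than `min_comparable` comparable
#' columns are flagged (attribute `flagged`); a pair with no comparable
#' columns at all is an error naming the pair.
#'
#' @param aligned A [protein_set()] of >= 3 domain sequences in common
#'   (profile) coordinates, e.g. `scan$aligned`.
#' @param min_comparable Columns below which a pair is flagged (default 20).
#' @return A symmetric numeric matrix with id dimnames, zero diagonal, and a
#'   `flagged` attribute (data.frame of low-overlap pairs).
#' @export
p_distance <- function(aligned, min_comparable = 20L) {
  stopifnot(inherits(aligned, "protein_set"))
  if (nrow(aligned) < 3L) stop_survey("p_distance needs >= 3 sequences")
  mat <- seq_to_matrix(aligned$sequence)
  ids <- aligned$id
  pdist_from_matrix(mat, ids, min_comparable)
}

pdist_from_matrix <- function(mat, ids, min_comparable = 20L) {
  n <- nrow(mat)
  ok <- mat != GAP_CHAR
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop_survey("no comparable columns between '", ids[i], "' and '",
                    ids[j], "'")
      d[i, j] <- d[j, i] <- sum(mat[i, comp] != mat[j, comp]) / nc
      if (nc < min_comparable)
        flagged[[length(flagged) + 1L]] <-
          data.frame(id1 = ids[i], id2 = ids[j], comparable = nc,
                     stringsAsFactors = FALSE)
    }
  }
  attr(d, "flagged") <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(id1 = character(), id2 = character(), comparable = integer())
  d
}

fmt_len <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' branch lengths from the standard two-point formulas; ties in Q are broken
#' by the lexicographically smallest pair of node labels (an internal node is
#' labeled by the smallest leaf label beneath it). The result is unrooted
#' with one trifurcating root. Negative branch-length estimates are clamped
#' to zero and the original value logged.
#'
#' @param dm Symmetric numeric matrix with zero diagonal, finite entries and
#'   unique id dimnames; n >= 3. Output of [p_distance()] qualifies.
#' @return An `ape` `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  n <- nrow(dm)
  if (n < 3L) stop_survey("neighbor joining needs >= 3 taxa")
  if (is.null(ids) || anyDuplicated(ids))
    stop_survey("distance matrix needs unique id dimnames")
  if (any(!is.finite(dm))) stop_survey("non-finite distances")
  if (max(abs(dm - t(dm))) > 1e-12) stop_survey("distance matrix not symmetric")

  newick <- ids            # growing subtree strings per active node
  reps <- ids              # lexicographic representative per active node
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    max(x, 0)
  }
  while (nrow(dm) > 3L) {
    m <- nrow(dm)
    R <- rowSums(dm)
    Q <- (m - 2) * dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(reps[cand[k, 1L]], reps[cand[k, 2L]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    li <- clamp(li); lj <- clamp(lj)
    new_nwk <- paste0("(", newick[i], ":", fmt_len(li), ",",
                      newick[j], ":", fmt_len(lj), ")")
    new_rep <- min(reps[i], reps[j])
    du <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    newick <- c(newick[keep], new_nwk)
    reps <- c(reps[keep], new_rep)
    rownames(dm) <- colnames(dm) <- reps
  }
  la <- clamp((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2)
  lb <- clamp((dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2)
  lc <- clamp((dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
  ord <- order(reps)
  lens <- c(la, lb, lc)[ord]
  parts <- paste0(newick[ord], ":", fmt_len(lens))
  if (clamped > 0L)
    survey_log("INFO", clamped, " negative branch length(s) clamped to 0")
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples profile columns with replacement `R` times, recomputes
#' [p_distance()] and [neighbor_joining()] for each replicate, and records
#' for every internal edge of the original tree the number of replicates
#' whose tree contains the same leaf bipartition. Supports are stored as
#' integer `node.label`s (counts out of `R`).
#'
#' @param aligned A [protein_set()] of aligned domains (>= 4 sequences for
#'   supports to be informative).
#' @param R Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param min_comparable Passed to [p_distance()].
#' @return The original NJ tree with `node.label` supports and attribute
#'   `replicates = R`.
#' @export
nj_bootstrap <- function(aligned, R = 1000L, seed = 1L,
                         min_comparable = 20L) {
  stopifnot(inherits(aligned, "protein_set"))
  if (!is_count(R) || R < 1L) stop_survey("R must be a positive integer")
  mat <- seq_to_matrix(aligned$sequence)
  ids <- aligned$id
  main <- neighbor_joining(pdist_from_matrix(mat, ids, min_comparable))
  set.seed(seed)
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    reps[[r]] <- neighbor_joining(
      pdist_from_matrix(mat[, cols, drop = FALSE], ids, min_comparable))
  }
  class(reps) <- "multiPhylo"
  supp <- suppressWarnings(ape::prop.clades(main, reps, rooted = FALSE))
  supp[is.na(supp)] <- 0L
  main$node.label <- as.character(as.integer(supp))
  attr(main, "replicates") <- R
  main
}

#' Assign subfamilies to query leaves from labeled reference leaves
#'
#' Each query leaf takes the subfamily of its nearest labeled leaf by
#' patristic distance (sum of branch lengths along the tree path). Distance
#' ties are broken by the majority subfamily among the tied references, then
#' lexicographically. Queries whose nearest reference lies beyond `ceiling`
#' are reported as unplaced rather than forced into a subfamily.
#'
#' @param tree A `phylo` containing both query and reference leaves.
#' @param labels Named character vector: reference leaf id -> subfamily.
#' @param ceiling Patristic-distance ceiling (default 0.8).
#' @return data.frame (`query_id`, `subfamily`, `reference_id`, `distance`,
#'   `placed`); `subfamily` is `NA` for unplaced queries.
#' @export
assign_subfamilies <- function(tree, labels, ceiling = 0.8) {
  stopifnot(inherits(tree, "phylo"))
  labels <- labels[!is.na(labels)]
  refs <- intersect(names(labels), tree$tip.label)
  if (!length(refs)) stop_survey("no labeled reference leaves in the tree")
  queries <- setdiff(tree$tip.label, names(labels))
  pat <- stats::cophenetic(tree)
  rows <- lapply(queries, function(q) {
    dq <- pat[q, refs]
    dmin <- min(dq)
    tied <- refs[dq - dmin < 1e-12]
    fams <- sort(table(labels[tied]), decreasing = TRUE)
    fam <- names(fams)[fams == fams[1L]]
    fam <- sort(fam)[1L]
    ref <- sort(tied[labels[tied] == fam])[1L]
    placed <- dmin <= ceiling
    data.frame(query_id = q,
               subfamily = if (placed) fam else NA_character_,
               reference_id = ref, distance = dmin, placed = placed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(query_id = character(), subfamily = character(),
               reference_id = character(), distance = numeric(),
               placed = logical())
  out
}
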