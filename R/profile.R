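#' Build a position-weight profile from a seed alignment of bHLH domains
#'
#' Column probabilities are `(count + pseudocount) / (n + 20 * pseudocount)`
#' where `n` counts the non-gap residues in the column; scores are log-odds
#' against the background in bits. Columns with more than 50% gaps are
#' dropped (and the drop logged), so the profile length can be shorter than
#' the input alignment.
#'
#' @param aligned A [protein_set()] (or character vector) of >= 2 aligned
#'   sequences of equal length; `-` marks gaps.
#' @param pseudocount Additive pseudocount (default 1).
#' @param background Length-20 probability vector over [AA_ALPHABET20]
#'   (default uniform 1/20).
#' @return A `domain_profile` with elements `length`, `probs` (20 x length),
#'   `weights` (21 x length, bits; row `X` scores 0 everywhere), `consensus`,
#'   and `kept_columns` (indices into the input alignment).
#' @export
build_profile <- function(aligned, pseudocount = 1,
                          background = rep(1 / 20, 20)) {
  seqs <- if (inherits(aligned, "protein_set")) aligned$sequence
          else toupper(as.character(aligned))
  if (length(seqs) < 2L) stop_survey("need >= 2 aligned sequences")
  mat <- seq_to_matrix(seqs)
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-9)
    stop_survey("background must be 20 probabilities summing to 1")
  gap_frac <- colMeans(mat == GAP_CHAR)
  keep <- which(gap_frac <= 0.5)
  if (length(keep) < ncol(mat))
    survey_log("INFO", "dropped ", ncol(mat) - length(keep),
               " column(s) with > 50% gaps")
  if (length(keep) < 30L)
    stop_survey("profile too short after gap filtering (", length(keep),
                " < 30 columns)")
  probs <- vapply(keep, function(j) {
    col <- mat[, j]
    col <- col[col != GAP_CHAR]
    counts <- table(factor(col, levels = AA_ALPHABET20))
    (as.numeric(counts) + pseudocount) /
      (length(col) + 20 * pseudocount)
  }, numeric(20))
  rownames(probs) <- AA_ALPHABET20
  weights <- log2(probs / background)
  weights <- rbind(weights, X = 0)           # ambiguity scores as background
  structure(list(length = length(keep), probs = probs, weights = weights,
                 consensus = AA_ALPHABET20[apply(probs, 2L, which.max)],
                 pseudocount = pseudocount, background = background,
                 kept_columns = keep),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("domain_profile:", x$length, "columns; consensus",
      paste(x$consensus, collapse = ""), "\n")
  invisible(x)
}

#' Locate the best profile hit in a protein (glocal scan)
#'
#' Aligns the *full* profile against any substring of the protein
#' (global in the profile, local in the protein) by affine-gap dynamic
#' programming. Flanking protein residues outside the hit are free, so the
#' score does not depend on flank content. Returns the maximum-scoring hit if
#' its score reaches `min_score`, otherwise `NULL`; absence of a domain is a
#' value, not an error. Score ties are resolved toward the earliest protein
#' position, and among DP states match is preferred over insertion over
#' deletion, making the traceback deterministic.
#'
#' @param profile A [build_profile()] result.
#' @param protein A single-row [protein_set()] (or a list with `id` and
#'   `sequence`); length >= 10.
#' @param min_score Acceptance threshold in bits (default 15).
#' @param gap_open,gap_extend Affine gap scores in bits (defaults -4, -1);
#'   a gap of length g scores `gap_open + (g - 1) * gap_extend`.
#' @return A `domain_hit` (`protein_id`, `start`, `end` 1-based inclusive,
#'   `score`, `column_map` with one protein index or `NA` per profile
#'   column) or `NULL`.
#' @export
scan_protein <- function(profile, protein, min_score = 15,
                         gap_open = -4, gap_extend = -1) {
  stopifnot(inherits(profile, "domain_profile"))
  id <- protein$id[1L]
  seq <- protein$sequence[1L]
  L <- nchar(seq)
  if (L < 10L) stop_survey("protein '", id, "' shorter than 10 residues")
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  W <- profile$length
  emit <- profile$weights[res, , drop = FALSE]   # L x W emission scores

  NEG <- -Inf
  M  <- matrix(NEG, L + 1L, W + 1L)
  Ix <- matrix(NEG, L + 1L, W + 1L)              # protein residue inserted
  Iy <- matrix(NEG, L + 1L, W + 1L)              # profile column deleted
  M[, 1L] <- 0                                    # free protein prefix (j = 0)
  # leading deletions from the free start of row i = 0
  jj <- seq_len(W)
  Iy[1L, jj + 1L] <- gap_open + (jj - 1L) * gap_extend
  for (i in seq_len(L)) {
    prev_best <- pmax(M[i, ], Ix[i, ], Iy[i, ])
    row_m <- c(0, emit[i, ] + prev_best[seq_len(W)])
    M[i + 1L, ] <- row_m
    Ix[i + 1L, ] <- pmax(M[i, ] + gap_open, Ix[i, ] + gap_extend)
    Ix[i + 1L, 1L] <- NEG
    # Iy[i+1, j] = max_{k < j} M[i+1, k] + gap_open + (j-1-k) * gap_extend
    a <- cummax(row_m[seq_len(W)] - (0:(W - 1L)) * gap_extend)
    Iy[i + 1L, jj + 1L] <- gap_open + (jj - 1L) * gap_extend + a
  }

  finals <- pmax(M[, W + 1L], Iy[, W + 1L])
  best <- max(finals)
  if (!is.finite(best) || best < min_score) return(NULL)
  i <- which(finals == best)[1L] - 1L            # earliest protein end
  state <- if (M[i + 1L, W + 1L] >= Iy[i + 1L, W + 1L]) "M" else "Iy"
  column_map <- rep(NA_integer_, W)
  j <- W
  while (j > 0L) {
    if (state == "M") {
      column_map[j] <- i
      val <- M[i + 1L, j + 1L] - emit[i, j]
      cand <- c(M = M[i, j], Ix = Ix[i, j], Iy = Iy[i, j])
      state <- names(cand)[which(abs(cand - val) < 1e-9)[1L]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {
      val <- Ix[i + 1L, j + 1L]
      state <- if (abs(M[i, j + 1L] + gap_open - val) < 1e-9) "M" else "Ix"
      i <- i - 1L
    } else {                                     # Iy: column j unmatched
      val <- Iy[i + 1L, j + 1L]
      state <- if (abs(M[i + 1L, j] + gap_open - val) < 1e-9) "M" else "Iy"
      j <- j - 1L
    }
  }
  matched <- column_map[!is.na(column_map)]
  structure(list(protein_id = id,
                 start = if (length(matched)) min(matched) else NA_integer_,
                 end = if (length(matched)) max(matched) else NA_integer_,
                 score = best, column_map = column_map),
            class = "domain_hit")
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("domain_hit: %s [%d-%d] score %.2f bits\n",
              x$protein_id, x$start, x$end, x$score))
  invisible(x)
}

#' Extract the hit's domain sequence in profile coordinates
#'
#' One character per profile column: the aligned residue, or `-` where the
#' column is deleted in this protein.
#'
#' @param hit A `domain_hit`.
#' @param record The matching single-row [protein_set()].
#' @return A string of length `length(hit$column_map)`.
#' @export
domain_sequence <- function(hit, record) {
  res <- strsplit(record$sequence[1L], "", fixed = TRUE)[[1L]]
  out <- rep(GAP_CHAR, length(hit$column_map))
  ok <- !is.na(hit$column_map)
  out[ok] <- res[hit$column_map[ok]]
  paste(out, collapse = "")
}

#' Scan a whole protein set against a profile
#'
#' Proteins without an accepted hit are retained in the summary table with
#' `NA` coordinates (a side table of misses, never a silent drop).
#'
#' @inheritParams scan_protein
#' @param records A [protein_set()].
#' @return A `scan_result`: `hits` (named list of `domain_hit` / `NULL`),
#'   `table` (one row per protein), and `aligned` (a [protein_set()] of
#'   domain sequences in profile coordinates, hits only).
#' @export
scan_proteins <- function(profile, records, min_score = 15,
                          gap_open = -4, gap_extend = -1) {
  stopifnot(inherits(records, "protein_set"))
  hits <- lapply(seq_len(nrow(records)), function(k)
    scan_protein(profile, records[k, ], min_score, gap_open, gap_extend))
  names(hits) <- records$id
  tab <- data.frame(
    protein_id = records$id,
    start = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h$start,
                   integer(1)),
    end = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h$end,
                 integer(1)),
    score = vapply(hits, function(h) if (is.null(h)) NA_real_ else h$score,
                   numeric(1)),
    stringsAsFactors = FALSE)
  with_hit <- !vapply(hits, is.null, logical(1))
  aligned <- NULL
  if (any(with_hit)) {
    dom <- vapply(which(with_hit), function(k)
      domain_sequence(hits[[k]], records[k, ]), character(1))
    aligned <- protein_set(records$id[with_hit], dom,
                           species = records$species[with_hit],
                           subfamily = records$subfamily[with_hit])
  }
  structure(list(hits = hits, table = tab, aligned = aligned,
                 profile_length = profile$length),
            class = "scan_result")
}

#' Default partition of the profile into structural regions
#'
#' 1-based inclusive profile-column spans: basic 1-14, helix 1 15-29, loop
#' 30-36, helix 2 37-end; each span can be overridden. This numbering places
#' the canonical conserved basic-region sites (His-2, Glu-7, Arg-8, Arg-10,
#' Arg-11) inside the basic span.
#'
#' @param profile A `domain_profile` (length >= 50 unless every span is
#'   overridden).
#' @param basic,helix1,loop,helix2 Optional length-2 integer vectors
#'   `c(first, last)`.
#' @return A `region_partition`.
#' @export
default_regions <- function(profile, basic = NULL, helix1 = NULL,
                            loop = NULL, helix2 = NULL) {
  len <- profile$length
  all_over <- !is.null(basic) && !is.null(helix1) && !is.null(loop) &&
    !is.null(helix2)
  if (len < 50L && !all_over)
    stop_survey("profile has ", len,
                " columns (< 50); supply explicit region spans")
  region_partition(basic = basic %||% c(1L, 14L),
                   helix1 = helix1 %||% c(15L, 29L),
                   loop = loop %||% c(30L, 36L),
                   helix2 = helix2 %||% c(37L, len),
                   profile_length = len)
}

#' Construct a validated region partition
#'
#' @param basic,helix1,loop,helix2 Length-2 integer spans (1-based
#'   inclusive profile columns); must be disjoint, in order, within the
#'   profile.
#' @param profile_length Number of profile columns.
#' @return A `region_partition` list of spans.
#' @export
region_partition <- function(basic, helix1, loop, helix2, profile_length) {
  spans <- list(basic = basic, helix1 = helix1, loop = loop, helix2 = helix2)
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2L || s[1L] > s[2L] || s[1L] < 1L ||
        s[2L] > profile_length)
      stop_survey("invalid span for ", nm, ": must be c(first, last) within 1..",
                  profile_length)
  }
  ends <- vapply(spans, `[`, numeric(1), 2L)
  starts <- vapply(spans, `[`, numeric(1), 1L)
  if (any(starts[-1L] <= ends[-length(ends)]))
    stop_survey("region spans must be disjoint and ordered ",
                "basic < helix1 < loop < helix2")
  structure(c(spans, list(profile_length = profile_length)),
            class = "region_partition")
}

region_columns <- function(regions, name) {
  s <- regions[[name]]
  seq.int(s[1L], s[2L])
}
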