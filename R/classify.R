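#' The four DNA-binding categories
#'
#' Category labels used throughout: `EG_BOX` (binds both E-box CANNTG and
#' G-box CACGTG), `E_BOX_ONLY`, `OTHER_BINDING` (binding-competent basic
#' region failing the E-box residue requirements) and `NON_BINDING` (too few
#' basic residues to contact DNA).
#' @export
BINDING_CATEGORIES <- c("EG_BOX", "E_BOX_ONLY", "OTHER_BINDING", "NON_BINDING")

#' Classifier rule for the basic region
#'
#' Encodes the residue criteria used to call DNA-binding ability from the
#' basic region: a minimum number of basic residues (K/R/H) for any binding
#' at all, column/residue requirements for E-box recognition, and additional
#' requirements that upgrade an E-box binder to an E/G-box binder. Columns
#' are 1-based profile columns and must fall inside the basic-region span.
#'
#' @param min_basic_residues Minimum count of `basic_residue_set` members in
#'   the basic region (default 6).
#' @param basic_residue_set Residues counted as basic (default K, R, H).
#' @param ebox_requirements Named list of required residues for E-box
#'   binding, as `list(column = residue)` pairs; default Glu at column 7 and
#'   Arg at column 10.
#' @param gbox_extra_requirements Additional requirements for G-box
#'   recognition; default His at column 2 and Arg at column 11.
#' @return A `classifier_rule`.
#' @export
classifier_rule <- function(min_basic_residues = 6L,
                            basic_residue_set = c("K", "R", "H"),
                            ebox_requirements = list("7" = "E", "10" = "R"),
                            gbox_extra_requirements = list("2" = "H",
                                                           "11" = "R")) {
  structure(list(min_basic_residues = as.integer(min_basic_residues),
                 basic_residue_set = basic_residue_set,
                 ebox_requirements = ebox_requirements,
                 gbox_extra_requirements = gbox_extra_requirements),
            class = "classifier_rule")
}

residue_at <- function(hit, record, column) {
  idx <- hit$column_map[column]
  if (is.na(idx)) return(GAP_CHAR)
  substr(record$sequence[1L], idx, idx)
}

#' Classify one domain hit into a DNA-binding category
#'
#' Counts basic residues over the basic-region columns of the hit; below the
#' rule's minimum the protein is `NON_BINDING`. Otherwise the E-box residue
#' requirements are checked, then the G-box extras: all of both gives
#' `EG_BOX`, E-box only gives `E_BOX_ONLY`, anything else `OTHER_BINDING`.
#' A gap at a required column counts as an unmet requirement, never as a
#' wildcard.
#'
#' @param hit A `domain_hit`.
#' @param record The matching single-row [protein_set()].
#' @param regions A [region_partition()].
#' @param rule A [classifier_rule()].
#' @return One of [BINDING_CATEGORIES], with attributes `n_basic` and
#'   `rule_hits` (named logical over all required columns).
#' @export
classify_hit <- function(hit, record, regions, rule = classifier_rule()) {
  basic_cols <- region_columns(regions, "basic")
  req_cols <- as.integer(c(names(rule$ebox_requirements),
                           names(rule$gbox_extra_requirements)))
  if (any(req_cols < regions$basic[1L] | req_cols > regions$basic[2L]))
    stop_survey("classifier rule column(s) outside the basic-region span")
  res <- vapply(basic_cols, residue_at, character(1), hit = hit,
                record = record)
  n_basic <- sum(res %in% rule$basic_residue_set)
  meets <- function(reqs) vapply(seq_along(reqs), function(k) {
    identical(residue_at(hit, record, as.integer(names(reqs)[k])),
              reqs[[k]])
  }, logical(1))
  e_ok <- meets(rule$ebox_requirements)
  g_ok <- meets(rule$gbox_extra_requirements)
  cat_out <- if (n_basic < rule$min_basic_residues) "NON_BINDING"
    else if (all(e_ok) && all(g_ok)) "EG_BOX"
    else if (all(e_ok)) "E_BOX_ONLY"
    else "OTHER_BINDING"
  structure(cat_out, n_basic = n_basic,
            rule_hits = stats::setNames(c(e_ok, g_ok),
                                        c(names(rule$ebox_requirements),
                                          names(rule$gbox_extra_requirements))))
}

#' Classify every hit of a scan
#'
#' @param scan A [scan_proteins()] result.
#' @param records The scanned [protein_set()].
#' @inheritParams classify_hit
#' @return A data.frame (`protein_id`, `category`, `n_basic_residues`,
#'   `rule_hits`); proteins without a domain hit are omitted. The category
#'   counts over the output always partition the classified set.
#' @export
classify_proteins <- function(scan, records, regions,
                              rule = classifier_rule()) {
  stopifnot(inherits(scan, "scan_result"))
  with_hit <- names(scan$hits)[!vapply(scan$hits, is.null, logical(1))]
  rows <- lapply(with_hit, function(id) {
    rec <- records[records$id == id, ]
    cl <- classify_hit(scan$hits[[id]], rec, regions, rule)
    data.frame(protein_id = id, category = as.character(cl),
               n_basic_residues = attr(cl, "n_basic"),
               rule_hits = paste0(names(attr(cl, "rule_hits")), ":",
                                  ifelse(attr(cl, "rule_hits"), "y", "n"),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-column conservation of a domain family
#'
#' For every profile column, the modal residue over non-gap entries, its
#' count and its fraction of *all* sequences (gaps stay in the denominator,
#' so a heavily gapped column can never look conserved).
#'
#' @param aligned A [protein_set()] of domain sequences in profile
#'   coordinates (e.g. `scan$aligned`); >= 2 sequences.
#' @param conserved_min_fraction Strict lower bound on the modal fraction for
#'   the "conserved" tier (default 0.4445, the more-than-100-of-225 rule).
#' @param high_min_fraction Inclusive bound for "highly conserved"
#'   (default 0.75).
#' @return A `conservation_profile`: data.frame (`column`, `modal_residue`,
#'   `count`, `fraction`) plus `n_sequences` and the two thresholds as
#'   attributes.
#' @export
conservation_profile <- function(aligned, conserved_min_fraction = 0.4445,
                                 high_min_fraction = 0.75) {
  if (is.null(aligned) || nrow(aligned) < 2L)
    stop_survey("conservation profile needs >= 2 aligned domains")
  mat <- seq_to_matrix(aligned$sequence)
  n <- nrow(mat)
  per_col <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != GAP_CHAR & col != "X"]
    if (!length(col))
      return(data.frame(column = j, modal_residue = GAP_CHAR, count = 0L,
                        fraction = 0, stringsAsFactors = FALSE))
    tab <- sort(table(col), decreasing = TRUE)
    data.frame(column = j, modal_residue = names(tab)[1L],
               count = as.integer(tab[1L]), fraction = as.integer(tab[1L]) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_col)
  structure(out, n_sequences = n,
            conserved_min_fraction = conserved_min_fraction,
            high_min_fraction = high_min_fraction,
            class = c("conservation_profile", "data.frame"))
}

#' Conserved and highly conserved profile columns
#'
#' "Conserved" columns have a modal-residue count strictly greater than
#' `conserved_min_fraction * n` (with the default fraction and n = 225 this
#' is the "in more than 100 sequences" rule); "highly conserved" columns have
#' a modal fraction at or above `high_min_fraction` (inclusive boundary).
#'
#' @param profile A [conservation_profile()].
#' @return A list with integer vectors `conserved` and `highly_conserved`.
#' @export
conserved_positions <- function(profile) {
  n <- attr(profile, "n_sequences")
  cmf <- attr(profile, "conserved_min_fraction")
  hmf <- attr(profile, "high_min_fraction")
  list(conserved = profile$column[profile$count > cmf * n],
       highly_conserved = profile$column[profile$fraction >= hmf])
}

#' Report deviations from a reference residue at one profile column
#'
#' Lists every domain whose residue at `column` differs from
#' `reference_residue`; a gap at the column is reported as `"lost"`.
#' Useful for questions like "which family members mutated or lost the
#' canonical Leu at helix-1 column 22?".
#'
#' @param aligned A [protein_set()] of domains in profile coordinates.
#' @param column 1-based profile column.
#' @param reference_residue Single residue letter.
#' @return data.frame (`protein_id`, `observed_residue`).
#' @export
mutation_report <- function(aligned, column, reference_residue) {
  mat <- seq_to_matrix(aligned$sequence)
  if (column < 1L || column > ncol(mat))
    stop_survey("column ", column, " outside profile (1..", ncol(mat), ")")
  obs <- mat[, column]
  differs <- obs != reference_residue
  data.frame(protein_id = aligned$id[differs],
             observed_residue = ifelse(obs[differs] == GAP_CHAR, "lost",
                                       obs[differs]),
             stringsAsFactors = FALSE)
}
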