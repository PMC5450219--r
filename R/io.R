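#' Construct a protein set
#'
#' The package's basic sequence container: a `data.frame` with class
#' `protein_set` holding one row per protein. Sequences are uppercased and
#' any character outside the 20 amino-acid letters (plus `X`) is replaced by
#' `X` with a warning, so translated assemblies carrying ambiguity codes can
#' be ingested without loss of the record.
#'
#' @param id Character vector of unique, non-empty accessions.
#' @param sequence Character vector of amino-acid sequences (length >= 1 each).
#' @param species Optional character vector of free-text species tags.
#' @param subfamily Optional character vector of subfamily labels (for
#'   labeled reference sets); `NA` where unlabeled.
#' @return A `protein_set` data.frame with columns `id`, `sequence`,
#'   `species`, `subfamily`.
#' @examples
#' ps <- protein_set(c("a", "b"), c("MKRH", "mkx"))
#' ps$sequence
#' @export
protein_set <- function(id, sequence, species = NA_character_,
                        subfamily = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop_survey("id and sequence must have the same length")
  if (any(!nzchar(id)) || anyNA(id))
    stop_survey("protein ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop_survey("duplicate protein id: '", dup, "'")
  }
  if (any(nchar(sequence) < 1L))
    stop_survey("empty sequence for id: '", id[nchar(sequence) < 1L][1L], "'")
  # gaps are legal so aligned domain sets can be carried in the same
  # container; anything else outside the 20-letter alphabet becomes X
  allowed <- paste0("[^", paste(AA_ALPHABET20, collapse = ""), "X-]")
  bad <- grepl(allowed, sequence)
  if (any(bad)) {
    survey_log("WARN", "non-standard residues replaced by X in ",
               sum(bad), " sequence(s)")
    sequence[bad] <- gsub(allowed, "X", sequence[bad])
  }
  out <- data.frame(id = id, sequence = sequence,
                    species = rep_len(as.character(species), length(id)),
                    subfamily = rep_len(as.character(subfamily), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Headers are parsed as `>id [key=value ...]`; recognised keys are
#' `species` and `subfamily` (written by [write_fasta()] for labeled
#' reference sets). Duplicate ids and empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_survey("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_survey("FASTA parse error in ",
                                                  path, ": ", conditionMessage(e)))
  if (length(set) == 0L) stop_survey("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  grab <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=\\S+"), headers))
    out <- rep(NA_character_, length(headers))
    hit <- grepl(paste0(key, "="), headers)
    out[hit] <- sub(paste0("^", key, "="), "", m)
    out
  }
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty))
    stop_survey("empty sequence at record ", empty[1L], " ('", ids[empty[1L]],
                "') in ", path)
  protein_set(ids, as.character(set),
              species = grab("species"), subfamily = grab("subfamily"))
}

#' Write a protein set as FASTA
#'
#' Sequences are wrapped at 60 columns. `species` and `subfamily` fields, when
#' present, are appended to the header as `key=value` tokens so that
#' `read_fasta(write_fasta(x))` round-trips labels as well as sequences.
#'
#' @param records A [protein_set()]; must be non-empty.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "protein_set"))
  if (nrow(records) == 0L) stop_survey("refusing to write an empty FASTA")
  hdr <- records$id
  tag <- function(key, val) ifelse(is.na(val), "", paste0(" ", key, "=", val))
  hdr <- paste0(hdr, tag("species", records$species),
                tag("subfamily", records$subfamily))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct an expression matrix
#'
#' FPKM values for genes (rows) by samples (columns), with a tissue label for
#' every sample. Values must be non-negative and every sample must appear in
#' the tissue map.
#'
#' @param values Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param tissue Named character vector mapping sample id to tissue label.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, tissue) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_survey("expression values need gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_survey("duplicate gene or sample ids in expression matrix")
  if (any(!is.finite(values)) || any(values < 0)) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)[1L, ]
    stop_survey("negative or non-finite FPKM for gene '",
                rownames(values)[bad[1L]], "', sample '",
                colnames(values)[bad[2L]], "'")
  }
  missing <- setdiff(colnames(values), names(tissue))
  if (length(missing))
    stop_survey("sample missing from tissue metadata: '", missing[1L], "'")
  structure(list(values = values,
                 tissue = as.character(tissue[colnames(values)])),
            names_tissue = NULL,
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$tissue)), "tissues\n")
  invisible(x)
}

#' Read an FPKM matrix and its sample metadata
#'
#' The matrix file is TSV with a header row of sample ids and gene ids in the
#' first column; the metadata file is TSV with columns `sample` and `tissue`.
#' Order of both axes is preserved.
#'
#' @param matrix_path Path to the FPKM TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, meta_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_survey("expression TSV needs gene ids plus samples")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1L]])
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "tissue") %in% names(meta)))
    stop_survey("metadata TSV must have columns 'sample' and 'tissue'")
  tissue <- stats::setNames(as.character(meta$tissue), as.character(meta$sample))
  expression_matrix(values, tissue)
}

#' Write an expression matrix (and optionally its metadata) as TSV
#' @param em An [expression_matrix()].
#' @param matrix_path Output TSV path for values.
#' @param meta_path Optional output TSV path for the sample/tissue table.
#' @export
write_expression <- function(em, matrix_path, meta_path = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  tab <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(
      data.frame(sample = colnames(em$values), tissue = em$tissue),
      meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are always written; bootstrap supports, when present as
#' `node.label`, are written as integer internal-node labels (not comments).
#'
#' @param tree An `ape` `phylo` object with >= 2 uniquely labeled leaves.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop_survey("tree must have >= 2 leaves")
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label))
    stop_survey("tree has an unlabeled leaf")
  if (anyDuplicated(tree$tip.label))
    stop_survey("tree leaf labels must be unique")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_survey("could not parse Newick in ", path)
  tr
}

#' Read a gene-location table
#'
#' TSV with columns `gene`, `chrom`, `start`, `end` (1-based inclusive).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with those columns; start < end enforced.
#' @export
read_locations <- function(path) {
  loc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(loc)))
    stop_survey("location TSV must have columns ", paste(need, collapse = ", "))
  if (any(loc$start >= loc$end))
    stop_survey("location with start >= end for gene '",
                loc$gene[loc$start >= loc$end][1L], "'")
  loc[, need]
}
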