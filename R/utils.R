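#' @keywords internal
"_PACKAGE"

# Standard 20-residue alphabet; X is the catch-all for ambiguity codes.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Emit a level-prefixed log line
#'
#' Messages go through [message()] so callers can silence them with
#' `suppressMessages()`; warnings go through [warning()].
#'
#' @param level One of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... Pieces pasted into the log line.
#' @keywords internal
survey_log <- function(level = "INFO", ...) {
  line <- paste0("[", level, "] ", paste0(..., collapse = ""))
  if (identical(level, "WARN")) warning(line, call. = FALSE) else message(line)
  invisible(line)
}

stop_survey <- function(...) stop(paste0(...), call. = FALSE)

# split a character vector of sequences into a matrix of single residues;
# all elements must share one length
seq_to_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_survey("sequences have unequal lengths (ragged alignment)")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == trunc(x) && x >= 0
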