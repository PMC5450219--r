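#' Run configuration
#'
#' Collects every tunable threshold of the survey in one validated list.
#' Defaults reproduce the package's standard analysis settings; any field can
#' be overridden by argument or from a YAML file via [read_run_config()].
#'
#' @param seed Integer seed; all randomness in a run flows from it.
#' @param min_score Minimum glocal profile score, in bits, to accept a domain
#'   hit (default 15).
#' @param gap_open,gap_extend Affine gap penalties (bits) for the profile
#'   scan; defaults -4 / -1 keep gaps cheap enough to absorb loop-length
#'   variation.
#' @param basic_span,helix1_span,loop_span,helix2_span Optional length-2
#'   integer vectors (1-based inclusive profile columns) overriding the
#'   default region partition; `NULL` means use [default_regions()].
#' @param min_basic_residues Minimum count of K/R/H in the basic region for a
#'   protein to be considered DNA-binding (default 6).
#' @param conserved_min_fraction Fraction of sequences a column's modal
#'   residue must strictly exceed to be "conserved" (default 0.4445, i.e. the
#'   more-than-100-of-225 rule).
#' @param high_min_fraction Inclusive fraction for "highly conserved" columns
#'   (default 0.75).
#' @param ortholog_min_length Aligned residue pairs must exceed
#'   `ortholog_min_length - 1` (default 61, i.e. strictly more than 60).
#' @param ortholog_min_identity Percent identity must strictly exceed this
#'   (default 80).
#' @param redundancy_threshold Global-identity threshold for redundancy
#'   clustering (default 0.95).
#' @param bootstrap_replicates Bootstrap replicates for the NJ tree
#'   (default 1000).
#' @param assign_ceiling Patristic-distance ceiling beyond which a query is
#'   left unplaced by subfamily assignment (default 0.8).
#' @param n_subgroups Number of expression subgroups to cut the dendrogram
#'   into (default 14).
#' @param linkage,metric Agglomeration method and distance for expression
#'   clustering (defaults "complete", "euclidean").
#' @param margin_threshold Standardized-mean margin for calling a subgroup
#'   tissue-specific (default 0.5).
#' @param verbose Emit `[INFO]` log lines (default TRUE).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       min_score = 15,
                       gap_open = -4,
                       gap_extend = -1,
                       basic_span = NULL,
                       helix1_span = NULL,
                       loop_span = NULL,
                       helix2_span = NULL,
                       min_basic_residues = 6L,
                       conserved_min_fraction = 0.4445,
                       high_min_fraction = 0.75,
                       ortholog_min_length = 61L,
                       ortholog_min_identity = 80,
                       redundancy_threshold = 0.95,
                       bootstrap_replicates = 1000L,
                       assign_ceiling = 0.8,
                       n_subgroups = 14L,
                       linkage = "complete",
                       metric = "euclidean",
                       margin_threshold = 0.5,
                       verbose = TRUE) {
  cfg <- list(seed = seed, min_score = min_score, gap_open = gap_open,
              gap_extend = gap_extend, basic_span = basic_span,
              helix1_span = helix1_span, loop_span = loop_span,
              helix2_span = helix2_span,
              min_basic_residues = min_basic_residues,
              conserved_min_fraction = conserved_min_fraction,
              high_min_fraction = high_min_fraction,
              ortholog_min_length = ortholog_min_length,
              ortholog_min_identity = ortholog_min_identity,
              redundancy_threshold = redundancy_threshold,
              bootstrap_replicates = bootstrap_replicates,
              assign_ceiling = assign_ceiling,
              n_subgroups = n_subgroups, linkage = linkage, metric = metric,
              margin_threshold = margin_threshold, verbose = verbose)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is_count(abs(cfg$seed))) stop_survey("seed must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$gap_open > 0 || cfg$gap_extend > 0)
    stop_survey("gap penalties must be <= 0 (they are scores, not costs)")
  frac_fields <- c("conserved_min_fraction", "high_min_fraction",
                   "redundancy_threshold")
  for (f in frac_fields)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_survey(f, " must lie in [0, 1]")
  if (cfg$ortholog_min_identity < 0 || cfg$ortholog_min_identity > 100)
    stop_survey("ortholog_min_identity must lie in [0, 100]")
  if (!is_count(cfg$min_basic_residues) ||
      !is_count(cfg$bootstrap_replicates) || cfg$bootstrap_replicates < 1 ||
      !is_count(cfg$n_subgroups) || cfg$n_subgroups < 1 ||
      !is_count(cfg$ortholog_min_length))
    stop_survey("count-valued thresholds must be non-negative integers")
  if (!cfg$linkage %in% c("complete", "average", "single", "ward.D2"))
    stop_survey("unsupported linkage: ", cfg$linkage)
  if (!cfg$metric %in% c("euclidean", "manhattan", "correlation"))
    stop_survey("unsupported metric: ", cfg$metric)
  if (cfg$assign_ceiling <= 0) stop_survey("assign_ceiling must be positive")
  if (cfg$margin_threshold < 0) stop_survey("margin_threshold must be >= 0")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [run_config()] defaults; unknown
#' fields are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_survey("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration as YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(path)
}
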