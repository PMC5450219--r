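write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full bHLH survey as one reproducible pipeline
#'
#' Executes, in order: profile build from the seed alignment, domain scan,
#' binding-category classification, conservation profiling, NJ phylogeny
#' with bootstrap and subfamily assignment (when labeled references are
#' supplied), redundancy clustering, ortholog calling (when a reference set
#' is supplied), chromosome distribution (when a location table is
#' supplied), and the expression stage (when an FPKM matrix is supplied).
#' Stages without inputs are skipped with a logged reason. Identical inputs,
#' config and seed give byte-identical TSV outputs.
#'
#' @param proteins A [protein_set()] of query proteins.
#' @param seed_alignment A [protein_set()] of aligned domains for
#'   [build_profile()].
#' @param out_dir Output directory (created if needed); all stage TSVs and
#'   the manifest land here.
#' @param config A [run_config()].
#' @param references Optional species-tagged [protein_set()] for ortholog
#'   calling; rows with a `subfamily` label are also used as phylogeny
#'   references for subfamily assignment.
#' @param expression Optional [expression_matrix()].
#' @param reference_gene_ids Reference gene ids for
#'   [normalize_expression()]; required when `expression` is given.
#' @param qpcr Optional qPCR [expression_matrix()] for [qpcr_agreement()].
#' @param locations Optional location data.frame (see [read_locations()]).
#' @return A `run_manifest`: config snapshot, input checksums, per-stage
#'   output paths, seed, timestamp, package version, and the in-memory stage
#'   results in `$results`.
#' @export
run_survey <- function(proteins, seed_alignment, out_dir,
                       config = run_config(), references = NULL,
                       expression = NULL, reference_gene_ids = NULL,
                       qpcr = NULL, locations = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_info <- function(...) if (config$verbose) survey_log("INFO", ...)
  paths <- list()
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_survey("stage '", name, "' failed: ", conditionMessage(e)))
  }

  log_info("stage profile: building from ", nrow(seed_alignment),
           " aligned domains")
  profile <- stage("profile", build_profile(seed_alignment))
  regions <- stage("profile", default_regions(
    profile, basic = config$basic_span, helix1 = config$helix1_span,
    loop = config$loop_span, helix2 = config$helix2_span))

  log_info("stage scan: ", nrow(proteins), " proteins")
  scan <- stage("scan", scan_proteins(profile, proteins,
                                      min_score = config$min_score,
                                      gap_open = config$gap_open,
                                      gap_extend = config$gap_extend))
  paths$hits <- write_tsv(scan$table, file.path(out_dir, "domain_hits.tsv"))
  if (!is.null(scan$aligned))
    paths$aligned_domains <- write_fasta(
      scan$aligned, file.path(out_dir, "aligned_domains.fasta"))

  rule <- classifier_rule(min_basic_residues = config$min_basic_residues)
  log_info("stage classify")
  classes <- stage("classify",
                   classify_proteins(scan, proteins, regions, rule))
  paths$classification <- write_tsv(
    classes, file.path(out_dir, "classification.tsv"))

  log_info("stage conservation")
  consv <- stage("conservation", conservation_profile(
    scan$aligned, conserved_min_fraction = config$conserved_min_fraction,
    high_min_fraction = config$high_min_fraction))
  tiers <- conserved_positions(consv)
  consv_out <- cbind(as.data.frame(consv),
                     tier = ifelse(consv$column %in% tiers$highly_conserved,
                                   "high",
                                   ifelse(consv$column %in% tiers$conserved,
                                          "conserved", "-")))
  paths$conservation <- write_tsv(consv_out,
                                  file.path(out_dir, "conservation.tsv"))

  tree <- NULL
  assignments <- NULL
  phylo_refs <- NULL
  if (!is.null(references) && any(!is.na(references$subfamily)))
    phylo_refs <- references[!is.na(references$subfamily), ]
  tree_set <- scan$aligned
  if (!is.null(phylo_refs)) {
    ref_scan <- stage("tree", scan_proteins(profile, phylo_refs,
                                            min_score = config$min_score,
                                            gap_open = config$gap_open,
                                            gap_extend = config$gap_extend))
    if (!is.null(ref_scan$aligned))
      tree_set <- protein_set(c(tree_set$id, ref_scan$aligned$id),
                              c(tree_set$sequence, ref_scan$aligned$sequence),
                              species = c(tree_set$species,
                                          ref_scan$aligned$species),
                              subfamily = c(tree_set$subfamily,
                                            ref_scan$aligned$subfamily))
  }
  if (!is.null(tree_set) && nrow(tree_set) >= 4L) {
    log_info("stage tree: NJ with ", config$bootstrap_replicates,
             " bootstrap replicates on ", nrow(tree_set), " domains")
    tree <- stage("tree", nj_bootstrap(tree_set,
                                       R = config$bootstrap_replicates,
                                       seed = config$seed))
    paths$tree <- write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    if (!is.null(phylo_refs)) {
      labels <- stats::setNames(tree_set$subfamily, tree_set$id)
      labels <- labels[!is.na(labels) & names(labels) %in% phylo_refs$id]
      assignments <- stage("tree", assign_subfamilies(
        tree, labels, ceiling = config$assign_ceiling))
      paths$subfamilies <- write_tsv(
        assignments, file.path(out_dir, "subfamilies.tsv"))
    }
  } else {
    log_info("stage tree skipped: fewer than 4 aligned domains")
  }

  log_info("stage redundancy")
  clusters <- stage("redundancy",
                    cluster_redundant(proteins, config$redundancy_threshold))
  paths$clusters <- write_tsv(
    data.frame(id = names(clusters$members),
               representative = unname(clusters$members)),
    file.path(out_dir, "redundancy_clusters.tsv"))

  orthologs <- NULL
  if (!is.null(references)) {
    log_info("stage orthologs: ", nrow(references), " references")
    orthologs <- stage("orthologs", call_orthologs(
      proteins, references, min_length = config$ortholog_min_length,
      min_identity = config$ortholog_min_identity))
    paths$orthologs <- write_tsv(as.data.frame(orthologs),
                                 file.path(out_dir, "orthologs.tsv"))
  } else log_info("stage orthologs skipped: no reference set")

  distribution <- NULL
  if (!is.null(locations)) {
    log_info("stage chromosomes")
    distribution <- stage("chromosomes",
                          chromosome_distribution(locations, proteins$id))
    paths$chromosomes <- write_tsv(
      data.frame(chromosome = names(distribution$counts),
                 n_genes = unname(distribution$counts)),
      file.path(out_dir, "chromosome_distribution.tsv"))
  } else log_info("stage chromosomes skipped: no location table")

  nm <- NULL; clustering <- NULL; blocks <- NULL; agreement <- NULL
  if (!is.null(expression)) {
    if (is.null(reference_gene_ids))
      stop_survey("stage 'expression' failed: reference_gene_ids required")
    log_info("stage expression")
    nm <- stage("expression",
                normalize_expression(expression, reference_gene_ids))
    k <- min(config$n_subgroups, nrow(nm$values))
    clustering <- stage("expression", cluster_subgroups(
      nm, k = k, linkage = config$linkage, metric = config$metric))
    blocks <- stage("expression", detect_blocks(
      clustering, nm, margin_threshold = config$margin_threshold))
    paths$normalized <- write_tsv(
      data.frame(gene = rownames(nm$values), nm$values, check.names = FALSE),
      file.path(out_dir, "normalized_expression.tsv"))
    paths$subgroups <- write_tsv(
      data.frame(gene = names(clustering$subgroup),
                 subgroup = unname(clustering$subgroup)),
      file.path(out_dir, "expression_subgroups.tsv"))
    paths$blocks <- write_tsv(blocks, file.path(out_dir, "tissue_blocks.tsv"))
    if (!is.null(qpcr)) {
      agreement <- stage("expression", qpcr_agreement(nm, qpcr))
      paths$qpcr <- write_tsv(agreement,
                              file.path(out_dir, "qpcr_agreement.tsv"))
    }
  } else log_info("stage expression skipped: no FPKM matrix")

  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  paths$config <- cfg_path

  manifest <- structure(list(
    config = config,
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("bhlhsurvey")),
    paths = paths,
    checksums = vapply(unlist(paths), function(p)
      unname(tools::md5sum(p)), character(1)),
    results = list(profile = profile, regions = regions, scan = scan,
                   classification = classes, conservation = consv,
                   conserved = tiers, tree = tree,
                   assignments = assignments, clusters = clusters,
                   orthologs = orthologs, distribution = distribution,
                   normalized = nm, clustering = clustering, blocks = blocks,
                   qpcr = agreement)),
    class = "run_manifest")
  manifest_tab <- data.frame(file = names(manifest$checksums),
                             md5 = unname(manifest$checksums))
  write_tsv(manifest_tab, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' Summarize a survey run as one headline-count table
#'
#' @param manifest A [run_survey()] manifest.
#' @return One-row data.frame: protein counts, the four category counts,
#'   conserved-position counts, subfamily count, ortholog counts (first
#'   partner species only / second only / both), redundancy cluster count
#'   and flagged tissue-block count; stages that did not run yield `NA`.
#' @export
summarize_run <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  res <- manifest$results
  cat_counts <- table(factor(res$classification$category,
                             levels = BINDING_CATEGORIES))
  orth <- attr(res$orthologs, "summary")
  data.frame(
    n_proteins = nrow(res$scan$table),
    n_with_hit = sum(!is.na(res$scan$table$score)),
    n_eg_box = as.integer(cat_counts[["EG_BOX"]]),
    n_e_box_only = as.integer(cat_counts[["E_BOX_ONLY"]]),
    n_other_binding = as.integer(cat_counts[["OTHER_BINDING"]]),
    n_non_binding = as.integer(cat_counts[["NON_BINDING"]]),
    n_conserved = length(res$conserved$conserved),
    n_highly_conserved = length(res$conserved$highly_conserved),
    n_subfamilies = if (is.null(res$assignments)) NA_integer_ else
      length(unique(stats::na.omit(res$assignments$subfamily))),
    n_orth_only_first = if (is.null(orth)) NA_integer_ else
      as.integer(orth[["only_first"]]),
    n_orth_only_second = if (is.null(orth)) NA_integer_ else
      as.integer(orth[["only_second"]]),
    n_orth_both = if (is.null(orth)) NA_integer_ else
      as.integer(orth[["both"]]),
    n_clusters = nrow(res$clusters$representatives),
    n_specific_blocks = if (is.null(res$blocks)) NA_integer_ else
      sum(res$blocks$specific))
}
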