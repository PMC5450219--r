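# Basic-region templates (profile columns 1-14) forcing each DNA-binding
# category under the default classifier rule. Binding categories carry >= 7
# basic residues so a single stray residue cannot cross the min-basic
# boundary; the non-binding template carries none.
CATEGORY_TEMPLATES <- c(
  EG_BOX        = "KHRKASERARRASA",
  E_BOX_ONLY    = "KNRKASERARRAKA",
  OTHER_BINDING = "KHRKASARARRAKA",
  NON_BINDING   = "SANAGSATASNAGA")

#' Specification for a synthetic bHLH family
#'
#' Describes a family of subfamily-structured domain sequences embedded in
#' random flanks, with basic regions forced to known DNA-binding categories.
#' The default category mix is the 133/45/28/19-over-225 partition observed
#' in the wheat family survey, so a 225-member family reproduces those
#' proportions.
#'
#' @param n_subfamilies Number of subfamilies (default 8).
#' @param members_per_subfamily Members per subfamily (default 10).
#' @param domain_length Domain columns (default 60, the canonical bHLH
#'   domain span; minimum 50 so the default region partition applies).
#' @param substitution_rate Per-position probability that a member deviates
#'   from its subfamily archetype (default 0.05).
#' @param flank_length_range Integer range of random flank lengths on each
#'   side (default c(10, 60)).
#' @param category_mix Named proportions over [BINDING_CATEGORIES]; must sum
#'   to 1.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A validated `family_spec`.
#' @export
family_spec <- function(n_subfamilies = 8L, members_per_subfamily = 10L,
                        domain_length = 60L, substitution_rate = 0.05,
                        flank_length_range = c(10L, 60L),
                        category_mix = c(EG_BOX = 133, E_BOX_ONLY = 45,
                                         OTHER_BINDING = 28,
                                         NON_BINDING = 19) / 225,
                        seed = 1L) {
  if (!is_count(n_subfamilies) || n_subfamilies < 1L ||
      !is_count(members_per_subfamily) || members_per_subfamily < 1L)
    stop_survey("subfamily counts must be positive integers")
  if (!is_count(domain_length) || domain_length < 50L)
    stop_survey("domain_length must be an integer >= 50")
  if (substitution_rate < 0 || substitution_rate > 1)
    stop_survey("substitution_rate must lie in [0, 1]")
  if (length(flank_length_range) != 2L ||
      flank_length_range[1L] > flank_length_range[2L] ||
      flank_length_range[1L] < 0L)
    stop_survey("flank_length_range must be c(min, max) with 0 <= min <= max")
  if (!setequal(names(category_mix), BINDING_CATEGORIES))
    stop_survey("category_mix must be named over all four binding categories")
  if (abs(sum(category_mix) - 1) > 1e-9 || any(category_mix < 0))
    stop_survey("category_mix proportions must be >= 0 and sum to 1")
  structure(list(n_subfamilies = as.integer(n_subfamilies),
                 members_per_subfamily = as.integer(members_per_subfamily),
                 domain_length = as.integer(domain_length),
                 substitution_rate = substitution_rate,
                 flank_length_range = as.integer(flank_length_range),
                 category_mix = category_mix[BINDING_CATEGORIES],
                 seed = as.integer(seed)),
            class = "family_spec")
}

# largest-remainder apportionment of n items over proportions p
apportion <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

random_aa <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE),
                               collapse = "")

#' Generate a synthetic bHLH protein family with known truth
#'
#' Each subfamily derives from a distinct random archetype domain; members
#' copy the archetype, substitute residues at `substitution_rate`, then have
#' their basic-region columns overwritten with a fixed template for their
#' assigned binding category (so the category truth always wins over both
#' archetype and mutation). Domains are embedded in random flanks.
#' Categories are apportioned over the family by largest remainder of
#' `category_mix` and distributed across subfamilies by a seeded
#' permutation.
#'
#' @param spec A [family_spec()].
#' @return A list: `records` (a [protein_set()] of full-length proteins),
#'   `truth` (data.frame `id`, `subfamily`, `category`, `domain_start`,
#'   `domain_end`, 1-based inclusive), and `archetypes` (a subfamily-labeled
#'   [protein_set()] of the archetype domains, usable as a seed alignment
#'   and as labeled phylogeny references).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  n_sub <- spec$n_subfamilies
  n <- n_sub * spec$members_per_subfamily
  W <- spec$domain_length

  # Archetypes differ freely outside the basic region but all carry the
  # canonical DNA-binding basic region (the E/G-box template), so a profile
  # built from them has a realistic basic region; members then deviate from
  # it only at their own category-determining residues.
  canonical <- CATEGORY_TEMPLATES[["EG_BOX"]]
  archetypes <- character(n_sub)
  repeat {
    archetypes <- vapply(seq_len(n_sub), function(k)
      paste0(canonical, random_aa(W - nchar(canonical))), character(1))
    if (!anyDuplicated(archetypes)) break
  }
  sub_names <- sprintf("SF%02d", seq_len(n_sub))

  counts <- apportion(spec$category_mix, n)
  categories <- sample(rep(BINDING_CATEGORIES, counts))

  ids <- sprintf("syn%03d", seq_len(n))
  subfam <- rep(sub_names, each = spec$members_per_subfamily)
  seqs <- character(n)
  dstart <- integer(n)
  dend <- integer(n)
  for (k in seq_len(n)) {
    dom <- strsplit(archetypes[match(subfam[k], sub_names)], "")[[1L]]
    mut <- stats::runif(W) < spec$substitution_rate
    if (any(mut))
      dom[mut] <- vapply(dom[mut], function(r)
        sample(setdiff(AA_ALPHABET20, r), 1L), character(1))
    tmpl <- strsplit(CATEGORY_TEMPLATES[[categories[k]]], "")[[1L]]
    dom[seq_along(tmpl)] <- tmpl
    fl <- sample(seq.int(spec$flank_length_range[1L],
                         spec$flank_length_range[2L]), 2L, replace = TRUE)
    seqs[k] <- paste0(random_aa(fl[1L]), paste(dom, collapse = ""),
                      random_aa(fl[2L]))
    dstart[k] <- fl[1L] + 1L
    dend[k] <- fl[1L] + W
  }
  list(records = protein_set(ids, seqs, subfamily = subfam),
       truth = data.frame(id = ids, subfamily = subfam,
                          category = categories, domain_start = dstart,
                          domain_end = dend, stringsAsFactors = FALSE),
       archetypes = protein_set(paste0("arch_", sub_names), archetypes,
                                species = "reference",
                                subfamily = sub_names))
}

#' Specification for a synthetic tissue-expression study
#'
#' Emulates a block-structured FPKM matrix: a log-normal expression
#' background, a subset of genes elevated `block_effect`-fold in one tissue
#' each, reference genes with a tissue-constant mean, and a qPCR panel equal
#' to the FPKM values of a gene subset perturbed by multiplicative noise.
#'
#' @param n_genes Number of (non-reference) genes (default 225).
#' @param n_tissues Number of tissues (default 7: endosperm, aleurone,
#'   seedling, spike, flag_leaf, shoot, root).
#' @param samples_per_tissue Samples per tissue (default 4).
#' @param block_assignments Either `NULL` (default: the first
#'   `10 * n_tissues` genes are assigned 10 per tissue) or a named character
#'   vector gene id -> tissue.
#' @param block_effect Fold elevation of a block gene in its tissue
#'   (default 4; must exceed 1).
#' @param noise_sd Log-scale multiplicative noise sd on every measurement
#'   (default 0.5).
#' @param n_reference_genes Reference (housekeeping) genes appended to the
#'   matrix (default 5).
#' @param qpcr_noise_sd Log-scale sd of the extra qPCR perturbation
#'   (default 0.75, calibrated by pilot simulation to a mean per-gene
#'   RNA-seq/qPCR correlation around 0.7).
#' @param seed Integer seed.
#' @return A validated `expression_spec`.
#' @export
expression_spec <- function(n_genes = 225L, n_tissues = 7L,
                            samples_per_tissue = 4L,
                            block_assignments = NULL, block_effect = 4,
                            noise_sd = 0.5, n_reference_genes = 5L,
                            qpcr_noise_sd = 0.75, seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1L || !is_count(n_tissues) ||
      n_tissues < 1L || !is_count(samples_per_tissue) ||
      samples_per_tissue < 1L || !is_count(n_reference_genes))
    stop_survey("counts must be positive integers")
  if (block_effect <= 1) stop_survey("block_effect must exceed 1")
  if (noise_sd < 0 || qpcr_noise_sd < 0)
    stop_survey("noise sds must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 samples_per_tissue = as.integer(samples_per_tissue),
                 block_assignments = block_assignments,
                 block_effect = block_effect, noise_sd = noise_sd,
                 n_reference_genes = as.integer(n_reference_genes),
                 qpcr_noise_sd = qpcr_noise_sd, seed = as.integer(seed)),
            class = "expression_spec")
}

default_tissues <- function(n) {
  base <- c("endosperm", "aleurone", "seedling", "spike", "flag_leaf",
            "shoot", "root")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("tissue%02d", seq.int(length(base) + 1L, n)))
}

#' Generate a synthetic block-structured expression study
#'
#' @param spec An [expression_spec()].
#' @return A list: `matrix` (an [expression_matrix()] including reference
#'   genes), `reference_ids`, `qpcr` (an [expression_matrix()] over a panel
#'   of up to six first-tissue block genes, FPKM values with multiplicative
#'   noise), and `truth_blocks` (named character gene -> tissue, `NA` for
#'   background genes).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(spec$seed)
  tissues <- default_tissues(spec$n_tissues)
  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  ref_ids <- sprintf("ref%02d", seq_len(spec$n_reference_genes))
  sample_ids <- paste0(rep(tissues, each = spec$samples_per_tissue), "_",
                       rep(seq_len(spec$samples_per_tissue),
                           times = spec$n_tissues))
  sample_tissue <- rep(tissues, each = spec$samples_per_tissue)

  blocks <- spec$block_assignments
  if (is.null(blocks)) {
    per <- min(10L, spec$n_genes %/% spec$n_tissues)
    assigned <- gene_ids[seq_len(per * spec$n_tissues)]
    blocks <- stats::setNames(rep(tissues, each = per), assigned)
  }
  if (!all(names(blocks) %in% gene_ids) || !all(blocks %in% tissues))
    stop_survey("block_assignments must map known genes to known tissues")
  truth <- stats::setNames(rep(NA_character_, spec$n_genes), gene_ids)
  truth[names(blocks)] <- blocks

  ns <- length(sample_ids)
  mu <- stats::setNames(stats::rlnorm(spec$n_genes, 1, 1), gene_ids)
  mu_ref <- stats::setNames(stats::rlnorm(spec$n_reference_genes, 1, 1),
                            ref_ids)
  noise <- function() if (spec$noise_sd > 0)
    exp(stats::rnorm(ns, 0, spec$noise_sd)) else rep(1, ns)
  vals <- t(vapply(gene_ids, function(g) {
    fold <- ifelse(!is.na(truth[g]) & sample_tissue == truth[g],
                   spec$block_effect, 1)
    mu[g] * fold * noise()
  }, numeric(ns)))
  ref_vals <- t(vapply(ref_ids, function(g) mu_ref[g] * noise(), numeric(ns)))
  values <- rbind(vals, ref_vals)
  rownames(values) <- c(gene_ids, ref_ids)
  colnames(values) <- sample_ids
  em <- expression_matrix(values, stats::setNames(sample_tissue, sample_ids))

  first_block <- names(blocks)[blocks == tissues[1L]]
  panel <- utils::head(if (length(first_block)) first_block else gene_ids, 6L)
  qvals <- values[panel, , drop = FALSE] *
    (if (spec$qpcr_noise_sd > 0)
       exp(matrix(stats::rnorm(length(panel) * ns, 0, spec$qpcr_noise_sd),
                  length(panel), ns)) else 1)
  qpcr <- expression_matrix(qvals, stats::setNames(sample_tissue, sample_ids))
  list(matrix = em, reference_ids = ref_ids, qpcr = qpcr,
       truth_blocks = truth)
}
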