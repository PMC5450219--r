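#' Reference-gene normalization and per-gene standardization
#'
#' Two-stage transform: (1) every sample's FPKM values are divided by the
#' mean FPKM of the reference genes in that sample, which cancels any
#' sample-wide scale factor; (2) each gene row is standardized to mean 0,
#' sd 1 across samples (the `scale` step). Reference genes are excluded from
#' the output rows. Constant rows cannot be standardized; they are set to 0
#' and flagged rather than dropped.
#'
#' @param em An [expression_matrix()].
#' @param reference_ids Gene ids of the reference (housekeeping) genes; all
#'   must be present, and no sample may have a zero or non-finite reference
#'   mean.
#' @return A `normalized_matrix`: list with `values` (standardized),
#'   `intermediate` (after stage 1, before standardization), `tissue`,
#'   `constant_genes`.
#' @export
normalize_expression <- function(em, reference_ids) {
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(reference_ids, rownames(em$values))
  if (length(missing))
    stop_survey("reference gene(s) absent from matrix: ",
                paste(missing, collapse = ", "))
  ref_mean <- colMeans(em$values[reference_ids, , drop = FALSE])
  bad <- !is.finite(ref_mean) | ref_mean == 0
  if (any(bad))
    stop_survey("zero or non-finite reference mean in sample '",
                colnames(em$values)[bad][1L], "'")
  genes <- setdiff(rownames(em$values), reference_ids)
  inter <- sweep(em$values[genes, , drop = FALSE], 2L, ref_mean, `/`)
  sds <- apply(inter, 1L, stats::sd)
  mns <- rowMeans(inter)
  constant <- sds == 0 | !is.finite(sds)
  values <- (inter - mns) / ifelse(constant, 1, sds)
  values[constant, ] <- 0
  if (any(constant))
    survey_log("INFO", sum(constant),
               " constant gene row(s) flagged, set to 0")
  structure(list(values = values, intermediate = inter, tissue = em$tissue,
                 constant_genes = genes[constant]),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  invisible(x)
}

nm_dist <- function(values, metric) {
  switch(metric,
         euclidean = stats::dist(values),
         manhattan = stats::dist(values, method = "manhattan"),
         correlation = stats::as.dist(1 - stats::cor(t(values))),
         stop_survey("unsupported metric: ", metric))
}

#' Cut expression profiles into subgroups by hierarchical clustering
#'
#' Agglomerative clustering of standardized gene rows (default: complete
#' linkage on Euclidean distance, the defaults of the usual heat-map
#' clustering), with the dendrogram cut into exactly `k` subgroups.
#' Subgroups are renumbered 1..k in order of first gene appearance, so the
#' labeling does not depend on dendrogram internals.
#'
#' @param nm A [normalize_expression()] result.
#' @param k Number of subgroups (default 14); must not exceed the gene count.
#' @param linkage Agglomeration method (default "complete").
#' @param metric One of "euclidean", "manhattan", "correlation".
#' @return A `subgroup_clustering`: list with `subgroup` (named integer
#'   gene -> 1..k), `hclust`, `k`.
#' @export
cluster_subgroups <- function(nm, k = 14L, linkage = "complete",
                              metric = "euclidean") {
  stopifnot(inherits(nm, "normalized_matrix"))
  ng <- nrow(nm$values)
  if (!is_count(k) || k < 1L || k > ng)
    stop_survey("k must be an integer in 1..", ng, " (genes)")
  hc <- stats::hclust(nm_dist(nm$values, metric), method = linkage)
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  structure(list(subgroup = stats::setNames(relabel, names(raw)),
                 hclust = hc, k = as.integer(k)),
            class = "subgroup_clustering")
}

#' Detect tissue-specific expression blocks among subgroups
#'
#' For each subgroup, the mean standardized value per tissue is computed
#' over its genes; the dominant tissue is the argmax, the specificity margin
#' is the gap between dominant and runner-up means, and a subgroup is
#' flagged tissue-specific when the margin reaches `margin_threshold`
#' standard-deviation units.
#'
#' @param clustering A [cluster_subgroups()] result.
#' @param nm The matching [normalize_expression()] result.
#' @param margin_threshold Flagging threshold (default 0.5).
#' @return data.frame (`subgroup`, `n_genes`, `dominant_tissue`, `margin`,
#'   `specific`).
#' @export
detect_blocks <- function(clustering, nm, margin_threshold = 0.5) {
  stopifnot(inherits(clustering, "subgroup_clustering"),
            inherits(nm, "normalized_matrix"))
  if (!setequal(names(clustering$subgroup), rownames(nm$values)))
    stop_survey("clustering and matrix must cover the same genes")
  tissues <- unique(nm$tissue)
  rows <- lapply(seq_len(clustering$k), function(sg) {
    genes <- names(clustering$subgroup)[clustering$subgroup == sg]
    sub <- nm$values[genes, , drop = FALSE]
    tmeans <- vapply(tissues, function(tt)
      mean(sub[, nm$tissue == tt, drop = FALSE]), numeric(1))
    ord <- order(tmeans, decreasing = TRUE)
    margin <- if (length(tmeans) > 1L)
      tmeans[ord[1L]] - tmeans[ord[2L]] else 0
    data.frame(subgroup = sg, n_genes = length(genes),
               dominant_tissue = tissues[ord[1L]], margin = margin,
               specific = margin >= margin_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene agreement between RNA-seq and qPCR measurements
#'
#' Pearson correlation per gene across shared samples, computed on
#' log2(x + 1)-transformed unstandardized values (set `log2_transform =
#' FALSE` for the raw scale); the two-sided p-value comes from the
#' t-distribution with n - 2 degrees of freedom. Genes with fewer than 3
#' shared samples are skipped with a warning.
#'
#' @param em An [expression_matrix()] (or `normalized_matrix`, whose stage-1
#'   intermediate values are then used) of RNA-seq values.
#' @param qpcr An [expression_matrix()] of qPCR relative expression.
#' @param log2_transform Apply log2(x + 1) first (default TRUE).
#' @return data.frame (`gene`, `n`, `r`, `p`).
#' @export
qpcr_agreement <- function(em, qpcr, log2_transform = TRUE) {
  stopifnot(inherits(qpcr, "expression_matrix"))
  vals <- if (inherits(em, "normalized_matrix")) em$intermediate
          else if (inherits(em, "expression_matrix")) em$values
          else stop_survey("em must be an expression or normalized matrix")
  genes <- intersect(rownames(qpcr$values), rownames(vals))
  if (!length(genes)) stop_survey("no shared genes between the two methods")
  samples <- intersect(colnames(qpcr$values), colnames(vals))
  tf <- if (log2_transform) function(x) log2(x + 1) else identity
  rows <- lapply(genes, function(g) {
    x <- tf(vals[g, samples])
    y <- tf(qpcr$values[g, samples])
    if (length(samples) < 3L) {
      survey_log("WARN", "gene '", g, "' skipped: < 3 shared samples")
      return(NULL)
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(gene = g, n = length(samples), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_survey("no gene had >= 3 shared samples")
  out
}
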