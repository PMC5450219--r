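toy_matrix <- function() {
  vals <- rbind(g1 = c(4, 6, 10, 2),
                g2 = c(1, 2, 3, 4),
                g3 = c(5, 5, 5, 5),      # constant after normalization? no
                ref1 = c(2, 2, 2, 2),
                ref2 = c(2, 2, 2, 2))
  colnames(vals) <- paste0("s", 1:4)
  expression_matrix(vals, stats::setNames(c("root", "root", "leaf", "leaf"),
                                          paste0("s", 1:4)))
}

test_that("normalization divides by the sample reference mean, then
           standardizes rows", {
  em <- toy_matrix()
  nm <- suppressMessages(normalize_expression(em, c("ref1", "ref2")))
  # reference mean is 2 in every sample: intermediate = FPKM / 2
  expect_equal(nm$intermediate["g1", "s1"], 2)
  expect_false(any(c("ref1", "ref2") %in% rownames(nm$values)))
  # standardized rows: mean 0, sd 1
  expect_true(all(abs(rowMeans(nm$values[c("g1", "g2"), ])) < 1e-9))
  expect_true(all(abs(apply(nm$values[c("g1", "g2"), ], 1, stats::sd) - 1)
                  < 1e-9))
  # constant row flagged and zeroed, not dropped
  expect_equal(nm$constant_genes, "g3")
  expect_true(all(nm$values["g3", ] == 0))
  # de-standardization recovers the intermediate values
  for (g in c("g1", "g2")) {
    back <- nm$values[g, ] * stats::sd(nm$intermediate[g, ]) +
      mean(nm$intermediate[g, ])
    expect_equal(unname(back), unname(nm$intermediate[g, ]),
                 tolerance = 1e-9)
  }
})

test_that("normalization is equivariant to per-sample scale factors", {
  em <- toy_matrix()
  scaled <- em$values
  scaled[, "s2"] <- scaled[, "s2"] * 37.5   # e.g. library-size distortion
  em2 <- expression_matrix(scaled, stats::setNames(em$tissue,
                                                   colnames(em$values)))
  nm1 <- suppressMessages(normalize_expression(em, c("ref1", "ref2")))
  nm2 <- suppressMessages(normalize_expression(em2, c("ref1", "ref2")))
  expect_equal(nm1$values, nm2$values, tolerance = 1e-12)
})

test_that("normalization rejects missing or degenerate references", {
  em <- toy_matrix()
  expect_error(normalize_expression(em, c("ref1", "nope")), "absent")
  vals <- em$values; vals[c("ref1", "ref2"), "s3"] <- 0
  em0 <- expression_matrix(vals, stats::setNames(em$tissue,
                                                 colnames(em$values)))
  expect_error(normalize_expression(em0, c("ref1", "ref2")),
               "reference mean in sample 's3'")
})

test_that("noise-free planted blocks split perfectly and order does not
           matter", {
  sim <- generate_expression(expression_spec(n_genes = 20, n_tissues = 2,
                                             samples_per_tissue = 3,
                                             noise_sd = 0, seed = 61))
  nm <- suppressMessages(normalize_expression(sim$matrix,
                                              sim$reference_ids))
  keep <- names(sim$truth_blocks)[!is.na(sim$truth_blocks)]
  nm$values <- nm$values[keep, ]
  nm$intermediate <- nm$intermediate[keep, ]
  cl <- cluster_subgroups(nm, k = 2)
  truth <- sim$truth_blocks[keep]
  expect_equal(length(unique(cl$subgroup)), 2L)
  expect_true(all(table(cl$subgroup, truth) %in%
                    c(0, as.vector(table(truth)))))
  # permuting gene rows relabels but does not change the partition
  perm <- rev(seq_len(nrow(nm$values)))
  nm2 <- nm; nm2$values <- nm$values[perm, ]
  cl2 <- cluster_subgroups(nm2, k = 2)
  agree <- outer(cl$subgroup[keep], cl$subgroup[keep], "==") ==
    outer(cl2$subgroup[keep], cl2$subgroup[keep], "==")
  expect_true(all(agree))
  # k equal to the gene count gives singletons
  cls <- cluster_subgroups(nm, k = nrow(nm$values))
  expect_equal(length(unique(cls$subgroup)), nrow(nm$values))
  expect_error(cluster_subgroups(nm, k = nrow(nm$values) + 1L), "k must")
})

test_that("block detection flags planted tissue-specific subgroups only", {
  sim <- generate_expression(expression_spec(seed = 62))
  nm <- suppressMessages(normalize_expression(sim$matrix,
                                              sim$reference_ids))
  cl <- cluster_subgroups(nm, k = 8)
  blocks <- detect_blocks(cl, nm)
  expect_true(all(blocks$margin >= 0))
  expect_equal(blocks$specific, blocks$margin >= 0.5)
  # the dominant tissue of every flagged block is a planted block tissue
  planted <- unique(stats::na.omit(sim$truth_blocks))
  expect_true(all(blocks$dominant_tissue[blocks$specific] %in% planted))

  # a flat subgroup has margin near zero
  flat_vals <- matrix(rep(c(1, 1.01), 8), nrow = 2,
                      dimnames = list(c("f1", "f2"), paste0("s", 1:8)))
  flat <- expression_matrix(rbind(flat_vals,
                                  ref1 = rep(1, 8)),
                            stats::setNames(rep(c("root", "leaf"), each = 4),
                                            paste0("s", 1:8)))
  nmf <- suppressMessages(normalize_expression(flat, "ref1"))
  clf <- cluster_subgroups(nmf, k = 1)
  bf <- detect_blocks(clf, nmf)
  expect_false(bf$specific[1])
})

test_that("qPCR agreement recovers exact and inverted relationships", {
  vals <- matrix(c(1, 2, 4, 8, 16, 32), 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  tis <- stats::setNames(rep("endosperm", 6), paste0("s", 1:6))
  em <- expression_matrix(vals, tis)
  expect_equal(qpcr_agreement(em, em)$r, 1, tolerance = 1e-12)
  anti <- expression_matrix(matrix(32 - vals, 1,
                                   dimnames = dimnames(vals)), tis)
  r_anti <- qpcr_agreement(em, anti, log2_transform = FALSE)$r
  expect_equal(r_anti, -1, tolerance = 1e-12)
  # r is invariant to affine rescaling of either vector
  scaled <- expression_matrix(vals * 7 + 0, tis)
  expect_equal(qpcr_agreement(em, scaled, log2_transform = FALSE)$r, 1,
               tolerance = 1e-12)
  # p-value comes from the t distribution with n - 2 df
  set.seed(63)
  x <- matrix(stats::rlnorm(6), 1, dimnames = list("g1", paste0("s", 1:6)))
  y <- matrix(stats::rlnorm(6), 1, dimnames = list("g1", paste0("s", 1:6)))
  got <- qpcr_agreement(expression_matrix(x, tis), expression_matrix(y, tis))
  ct <- stats::cor.test(log2(x + 1), log2(y + 1))
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})
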