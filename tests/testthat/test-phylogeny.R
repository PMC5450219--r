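test_that("p-distance counts mismatches over comparable columns", {
  al <- protein_set(c("a", "b", "c"), c("AAAA", "AAAT", "AAAA"))
  d <- p_distance(al, min_comparable = 2L)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))

  # low-overlap pairs are flagged, zero-overlap pairs are an error
  al2 <- protein_set(c("a", "b", "c"),
                     c("KKKKKKKKKK", "KKKKK-----", "---KKKKKKK"))
  d2 <- p_distance(al2, min_comparable = 5L)
  flagged <- attr(d2, "flagged")
  expect_true(any(flagged$id1 == "b" & flagged$id2 == "c"))
  al3 <- protein_set(c("a", "b", "c"),
                     c("KKKKKKKKKK", "KKKKK-----", "-----KKKKK"))
  expect_error(p_distance(al3), "no comparable columns.*'b' and 'c'")
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  pl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(pl[["a"]], (.3 + .4 - .5) / 2)
  expect_equal(pl[["b"]], (.3 + .5 - .4) / 2)
  expect_equal(pl[["c"]], (.4 + .5 - .3) / 2)
})

test_that("NJ reconstructs additive trees exactly", {
  for (nwk in c("((a:0.1,b:0.2):0.15,(c:0.3,d:0.05):0.2,e:0.4);",
                "((a:0.12,(b:0.07,c:0.22):0.05):0.1,d:0.3,(e:0.2,f:0.09):0.14);")) {
    tru <- ape::read.tree(text = nwk)
    tr <- neighbor_joining(stats::cophenetic(tru))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tru)), 0,
                 ignore_attr = TRUE)
    expect_equal(stats::cophenetic(tr)[tru$tip.label, tru$tip.label],
                 stats::cophenetic(tru), tolerance = 1e-9)
  }
})

test_that("NJ topology agrees with an independent implementation on random
           matrices", {
  set.seed(202)
  for (k in 1:50) {
    d <- random_dist(sample(4:6, 1))
    t1 <- suppressMessages(neighbor_joining(d))
    t2 <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ output is invariant to taxon input order", {
  set.seed(17)
  tru <- ape::rtree(7)
  d <- stats::cophenetic(tru)
  t1 <- neighbor_joining(d)
  perm <- sample(rownames(d))
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("negative branch estimates are clamped to zero with a log entry", {
  # triangle-inequality violation forces a negative two-point estimate
  d <- matrix(c(0, 0.2, 1.0,
                0.2, 0, 0.3,
                1.0, 0.3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_message(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["b"]], 0)  # (0.2 + 0.3 - 1.0) / 2 < 0, clamped
})

test_that("bootstrap supports are counts bounded by R, and saturate for
           unambiguous families", {
  fam <- generate_family(family_spec(n_subfamilies = 4,
                                     members_per_subfamily = 3,
                                     substitution_rate = 0.05, seed = 41))
  prof <- build_profile(fam$archetypes)
  sc <- scan_proteins(prof, fam$records)
  R <- 50L
  tr <- suppressMessages(nj_bootstrap(sc$aligned, R = R, seed = 9))
  supp <- as.integer(tr$node.label)
  expect_true(all(supp >= 0 & supp <= R))
  # edges separating the four well-separated subfamilies reach >= 0.95 R
  bysub <- split(fam$truth$id, fam$truth$subfamily)
  for (ids in bysub) {
    mrca <- ape::getMRCA(tr, ids)
    node_supp <- supp[mrca - length(tr$tip.label)]
    desc <- ape::extract.clade(tr, mrca)$tip.label
    if (setequal(desc, ids))  # subfamily is monophyletic in the main tree
      expect_gte(node_supp, 0.95 * R)
  }
})

test_that("identical columns across sequences give full bootstrap support", {
  al <- protein_set(letters[1:4],
                    c(strrep("A", 30), strrep("C", 30),
                      strrep("D", 30), strrep("E", 30)))
  tr <- nj_bootstrap(al, R = 10L, seed = 3, min_comparable = 5L)
  expect_true(all(as.integer(tr$node.label) == 10L))
})

test_that("subfamily assignment follows nearest labeled leaf with a
           distance ceiling", {
  # query at distance 0 from a labeled reference takes its subfamily
  tru <- ape::read.tree(text = "((q1:0,r1:0):0.1,(q2:0.05,r2:0.02):0.1,r3:0.6);")
  labels <- c(r1 = "Ia", r2 = "II", r3 = "XII")
  asg <- assign_subfamilies(tru, labels, ceiling = 0.8)
  expect_equal(asg$subfamily[asg$query_id == "q1"], "Ia")
  expect_equal(asg$distance[asg$query_id == "q1"], 0)
  expect_equal(asg$subfamily[asg$query_id == "q2"], "II")
  # ceiling turns distant queries into explicit non-assignments
  asg2 <- assign_subfamilies(tru, labels, ceiling = 0.01)
  expect_false(asg2$placed[asg2$query_id == "q2"])
  expect_true(is.na(asg2$subfamily[asg2$query_id == "q2"]))
})

test_that("assignment recovers planted subfamilies and never exceeds the
           label set", {
  for (rate in c(0, 0.05)) {
    fam <- generate_family(family_spec(n_subfamilies = 8,
                                       members_per_subfamily = 10,
                                       substitution_rate = rate, seed = 43))
    prof <- build_profile(fam$archetypes)
    sc <- scan_proteins(prof, fam$records)
    all_dom <- protein_set(c(sc$aligned$id, fam$archetypes$id),
                           c(sc$aligned$sequence, fam$archetypes$sequence))
    tr <- suppressMessages(neighbor_joining(p_distance(all_dom)))
    labels <- stats::setNames(fam$archetypes$subfamily, fam$archetypes$id)
    asg <- assign_subfamilies(tr, labels)
    acc <- mean(asg$subfamily ==
                  fam$truth$subfamily[match(asg$query_id, fam$truth$id)],
                na.rm = TRUE)
    if (rate == 0) expect_equal(acc, 1) else expect_gte(acc, 0.95)
    expect_lte(length(unique(stats::na.omit(asg$subfamily))),
               length(unique(labels)))
  }
})
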