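# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive: plain recursion and exhaustive
# counting, sharing no code with the package's implementations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein_set <- function(n, len_range = c(5L, 40L), prefix = "p") {
  lens <- sample(seq.int(len_range[1L], len_range[2L]), n, replace = TRUE)
  protein_set(sprintf("%s%03d", prefix, seq_len(n)),
              vapply(lens, function(l)
                paste(sample(AA20, l, TRUE), collapse = ""), character(1)))
}

# Exhaustive glocal alignment score: every way of threading all profile
# columns through a substring of the protein, affine gaps, free flanks.
# States mirror the scoring rules only, not the DP: first gap residue costs
# `open`, each further one `extend`; gap-state switches are disallowed.
oracle_glocal <- function(weights, seq, open = -4, extend = -1) {
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(res)
  W <- ncol(weights)
  rec <- function(i, j, state) {
    if (j == W) return(0)
    best <- -Inf
    if (i < L)  # match column j+1 to residue i+1
      best <- max(best, weights[res[i + 1L], j + 1L] + rec(i + 1L, j + 1L, "M"))
    if (i < L && j > 0L && j < W && state != "Iy")  # insert protein residue
      best <- max(best, (if (state == "Ix") extend else open) +
                    rec(i + 1L, j, "Ix"))
    if (state != "Ix")                              # delete profile column
      best <- max(best, (if (state == "Iy") extend else open) +
                    rec(i, j + 1L, "Iy"))
    best
  }
  max(vapply(0:L, function(s) rec(s, 0L, "S"), numeric(1)))
}

# Exhaustive local alignment score under Biostrings gap semantics
# (a gap of length g costs open + g * extend). Optimal local alignments
# start and end with an aligned pair; interior gaps are enumerated.
oracle_local <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  la <- length(av); lb <- length(bv)
  rec <- function(i, j, state) {
    best <- 0  # stopping is always allowed (local)
    if (i < la && j < lb)
      best <- max(best, mat[av[i + 1L], bv[j + 1L]] + rec(i + 1L, j + 1L, "M"))
    if (i < la && state != "Iy")
      best <- max(best, -(if (state == "Ix") extend else open + extend) +
                    rec(i + 1L, j, "Ix"))
    if (j < lb && state != "Ix")
      best <- max(best, -(if (state == "Iy") extend else open + extend) +
                    rec(i, j + 1L, "Iy"))
    best
  }
  best <- 0
  for (i in 0:(la - 1L)) for (j in 0:(lb - 1L))
    best <- max(best, mat[av[i + 1L], bv[j + 1L]] + rec(i + 1L, j + 1L, "M"))
  best
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, lo = 0.05, hi = 1) {
  d <- matrix(stats::runif(n * n, lo, hi), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}

# aligned family with planted per-column conservation: `conserved_cols` get
# their modal residue in `high_n` of `n` sequences, all other columns in at
# most `low_n`
planted_conservation_family <- function(n = 225L, width = 60L,
                                        conserved_cols = 1:19,
                                        high_n = 101L, low_n = 100L) {
  stopifnot(high_n > low_n, low_n >= ceiling(n / 4))
  mat <- matrix("", n, width)
  for (j in seq_len(width)) {
    modal <- AA20[(j %% 20L) + 1L]
    others <- setdiff(AA20, modal)
    k <- if (j %in% conserved_cols) high_n else low_n
    fill <- rep(others, length.out = n - k)
    mat[, j] <- sample(c(rep(modal, k), fill))
  }
  protein_set(sprintf("fam%03d", seq_len(n)),
              apply(mat, 1L, paste, collapse = ""))
}
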