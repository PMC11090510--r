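test_that("greedy clustering partitions sequences at the identity threshold", {
  s <- c(a = "MKVLAEKWQRTS", b = "MKVLAEKWQRTS", c = "MKVLAEKWQRTS")
  cl <- greedy_cluster(s, 0.5)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, names(s))
  # two sequences below threshold stay apart (identity 8/20 = 0.4)
  s20 <- "ACDEFGHIKLMNPQRSTVWY"
  x <- strsplit(s20, "")[[1]]
  x[1:12] <- rev(x[1:12])
  s2 <- c(p = s20, q = paste(x, collapse = ""))
  expect_lt(pairwise_identity(s2[["p"]], s2[["q"]]), 0.5)
  expect_length(greedy_cluster(s2, 0.5), 2)
  expect_length(greedy_cluster(character(0), 0.5), 0)
  expect_error(greedy_cluster(s, 0), "threshold")
})

test_that("greedy clustering is invariant to input order", {
  set.seed(21)
  seqs <- generate_clustering_fixture(3, 4, 0.1, seed = 21)
  cl1 <- greedy_cluster(seqs, 0.5)
  cl2 <- greedy_cluster(rev(seqs), 0.5)
  cl3 <- greedy_cluster(seqs[sample(length(seqs))], 0.5)
  sig <- function(cl) lapply(cl, function(x) sort(x$members))
  expect_identical(sig(cl1), sig(cl2))
  expect_identical(sig(cl1), sig(cl3))
  # partition: disjoint and exhaustive
  members <- unlist(sig(cl1))
  expect_identical(sort(members), sort(names(seqs)))
})

test_that("center-star alignment keeps rows equal and de-gaps to the input", {
  s1 <- c(only = "MKVLAE")
  cl <- align_cluster(greedy_cluster(s1, 0.5)[[1]], s1)
  expect_identical(unname(cl$alignment), "MKVLAE")
  s2 <- c(a = "ACDEFG", b = "ACEFG")
  cl2 <- align_cluster(greedy_cluster(s2, 0.5)[[1]], s2)
  expect_length(unique(nchar(cl2$alignment)), 1)
  expect_identical(cl2$alignment[["b"]], "AC-EFG")   # one gap inserted
  set.seed(31)
  for (rep in 1:3) {
    fam <- generate_clustering_fixture(1, 5, 0.15, seed = 30 + rep)
    cl5 <- align_cluster(greedy_cluster(fam, 0.3)[[1]], fam)
    expect_length(unique(nchar(cl5$alignment)), 1)
    for (id in names(fam))
      expect_identical(gsub("-", "", cl5$alignment[[id]]), fam[[id]])
  }
})

test_that("profiles are column-normalised with pseudocounts", {
  p <- build_profile("A")
  expect_equal(sum(p$mat[, 1]), 1, tolerance = 1e-9)
  expect_equal(unname(p$mat["A", 1]), 1.01 / 1.21, tolerance = 1e-9)
  expect_gt(p$mat["A", 1], 0.8)
  p2 <- build_profile(c("AC", "AG"))
  expect_equal(colSums(p2$mat), c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("profile cross-scores are symmetric and self-dominated", {
  set.seed(41)
  for (i in 1:10) {
    a <- build_profile(vapply(1:3, function(j) rand_seq(25), character(1)))
    b <- build_profile(vapply(1:3, function(j) rand_seq(25), character(1)))
    expect_equal(cross_score(a, b), cross_score(b, a))
    # Cauchy-Schwarz: cross bounded by the geometric mean of self-scores
    expect_lte(cross_score(a, b),
               sqrt(self_score(a) * self_score(b)) + 1e-9)
    expect_lte(cross_score(a, b), max(self_score(a), self_score(b)) + 1e-9)
  }
})

test_that("merge_round applies the strict > 0.1 ratio rule", {
  # identical sequences in two clusters: ratio 1.0 -> merged
  s <- c(x = "MKVLAEKWQRTSMKVLAEKW", y = "MKVLAEKWQRTSMKVLAEKW")
  cl <- lapply(names(s), function(id) {
    c0 <- greedy_cluster(s[id], 0.5)[[1]]
    c0 <- align_cluster(c0, s)
    c0$profile <- build_profile(c0$alignment)
    c0
  })
  expect_length(merge_round(cl, s), 1)

  # hand-built profiles with a cross/self ratio of exactly 0.1: not merged
  mk_prof <- function(freqs) {
    mat <- matrix(0, 21, 1, dimnames = list(PROFILE_ALPHABET_TEST, NULL))
    mat[names(freqs), 1] <- freqs
    structure(list(mat = mat, length = 1L), class = "seq_profile")
  }
  s2 <- c(u = "A", v = "C")
  cl2 <- lapply(names(s2), function(id) {
    c0 <- greedy_cluster(s2[id], 0.5)[[1]]
    c0 <- align_cluster(c0, s2)
    c0
  })
  cl2[[1]]$profile <- mk_prof(c(A = 1))
  cl2[[2]]$profile <- mk_prof(c(A = 0.1, C = 0.9))
  expect_equal(cross_score(cl2[[1]]$profile, cl2[[2]]$profile) /
                 max(self_score(cl2[[1]]$profile),
                     self_score(cl2[[2]]$profile)), 0.1)
  expect_length(merge_round(cl2, s2), 2)       # ratio == 0.1: kept apart
  cl2[[2]]$profile <- mk_prof(c(A = 0.2, C = 0.8))
  expect_length(merge_round(cl2, s2), 1)       # ratio 0.2 > 0.1: merged
})

test_that("merging is single-linkage over the pair graph", {
  # B shares a distinct 40-aa block with A and with C; A and C are unrelated
  set.seed(51)
  blkAB <- rand_seq(40); blkBC <- rand_seq(40)
  A <- paste0(blkAB, rand_seq(160))
  B <- paste0(blkAB, rand_seq(120), blkBC)
  C <- paste0(rand_seq(160), blkBC)
  s <- c(A = A, B = B, C = C)
  cl <- greedy_cluster(s, 0.5)
  expect_length(cl, 3)
  merged <- merge_round(cl, s)
  expect_length(merged, 1)   # A~B and B~C exceed 0.1; A joins via linkage
})

test_that("iterative clustering respects the round budget and stops early", {
  # progressive-merge fixture: A and B share a periodic scaffold (merge in
  # round 1); C shares one block with each of A and B at a single offset,
  # crossing the ratio threshold only after the A+B merge lowers the
  # denominator self-score (merge in round 2); round 3 confirms closure
  set.seed(11)
  scaf <- sample(AA_ALPHA, 300, replace = TRUE)
  a <- sample(AA_ALPHA, 300, replace = TRUE)
  b <- sample(AA_ALPHA, 300, replace = TRUE)
  anchor <- seq(1, 300, by = 5)
  a[anchor] <- scaf[anchor]; b[anchor] <- scaf[anchor]
  blkA <- sample(AA_ALPHA, 20, replace = TRUE)
  blkB <- sample(AA_ALPHA, 20, replace = TRUE)
  a[121:140] <- blkA
  b[181:200] <- blkB
  cc <- sample(AA_ALPHA, 100, replace = TRUE)
  cc[10:29] <- blkA; cc[70:89] <- blkB
  seqs <- c(A = paste(a, collapse = ""), B = paste(b, collapse = ""),
            C = paste(cc, collapse = ""))

  # designed preconditions: in round 1 only A~B exceeds the ratio
  cl0 <- greedy_cluster(seqs, 0.5)
  expect_length(cl0, 3)
  cl0 <- lapply(cl0, function(x) {
    x <- align_cluster(x, seqs); x$profile <- build_profile(x$alignment); x
  })
  selfs <- vapply(cl0, function(x) self_score(x$profile), numeric(1))
  ratio <- function(i, j) cross_score(cl0[[i]]$profile, cl0[[j]]$profile) /
    max(selfs[i], selfs[j])
  expect_gt(ratio(1, 2), 0.1)
  expect_lt(ratio(1, 3), 0.1)
  expect_lt(ratio(2, 3), 0.1)

  res <- iterate_clustering(seqs, default_config())
  expect_length(res, 1)                      # closure reached
  expect_identical(attr(res, "rounds"), 3L)  # merge, merge, confirm
  # capping the iterations stops the cascade after the first round
  res1 <- iterate_clustering(seqs, default_config(iterations = 1L))
  expect_length(res1, 2)

  # mutually dissimilar input: unchanged after one early-stopped round
  set.seed(61)
  dis <- c(u = rand_seq(80), v = rand_seq(200), w = rand_seq(140))
  resd <- iterate_clustering(dis, default_config())
  expect_length(resd, 3)
  expect_identical(attr(resd, "rounds"), 1L)
})

test_that("cluster counts never increase across rounds", {
  for (seed in c(71, 72)) {
    seqs <- generate_clustering_fixture(4, 3, 0.25, seed = seed)
    cl <- greedy_cluster(seqs, 0.5)
    n_prev <- length(cl)
    cl <- coconutscan::merge_round(cl, seqs)
    for (r in 1:3) {
      cl2 <- merge_round(cl, seqs)
      expect_lte(length(cl2), length(cl))
      cl <- cl2
    }
    expect_lte(length(cl), n_prev)
    # idempotence once closed: another round changes nothing
    expect_length(merge_round(cl, seqs), length(cl))
  }
})

test_that("representative selection applies the 0.9 identity threshold", {
  base <- "ACDEFGHIKLMNPQRSTVWY"
  mut <- function(k) {
    x <- strsplit(base, "")[[1]]
    x[seq_len(k)] <- c("W", "Y", "V")[seq_len(k)]
    paste(x, collapse = "")
  }
  hi <- c(r1 = base, r2 = mut(1))    # identity 0.95
  expect_equal(pairwise_identity(hi[[1]], hi[[2]]), 0.95)
  expect_length(select_representatives(hi), 1)
  lo <- c(r1 = base, r2 = mut(3))    # identity 0.85
  expect_equal(pairwise_identity(lo[[1]], lo[[2]]), 0.85)
  expect_length(select_representatives(lo), 2)
  expect_identical(select_representatives(c(one = base)), "one")
})

test_that("neighbor joining recovers additive matrices exactly", {
  # 4-leaf tree ((A:1,B:2):1,(C:3,D:4)) and its path-length matrix
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_equal(as.matrix(stats::cophenetic(tr))[LETTERS[1:4], LETTERS[1:4]],
               D, tolerance = 1e-8)
  # random additive 8-leaf matrices
  set.seed(81)
  for (i in 1:3) {
    t0 <- ape::rtree(8)
    D8 <- stats::cophenetic(t0)
    t1 <- nj_tree(D8)
    expect_equal(as.matrix(stats::cophenetic(t1))[rownames(D8), rownames(D8)],
                 as.matrix(D8), tolerance = 1e-8)
  }
  # leaf-label permutation of the input gives the same tree up to relabeling
  perm <- c("C", "A", "D", "B")
  t2 <- nj_tree(D[perm, perm])
  expect_equal(as.matrix(stats::cophenetic(t2))[LETTERS[1:4], LETTERS[1:4]],
               D, tolerance = 1e-8)
  expect_error(nj_tree(c(one = "MKV")), "at least 2")
})
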