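test_that("k-mer distance matches hand-derived cases", {
  expect_equal(kmer_distance("ACDEFG", "ACDEFG"), 0)
  expect_equal(kmer_distance("AAAA", "CCCC", 3), 1)
  expect_equal(kmer_distance("ACDE", "CDEF", 3), 0.5)  # shared {CDE} of 2
  d <- kmer_distance_matrix(c(a = "ACDEFG", b = "ACDEFG", c = "KKKKKK"))
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 1)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("UPGMA reproduces hand-computed trees and tie-breaks", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.2)
  expect_equal(t2$merge, matrix(c(-2L, -1L), 1))

  labs <- c("A", "B", "C")
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(labs, labs))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(1, 2))           # (4+4)/2 = 4, halved
  expect_equal(t3$merge[1, ], c(-2L, -1L))   # A joins B first
  expect_equal(t3$merge[2, ], c(-3L, 1L))
  expect_equal(as_newick(t3), "(C:2,(B:1,A:1):1);")

  deq <- matrix(1, 4, 4); diag(deq) <- 0
  rownames(deq) <- colnames(deq) <- letters[1:4]
  teq <- upgma(deq)
  expect_equal(teq$merge[1, ], c(-2L, -1L))  # lowest-index pair first
})

test_that("row-minimum UPGMA equals the naive cubic reference", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(3:20, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- round(runif(n * (n - 1) / 2), 2)
    d <- d + t(d)
    rownames(d) <- colnames(d) <- sprintf("t%d", 1:n)
    fast <- upgma(d)
    slow <- naive_upgma(d)
    expect_identical(fast$merge, slow$merge)
    expect_equal(fast$height, slow$height)
  }
})

test_that("UPGMA heights agree with hclust average linkage", {
  skip_if_not_installed("ape")
  set.seed(11)
  n <- 12
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)  # distinct, no ties
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("t%d", 1:n)
  tree <- upgma(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(sort(tree$height * 2), sort(hc$height))
  # identical tree shape: cophenetic distances must agree
  ph <- ape::read.tree(text = as_newick(tree))
  cop <- ape::cophenetic.phylo(ph)
  cop_hc <- as.matrix(stats::cophenetic(hc))
  expect_equal(cop[rownames(cop_hc), colnames(cop_hc)], cop_hc,
               tolerance = 1e-4)
})

test_that("pairwise alignment reproduces closed-form cases", {
  r <- pairwise_align("AAAA", "AAAA")
  expect_equal(r$score, 16)
  expect_equal(unname(r$alignment$rows), c("AAAA", "AAAA"))

  r2 <- pairwise_align("", "A")
  expect_equal(r2$score, -8)
  expect_equal(unname(r2$alignment$rows), c("-", "A"))

  r3 <- pairwise_align("A", "")
  expect_equal(r3$score, -8)
  expect_equal(unname(r3$alignment$rows), c("A", "-"))
})

test_that("DP score equals exhaustive enumeration on random short pairs", {
  set.seed(5)
  sub <- load_matrix("BLOSUM62")
  for (rep in 1:25) {
    a <- random_residues(sample(1:6, 1))
    b <- random_residues(sample(0:6, 1))
    got <- pairwise_align(a, b)$score
    want <- brute_force_score(a, b, sub, 8, 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("emitted alignments re-score to exactly the reported score", {
  set.seed(6)
  for (rep in 1:20) {
    a <- random_residues(sample(1:12, 1))
    b <- random_residues(sample(1:12, 1))
    r <- pairwise_align(a, b, matrix = "GONNET250",
                        gaps = gap_model(11, 2))
    expect_equal(rescore_alignment(r$alignment, "GONNET250",
                                   gap_model(11, 2)), r$score)
    expect_equal(degap(r$alignment$rows[[1]]), a)
    expect_equal(degap(r$alignment$rows[[2]]), b)
  }
})

test_that("branch matrices have DP-table shape and traceback is finite", {
  r <- pairwise_align("ACDEF", "ADF", keep_state = TRUE)
  st <- r$state
  expect_equal(dim(st$bM), c(6, 4))
  expect_equal(dim(st$bX), c(6, 4))
  expect_equal(dim(st$bY), c(6, 4))
  moves <- tmaligner:::traceback_moves(st)
  expect_lte(length(moves), 5 + 3)
  expect_gte(length(moves), 5)
  expect_equal(sum(moves != "left"), 5)  # consumes all of sequence A
  expect_equal(sum(moves != "up"), 3)    # and all of B
})

test_that("profile alignment reduces to pairwise and preserves members", {
  pa <- pairwise_align("ACDEF", "ACEF", ids = c("x", "y"))
  p <- new_msa("x", "ACDEF")
  q <- new_msa("y", "ACEF")
  pr <- profile_align(p, q)
  expect_equal(pr$score, pa$score)
  expect_equal(pr$alignment$rows, pa$alignment$rows)

  same <- profile_align(new_msa("x", "ACDEF"), new_msa("y", "ACDEF"))
  expect_equal(same$alignment$width, 5)  # no new gap columns

  expect_error(profile_align(new_msa("x", "AC"), structure(
    list(ids = character(0), rows = character(0), width = 0L,
         col_labels = NULL), class = "tm_msa")), "empty profile")
})

test_that("existing gap structure is preserved under profile merging", {
  p <- new_msa(c("a", "b"), c("AC-EF", "ACDEF"))
  q <- new_msa("c", "CEF")
  merged <- profile_align(p, q)$alignment
  sub <- gsub("-+", "-", merged$rows[["a"]])
  expect_equal(degap(merged$rows[["a"]]), "ACEF")
  expect_equal(degap(merged$rows[["b"]]), "ACDEF")
  # row "a" keeps its gap relative to row "b": columns of a's residues
  # within the merged alignment are a subsequence of b's residue columns
  ma <- strsplit(merged$rows[["a"]], "")[[1]]
  mb <- strsplit(merged$rows[["b"]], "")[[1]]
  expect_true(all(ma[ma != "-"] == mb[ma != "-"]))
})

test_that("progressive alignment handles identical and ordered inputs", {
  seqs <- c(s1 = "MKILV", s2 = "MKILV", s3 = "MKILV")
  tree <- upgma(kmer_distance_matrix(seqs))
  aln <- progressive_align(seqs, tree)
  expect_equal(aln$width, 5)
  expect_equal(aln$ids, names(seqs))
  expect_true(all(vapply(names(seqs),
                         function(id) degap(aln$rows[[id]]) == seqs[[id]],
                         TRUE)))

  seqs2 <- c(a = "ACDE", b = "ACD")
  t2 <- upgma(kmer_distance_matrix(seqs2))
  pa <- pairwise_align("ACDE", "ACD", ids = c("a", "b"))
  expect_equal(unname(progressive_align(seqs2, t2)$rows),
               unname(pa$alignment$rows))

  expect_error(progressive_align(c(x = "AC"), structure(
    list(merge = matrix(c(-1L, -2L), 1), height = 0.1,
         labels = c("x", "y")), class = "guide_tree")), "match")
})

test_that("guide-tree order scores at least as well as an arbitrary order", {
  seqs <- c(a = "MKILV", b = "MKLV", c = "AQRST", d = "AQRT")
  sub <- load_matrix("BLOSUM62")
  tree <- upgma(kmer_distance_matrix(seqs))
  chain <- structure(list(
    merge = rbind(c(-2L, -1L), c(-3L, 1L), c(-4L, 2L)),
    height = c(0.1, 0.2, 0.3), labels = names(seqs)),
    class = "guide_tree")
  by_tree <- progressive_align(seqs, tree)
  by_chain <- progressive_align(seqs, chain)
  expect_gte(column_pair_score(by_tree, sub),
             column_pair_score(by_chain, sub))
})
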