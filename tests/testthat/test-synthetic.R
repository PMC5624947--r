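test_that("a mutation-free family is identical and gapless", {
  fam <- simulate_family(n_sequences = 4, substitution_rate = 0,
                         loop_indel_rate = 0, seed = 1)
  expect_equal(length(unique(fam$records$residues)), 1)
  expect_equal(fam$true_alignment$width,
               nchar(fam$records$residues[1]))
  expect_false(any(grepl("-", unname(fam$true_alignment$rows), fixed = TRUE)))
  expect_equal(measure_identity(fam), 100)
})

test_that("the same seed reproduces the family byte for byte", {
  a <- simulate_family(seed = 123)
  b <- simulate_family(seed = 123)
  expect_identical(a$records, b$records)
  expect_identical(a$true_alignment$rows, b$true_alignment$rows)
  expect_identical(a$true_topology, b$true_topology)
  c <- simulate_family(seed = 124)
  expect_false(identical(a$records$residues, c$records$residues))
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(55)
  x1 <- runif(3)
  set.seed(55)
  invisible(simulate_family(seed = 9))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("K = 0 gives an all-loop soluble family", {
  fam <- simulate_family(n_sequences = 3, n_helices = 0, seed = 2)
  for (ann in fam$true_topology) {
    expect_equal(sum(ann$label == "TMhelix"), 0)
  }
})

test_that("family invariants hold across random parameter draws", {
  set.seed(321)
  for (rep in 1:15) {
    fam <- simulate_family(
      n_sequences = sample(2:8, 1),
      n_helices = sample(0:7, 1),
      substitution_rate = runif(1, 0, 0.5),
      loop_indel_rate = runif(1, 0, 0.5),
      seed = 2000 + rep)
    # round trip: degapped rows equal the records
    for (i in seq_len(nrow(fam$records))) {
      expect_identical(degap(fam$true_alignment$rows[[fam$records$id[i]]]),
                       fam$records$residues[i])
    }
    # topology tiles each sequence
    for (i in seq_len(nrow(fam$records))) {
      ann <- fam$true_topology[[fam$records$id[i]]]
      expect_equal(ann$end[nrow(ann)], nchar(fam$records$residues[i]))
    }
    # TM columns of the true alignment are indel-free: for every member,
    # columns holding its TM residues hold residues (not gaps) in every row
    m <- as.matrix(fam$true_alignment)
    tm_col <- rep(FALSE, ncol(m))
    for (i in seq_len(nrow(m))) {
      id <- rownames(m)[i]
      ann <- fam$true_topology[[id]]
      tmr <- unlist(lapply(which(ann$label == "TMhelix"), function(s) {
        (ann$start[s] + 1L):ann$end[s]
      }))
      ridx <- cumsum(m[i, ] != "-")
      tm_col <- tm_col | (m[i, ] != "-" & ridx %in% tmr)
    }
    if (any(tm_col)) {
      expect_false(any(m[, tm_col] == "-"))
    }
  }
})

test_that("identity decreases with the substitution rate", {
  idents <- vapply(c(0, 0.2, 0.4), function(rate) {
    mean(vapply(1:20, function(s) {
      measure_identity(simulate_family(n_sequences = 2,
                                       substitution_rate = rate,
                                       loop_indel_rate = 0,
                                       seed = 3000 + s))
    }, 0))
  }, 0)
  expect_equal(idents[1], 100)
  expect_true(all(diff(idents) < 0))
})

test_that("identity counts matches over aligned residue pairs", {
  rows <- c(m1 = paste(rep("A", 100), collapse = ""),
            m2 = paste(c(rep("A", 99), "C"), collapse = ""))
  fam <- structure(list(true_alignment = new_msa(names(rows),
                                                 unname(rows))),
                   class = "sim_family")
  expect_equal(measure_identity(fam), 99)
  expect_error(measure_identity(structure(
    list(true_alignment = new_msa("m1", "ACDE")), class = "sim_family")),
    "at least 2")
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_family(substitution_rate = 1), "rates")
  expect_error(simulate_family(loop_indel_rate = -0.1), "rates")
  expect_error(simulate_family(n_sequences = 0), "family size")
})
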