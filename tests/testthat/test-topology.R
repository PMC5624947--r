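test_that("hydropathy profile matches the Kyte-Doolittle table", {
  expect_equal(hydropathy_profile("AIR", window = 1), c(1.8, 4.5, -4.5))
  expect_equal(hydropathy_profile("III", window = 3), rep(4.5, 3))
  expect_equal(hydropathy_profile("A", window = 19), 1.8)
  # truncated-window means at the ends, independently recomputed
  v <- c(A = 1.8, I = 4.5, R = -4.5, L = 3.8, G = -0.4)
  prof <- hydropathy_profile("AIRLG", window = 3)
  manual <- vapply(1:5, function(i) {
    mean(v[max(1, i - 1):min(5, i + 1)])
  }, 0)
  expect_equal(prof, manual)
  expect_error(hydropathy_profile("", 3), "empty")
  expect_error(hydropathy_profile("AIR", 4), "odd")
})

test_that("a planted hydrophobic run is called as one helix within 3 residues", {
  res <- paste0(strrep("R", 10), strrep("I", 21), strrep("R", 10))
  ann <- predict_topology(list(id = "x", residues = res))
  tm <- ann[ann$label == "TMhelix", ]
  expect_equal(nrow(tm), 1)
  expect_lte(abs(tm$start - 10), 3)
  expect_lte(abs(tm$end - 31), 3)
})

test_that("all-polar sequences yield a single outside segment", {
  ann <- predict_topology(list(id = "x", residues = strrep("R", 40)))
  expect_equal(ann$label, "outside")
  expect_equal(ann$start, 0L)
  expect_equal(ann$end, 40L)
})

test_that("very long hydrophobic runs are split into legal helix lengths", {
  ann <- predict_topology(list(id = "x", residues = strrep("I", 200)))
  tm <- ann[ann$label == "TMhelix", ]
  expect_gt(nrow(tm), 1)
  expect_true(all(tm$end - tm$start <= 35))
  expect_true(all(tm$end - tm$start >= 15))
  # full coverage, no overlaps
  expect_equal(ann$start[1], 0L)
  expect_equal(ann$end[nrow(ann)], 200L)
})

test_that("segment_sequence slices regions that concatenate to the input", {
  rec <- list(id = "x", residues = "ACDEFGHIKL")
  ann <- read_tm_annotations(
    text = paste("x TMHMM2.0 outside 1 4",
                 "x TMHMM2.0 TMhelix 5 8",
                 "x TMHMM2.0 inside 9 10", sep = "\n"))$x
  seg <- segment_sequence(rec, ann)
  expect_equal(seg$regions$seq, c("ACDE", "FGHI", "KL"))
  expect_equal(seg$regions$label, c("outside", "TMhelix", "inside"))

  short <- read_tm_annotations(
    text = "x TMHMM2.0 outside 1 9")$x
  expect_error(segment_sequence(rec, short), "cover")
})

test_that("TM-count classification finds the dominant class, ties upward", {
  mk <- function(id, n_tm) {
    res <- paste0(strrep("G", 8),
                  paste(rep(paste0(strrep("I", 20), strrep("G", 12)), n_tm),
                        collapse = ""))
    if (n_tm == 0) res <- strrep("G", 30)
    rec <- list(id = id, residues = res)
    segment_sequence(rec, predict_topology(rec))
  }
  segs <- list(mk("a", 7), mk("b", 7), mk("c", 7), mk("d", 2))
  cls <- classify_by_tm_count(segs)
  expect_equal(cls$dominant_count, 7)
  expect_equal(lengths(cls$groups)[["7"]], 3)
  expect_equal(lengths(cls$groups)[["2"]], 1)

  cls2 <- classify_by_tm_count(list(mk("a", 3), mk("b", 5)))
  expect_equal(cls2$dominant_count, 5)

  cls3 <- classify_by_tm_count(list(mk("a", 0), mk("b", 0)))
  expect_equal(cls3$dominant_count, 0)

  expect_error(classify_by_tm_count(list()), "no sequences")
})

test_that("predicted annotations always segment their sequence cleanly", {
  set.seed(7)
  for (rep in 1:25) {
    fam <- simulate_family(n_sequences = 1,
                           n_helices = sample(0:4, 1),
                           substitution_rate = runif(1, 0, 0.4),
                           seed = 1000 + rep)
    rec <- fam$records[1, ]
    ann <- predict_topology(rec)
    seg <- segment_sequence(rec, ann)
    expect_equal(paste(seg$regions$seq, collapse = ""), rec$residues)
    # tiling invariants
    expect_equal(ann$start[1], 0L)
    expect_equal(ann$end[nrow(ann)], nchar(rec$residues))
    if (nrow(ann) > 1) {
      expect_equal(ann$start[-1], ann$end[-nrow(ann)])
      expect_true(all(ann$label[-1] != ann$label[-nrow(ann)]))
    }
  }
})
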