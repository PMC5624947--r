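# Independent oracles: brute-force enumeration, naive reference
# implementations and third-party routines used only to cross-check the
# package's own code paths.

# exhaustive enumeration of every global alignment path, scored with the
# affine convention open + (L-1)*ext per maximal gap run
brute_force_score <- function(a, b, sub, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, 1L, sc + sub[ca[i], cb[j]])
    if (i <= na) rec(i + 1L, j, 2L,
                     sc - if (last == 2L) gap_extend else gap_open)
    if (j <= nb) rec(i, j + 1L, 3L,
                     sc - if (last == 3L) gap_extend else gap_open)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# textbook O(N^3) UPGMA with the same tie-break (lowest row-major pair)
naive_upgma <- function(d) {
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  D <- unname(d)
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    a <- NA; b <- NA; bv <- Inf
    for (i in act) {
      for (j in act) {
        if (i < j && D[i, j] < bv) {
          bv <- D[i, j]; a <- i; b <- j
        }
      }
    }
    height[step] <- bv / 2
    merge[step, ] <- sort(c(code[a], code[b]))
    for (l in act) {
      if (l != a && l != b) {
        D[a, l] <- D[l, a] <- (sizes[a] * D[a, l] + sizes[b] * D[b, l]) /
          (sizes[a] + sizes[b])
      }
    }
    active[b] <- FALSE
    sizes[a] <- sizes[a] + sizes[b]
    code[a] <- step
  }
  list(merge = merge, height = height, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-occurrence multi-pattern scan through Biostrings (finds overlapping
# matches, unlike gregexpr)
oracle_scan <- function(patterns, text) {
  hp <- integer(0); hx <- integer(0)
  subj <- Biostrings::BString(text)
  for (k in seq_along(patterns)) {
    if (nchar(patterns[k]) > nchar(text)) next
    m <- Biostrings::matchPattern(patterns[k], subj)
    st <- BiocGenerics::start(m) - 1L
    hp <- c(hp, rep(k, length(st)))
    hx <- c(hx, st)
  }
  ord <- order(hx, hp)
  data.frame(pattern = hp[ord], pos = hx[ord])
}

# naive sum-of-pairs scorer: enumerate aligned residue pairs as string keys
oracle_sp <- function(test, ref) {
  pair_keys <- function(msa) {
    m <- as.matrix(msa)
    m <- m[sort(rownames(m)), , drop = FALSE]
    ids <- rownames(m)
    ridx <- t(apply(m != "-", 1L, cumsum))
    keys <- character(0)
    for (col in seq_len(ncol(m))) {
      have <- which(m[, col] != "-")
      if (length(have) < 2L) next
      for (u in seq_along(have)[-length(have)]) {
        for (v in (u + 1L):length(have)) {
          i <- have[u]; j <- have[v]
          keys <- c(keys, paste0(ids[i], ":", ridx[i, col], "|",
                                 ids[j], ":", ridx[j, col]))
        }
      }
    }
    keys
  }
  rk <- pair_keys(ref)
  tk <- pair_keys(test)
  sum(rk %in% tk) / length(rk)
}

# simple column-wise substitution-score sum of an alignment (no gap terms)
column_pair_score <- function(msa, sub) {
  m <- as.matrix(msa)
  total <- 0
  for (col in seq_len(ncol(m))) {
    have <- which(m[, col] != "-")
    if (length(have) < 2L) next
    for (u in seq_along(have)[-length(have)]) {
      for (v in (u + 1L):length(have)) {
        total <- total + sub[m[have[u], col], m[have[v], col]]
      }
    }
  }
  total
}

random_residues <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random gapped alignment over random records (for self-consistency checks)
random_alignment <- function(n_rows = 4L, len = 12L) {
  width <- len + 6L
  rows <- vapply(seq_len(n_rows), function(i) {
    res <- strsplit(random_residues(len, LETTERS[c(1, 3, 4, 5, 7, 9)]),
                    "")[[1]]
    gaps <- sample(width, width - len)
    row <- rep("-", width)
    row[-gaps] <- res
    paste(row, collapse = "")
  }, "")
  aln <- new_msa(sprintf("r%d", seq_len(n_rows)), rows)
  # drop all-gap columns so the alignment is a valid finished alignment
  m <- as.matrix(aln)
  keep <- colSums(m != "-") > 0
  new_msa(aln$ids,
          apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""))
}
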