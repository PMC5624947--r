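# Pairwise/profile affine-gap dynamic programming with branch-matrix
# traceback, k-mer distances, and UPGMA guide trees.

# residue counts per column (gaps excluded), 21 x width
profile_counts <- function(msa) {
  w <- msa$width
  n <- length(msa$ids)
  if (w == 0L) return(matrix(0, length(TM_ALPHABET), 0))
  chm <- do.call(rbind, strsplit(unname(msa$rows), ""))
  idx <- match(chm, TM_ALPHABET)          # NA for gaps
  dim(idx) <- dim(chm)
  counts <- matrix(0, length(TM_ALPHABET), w)
  for (j in seq_len(w)) {
    counts[, j] <- tabulate(idx[, j], nbins = length(TM_ALPHABET))
  }
  counts
}

#' k-mer dissimilarity between two sequences
#'
#' Fractional k-mer distance used for guide-tree construction:
#' `1 - shared / (min(len) - k + 1)` where `shared` counts k-mer types with
#' their minimum multiplicity in the two sequences. `k` is clamped to the
#' shorter sequence when needed. Identical sequences have distance 0.
#'
#' @param a,b Residue strings.
#' @param k Word length (default 3).
#' @return Dissimilarity in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, k = 3L) {
  na <- nchar(a); nb <- nchar(b)
  k <- max(1L, min(k, na, nb))
  denom <- min(na, nb) - k + 1L
  if (denom < 1L) return(if (identical(a, b)) 0 else 1)
  ka <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  ta <- table(ka); tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
  max(0, 1 - shared / denom)
}

#' Pairwise k-mer distance matrix
#'
#' @param seqs Named character vector of residue strings (>= 2).
#' @param k Word length.
#' @return Symmetric matrix of [kmer_distance()] values with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k)
    }
  }
  d
}

# smallest-index minimum of a distance-matrix row among active columns
row_min <- function(drow, active, self) {
  cand <- which(active)
  cand <- cand[cand != self]
  v <- drow[cand]
  j <- cand[which.min(v)]            # which.min ties -> smallest index
  c(j = j, v = drow[j])
}

#' UPGMA guide tree
#'
#' Agglomerative average-linkage clustering: the closest pair of clusters is
#' merged at height d/2 and distances to the merged cluster are
#' size-weighted averages. The closest pair is found through an array of
#' per-row minimum references, making each merge O(N) and the whole tree
#' O(N^2); the result (topology and heights) is identical to the cubic
#' textbook algorithm under the tie-break "lowest (i, j) pair in row-major
#' order".
#'
#' @param d Symmetric distance matrix with labelled rows.
#' @return A `guide_tree`: list with `merge` (hclust convention), `height`
#'   (merge heights, d/2) and `labels`.
#' @export
upgma <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2L, isSymmetric(unname(d)))
  labels <- rownames(d) %||% as.character(seq_len(n))
  D <- unname(d)
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n)                   # hclust cluster codes
  rm_j <- integer(n); rm_v <- numeric(n)
  for (i in seq_len(n)) {
    rm <- row_min(D[i, ], active, i)
    rm_j[i] <- rm[["j"]]; rm_v[i] <- rm[["v"]]
  }
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    rows <- which(active)
    if (length(rows) == 1L) break
    best <- rows[rm_v[rows] == min(rm_v[rows])][1]   # smallest i on ties
    a <- best; b <- rm_j[best]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    height[step] <- D[a, b] / 2
    merge[step, ] <- sort(c(code[a], code[b]))
    others <- rows[!(rows %in% c(a, b))]
    newd <- (sizes[a] * D[a, others] + sizes[b] * D[b, others]) /
      (sizes[a] + sizes[b])
    D[a, others] <- D[others, a] <- newd
    active[b] <- FALSE
    sizes[a] <- sizes[a] + sizes[b]
    code[a] <- step
    if (step == n - 1L) break
    rm <- row_min(D[a, ], active, a)
    rm_j[a] <- rm[["j"]]; rm_v[a] <- rm[["v"]]
    for (l in which(active)) {
      if (l == a) next
      if (rm_j[l] %in% c(a, b)) {
        rm <- row_min(D[l, ], active, l)
        rm_j[l] <- rm[["j"]]; rm_v[l] <- rm[["v"]]
      } else if (D[l, a] < rm_v[l] ||
                 (D[l, a] == rm_v[l] && a < rm_j[l])) {
        rm_j[l] <- a; rm_v[l] <- D[l, a]
      }
    }
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("UPGMA guide tree with", length(x$labels), "leaves; root height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Export a guide tree as a Newick string
#'
#' Branch lengths are differences of merge heights (the tree is
#' ultrametric).
#'
#' @param tree A `guide_tree`.
#' @return A Newick string terminated by `";"`.
#' @export
as_newick <- function(tree) {
  sub_nwk <- function(node, parent_h) {
    if (node < 0L) {
      sprintf("%s:%.6g", tree$labels[-node], parent_h)
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%.6g",
              sub_nwk(tree$merge[node, 1], h),
              sub_nwk(tree$merge[node, 2], h),
              parent_h - h)
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", sub_nwk(tree$merge[root, 1], h), ",",
         sub_nwk(tree$merge[root, 2], h), ");")
}

# dynamic programming ----------------------------------------------------

# run the three-layer DP on two profiles; returns the raw DP state
profile_dp_state <- function(p, q, sub, gaps) {
  ca <- profile_counts(p); cb <- profile_counts(q)
  na <- length(p$ids); nb <- length(q$ids)
  S <- sub[TM_ALPHABET, TM_ALPHABET]
  P <- crossprod(ca, S %*% cb) / (na * nb)
  st <- .gotoh_dp(P, gaps$gap_open, gaps$gap_extend)
  st$m <- nrow(P); st$n <- ncol(P)
  st
}

# recover the move sequence (diag/up/left) purely from the branch matrices
traceback_moves <- function(st) {
  i <- st$m; j <- st$n; layer <- st$final_layer
  moves <- character(i + j)
  pos <- i + j
  while (i > 0L || j > 0L) {
    if (pos < 1L) stop("branch-matrix traceback overran (m + n) steps")
    if (layer == 1L) {
      moves[pos] <- "diag"
      layer <- st$bM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (layer == 2L) {
      moves[pos] <- "up"
      layer <- st$bX[i + 1L, j + 1L]
      i <- i - 1L
    } else if (layer == 3L) {
      moves[pos] <- "left"
      layer <- st$bY[i + 1L, j + 1L]
      j <- j - 1L
    } else {
      stop("invalid branch code in traceback")
    }
    pos <- pos - 1L
  }
  moves[(pos + 1L):length(moves)]
}

# insert whole gap columns into both profiles according to the moves
merge_profiles <- function(p, q, moves, col_labels = NULL) {
  consume_a <- moves != "left"
  consume_b <- moves != "up"
  expand <- function(msa, consume) {
    src <- cumsum(consume)
    if (msa$width == 0L) {
      rows <- rep(strrep(GAP_CHAR, length(moves)), length(msa$ids))
      return(stats::setNames(rows, msa$ids))
    }
    chm <- do.call(rbind, strsplit(unname(msa$rows), ""))
    out <- matrix(GAP_CHAR, nrow(chm), length(moves))
    out[, consume] <- chm[, src[consume], drop = FALSE]
    stats::setNames(apply(out, 1L, paste, collapse = ""), msa$ids)
  }
  rows <- c(expand(p, consume_a), expand(q, consume_b))
  new_msa(c(p$ids, q$ids), unname(rows), col_labels = col_labels)
}

#' Optimal global pairwise alignment
#'
#' Global affine-gap alignment (Gotoh three-layer recurrence). Transitions
#' are recorded in a branch matrix per layer, and the alignment is
#' recovered solely from those branch matrices; ties prefer diagonal over
#' up over left moves. Terminal gaps are penalized like internal ones.
#'
#' @param a,b Residue strings (either may be empty).
#' @param matrix Substitution matrix name or matrix (default `"BLOSUM62"`).
#' @param gaps A [gap_model()].
#' @param ids Row ids for the output alignment.
#' @param keep_state If `TRUE`, attach the DP layers and branch matrices.
#' @return List with `score` and `alignment` (a 2-row `tm_msa`); with
#'   `keep_state`, also `state`.
#' @examples
#' pairwise_align("AAAA", "AAAA")$score  # 16 under BLOSUM62
#' @export
pairwise_align <- function(a, b, matrix = "BLOSUM62", gaps = gap_model(),
                           ids = c("A", "B"), keep_state = FALSE) {
  sub <- load_matrix(matrix)
  p <- new_msa(ids[1], a)
  q <- new_msa(ids[2], b)
  res <- profile_align_impl(p, q, sub, gaps, keep_state = keep_state)
  res
}

# shared implementation for pairwise and profile alignment
profile_align_impl <- function(p, q, sub, gaps, keep_state = FALSE) {
  wp <- p$width; wq <- q$width
  if (wp == 0L || wq == 0L) {
    w <- max(wp, wq)
    score <- if (w > 0L) -gap_cost(gaps, w) else 0
    moves <- if (wp == 0L) rep("left", w) else rep("up", w)
    aln <- merge_profiles(p, q, moves)
    return(list(score = score, alignment = aln))
  }
  st <- profile_dp_state(p, q, sub, gaps)
  moves <- traceback_moves(st)
  aln <- merge_profiles(p, q, moves)
  out <- list(score = st$score, alignment = aln)
  if (keep_state) out$state <- st
  out
}

#' Align two profiles
#'
#' Same recurrence as [pairwise_align()]; the column-vs-column score is the
#' average substitution score over all residue pairs between the two
#' columns (gap symbols contribute 0 to the numerator; the denominator is
#' `members(p) * members(q)`). Existing gaps are never touched: only whole
#' gap columns are inserted into either profile.
#'
#' @param p,q Alignments (`tm_msa`) acting as profiles.
#' @inheritParams pairwise_align
#' @return List with `score` and the merged `alignment`.
#' @export
profile_align <- function(p, q, matrix = "BLOSUM62", gaps = gap_model(),
                          keep_state = FALSE) {
  if (length(p$ids) == 0L || length(q$ids) == 0L) stop("empty profile")
  profile_align_impl(p, q, load_matrix(matrix), gaps, keep_state = keep_state)
}

#' Progressive multiple alignment over a guide tree
#'
#' Merges profiles by post-order traversal of the guide tree (most similar
#' clusters first). Output rows follow the input order.
#'
#' @param seqs Named character vector of residue strings (may include empty
#'   strings, which become all-gap rows).
#' @param tree A `guide_tree` whose labels equal `names(seqs)`.
#' @inheritParams pairwise_align
#' @return A `tm_msa` alignment.
#' @export
progressive_align <- function(seqs, tree, matrix = "BLOSUM62",
                              gaps = gap_model()) {
  if (!setequal(tree$labels, names(seqs))) {
    stop("guide-tree leaves do not match sequence ids")
  }
  sub <- load_matrix(matrix)
  leaf <- function(lbl) new_msa(lbl, seqs[[lbl]])
  prof <- vector("list", nrow(tree$merge))
  get_node <- function(codeval) {
    if (codeval < 0L) leaf(tree$labels[-codeval]) else prof[[codeval]]
  }
  for (k in seq_len(nrow(tree$merge))) {
    p <- get_node(tree$merge[k, 1])
    q <- get_node(tree$merge[k, 2])
    prof[[k]] <- profile_align_impl(p, q, sub, gaps)$alignment
  }
  final <- prof[[nrow(tree$merge)]]
  new_msa(names(seqs), unname(final$rows[names(seqs)]))
}

#' Re-score an emitted pairwise alignment column by column
#'
#' Utility used to verify score/alignment consistency: sums substitution
#' scores over residue-residue columns and charges each maximal gap run
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param alignment A 2-row `tm_msa`.
#' @inheritParams pairwise_align
#' @return The alignment score.
#' @export
rescore_alignment <- function(alignment, matrix = "BLOSUM62",
                              gaps = gap_model()) {
  stopifnot(length(alignment$ids) == 2L)
  sub <- load_matrix(matrix)
  m <- as.matrix(alignment)
  score <- 0
  for (r in 1:2) {
    isgap <- m[r, ] == GAP_CHAR
    if (any(isgap)) {
      runs <- rle(isgap)
      score <- score - sum(gap_cost(gaps, runs$lengths[runs$values]))
    }
  }
  both <- m[1, ] != GAP_CHAR & m[2, ] != GAP_CHAR
  score + sum(sub[cbind(m[1, both], m[2, both])])
}
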