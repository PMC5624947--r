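# End-to-end workflow: predict/import topology, partition, classify by TM
# count, region-wise progressive alignment of the dominant class, stitch,
# merge off-class sequences, report.

#' Configuration for [tm_align()]
#'
#' Defaults follow the method's stated defaults: PHAT-selected matrix for
#' transmembrane regions with gap opening penalty 8 and extension penalty 1.
#' Loop (cytoplasmic / non-cytoplasmic) regions default to BLOSUM62, since
#' they behave like soluble sequence; setting `matrix` forces a single
#' matrix everywhere.
#'
#' @param matrix Optional matrix name forcing one matrix for all regions.
#' @param tm_matrix Matrix for transmembrane slots (default `"PHAT"`).
#' @param loop_matrix Matrix for loop slots and whole-sequence merges
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 8 and 1).
#' @param window,threshold,min_helix_len,max_helix_len Topology predictor
#'   parameters, see [topology_params()].
#' @param consensus_fraction Majority fraction for the consensus row.
#' @param max_seqs Input cap mirroring the public server's default load
#'   limit (5000); 0 disables the cap.
#' @return A list of class `tm_align_config`.
#' @export
tm_align_config <- function(matrix = NULL, tm_matrix = "PHAT",
                            loop_matrix = "BLOSUM62", gap_open = 8,
                            gap_extend = 1, window = 19L, threshold = 1.6,
                            min_helix_len = 15L, max_helix_len = 35L,
                            consensus_fraction = 0.5, max_seqs = 5000L) {
  if (!is.null(matrix)) tm_matrix <- loop_matrix <- matrix
  structure(list(matrix = matrix, tm_matrix = tm_matrix,
                 loop_matrix = loop_matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 predictor = topology_params(window, threshold,
                                             min_helix_len, max_helix_len),
                 consensus_fraction = consensus_fraction,
                 max_seqs = as.integer(max_seqs)),
            class = "tm_align_config")
}

#' Region-aware multiple sequence alignment of transmembrane proteins
#'
#' Runs the full workflow: topology (predicted by hydropathy analysis, or
#' imported annotations when supplied) \eqn{\to} partition into
#' transmembrane/loop regions \eqn{\to} group sequences by TM count
#' \eqn{\to} UPGMA guide tree on the dominant group \eqn{\to} independent
#' progressive alignment of each region slot \eqn{\to} Wu-Manber-anchored
#' stitching into a seed alignment \eqn{\to} profile-merge of off-class
#' sequences (in order of increasing k-mer distance to the seed consensus)
#' \eqn{\to} final reporting. Transmembrane columns of the seed alignment
#' contain only transmembrane residues or gaps, so helices are never
#' disrupted by loop indels. When no sequence has a predicted helix the
#' method falls back to plain progressive alignment with a warning.
#'
#' @param records Record data frame from [read_fasta()] (>= 2 rows).
#' @param topology Optional named list of imported annotations (from
#'   [read_tm_annotations()]); must cover every record id. Overrides
#'   prediction.
#' @param config A [tm_align_config()].
#' @return An object of class `tm_align` with elements `alignment` (the
#'   full `tm_msa`, with per-column region labels), `seed_alignment` (the
#'   stitched dominant-class alignment), `consensus`, `tm_info`, `tree`,
#'   `dominant_count`, `tm_counts` and `params`.
#' @export
tm_align <- function(records, topology = NULL, config = tm_align_config()) {
  if (nrow(records) < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(records$id)) stop("duplicate record ids")
  if (config$max_seqs > 0L && nrow(records) > config$max_seqs) {
    stop("more than max_seqs (", config$max_seqs, ") input sequences")
  }
  gaps <- gap_model(config$gap_open, config$gap_extend)

  annotations <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    if (!is.null(topology)) {
      ann <- topology[[rec$id]]
      if (is.null(ann)) stop("imported topology is missing id ", rec$id)
      ann
    } else {
      predict_topology(rec, config$predictor)
    }
  })
  names(annotations) <- records$id
  segmented <- lapply(seq_len(nrow(records)), function(i) {
    segment_sequence(records[i, ], annotations[[i]])
  })

  cls <- classify_by_tm_count(segmented)
  k <- cls$dominant_count
  tm_counts <- vapply(segmented, function(s) tm_count(s$annotation), 0L)

  if (k == 0L) {
    warning("no transmembrane helices in any sequence; ",
            "falling back to plain progressive alignment")
    seqs <- stats::setNames(records$residues, records$id)
    tree <- upgma(kmer_distance_matrix(seqs))
    aln <- progressive_align(seqs, tree, config$loop_matrix, gaps)
    aln$col_labels <- rep("loop", aln$width)
    seed <- aln
  } else {
    dom_idx <- cls$groups[[as.character(k)]]
    dom <- segmented[dom_idx]
    dom_ids <- vapply(dom, `[[`, "", "id")
    dom_seqs <- stats::setNames(vapply(dom, `[[`, "", "residues"), dom_ids)

    # one guide tree on whole sequences, reused for every region slot
    tree <- if (length(dom) >= 2L) upgma(kmer_distance_matrix(dom_seqs))

    slot_strings <- lapply(dom, region_slots, k = k)
    n_slots <- 2L * k + 1L
    blocks <- vector("list", n_slots)
    for (s in seq_len(n_slots)) {
      is_tm <- s %% 2L == 0L
      mat <- if (is_tm) config$tm_matrix else config$loop_matrix
      seqs_s <- stats::setNames(
        vapply(slot_strings, `[`, "", s), dom_ids)
      blocks[[s]] <- if (length(dom) >= 2L) {
        progressive_align(seqs_s, tree, mat, gaps)
      } else {
        new_msa(dom_ids, unname(seqs_s))
      }
    }
    seed <- stitch(blocks, dom)
    assert_roundtrip(seed, records[match(dom_ids, records$id), ])

    # merge off-class sequences into the seed, closest first
    off_idx <- setdiff(seq_along(segmented), dom_idx)
    if (length(off_idx) > 0L) {
      cons <- degap(consensus_sequence(seed, config$consensus_fraction))
      dvals <- vapply(off_idx, function(i) {
        kmer_distance(segmented[[i]]$residues, cons)
      }, 0)
      aln <- seed
      for (i in off_idx[order(dvals)]) {
        one <- new_msa(segmented[[i]]$id, segmented[[i]]$residues)
        merged <- profile_align(aln, one, config$loop_matrix, gaps)$alignment
        old_labels <- aln$col_labels
        # columns newly inserted into the seed profile carry no region label
        lab <- rep("mixed", merged$width)
        lab[degap_cols(merged, aln$ids)] <- old_labels
        merged$col_labels <- lab
        aln <- merged
      }
    } else {
      aln <- seed
    }
    aln <- new_msa(records$id, unname(aln$rows[records$id]),
                   col_labels = aln$col_labels)
  }

  aln <- strip_allgap_columns(aln)
  assert_roundtrip(aln, records)
  res <- structure(
    list(alignment = aln, seed_alignment = seed,
         consensus = consensus_sequence(aln, config$consensus_fraction),
         tm_info = tm_info(segmented), tree = tree,
         dominant_count = k,
         tm_counts = stats::setNames(tm_counts, records$id),
         params = config, n_sequences = nrow(records)),
    class = "tm_align")
  res
}

# columns of `merged` that originate from the old profile (identified as the
# columns where not every old row is a gap, plus old all-gap columns kept in
# order); old profiles produced by this pipeline never contain all-gap
# columns, so the simple mask is exact
degap_cols <- function(merged, old_ids) {
  m <- as.matrix(merged)[old_ids, , drop = FALSE]
  which(colSums(m != GAP_CHAR) > 0L)
}

#' Stitch region-slot alignments into a full-length alignment
#'
#' Horizontally concatenates the slot alignments in topology order
#' (loop0, TM1, loop1, ..., TMK, loopK). Before concatenation each member's
#' degapped slot rows are verified (via Wu-Manber anchoring,
#' [locate_anchors()]) to tile its original sequence exactly; a failure
#' indicates corrupted segmentation. Columns inherit the slot's region
#' label (`"TM"` or `"loop"`).
#'
#' @param blocks List of slot alignments (`tm_msa`), all with identical row
#'   ids in identical order.
#' @param segmented List of `segmented_seq` for the same members.
#' @return A `tm_msa` with column labels.
#' @export
stitch <- function(blocks, segmented) {
  ids <- blocks[[1]]$ids
  res_by_id <- stats::setNames(
    vapply(segmented, `[[`, "", "residues"),
    vapply(segmented, `[[`, "", "id"))
  for (id in ids) {
    regions <- vapply(blocks, function(b) degap(b$rows[[id]]), "")
    locate_anchors(regions, res_by_id[[id]])
  }
  rows <- vapply(ids, function(id) {
    paste(vapply(blocks, function(b) b$rows[[id]], ""), collapse = "")
  }, "")
  labels <- unlist(lapply(seq_along(blocks), function(s) {
    rep(if (s %% 2L == 0L) "TM" else "loop", blocks[[s]]$width)
  }))
  new_msa(ids, unname(rows), col_labels = labels)
}

#' Sum-of-pairs score against a reference alignment
#'
#' The fraction of residue pairs aligned in the reference (over all
#' sequence pairs and reference columns) that are also aligned in the test
#' alignment. Reference columns containing gaps contribute only their
#' residue-residue pairs. Both alignments must contain the same ids with
#' identical degapped residues.
#'
#' @param test,reference `tm_msa` alignments.
#' @return Score in `[0, 1]`; 1 means every reference pair is reproduced.
#' @export
sp_score <- function(test, reference) {
  if (!setequal(test$ids, reference$ids)) {
    stop("test and reference alignments contain different ids")
  }
  for (id in reference$ids) {
    if (!identical(degap(test$rows[[id]]), degap(reference$rows[[id]]))) {
      stop("degapped residues differ for id ", id)
    }
  }
  ids <- reference$ids
  res_index <- function(msa) {
    m <- as.matrix(msa)[ids, , drop = FALSE]
    idx <- matrix(NA_integer_, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) {
      nongap <- m[i, ] != GAP_CHAR
      idx[i, nongap] <- cumsum(nongap)[nongap]
    }
    idx
  }
  it <- res_index(test)
  ir <- res_index(reference)
  lens <- apply(!is.na(ir), 1L, sum)
  num <- 0; denom <- 0
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      # test-side partner map: residue a of seq i -> residue of seq j
      tmap <- rep(NA_integer_, lens[i])
      both_t <- !is.na(it[i, ]) & !is.na(it[j, ])
      tmap[it[i, both_t]] <- it[j, both_t]
      both_r <- !is.na(ir[i, ]) & !is.na(ir[j, ])
      denom <- denom + sum(both_r)
      num <- num + sum(tmap[ir[i, both_r]] == ir[j, both_r], na.rm = TRUE)
    }
  }
  if (denom == 0) stop("reference alignment aligns no residue pairs")
  num / denom
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent symbol (gaps included) provided its
#' frequency strictly exceeds `majority_fraction`; otherwise `X`.
#'
#' @param alignment A `tm_msa`.
#' @param majority_fraction Strict majority threshold (default 0.5).
#' @return Consensus string of length `alignment$width`.
#' @export
consensus_sequence <- function(alignment, majority_fraction = 0.5) {
  m <- as.matrix(alignment)
  n <- nrow(m)
  cols <- apply(m, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    top <- tab[tab == tab[1]]
    # deterministic tie handling: letters before the gap symbol
    sym <- names(top)[order(names(top) == GAP_CHAR, names(top))][1]
    if (tab[1] / n > majority_fraction) sym else "X"
  })
  paste(cols, collapse = "")
}

#' Per-sequence transmembrane report
#'
#' One row per topology segment per sequence: label, 1-based inclusive
#' coordinates, length and the segment's residues, plus the sequence's TM
#' count.
#'
#' @param segmented List of `segmented_seq` objects.
#' @return A data frame (`id`, `tm_count`, `label`, `start`, `end`,
#'   `length`, `seq`).
#' @export
tm_info <- function(segmented) {
  do.call(rbind, lapply(segmented, function(s) {
    a <- s$annotation
    data.frame(id = s$id, tm_count = tm_count(a), label = a$label,
               start = a$start + 1L, end = a$end,
               length = a$end - a$start, seq = s$regions$seq,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.tm_align <- function(x, ...) {
  cat("tm_align result\n")
  cat("  sequences:      ", x$n_sequences, "\n")
  cat("  dominant class: ", x$dominant_count, "TM helices (",
      sum(x$tm_counts == x$dominant_count), "members )\n")
  cat("  alignment:      ", x$alignment$width, "columns\n")
  if (!is.null(x$alignment$col_labels)) {
    cat("  TM columns:     ", sum(x$alignment$col_labels == "TM"), "\n")
  }
  invisible(x)
}

#' @method summary tm_align
#' @export
summary.tm_align <- function(object, ...) {
  print(object)
  cat("  TM counts:       ",
      paste(sprintf("%s:%d", names(object$tm_counts), object$tm_counts),
            collapse = " "), "\n")
  cons <- object$consensus
  if (nchar(cons) > 60L) cons <- paste0(substr(cons, 1, 57), "...")
  cat("  consensus:       ", cons, "\n")
  invisible(object)
}
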