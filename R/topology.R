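# Topology prediction and region partitioning.
#
# Internal coordinates are 0-based half-open throughout; conversion to the
# 1-based inclusive TMHMM dialect happens only in seqio.

new_topology <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  if (any(start >= end)) stop("topology segment with start >= end")
  if (!all(label %in% REGION_LABELS)) stop("invalid topology label")
  df <- data.frame(label = label, start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  # merge adjacent segments sharing a label so annotations are canonical
  if (nrow(df) > 1L) {
    keep <- c(TRUE, df$label[-1] != df$label[-nrow(df)])
    grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
    df <- data.frame(label = df$label[keep],
                     start = as.integer(tapply(df$start, grp, min)),
                     end = as.integer(tapply(df$end, grp, max)),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) > 1L && any(df$start[-1] != df$end[-nrow(df)])) {
    stop("topology segments must tile the sequence contiguously")
  }
  rownames(df) <- NULL
  class(df) <- c("tm_topology", "data.frame")
  df
}

tm_count <- function(annotation) sum(annotation$label == "TMhelix")

#' Topology predictor parameters
#'
#' Parameters of the built-in hydropathy sliding-window transmembrane
#' predictor. `window` is the (odd) averaging window in residues,
#' `threshold` the mean Kyte-Doolittle hydropathy a position must reach to
#' be called membrane-embedded, and `min_helix_len`/`max_helix_len` clamp
#' predicted helices to a biologically plausible length range.
#'
#' @param window Odd positive integer, default 19 (a typical helix span).
#' @param threshold Hydropathy threshold, default 1.6.
#' @param min_helix_len Minimum helix length, default 15.
#' @param max_helix_len Maximum helix length, default 35.
#' @return A list of class `topology_params`.
#' @export
topology_params <- function(window = 19L, threshold = 1.6,
                            min_helix_len = 15L, max_helix_len = 35L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd positive")
  if (min_helix_len > max_helix_len) {
    stop("min_helix_len must be <= max_helix_len")
  }
  structure(list(window = as.integer(window), threshold = threshold,
                 min_helix_len = as.integer(min_helix_len),
                 max_helix_len = as.integer(max_helix_len)),
            class = "topology_params")
}

#' Kyte-Doolittle hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy index in a window centred at each
#' position; at the sequence ends the window is truncated to the available
#' positions.
#'
#' @param residues Residue string (20 amino acids plus X).
#' @param window Odd window size.
#' @return Numeric vector, one score per residue.
#' @examples
#' hydropathy_profile("AIR", window = 1)
#' @export
hydropathy_profile <- function(residues, window = 19L) {
  if (!nzchar(residues)) stop("empty sequence")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd positive")
  v <- KD_INDEX[strsplit(toupper(residues), "")[[1]]]
  if (anyNA(v)) stop("invalid residue in sequence")
  n <- length(v)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  unname((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# Split an above-threshold run at its lowest-profile interior position
# (ties -> leftmost), recursively, whenever it is longer than the largest
# core a single helix can produce. Window averaging erodes each end of a
# true helix's run by up to (window-1)/2 positions, so a single helix of
# length <= max_len yields a run core of at most max_len - (window-1)/2;
# anything longer must span more than one helix. start/end are 0-based
# half-open.
split_run <- function(start, end, profile, raw, min_len, max_len, half_win) {
  max_core <- max(max_len - half_win, min_len)
  min_core <- max(min_len - half_win, 1L)
  len <- end - start
  if (len <= max_core) return(list(c(start, end)))
  if (start + min_core > end - min_core) {
    # too long to keep, too short to split: keep the best-scoring
    # max_core window (ties -> leftmost)
    s_cand <- start:(end - max_core)
    cs <- c(0, cumsum(profile))
    sums <- cs[s_cand + max_core + 1L] - cs[s_cand + 1L]
    s <- s_cand[which.max(sums)]
    return(list(c(s, s + max_core)))
  }
  # cut at the least hydrophobic *raw* position (the buried loop residue);
  # the smoothed profile locates the run, the raw index pins the loop. The
  # cut position itself reverts to loop, so the two parts never abut
  # (adjacent helices are not representable in a topology annotation).
  cand <- (start + min_core):(end - min_core)
  cut <- cand[which.min(raw[cand + 1L])]
  c(split_run(start, cut, profile, raw, min_len, max_len, half_win),
    split_run(cut + 1L, end, profile, raw, min_len, max_len, half_win))
}

#' Predict transmembrane topology from hydropathy
#'
#' A functional substitute for an external HMM-based predictor: maximal
#' runs of positions whose windowed Kyte-Doolittle hydropathy reaches
#' `threshold` become transmembrane helices. Runs longer than
#' `max_helix_len` are split recursively at their lowest-scoring interior
#' position; runs shorter than `min_helix_len` are extended one flank
#' position at a time (higher-profile side first, ties to the left) until
#' they reach `min_helix_len`, or dropped if there is no room. Remaining
#' stretches are labelled as loops, alternating `outside`/`inside` with the
#' N-terminal stretch labelled `outside` (hydropathy alone cannot orient
#' the protein; the alignment treats the two loop classes symmetrically).
#'
#' @param record A one-row record data frame (or list with `id` and
#'   `residues`).
#' @param params A [topology_params()] object.
#' @return A topology annotation: data frame with columns `label`, `start`,
#'   `end` (0-based half-open) tiling the sequence.
#' @export
predict_topology <- function(record, params = topology_params()) {
  res <- record$residues
  n <- nchar(res)
  prof <- hydropathy_profile(res, params$window)
  above <- prof >= params$threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])
  half_win <- (params$window - 1L) %/% 2L
  raw <- unname(KD_INDEX[strsplit(toupper(res), "")[[1]]])
  tm <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    tm <- c(tm, split_run(starts[i], ends[i], prof, raw,
                          params$min_helix_len, params$max_helix_len,
                          half_win))
  }
  # Boundary refinement: the windowed profile locates helix cores but
  # erodes their edges by up to half a window and can also bleed into the
  # flanking loops. Each core edge is therefore trimmed back over residues
  # whose raw hydropathy falls below the threshold, then extended over
  # contiguous residues whose raw hydropathy clears it (clamped to
  # max_helix_len and to a >= 1-residue loop between helices); cores still
  # shorter than min_helix_len are padded one flank position at a time,
  # higher-profile side first.
  out <- list()
  for (i in seq_along(tm)) {
    s <- tm[[i]][1]; e <- tm[[i]][2]
    lo <- if (length(out)) out[[length(out)]][2] + 1L else 0L
    hi <- if (i < length(tm)) tm[[i + 1L]][1] - 1L else n
    while (e - s > params$min_helix_len &&
           raw[s + 1L] < params$threshold) s <- s + 1L  # raw is 1-based
    while (e - s > params$min_helix_len &&
           raw[e] < params$threshold) e <- e - 1L
    while (e - s < params$max_helix_len && s > lo &&
           raw[s] >= params$threshold) s <- s - 1L
    while (e - s < params$max_helix_len && e < hi &&
           raw[e + 1L] >= params$threshold) e <- e + 1L
    while (e - s < params$min_helix_len && (s > lo || e < hi)) {
      left_ok <- s > lo
      right_ok <- e < hi
      take_left <- left_ok &&
        (!right_ok || prof[s] >= prof[e + 1L])  # prof is 1-based
      if (take_left) s <- s - 1L else e <- e + 1L
    }
    if (e - s >= params$min_helix_len) out <- c(out, list(c(s, e)))
  }
  # assemble segments: loops alternate outside/inside, starting outside
  label <- character(0); start <- integer(0); end <- integer(0)
  pos <- 0L; loop_idx <- 0L
  loop_label <- function(k) if (k %% 2L == 0L) "outside" else "inside"
  for (seg in out) {
    if (seg[1] > pos) {
      label <- c(label, loop_label(loop_idx))
      start <- c(start, pos); end <- c(end, seg[1])
    }
    loop_idx <- loop_idx + 1L
    label <- c(label, "TMhelix")
    start <- c(start, seg[1]); end <- c(end, seg[2])
    pos <- seg[2]
  }
  if (pos < n || length(label) == 0L) {
    label <- c(label, loop_label(loop_idx))
    start <- c(start, pos); end <- c(end, n)
  }
  new_topology(label, start, end)
}

#' Partition a sequence into its topology regions
#'
#' @param record A one-row record data frame (or list with `id`, `residues`).
#' @param annotation A topology annotation covering exactly the sequence.
#' @return A list of class `segmented_seq` with fields `id`, `residues`,
#'   `annotation` and `regions` (data frame of `label`, `seq`).
#' @export
segment_sequence <- function(record, annotation) {
  res <- record$residues
  if (annotation$end[nrow(annotation)] != nchar(res) ||
      annotation$start[1] != 0L) {
    stop("annotation does not cover sequence ", record$id,
         " (length ", nchar(res), ")")
  }
  segs <- substring(res, annotation$start + 1L, annotation$end)
  stopifnot(identical(paste(segs, collapse = ""), res))
  structure(list(id = record$id, residues = res, annotation = annotation,
                 regions = data.frame(label = annotation$label, seq = segs,
                                      stringsAsFactors = FALSE)),
            class = "segmented_seq")
}

#' Group sequences by transmembrane count
#'
#' Sequences are grouped by the number of predicted (or imported) TM
#' helices; the dominant class — the largest group, ties broken towards the
#' larger TM count — seeds the alignment.
#'
#' @param segmented List of `segmented_seq` objects.
#' @return List with `groups` (named list, TM count -> integer indices into
#'   `segmented`) and `dominant_count`.
#' @export
classify_by_tm_count <- function(segmented) {
  if (length(segmented) == 0L) stop("no sequences to classify")
  counts <- vapply(segmented, function(s) tm_count(s$annotation), 0L)
  groups <- split(seq_along(segmented), counts)
  sizes <- lengths(groups)
  keys <- as.integer(names(groups))
  best <- which(sizes == max(sizes))
  dominant <- max(keys[best])
  list(groups = groups, dominant_count = dominant)
}

# region slot strings for a member of the dominant class with K helices:
# 2K+1 slots (loop0, TM1, loop1, ..., TMK, loopK); loops between helices may
# be empty when a sequence begins/ends with a helix or two helices abut
region_slots <- function(seg, k) {
  ann <- seg$annotation
  if (tm_count(ann) != k) stop("sequence ", seg$id, " does not have ", k,
                               " TM helices")
  slots <- character(2L * k + 1L)
  tm_i <- 0L
  for (j in seq_len(nrow(ann))) {
    piece <- substring(seg$residues, ann$start[j] + 1L, ann$end[j])
    if (ann$label[j] == "TMhelix") {
      tm_i <- tm_i + 1L
      slots[2L * tm_i] <- piece
    } else {
      slot <- 2L * tm_i + 1L
      slots[slot] <- paste0(slots[slot], piece)
    }
  }
  slots
}
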