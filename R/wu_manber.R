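# Wu-Manber multi-pattern exact matching: SHIFT/HASH/PREFIX tables built in
# a preprocessing pass, then a block-wise scan of the text. Blocks address
# the tables by their literal string (dictionary contract), which preserves
# the algorithm's shift values, candidate filtering and prefix verification
# while making hash collisions moot.

#' Build Wu-Manber tables for a pattern set
#'
#' The match window `m` is the length of the shortest pattern (among
#' patterns at least `S` long). For every block of `S` characters occurring
#' in the first `m` characters of a pattern, `SHIFT[block]` is
#' `m - 1 - (rightmost 0-based end position of the block)`; blocks ending at
#' position `m - 1` get shift 0 and a HASH entry listing the candidate
#' patterns, whose first `S` characters are kept in the PREFIX table for
#' quick filtering. Blocks absent from every pattern shift the window by
#' `m - S`. Patterns shorter than `S` are diverted to a naive-scan fallback
#' set.
#'
#' @param patterns Non-empty character vector of non-empty patterns.
#' @param S Block size, 2 or 3.
#' @return A list of class `wm_tables`.
#' @export
wm_build_tables <- function(patterns, S = 2L) {
  if (length(patterns) == 0L) stop("empty pattern list")
  if (any(!nzchar(patterns))) stop("empty string pattern")
  if (!S %in% c(2L, 3L)) stop("block size S must be 2 or 3")
  lens <- nchar(patterns)
  tabled <- which(lens >= S)
  fallback <- which(lens < S)
  tables <- list(patterns = patterns, S = as.integer(S),
                 fallback = fallback, m = NA_integer_,
                 shift = NULL, hash = NULL, prefix = NULL,
                 default_shift = NA_integer_)
  if (length(tabled) > 0L) {
    m <- min(lens[tabled])
    shift <- new.env(parent = emptyenv())
    hash <- new.env(parent = emptyenv())
    for (pi in tabled) {
      p <- substr(patterns[pi], 1L, m)
      for (end in S:m) {                       # 1-based end of the block
        block <- substr(p, end - S + 1L, end)
        s_val <- m - end                       # = m - 1 - (0-based end)
        old <- shift[[block]]
        if (is.null(old) || s_val < old) shift[[block]] <- s_val
        if (s_val == 0L) {
          hash[[block]] <- unique(c(hash[[block]], pi))
        }
      }
    }
    tables$m <- as.integer(m)
    tables$shift <- shift
    tables$hash <- hash
    tables$prefix <- substr(patterns, 1L, S)
    tables$default_shift <- as.integer(m - S)
  }
  class(tables) <- "wm_tables"
  tables
}

# naive fallback for patterns shorter than the block size
naive_scan_one <- function(pattern, text) {
  lp <- nchar(pattern); lt <- nchar(text)
  if (lp > lt) return(integer(0))
  starts <- seq_len(lt - lp + 1L)
  starts[substring(text, starts, starts + lp - 1L) == pattern] - 1L
}

#' Scan a text with Wu-Manber tables
#'
#' Slides a match window of width `m` over the text; the last `S`
#' characters of the window are looked up in the SHIFT table, and only when
#' the shift is zero are the HASH candidates checked (prefix first, then
#' the full pattern). Patterns in the naive fallback set are scanned
#' directly and merged in.
#'
#' @param tables A `wm_tables` object.
#' @param text Text string.
#' @return Data frame of hits with columns `pattern` (index into the
#'   pattern set) and `pos` (0-based start), sorted by `(pos, pattern)`.
#' @export
wm_scan <- function(tables, text) {
  hits_p <- integer(0); hits_x <- integer(0)
  lt <- nchar(text)
  if (!is.na(tables$m) && lt >= tables$m) {
    m <- tables$m; S <- tables$S
    pats <- tables$patterns; plens <- nchar(pats)
    i <- m                                    # 1-based window end
    while (i <= lt) {
      block <- substr(text, i - S + 1L, i)
      sh <- tables$shift[[block]]
      if (is.null(sh)) sh <- tables$default_shift
      if (sh > 0L) {
        i <- i + sh
        next
      }
      cand <- tables$hash[[block]]
      start <- i - m + 1L
      for (pi in cand) {
        if (substr(text, start, start + S - 1L) != tables$prefix[pi]) next
        if (start + plens[pi] - 1L <= lt &&
            substr(text, start, start + plens[pi] - 1L) == pats[pi]) {
          hits_p <- c(hits_p, pi)
          hits_x <- c(hits_x, start - 1L)
        }
      }
      i <- i + 1L
    }
  }
  for (pi in tables$fallback) {
    pos <- naive_scan_one(tables$patterns[pi], text)
    hits_p <- c(hits_p, rep(pi, length(pos)))
    hits_x <- c(hits_x, pos)
  }
  ord <- order(hits_x, hits_p)
  data.frame(pattern = hits_p[ord], pos = hits_x[ord])
}

#' Anchor region strings inside their source sequence
#'
#' Given the ordered region substrings of a sequence, finds (via Wu-Manber
#' matching) the start of each region such that the chosen occurrences form
#' the maximal consistent chain: strictly increasing, contiguous
#' (`start[i+1] = start[i] + nchar(region[i])`) and covering the whole
#' sequence. When a region occurs several times, the leftmost occurrence
#' consistent with the chain is used. Zero-length regions are legal and
#' anchored at the current offset.
#'
#' @param region_strings Ordered character vector of region substrings.
#' @param full_sequence The sequence they were sliced from.
#' @return Integer vector of 0-based start positions, one per region.
#' @export
locate_anchors <- function(region_strings, full_sequence) {
  nonempty <- which(nzchar(region_strings))
  occ <- vector("list", length(region_strings))
  if (length(nonempty) > 0L) {
    tabs <- wm_build_tables(region_strings[nonempty], S = 2L)
    hits <- wm_scan(tabs, full_sequence)
    for (k in seq_along(nonempty)) {
      occ[[nonempty[k]]] <- hits$pos[hits$pattern == k]
    }
  }
  starts <- integer(length(region_strings))
  pos <- 0L
  for (r in seq_along(region_strings)) {
    len <- nchar(region_strings[r])
    if (len > 0L && !(pos %in% occ[[r]])) {
      stop("no consistent anchor chain: region ", r,
           " not found at offset ", pos)
    }
    starts[r] <- pos
    pos <- pos + len
  }
  if (pos != nchar(full_sequence)) {
    stop("no consistent anchor chain: regions do not tile the sequence")
  }
  starts
}
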