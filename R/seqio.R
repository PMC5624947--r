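#' Read protein sequences from a FASTA file
#'
#' Reads unaligned protein sequences. Residues are uppercased, a terminal
#' `'*'` stop symbol is stripped, and every residue must be one of the 20
#' standard amino acids or `X`. Record ids must be unique.
#'
#' @param file Path to a FASTA file. Ignored when `text` is given.
#' @param text Optional character scalar holding FASTA text directly.
#' @return A data frame with columns `id`, `desc` and `residues`, one row
#'   per record, in file order.
#' @examples
#' recs <- read_fasta(text = ">s1 first\nACDE\n>s2\nMKLV\n")
#' recs$residues
#' @export
read_fasta <- function(file = NULL, text = NULL) {
  set <- read_fasta_raw(file, text)
  ids <- vapply(names(set), function(h) strsplit(h, "[ \t]+")[[1]][1], "")
  desc <- vapply(names(set), function(h) {
    h2 <- sub("^[^ \t]+[ \t]*", "", h)
    if (is.na(h2)) "" else h2
  }, "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < 1L) stop("empty sequence for id ", ids[i])
    validate_residues(seqs[i], ids[i])
  }
  data.frame(id = unname(ids), desc = unname(desc),
             residues = unname(seqs), stringsAsFactors = FALSE)
}

# FASTA mechanics via Biostrings; BStringSet so gapped input is representable
read_fasta_raw <- function(file, text) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  if (is.null(file)) stop("either 'file' or 'text' must be given")
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0L) stop("no sequences in input")
  set
}

validate_residues <- function(s, id) {
  ok <- strsplit(s, "")[[1]] %in% TM_ALPHABET
  if (!all(ok)) {
    stop("invalid residue '", substr(s, which(!ok)[1], which(!ok)[1]),
         "' at position ", which(!ok)[1], " in sequence ", id)
  }
  invisible(TRUE)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but rows may contain gap characters; `'.'` gaps are
#' normalised to `'-'`. Returns a [tm_msa] alignment object.
#'
#' @inheritParams read_fasta
#' @return A `tm_msa` alignment.
#' @export
read_alignment <- function(file = NULL, text = NULL) {
  set <- read_fasta_raw(file, text)
  ids <- vapply(names(set), function(h) strsplit(h, "[ \t]+")[[1]][1], "")
  rows <- gsub(".", "-", toupper(as.character(set)), fixed = TRUE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  for (i in seq_along(rows)) {
    validate_residues(gsub("-", "", rows[i], fixed = TRUE), ids[i])
  }
  new_msa(unname(ids), unname(rows))
}

#' Write sequences or an alignment to FASTA
#'
#' @param x A record data frame (as returned by [read_fasta()]), a `tm_msa`
#'   alignment, or a named character vector of sequences.
#' @param file Output path; when `NULL` the FASTA text is returned invisibly
#'   as a character scalar instead of being written.
#' @param line_width Residues per line (default 60).
#' @return Invisibly, the FASTA text.
#' @export
write_fasta <- function(x, file = NULL, line_width = 60L) {
  if (line_width < 1L) stop("line_width must be >= 1")
  if (inherits(x, "tm_msa")) {
    ids <- x$ids; seqs <- unname(x$rows); desc <- rep("", length(ids))
  } else if (is.data.frame(x)) {
    ids <- x$id; seqs <- x$residues; desc <- x$desc %||% rep("", nrow(x))
  } else if (is.character(x) && !is.null(names(x))) {
    ids <- names(x); seqs <- unname(x); desc <- rep("", length(x))
  } else {
    stop("unsupported input to write_fasta")
  }
  if (length(ids) == 0L) stop("nothing to write")
  out <- character(0)
  for (i in seq_along(ids)) {
    hdr <- if (nzchar(desc[i])) paste(ids[i], desc[i]) else ids[i]
    body <- substring(seqs[i],
                      seq(1L, max(nchar(seqs[i]), 1L), by = line_width),
                      pmin(seq(1L, max(nchar(seqs[i]), 1L), by = line_width) +
                             line_width - 1L, nchar(seqs[i])))
    out <- c(out, paste0(">", hdr), body)
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) cat(txt, file = file)
  invisible(txt)
}

#' Read TMHMM-style topology annotations
#'
#' Parses the TMHMM long-format dialect: one line per segment,
#' `"<id> TMHMM2.0 <label> <start> <end>"` with labels `inside`, `TMhelix`
#' or `outside` and 1-based inclusive coordinates. Lines starting with `#`
#' are ignored. Per sequence, segments must start at 1 and tile the sequence
#' contiguously. Coordinates are converted to the package's internal 0-based
#' half-open convention here and only here.
#'
#' @inheritParams read_fasta
#' @return A named list of topology annotations (one per id), each a data
#'   frame with columns `label`, `start`, `end` (0-based half-open).
#' @export
read_tm_annotations <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) != 5L) stop("malformed annotation line: ", ln)
    id <- f[1]; label <- f[3]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (!(label %in% REGION_LABELS)) {
      stop("unknown topology label '", label, "' for ", id)
    }
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      stop("bad coordinates in annotation line: ", ln)
    }
    out[[id]] <- rbind(out[[id]],
                       data.frame(label = label, start = start - 1L,
                                  end = end, stringsAsFactors = FALSE))
  }
  lapply(out, function(df) {
    df <- df[order(df$start), , drop = FALSE]
    if (df$start[1] != 0L) stop("annotation must start at position 1")
    if (nrow(df) > 1L) {
      gaps <- df$start[-1] != df$end[-nrow(df)]
      if (any(gaps)) {
        stop("annotation coverage gap/overlap at position ",
             df$end[which(gaps)[1]] + 1L)
      }
    }
    new_topology(df$label, df$start, df$end)
  })
}

#' Write topology annotations in the TMHMM long-format dialect
#'
#' @param annotations Named list of topology annotations (0-based half-open,
#'   as produced by [predict_topology()] or [read_tm_annotations()]).
#' @param file Output path; `NULL` returns the text invisibly.
#' @return Invisibly, the annotation text.
#' @export
write_tm_annotations <- function(annotations, file = NULL) {
  lines <- character(0)
  for (id in names(annotations)) {
    a <- annotations[[id]]
    lines <- c(lines, sprintf("%s\tTMHMM2.0\t%s\t%d\t%d",
                              id, a$label, a$start + 1L, a$end))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) cat(txt, file = file)
  invisible(txt)
}

# alignment container ----------------------------------------------------

#' Construct an alignment object
#'
#' A `tm_msa` is an ordered set of equal-width gapped rows with provenance
#' to the input records, plus an optional per-column region label
#' (`"TM"`, `"loop"` or `"mixed"`).
#'
#' @param ids Character vector of record ids (unique).
#' @param rows Character vector of gapped strings, same length as `ids`.
#' @param col_labels Optional character vector, one label per column.
#' @return An object of class `tm_msa`.
#' @export
new_msa <- function(ids, rows, col_labels = NULL) {
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids))
  w <- unique(nchar(rows))
  if (length(rows) == 0L) stop("alignment must have at least one row")
  if (length(w) != 1L) stop("alignment rows differ in width")
  if (!is.null(col_labels) && length(col_labels) != w) {
    stop("col_labels length must equal alignment width")
  }
  structure(list(ids = ids, rows = stats::setNames(rows, ids),
                 width = w, col_labels = col_labels),
            class = "tm_msa")
}

#' @export
print.tm_msa <- function(x, ...) {
  cat("Multiple sequence alignment:", length(x$ids), "rows x",
      x$width, "columns\n")
  show <- head(x$ids, 6L)
  for (id in show) {
    row <- x$rows[[id]]
    if (nchar(row) > 60L) row <- paste0(substr(row, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", id, row))
  }
  if (length(x$ids) > 6L) cat("  ...", length(x$ids) - 6L, "more rows\n")
  invisible(x)
}

#' Remove gaps from a row or sequence
#' @param s Character vector of (possibly gapped) strings.
#' @return The strings with all `'-'` removed.
#' @export
degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' @method as.matrix tm_msa
#' @export
as.matrix.tm_msa <- function(x, ...) {
  if (x$width == 0L) {
    return(matrix(character(0), nrow = length(x$ids), ncol = 0L,
                  dimnames = list(x$ids, NULL)))
  }
  m <- do.call(rbind, strsplit(unname(x$rows), ""))
  rownames(m) <- x$ids
  m
}

# Round-trip invariant: degapping each row reproduces the input residues.
# Called after every pipeline stage that returns an alignment.
assert_roundtrip <- function(msa, records) {
  res <- stats::setNames(records$residues, records$id)
  for (id in msa$ids) {
    if (!identical(degap(msa$rows[[id]]), unname(res[[id]]))) {
      stop("round-trip invariant violated for sequence ", id)
    }
  }
  invisible(TRUE)
}

# drop columns that are gaps in every row (finished alignments only)
strip_allgap_columns <- function(msa) {
  m <- as.matrix(msa)
  keep <- colSums(m != GAP_CHAR) > 0L
  if (all(keep)) return(msa)
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  new_msa(msa$ids, unname(rows),
          col_labels = if (!is.null(msa$col_labels)) msa$col_labels[keep])
}
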