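# Substitution matrices and the affine gap model.

MATRIX_FILES <- c(PHAT = "PHAT_synthetic.mat",
                  BLOSUM62 = "BLOSUM62.mat",
                  GONNET250 = "GONNET250.mat")

#' Read a substitution matrix file
#'
#' Format: `#` comment lines, then one line with the residue alphabet
#' (space-separated letters), then one line per residue giving its full row
#' of integer scores (optionally prefixed with the residue letter).
#'
#' @param file Path to a matrix file.
#' @param name Name to attach to the matrix.
#' @return A symmetric integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(file, name = basename(file)) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  alpha <- strsplit(lines[1], "[ \t]+")[[1]]
  n <- length(alpha)
  if (length(lines) != n + 1L) stop("matrix file must have ", n, " score rows")
  m <- matrix(0L, n, n, dimnames = list(alpha, alpha))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "[ \t]+")[[1]]
    if (length(f) == n + 1L) f <- f[-1]          # leading row letter
    if (length(f) != n) stop("row ", i, " has wrong number of entries")
    m[i, ] <- as.integer(f)
  }
  if (!isSymmetric(unname(m))) stop("substitution matrix is not symmetric")
  attr(m, "name") <- name
  m
}

#' Load a packaged substitution matrix
#'
#' Three matrices are provided: `BLOSUM62` (standard half-bit table),
#' `GONNET250` (the Gonnet et al. 1992 PAM250-equivalent table, entries
#' scaled by 10 and rounded to integers so dynamic programming stays
#' integer-exact) and `PHAT` for transmembrane blocks. The packaged PHAT
#' selection resolves to a synthetic BLOSUM62-derived transmembrane-adapted
#' table (see `inst/extdata/PHAT_synthetic.mat` for its construction), not
#' the published PHAT(75/73) matrix; users holding the published table can
#' load it with [read_score_matrix()] and pass it anywhere a matrix name is
#' accepted. `X` scores 0 against everything.
#'
#' @param name One of `"PHAT"`, `"BLOSUM62"`, `"GONNET250"`
#'   (case-insensitive), or an already-loaded matrix (returned unchanged).
#' @return A symmetric integer matrix over the 20 amino acids plus X.
#' @examples
#' m <- load_matrix("BLOSUM62")
#' m["A", "A"]
#' @export
load_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  key <- toupper(name)
  if (!key %in% names(MATRIX_FILES)) {
    stop("unknown substitution matrix '", name, "'; valid names: ",
         paste(names(MATRIX_FILES), collapse = ", "))
  }
  file <- system.file("extdata", MATRIX_FILES[[key]], package = "tmaligner",
                      mustWork = TRUE)
  m <- read_score_matrix(file, name = key)
  if (!identical(sort(rownames(m)), sort(TM_ALPHABET))) {
    stop("packaged matrix has unexpected alphabet")
  }
  m[TM_ALPHABET, TM_ALPHABET]
}

#' Affine gap model
#'
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`: the opening
#' penalty is charged once per gap, the extension penalty once per
#' additional column. Defaults follow the method's stated defaults
#' (open 8, extend 1).
#'
#' @param gap_open Non-negative opening penalty (default 8).
#' @param gap_extend Non-negative extension penalty (default 1).
#' @return A list of class `gap_model`.
#' @export
gap_model <- function(gap_open = 8, gap_extend = 1) {
  if (gap_extend < 0 || gap_open < gap_extend) {
    stop("need gap_open >= gap_extend >= 0")
  }
  structure(list(gap_open = gap_open, gap_extend = gap_extend),
            class = "gap_model")
}

#' Cost of a gap of given length
#'
#' @param model A [gap_model()].
#' @param length Gap length (>= 1).
#' @return The (positive) penalty `gap_open + (length - 1) * gap_extend`.
#' @examples
#' gap_cost(gap_model(), 1)  # 8
#' gap_cost(gap_model(), 3)  # 10
#' @export
gap_cost <- function(model, length) {
  if (any(length < 1L)) stop("gap length must be >= 1")
  model$gap_open + (length - 1L) * model$gap_extend
}
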