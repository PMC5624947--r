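# Seeded simulator for families of alpha-helical transmembrane proteins
# with recorded true topology and true alignment. Substitutions act
# everywhere; insertions/deletions are confined to loops, so transmembrane
# columns of the true alignment are indel-free — the property the aligner
# exploits ("helices are never disrupted").

# helix residues: apolar bilayer-core pool, weighted towards I/L/V/F as in
# real TM helices (mean Kyte-Doolittle hydropathy ~ +3.6)
HELIX_POOL <- c(I = 0.25, L = 0.25, V = 0.20, F = 0.15, M = 0.075, A = 0.075)

# loop residues: full-alphabet pool biased towards the small/polar residues
# that dominate real loops (G/S/T/A/P enriched, charged present; mean
# Kyte-Doolittle hydropathy ~ -1.5, typical of soluble segments)
LOOP_POOL <- c(G = 0.14, S = 0.14, T = 0.12, A = 0.10, P = 0.08, N = 0.06,
               D = 0.06, E = 0.06, K = 0.06, Q = 0.05, R = 0.04, H = 0.03,
               Y = 0.03, W = 0.02, L = 0.01)

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

draw_pool <- function(n, pool) {
  if (n == 0L) return(character(0))
  sample(names(pool), n, replace = TRUE, prob = pool)
}

# replace with a *different* residue from the pool, weights renormalised
substitute_residues <- function(chars, rate, pool) {
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    p <- pool[names(pool) != chars[i]]
    chars[i] <- sample(names(p), 1L, prob = p)
  }
  chars
}

#' Simulate a transmembrane protein family with known truth
#'
#' Draws a common ancestor with `n_helices` hydrophobic helices separated
#' by polar loops, then derives `n_sequences` descendants by i.i.d.
#' substitutions (helix substitutions stay within the hydrophobic pool, so
#' helices remain hydrophobic) and loop-confined insertions/deletions with
#' geometrically distributed lengths (mean 3). The true alignment is
#' constructed from the edit history and the true topology is recorded per
#' descendant. The same seed always reproduces the same family.
#'
#' @param n_sequences Number of descendants (default 8).
#' @param n_helices Number of TM helices K (default 7; 0 gives a soluble,
#'   all-loop family).
#' @param helix_len_range Helix length range, default `c(18, 25)`.
#' @param loop_len_range Loop length range, default `c(5, 40)`.
#' @param substitution_rate Per-site substitution probability (default 0.3,
#'   which yields roughly 50% mean pairwise identity between descendants).
#' @param loop_indel_rate Per-loop probability of one insertion or deletion
#'   event per descendant (default 0.3).
#' @param seed Integer seed for the family's private RNG stream.
#' @return A list of class `sim_family`: `records` (data frame as from
#'   [read_fasta()]), `true_topology` (named list of annotations),
#'   `true_alignment` (`tm_msa`), and `params`.
#' @export
simulate_family <- function(n_sequences = 8L, n_helices = 7L,
                            helix_len_range = c(18L, 25L),
                            loop_len_range = c(5L, 40L),
                            substitution_rate = 0.3,
                            loop_indel_rate = 0.3, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      loop_indel_rate < 0 || loop_indel_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  if (n_sequences < 1L || n_helices < 0L) stop("invalid family size")
  with_local_seed(seed, {
    k <- n_helices
    n_pieces <- 2L * k + 1L
    is_helix <- seq_len(n_pieces) %% 2L == 0L
    piece_len <- integer(n_pieces)
    piece_len[is_helix] <- sample(helix_len_range[1]:helix_len_range[2],
                                  k, replace = TRUE)
    piece_len[!is_helix] <- sample(loop_len_range[1]:loop_len_range[2],
                                   k + 1L, replace = TRUE)
    ancestor <- lapply(seq_len(n_pieces), function(p) {
      draw_pool(piece_len[p], if (is_helix[p]) HELIX_POOL else LOOP_POOL)
    })

    ids <- sprintf("seq%d", seq_len(n_sequences))
    # per member and piece: residue chars, kept-mask, insertion offset/string
    members <- lapply(seq_len(n_sequences), function(m) {
      lapply(seq_len(n_pieces), function(p) {
        pool <- if (is_helix[p]) HELIX_POOL else LOOP_POOL
        chars <- substitute_residues(ancestor[[p]], substitution_rate, pool)
        kept <- rep(TRUE, length(chars))
        ins_at <- NA_integer_; ins_str <- ""
        if (!is_helix[p] && length(chars) > 0L &&
            runif(1) < loop_indel_rate) {
          len <- 1L + rgeom(1L, 1 / 3)        # mean 3
          if (runif(1) < 0.5) {               # deletion
            start <- sample.int(length(chars), 1L)
            kept[start:min(length(chars), start + len - 1L)] <- FALSE
          } else {                            # insertion
            ins_at <- sample.int(length(chars) + 1L, 1L) - 1L  # offset 0..L
            ins_str <- paste(draw_pool(len, LOOP_POOL), collapse = "")
          }
        }
        list(chars = chars, kept = kept, ins_at = ins_at, ins_str = ins_str)
      })
    })

    # build the true alignment piece by piece
    piece_aln <- lapply(seq_len(n_pieces), function(p) {
      lp <- piece_len[p]
      rows <- rep("", n_sequences)
      for (off in 0:lp) {
        # insertion blocks after ancestor position `off`, in member order
        for (m in seq_len(n_sequences)) {
          pc <- members[[m]][[p]]
          if (!is.na(pc$ins_at) && pc$ins_at == off) {
            w <- nchar(pc$ins_str)
            blk <- rep(strrep(GAP_CHAR, w), n_sequences)
            blk[m] <- pc$ins_str
            rows <- paste0(rows, blk)
          }
        }
        if (off < lp) {
          j <- off + 1L
          col <- vapply(members, function(mm) {
            pc <- mm[[p]]
            if (pc$kept[j]) pc$chars[j] else GAP_CHAR
          }, "")
          rows <- paste0(rows, col)
        }
      }
      rows
    })
    true_rows <- do.call(paste0, piece_aln)
    true_alignment <- new_msa(ids, true_rows)

    residues <- degap(true_rows)
    records <- data.frame(id = ids, desc = "", residues = residues,
                          stringsAsFactors = FALSE)

    true_topology <- lapply(seq_len(n_sequences), function(m) {
      lens <- vapply(seq_len(n_pieces), function(p) {
        pc <- members[[m]][[p]]
        sum(pc$kept) + nchar(pc$ins_str)
      }, 0L)
      label <- ifelse(is_helix, "TMhelix",
                      ifelse(seq_len(n_pieces) %% 4L == 1L,
                             "outside", "inside"))
      keep <- lens > 0L
      ends <- cumsum(lens)[keep]
      starts <- c(0L, cumsum(lens))[c(keep, FALSE)]
      new_topology(label[keep], starts, ends)
    })
    names(true_topology) <- ids

    structure(list(records = records, true_topology = true_topology,
                   true_alignment = true_alignment,
                   params = list(n_sequences = n_sequences,
                                 n_helices = n_helices,
                                 helix_len_range = helix_len_range,
                                 loop_len_range = loop_len_range,
                                 substitution_rate = substitution_rate,
                                 loop_indel_rate = loop_indel_rate,
                                 seed = seed)),
              class = "sim_family")
  })
}

#' Mean pairwise percent identity of a simulated family
#'
#' Computed on the recorded true alignment: for each sequence pair, matches
#' divided by aligned residue-residue columns, averaged over pairs.
#'
#' @param family A `sim_family`.
#' @return Mean pairwise identity in percent.
#' @export
measure_identity <- function(family) {
  m <- as.matrix(family$true_alignment)
  n <- nrow(m)
  if (n < 2L) stop("identity needs at least 2 family members")
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- m[i, ] != GAP_CHAR & m[j, ] != GAP_CHAR
      vals <- c(vals, 100 * sum(m[i, both] == m[j, both]) / sum(both))
    }
  }
  mean(vals)
}
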