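# Karlin-Altschul constants for gapped BLOSUM62 (gap open 11, extend 1),
# used to rescale raw scores to bit scores.
KA_LAMBDA <- 0.267
KA_K <- 0.041

encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, AA_ALPHABET)
  if (anyNA(codes)) {
    stop("sequence contains characters outside the amino-acid alphabet: ",
         paste(unique(chars[is.na(codes)]), collapse = ""))
  }
  codes - 1L
}

#' Exact local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (a gap of length g costs
#' `gap_open + g * gap_extend`; the defaults are BLAST's protein
#' defaults, BLOSUM62 with open 11 / extend 1).  Used in place of a
#' heuristic search for the all-vs-all comparison of SRCR-like domain
#' instances: it is deterministic and has the same score semantics.
#' The raw score is rescaled to a bit score with the gapped
#' Karlin-Altschul constants, and the fraction of positive-scoring
#' aligned residue pairs (gap columns excluded, the "percent positives"
#' convention) is reported for the homology criterion.
#'
#' @param seq1,seq2 amino-acid strings (`X` allowed; it scores 0
#'   against everything).
#' @param matrix substitution matrix (default [blosum62_matrix()]).
#' @param gap_open,gap_extend affine gap parameters.
#' @return An `alignment_result`: list with `score`, `bit_score`,
#'   `positives_fraction`, `n_aligned` (residue-residue columns),
#'   `aligned1`, `aligned2` (gapped strings; empty when the best local
#'   score is 0).
#' @export
#' @examples
#' local_align("ACDE", "ACDE")$score  # 24
local_align <- function(seq1, seq2, matrix = blosum62_matrix(),
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("empty sequence")
  a <- encode_seq(seq1); b <- encode_seq(seq2)
  res <- sw_align_cpp(a, b, matrix, gap_open, gap_extend)
  build_alignment_result(res, seq1, seq2, matrix)
}

build_alignment_result <- function(res, seq1, seq2, matrix) {
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(seq2, "")[[1]]
  ap <- res$a_pos; bp <- res$b_pos
  al1 <- ifelse(ap == 0L, "-", c1[pmax(ap, 1L)])
  al2 <- ifelse(bp == 0L, "-", c2[pmax(bp, 1L)])
  resres <- ap != 0L & bp != 0L
  n_aligned <- sum(resres)
  positives <- 0L
  if (n_aligned > 0) {
    sc <- matrix[cbind(toupper(al1[resres]), toupper(al2[resres]))]
    positives <- sum(sc > 0)
  }
  structure(list(
    score = res$score,
    bit_score = (KA_LAMBDA * res$score - log(KA_K)) / log(2),
    positives_fraction = if (n_aligned > 0) positives / n_aligned else 0,
    n_aligned = n_aligned,
    aligned1 = paste(al1, collapse = ""),
    aligned2 = paste(al2, collapse = "")), class = "alignment_result")
}

#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch with the same affine-gap model as [local_align()],
#' terminal gaps penalised.  Used by the centre-star progressive
#' multiple aligner.
#'
#' @inheritParams local_align
#' @return List with `score`, `aligned1`, `aligned2`.
#' @export
global_align <- function(seq1, seq2, matrix = blosum62_matrix(),
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("empty sequence")
  a <- encode_seq(seq1); b <- encode_seq(seq2)
  res <- nw_align_cpp(a, b, matrix, gap_open, gap_extend)
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(seq2, "")[[1]]
  list(score = res$score,
       aligned1 = paste(ifelse(res$a_pos == 0L, "-", c1[pmax(res$a_pos, 1L)]),
                        collapse = ""),
       aligned2 = paste(ifelse(res$b_pos == 0L, "-", c2[pmax(res$b_pos, 1L)]),
                        collapse = ""))
}
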