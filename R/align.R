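# Affine-gap local alignment shared by the IRES annotator and the
# cross-species conservation module. The dynamic programming is done by
# Biostrings::pairwiseAlignment (Smith-Waterman with affine gaps); this
# wrapper fixes the scoring conventions used throughout the package:
# a gap of length k costs |gap_open| + k * |gap_extend|, and N is scored
# as a mismatch against every base including itself, so ambiguous windows
# never support a hit.

align_submat <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", "N"] <- mismatch
  mat
}

#' Local (Smith-Waterman) alignment of two DNA sequences
#'
#' @param query,subject DNA strings (A/C/G/T/N).
#' @param match,mismatch match reward and mismatch penalty (e.g. +2/-3).
#' @param gap_open,gap_extend affine gap penalties (negative values); a gap
#'   of length k costs `|gap_open| + k * |gap_extend|`.
#' @return list with `score` (raw alignment score), `aln_len` (alignment
#'   columns, gaps included), `n_match` (identical columns), `identity`
#'   (`n_match / aln_len`), and the 1-based query/subject ranges
#'   `q_start`, `q_end`, `s_start`, `s_end`. A `score` of 0 with
#'   `aln_len` 0 means no positive-scoring local alignment exists.
#' @export
local_align <- function(query, subject, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2) {
  query <- normalize_dna(query, "query")
  subject <- normalize_dna(subject, "subject")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = align_submat(match, mismatch),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(list(score = 0, aln_len = 0L, n_match = 0L, identity = NA_real_,
                q_start = NA_integer_, q_end = NA_integer_,
                s_start = NA_integer_, s_end = NA_integer_))
  }
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pat)
  pv <- strsplit(pat, "", fixed = TRUE)[[1]]
  sv <- strsplit(sub, "", fixed = TRUE)[[1]]
  nm <- sum(pv == sv & pv != "-" & pv != "N")
  list(score = score, aln_len = cols, n_match = nm, identity = nm / cols,
       q_start = Biostrings::start(Biostrings::pattern(aln)),
       q_end = Biostrings::end(Biostrings::pattern(aln)),
       s_start = Biostrings::start(Biostrings::subject(aln)),
       s_end = Biostrings::end(Biostrings::subject(aln)))
}
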