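# Internal string/sequence helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement a DNA string
#'
#' Plain-character reverse complement over the A/C/G/T/N alphabet.
#' Vectorised over `x`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("ATGCN")
revcomp_dna <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Uppercase, U->T, and check the alphabet; `what` names the record in errors.
normalize_dna <- function(seq, what = "sequence") {
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N,U}", what),
         call. = FALSE)
  }
  seq
}

# 0-based half-open interval containment for scalar position vectors.
pos_in <- function(pos, start, end) pos >= start & pos < end

# Stable version string used in output headers / manifests.
circribo_version <- function() {
  as.character(utils::packageVersion("circribo"))
}
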