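# Domain types: CircRNA records and circular-coordinate arithmetic.
#
# Conventions (used everywhere in the package):
#   * all coordinates are 0-based, half-open;
#   * position 0 of a circRNA sequence is the back-splice acceptor, i.e. the
#     first transcribed base after the back-splice junction (BSJ); the BSJ
#     sits between sequence index L-1 and index 0;
#   * minus-strand circRNAs store `seq` already reverse-complemented into
#     transcript orientation, while `blocks` stay in genome orientation.

#' Construct a circRNA record
#'
#' A `circ_rna` holds the full-length circular sequence of a back-spliced
#' transcript in transcript orientation (5'->3' around the circle), together
#' with its genomic exon blocks when known.
#'
#' @param circ_id unique identifier.
#' @param seq full-length circular sequence (A/C/G/T/N; U is normalised to T,
#'   case is normalised to upper). Position 0 is the back-splice acceptor.
#' @param chrom chromosome name (may be `NA` when blocks are unknown).
#' @param strand `"+"` or `"-"`.
#' @param blocks integer matrix with columns `start`, `end` (0-based,
#'   half-open genomic intervals), rows sorted by genomic start and pairwise
#'   disjoint; `NULL` when no genomic annotation is available. Block widths
#'   must sum to `nchar(seq)`.
#' @param host_gene optional host (parental) gene symbol.
#' @param species optional species label.
#' @return an object of class `circ_rna`.
#' @export
#' @examples
#' c1 <- circ_rna("c1", "ATGGCATAA")
#' nchar(c1$seq)
circ_rna <- function(circ_id, seq, chrom = NA_character_, strand = "+",
                     blocks = NULL, host_gene = NA_character_,
                     species = NA_character_) {
  stopifnot(is.character(circ_id), length(circ_id) == 1L, nzchar(circ_id))
  seq <- normalize_dna(seq, what = sprintf("circRNA '%s'", circ_id))
  if (nchar(seq) < 1L) stop(sprintf("circRNA '%s' has empty sequence", circ_id))
  if (!strand %in% c("+", "-")) {
    stop(sprintf("circRNA '%s': strand must be '+' or '-'", circ_id))
  }
  if (!is.null(blocks)) {
    blocks <- as.matrix(blocks)
    if (ncol(blocks) != 2L) stop("blocks must have two columns (start, end)")
    storage.mode(blocks) <- "integer"
    colnames(blocks) <- c("start", "end")
    if (any(blocks[, "end"] <= blocks[, "start"])) {
      stop(sprintf("circRNA '%s': block end must exceed block start", circ_id))
    }
    blocks <- blocks[order(blocks[, "start"]), , drop = FALSE]
    if (nrow(blocks) > 1L &&
        any(blocks[-1L, "start"] < blocks[-nrow(blocks), "end"])) {
      stop(sprintf("circRNA '%s': blocks overlap", circ_id))
    }
    if (sum(blocks[, "end"] - blocks[, "start"]) != nchar(seq)) {
      stop(sprintf(
        "circRNA '%s': sum of block lengths (%d) != sequence length (%d)",
        circ_id, sum(blocks[, "end"] - blocks[, "start"]), nchar(seq)))
    }
    if (is.na(chrom) || !nzchar(chrom)) {
      stop(sprintf("circRNA '%s': blocks given but chrom is missing", circ_id))
    }
  }
  structure(
    list(circ_id = circ_id, chrom = chrom, strand = strand, blocks = blocks,
         seq = seq, host_gene = host_gene, species = species),
    class = "circ_rna")
}

#' @export
print.circ_rna <- function(x, ...) {
  cat(sprintf("<circ_rna %s> %d nt, strand %s, %s block(s)%s\n",
              x$circ_id, nchar(x$seq), x$strand,
              if (is.null(x$blocks)) "no" else nrow(x$blocks),
              if (is.na(x$host_gene)) "" else paste0(", gene ", x$host_gene)))
  invisible(x)
}

#' Extract a substring from a circular sequence with wrap-around
#'
#' Walks the circle starting at `start` (0-based) for `length` characters,
#' wrapping past the back-splice junction as many times as needed.
#'
#' @param circ a `circ_rna` object or a plain character sequence.
#' @param start 0-based start position, `0 <= start < L`.
#' @param length number of characters to return (positive; may exceed `L`).
#' @return character scalar of exactly `length` characters.
#' @export
#' @examples
#' circular_substring("ABCDEF", 4, 4)  # "EFAB"
circular_substring <- function(circ, start, length) {
  seq <- if (inherits(circ, "circ_rna")) circ$seq else circ
  L <- nchar(seq)
  if (length <= 0L) stop("length must be positive")
  if (start < 0L || start >= L) stop("start must satisfy 0 <= start < L")
  reps <- ceiling((start + length) / L)
  substr(strrep(seq, reps), start + 1L, start + length)
}

#' Map between circle and genome coordinates
#'
#' Returns the genomic position (0-based) of every circle position
#' `0..L-1`, honouring exon blocks and strand: for minus-strand circRNAs
#' circle position 0 corresponds to the highest genomic coordinate of the
#' span and positions run genomically backwards.
#'
#' @param circ a `circ_rna` with non-`NULL` blocks.
#' @return integer vector `m` of length `L` with `m[i + 1]` the genomic
#'   position of circle position `i`.
#' @export
circle_genome_map <- function(circ) {
  stopifnot(inherits(circ, "circ_rna"))
  if (is.null(circ$blocks)) {
    stop(sprintf("circRNA '%s' has no genomic blocks; coordinate mapping impossible",
                 circ$circ_id))
  }
  gpos <- unlist(lapply(seq_len(nrow(circ$blocks)), function(i) {
    seq.int(circ$blocks[i, "start"], circ$blocks[i, "end"] - 1L)
  }), use.names = FALSE)
  if (circ$strand == "-") gpos <- rev(gpos)
  as.integer(gpos)
}
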