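# Cross-species conserved ribo-circRNA inference: 2x50-nt BSJ flank
# sequences extracted from the reference genome, all-vs-all local alignment
# restricted to orthologous host genes, and a reciprocal-best-hit (RBH)
# decision with alignment-length and bit-score cutoffs.

#' Conservation analysis parameters
#'
#' Defaults: 50-nt genomic fragments on either side of the BSJ (100-nt
#' flank sequence), alignment length >= 80 columns, bit-score >= 150 bits;
#' +1/-2 match/mismatch scoring with affine gaps (5 + 2k), and the BLAST
#' normalisation constants lambda = 1.28, K = 0.46 calibrated for +1/-2.
#'
#' @param flank genomic fragment length on each side of the BSJ (nt).
#' @param min_aln_len minimum alignment length (columns).
#' @param min_bit_score minimum bit-score (bits).
#' @param match,mismatch,gap_open,gap_extend local-alignment scores.
#' @param lambda,K Karlin-Altschul constants for bit-score normalisation.
#' @return list of class `conservation_params`.
#' @export
conservation_params <- function(flank = 50L, min_aln_len = 80L,
                                min_bit_score = 150, match = 1,
                                mismatch = -2, gap_open = -5,
                                gap_extend = -2, lambda = 1.28, K = 0.46) {
  stopifnot(flank >= 1L, min_aln_len > 0L, min_bit_score > 0,
            lambda > 0, K > 0)
  structure(list(flank = as.integer(flank),
                 min_aln_len = as.integer(min_aln_len),
                 min_bit_score = min_bit_score, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "conservation_params")
}

#' Extract the genomic BSJ flank sequence of a circRNA
#'
#' Concatenates the last `flank` genomic bases of the circRNA span
#' (adjacent to the back-splice donor) with the first `flank` bases from
#' the acceptor, in transcript orientation (donor side first, so the BSJ
#' sits at index `flank`). For minus-strand circRNAs the donor lies at the
#' genomic span start and both fragments are reverse-complemented.
#'
#' @param circ a [circ_rna()] with blocks.
#' @param genome named character vector of chromosome sequences.
#' @param params a [conservation_params()].
#' @return data.frame with `circ_id`, `species`, `host_gene`, `seq`
#'   (length 2x`flank`).
#' @export
extract_bsj_flanks <- function(circ, genome, params = conservation_params()) {
  if (is.null(circ$blocks)) {
    stop(sprintf("circRNA '%s' has no blocks; flank extraction impossible",
                 circ$circ_id))
  }
  if (!circ$chrom %in% names(genome)) {
    stop(sprintf("circRNA '%s': chromosome '%s' absent from genome",
                 circ$circ_id, circ$chrom))
  }
  chrom_seq <- genome[[circ$chrom]]
  f <- params$flank
  span_start <- min(circ$blocks[, "start"])
  span_end <- max(circ$blocks[, "end"])
  if (span_start < 0L || span_end > nchar(chrom_seq) ||
      span_end - span_start < f) {
    stop(sprintf("circRNA '%s': %d-nt flank extends past available sequence",
                 circ$circ_id, f))
  }
  lo <- substr(chrom_seq, span_start + 1L, span_start + f)     # acceptor side (+)
  hi <- substr(chrom_seq, span_end - f + 1L, span_end)         # donor side (+)
  seq <- if (circ$strand == "+") {
    paste0(hi, lo)                       # donor -> acceptor
  } else {
    # minus strand: donor at genomic span start, acceptor at span end
    paste0(revcomp_dna(lo), revcomp_dna(hi))
  }
  data.frame(circ_id = circ$circ_id, species = circ$species,
             host_gene = circ$host_gene, seq = normalize_dna(seq))
}

#' BLAST-style bit-score normalisation
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score raw local-alignment score.
#' @param params a [conservation_params()] supplying `lambda` and `K`.
#' @return bit-score in bits (vectorised over `raw_score`).
#' @export
bit_score <- function(raw_score, params = conservation_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

# Best hit among candidate alignments: highest raw score, ties broken by
# longer alignment, then lexicographically smaller opposing id.
best_hit_idx <- function(score, aln_len, other_id) {
  ord <- order(-score, -aln_len, other_id)
  ord[1L]
}

#' Find conserved circRNA pairs between two species by reciprocal best hit
#'
#' All-vs-all local alignment of BSJ flank sequences restricted to pairs
#' whose host genes are orthologous; a pair is reported when each sequence
#' is the other's best hit (by raw score; ties broken by alignment length
#' then identifier) and the alignment reaches both the length and
#' bit-score cutoffs.
#'
#' @param flanks_a,flanks_b data.frames from [extract_bsj_flanks()]
#'   (columns `circ_id`, `species`, `host_gene`, `seq`), one per species.
#' @param orthologs an [ortholog_table()].
#' @param params a [conservation_params()].
#' @return data.frame with `circ_a`, `circ_b`, `species_a`, `species_b`,
#'   `aln_len`, `raw_score`, `bit_score`, `is_reciprocal_best`.
#' @export
find_conserved_pairs <- function(flanks_a, flanks_b, orthologs,
                                 params = conservation_params()) {
  empty <- data.frame(circ_a = character(), circ_b = character(),
                      species_a = character(), species_b = character(),
                      aln_len = integer(), raw_score = numeric(),
                      bit_score = numeric(), is_reciprocal_best = logical())
  if (nrow(flanks_a) == 0L || nrow(flanks_b) == 0L) return(empty)
  na <- nrow(flanks_a); nb <- nrow(flanks_b)
  allowed <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j) {
    is_orthologous(orthologs, flanks_a$host_gene[i], flanks_b$host_gene[j])
  }))
  score <- matrix(-Inf, na, nb)
  alen <- matrix(0L, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (!allowed[i, j]) next
      a <- local_align(flanks_a$seq[i], flanks_b$seq[j], params$match,
                       params$mismatch, params$gap_open, params$gap_extend)
      score[i, j] <- a$score
      alen[i, j] <- a$aln_len
    }
  }
  out <- list()
  for (i in seq_len(na)) {
    cand <- which(allowed[i, ] & score[i, ] > -Inf)
    if (length(cand) == 0L) next
    j <- cand[best_hit_idx(score[i, cand], alen[i, cand],
                           flanks_b$circ_id[cand])]
    # reciprocal: is i the best hit of j among j's candidates?
    cand_b <- which(allowed[, j] & score[, j] > -Inf)
    i_best <- cand_b[best_hit_idx(score[cand_b, j], alen[cand_b, j],
                                  flanks_a$circ_id[cand_b])]
    if (i_best != i) next
    bits <- bit_score(score[i, j], params)
    if (alen[i, j] < params$min_aln_len || bits < params$min_bit_score) next
    out[[length(out) + 1L]] <- data.frame(
      circ_a = flanks_a$circ_id[i], circ_b = flanks_b$circ_id[j],
      species_a = flanks_a$species[i], species_b = flanks_b$species[j],
      aln_len = alen[i, j], raw_score = score[i, j], bit_score = bits,
      is_reciprocal_best = TRUE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$circ_a, res$circ_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}
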